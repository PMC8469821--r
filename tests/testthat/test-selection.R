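converged_stub <- function(params, gamma, kind = "dpd", family = "normal")
  structure(list(params = params, gamma = gamma, kind = kind,
                 family = family, converged = TRUE), class = "div_fit")

test_that("H-score matches the hand-evaluated single-observation value", {
  sp <- div_spec("dpd", 0.2, normal_family())
  fit <- converged_stub(c(mu = 0, sigma2 = 1), 0.2)
  # 2 (gamma y^2 - s2)/s2^2 phi^gamma + y^2/s2^2 phi^(2 gamma) at y = 0
  expect_equal(h_score(sp, 0, fit), -2 * dnorm(0)^0.2, tolerance = 1e-12)
  expect_equal(h_score(sp, 0, fit), -1.6642249, tolerance = 1e-6)
})

test_that("H-score at gamma = 0 is the Gaussian score-matching statistic", {
  set.seed(21)
  y <- rnorm(40, 1, 2)
  fit <- div_fit(div_spec("dpd", 0, normal_family()), y)
  m <- fit$params[["mu"]]; s2 <- fit$params[["sigma2"]]
  expect_equal(h_score(div_spec("dpd", 0, normal_family()), y, fit),
               mean(-2 / s2 + (y - m)^2 / s2^2), tolerance = 1e-10)
})

test_that("closed forms equal the generic assembly on randomized instances", {
  set.seed(22)
  for (k in 1:25) {
    g <- round(runif(1, 0, 0.6), 2)
    if (k %% 3 == 0) {
      fam <- gamma_family()
      y <- rgamma(30, 2, rate = 4)
      th <- c(alpha = runif(1, 1.2, 3), beta = runif(1, 2, 6))
      kinds <- "dpd"
    } else if (k %% 3 == 1) {
      fam <- normal_family()
      y <- rnorm(30, 1, 1.5)
      th <- c(mu = rnorm(1), sigma2 = runif(1, 0.5, 3))
      kinds <- c("dpd", "gamma_div")
    } else {
      fam <- regression_family(2)
      X <- matrix(rnorm(60), 30, 2)
      y <- drop(1 + X %*% c(1, -0.5) + rnorm(30, 0, 0.8))
      th <- c(beta0 = 1, beta1 = 1, beta2 = -0.5, sigma2 = 0.8)
      kinds <- c("dpd", "gamma_div")
    }
    for (kind in kinds) {
      sp <- div_spec(kind, g, fam)
      fit <- converged_stub(th, g, kind, fam$id)
      d <- if (fam$id == "normal_regression") div_data(y, X) else y
      expect_equal(h_score(sp, d, fit, method = "closed"),
                   h_score(sp, d, fit, method = "generic"),
                   tolerance = 1e-10)
    }
  }
})

test_that("H-score is invariant to permutation of observations", {
  set.seed(23)
  y <- rgamma(50, 2, rate = 4)
  sp <- div_spec("dpd", 0.3, gamma_family())
  fit <- div_fit(sp, y)
  expect_equal(h_score(sp, y, fit), h_score(sp, sample(y), fit),
               tolerance = 1e-12)
})

test_that("selection returns the grid argmin with per-point consistency", {
  set.seed(24)
  y <- c(rnorm(90, 2, 1), rnorm(10, 9, 1))
  grid <- seq(0, 0.5, by = 0.05)
  sel <- select_gamma("dpd", normal_family(), y, grid)
  expect_length(sel$h_scores, length(grid))
  # recompute independently point by point
  hs <- vapply(grid, function(g) {
    sp <- div_spec("dpd", g, normal_family())
    h_score(sp, y, div_fit(sp, y))
  }, 0)
  expect_equal(sel$h_scores, hs, tolerance = 1e-6)
  expect_equal(sel$gamma_opt, grid[which.min(hs)])
  expect_equal(sel$fit_opt$gamma, sel$gamma_opt)
  # singleton grid
  expect_equal(select_gamma("dpd", normal_family(), y, 0.3)$gamma_opt, 0.3)
})

test_that("classical speed-of-light data selects gamma = 0.09", {
  sel <- select_gamma("dpd", normal_family(), MASS::newcomb,
                      seq(0, 0.70, by = 0.01))
  expect_equal(sel$gamma_opt, 0.09)
})

test_that("exact marginal-likelihood score approaches the criterion as n
           grows", {
  set.seed(1)
  y40 <- rnorm(40, 2, 1)
  gaps <- vapply(c(10, 20, 40), function(n) {
    y <- y40[1:n]
    sp <- div_spec("dpd", 0.2, normal_family())
    fit <- div_fit(sp, y)
    abs(h_score(sp, y, fit) -
          exact_h_score_oracle("dpd", normal_family(), y, 0.2))
  }, 0)
  expect_true(all(diff(gaps) < 0))
})

test_that("exact-score oracle handles the gamma family and guards its scope", {
  set.seed(1)
  y <- rgamma(30, 2, rate = 4)
  sp <- div_spec("dpd", 0.1, gamma_family())
  fit <- div_fit(sp, y)
  hn <- h_score(sp, y, fit)
  hstar <- exact_h_score_oracle("dpd", gamma_family(), y, 0.1)
  expect_lt(abs(hn - hstar) / abs(hstar), 0.35)
  expect_identical(sign(hn), sign(hstar))
  expect_error(exact_h_score_oracle("dpd", normal_family(), rnorm(60), 0.2),
               "n <= 50")
  expect_error(exact_h_score_oracle("dpd", regression_family(1),
                                    rnorm(10), 0.2), "two-parameter")
})
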