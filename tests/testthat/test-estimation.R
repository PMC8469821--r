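test_that("gamma = 0 fits are the closed-form Gaussian MLE", {
  fit <- div_fit(div_spec("dpd", 0, normal_family()), c(1, 2, 3))
  expect_true(fit$converged)
  expect_equal(unname(fit$params), c(2, 2 / 3), tolerance = 1e-8)
})

test_that("DPD fit matches a dense brute-force grid search", {
  set.seed(100)
  y <- rnorm(20, 1, 1.2)
  sp <- div_spec("dpd", 0.3, normal_family())
  fit <- div_fit(sp, y)
  oracle <- grid_search_normal(sp, y)
  expect_equal(unname(fit$params), unname(oracle), tolerance = 2e-3)
})

test_that("estimates are consistent on large clean samples", {
  set.seed(200)
  y <- rgamma(1e5, 2, rate = 4)
  fit <- div_fit(div_spec("dpd", 0, gamma_family()), y)
  # 3 Monte-Carlo standard errors of the MLE at n = 1e5
  se_a <- sqrt(2 / (2 * trigamma(2) - 1) / 1e5)
  expect_lt(abs(fit$params[["alpha"]] - 2), 3 * se_a)
  expect_lt(abs(fit$params[["beta"]] - 4) / 4, 3 * 1.3 * se_a / 2)
})

test_that("warm-started path equals cold starts on clean data", {
  set.seed(3)
  y <- rnorm(100, 2, 1)
  path <- div_fit_path("dpd", normal_family(), y, c(0, 0.1, 0.25))
  for (k in 2:3) {
    cold <- div_fit(div_spec("dpd", attr(path, "gamma_grid")[k],
                             normal_family()), y)
    expect_equal(path[[k]]$params, cold$params, tolerance = 1e-6)
  }
  single <- div_fit_path("dpd", normal_family(), y, 0)
  expect_equal(single[[1]]$params,
               c(mu = mean(y), sigma2 = mean((y - mean(y))^2)),
               tolerance = 1e-8)
})

test_that("inadmissible grid points are flagged, not fatal", {
  # alpha-hat near 0.45 makes alpha(1+g) - g <= 0 at g ~ 0.85
  set.seed(4)
  y <- rgamma(60, 0.45, rate = 1)
  path <- div_fit_path("dpd", gamma_family(), y, c(0, 0.5, 0.9))
  expect_false(is.null(path[[1]]))
  skipped <- attr(path, "skipped")
  expect_true(is.null(path[[3]]) || !path[[3]]$converged ||
                nzchar(skipped[3]) ||
                gamma_admissible(gamma_family(), path[[3]]$params, 0.9))
})

test_that("robustness to a gross outlier grows with gamma", {
  set.seed(5)
  y <- c(rnorm(40, 2, 1), 30)
  dev <- vapply(c(0, 0.1, 0.3, 0.5), function(g) {
    abs(div_fit(div_spec("dpd", g, normal_family()), y)$params[["mu"]] -
          median(y))
  }, 0)
  # the outlier's pull collapses once gamma > 0 and never returns; allow
  # sub-1% jitter of the robust fits around the median
  expect_true(all(diff(dev) <= 0.01))
  expect_lt(dev[4], 0.3)
  expect_gt(dev[1], 0.5)
})

test_that("transformed and original gamma-divergence share the maximizer", {
  set.seed(6)
  for (k in 1:20) {
    fam <- if (k %% 2) normal_family() else gamma_family()
    y <- if (fam$id == "normal") rnorm(50, 1, 1.5) else rgamma(50, 2, rate = 3)
    if (k %% 4 == 1) y[1:3] <- y[1:3] + 6   # some contaminated sets
    g <- sample(c(0.1, 0.25, 0.4), 1)
    fit <- div_fit(div_spec("gamma_div", g, fam), y)
    orig <- fit_gamma_div_original(fam, y, g)
    expect_equal(unname(fit$params), unname(orig), tolerance = 1e-5)
  }
})

test_that("RMSE halves (within MC error) when n quadruples on clean data", {
  rmse_at <- function(n, R = 120) {
    errs <- vapply(seq_len(R), function(r) {
      set.seed(7000 + 17 * r + n)
      y <- rnorm(n, 2, 1)
      div_fit(div_spec("dpd", 0.3, normal_family()), y)$params[["mu"]] - 2
    }, 0)
    sqrt(mean(errs^2))
  }
  ratio <- rmse_at(400) / rmse_at(100)
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.68)
})

test_that("sandwich covariance is symmetric and reduces to the MLE variance", {
  set.seed(8)
  y <- rnorm(500, 2, 1)
  sp <- div_spec("dpd", 0, normal_family())
  fit <- div_fit(sp, y)
  V <- sandwich_covariance(sp, y, fit)
  expect_identical(V, t(V))
  expect_equal(V["mu", "mu"], fit$params[["sigma2"]] / 500,
               tolerance = 0.05)
  expect_error(sandwich_covariance(
    sp, y, structure(list(converged = FALSE), class = "div_fit")),
    "converged")
})

test_that("Wald intervals at gamma = 0.3 attain nominal coverage", {
  R <- 1000
  hits <- logical(R)
  sp <- div_spec("dpd", 0.3, normal_family())
  for (r in seq_len(R)) {
    set.seed(40000 + r)
    y <- rnorm(100, 2, 1)
    fit <- div_fit(sp, y)
    ci <- wald_interval(sp, y, fit)
    hits[r] <- ci["mu", "lower"] <= 2 && 2 <= ci["mu", "upper"]
  }
  cover <- 100 * mean(hits)
  expect_gte(cover, 92.5)
  expect_lte(cover, 97)
})

test_that("datasets are validated", {
  expect_error(div_data(c(1, NA, 3)), "missing")
  expect_error(div_data(numeric(0)), "empty")
  expect_error(div_data(1:5, matrix(1, 3, 2)), "rows")
  expect_error(div_fit(div_spec("dpd", 0, normal_family()), c(1, 2)),
               "at least")
})
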