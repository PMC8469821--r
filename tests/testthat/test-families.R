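test_that("densities match closed-form hand evaluations", {
  nf <- normal_family()
  expect_equal(family_density(nf, 0, c(mu = 0, sigma2 = 1)),
               1 / sqrt(2 * pi), tolerance = 1e-12)
  gf <- gamma_family()
  expect_equal(family_density(gf, 1, c(alpha = 1, beta = 1)), exp(-1),
               tolerance = 1e-12)
  # direct evaluation of b^a y^(a-1) exp(-b y) / Gamma(a)
  expect_equal(family_density(gf, 0.5, c(alpha = 2, beta = 4)),
               4^2 * 0.5 * exp(-2) / gamma(2), tolerance = 1e-12)
  rf <- regression_family(2)
  th <- c(beta0 = 1, beta1 = 2, beta2 = -1, sigma2 = 0.5)
  X <- rbind(c(0.5, 1))
  expect_equal(family_density(rf, 3, th, X),
               dnorm(3, 1 + 2 * 0.5 - 1, sqrt(0.5)), tolerance = 1e-12)
})

test_that("parameter and support domains are enforced", {
  gf <- gamma_family()
  expect_error(family_density(gf, 1, c(alpha = -1, beta = 1)), "positive")
  expect_error(family_density(gf, -0.5, c(alpha = 2, beta = 4)),
               "observations > 0")
  expect_error(family_density(normal_family(), 0, c(mu = 0, sigma2 = 0)),
               "positive")
})

test_that("analytic observation derivatives match finite differences", {
  for (inst in random_instances(20)) {
    fam <- inst$family; th <- inst$theta; y <- inst$y
    f <- function(yy) family_density(fam, yy, th)
    expect_equal(family_density_dy(fam, y, th), fd_dy(f, y),
                 tolerance = 1e-6)
    expect_equal(family_density_d2y(fam, y, th), fd_d2y(f, y),
                 tolerance = 1e-5)
  }
  # symmetry at the normal mode
  expect_equal(family_density_dy(normal_family(), 1.3,
                                 c(mu = 1.3, sigma2 = 2)), 0)
  # exponential special case of the gamma recursion
  expect_equal(family_density_dy(gamma_family(), 1, c(alpha = 1, beta = 1)),
               -exp(-1), tolerance = 1e-12)
})

test_that("power integral matches closed forms and quadrature", {
  nf <- normal_family(); gf <- gamma_family()
  expect_equal(power_integral(nf, c(mu = 3, sigma2 = 1), 1),
               (2 * pi)^(-1 / 2) * 2^(-1 / 2), tolerance = 1e-12)
  # gamma = 0: integral of a density
  for (fam in list(nf, gf)) {
    th <- if (fam$id == "normal") c(mu = 1, sigma2 = 2)
          else c(alpha = 2, beta = 4)
    expect_identical(power_integral(fam, th, 0), 1)
  }
  # quadrature oracle on randomized instances
  set.seed(9)
  for (k in 1:8) {
    g <- runif(1, 0.05, 0.8)
    th <- c(mu = rnorm(1), sigma2 = runif(1, 0.3, 3))
    q <- integrate(function(t) dnorm(t, th[1], sqrt(th[2]))^(1 + g),
                   -Inf, Inf, rel.tol = 1e-12)$value
    expect_equal(power_integral(nf, th, g), q, tolerance = 1e-8)
    thg <- c(alpha = runif(1, 0.8, 4), beta = runif(1, 0.5, 6))
    qg <- integrate(function(t) dgamma(t, thg[1], rate = thg[2])^(1 + g),
                    0, Inf, rel.tol = 1e-12)$value
    expect_equal(power_integral(gf, thg, g), qg, tolerance = 1e-8)
  }
  # explicit spec'd case
  q <- integrate(function(t) dgamma(t, 2, rate = 4)^1.3, 0, Inf,
                 rel.tol = 1e-12)$value
  expect_equal(power_integral(gf, c(alpha = 2, beta = 4), 0.3), q,
               tolerance = 1e-8)
})

test_that("power integral is continuous in gamma near zero", {
  gf <- gamma_family()
  th <- c(alpha = 2, beta = 4)
  gs <- c(1e-6, 1e-4, 1e-2)
  vals <- vapply(gs, function(g) power_integral(gf, th, g), 0)
  expect_true(all(abs(vals - 1) < c(1e-4, 1e-2, 0.5)))
  expect_true(all(diff(abs(vals - 1)) > 0))
})

test_that("inadmissible gamma-family power is rejected, not clipped", {
  gf <- gamma_family()
  # alpha(1+g) - g <= 0  <=>  g >= alpha/(1-alpha) for alpha < 1
  expect_error(power_integral(gf, c(alpha = 0.3, beta = 1), 0.5),
               "does not exist")
  expect_true(gamma_admissible(gf, c(alpha = 2, beta = 4), 0.5))
  expect_false(gamma_admissible(gf, c(alpha = 0.3, beta = 1), 0.5))
})
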