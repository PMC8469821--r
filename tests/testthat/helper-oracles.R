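# Shared oracles: finite differences, quadrature, brute-force grid search,
# and the original (non-additive) gamma-divergence maximizer.

fd_dy <- function(f, y, h = 1e-5) (f(y + h) - f(y - h)) / (2 * h)
fd_d2y <- function(f, y, h = 1e-5) (f(y + h) - 2 * f(y) + f(y - h)) / h^2

# random (family, y, theta) instances for derivative / power-integral checks
random_instances <- function(m, seed = 1203) {
  set.seed(seed)
  lapply(seq_len(m), function(i) {
    if (i %% 2 == 0) {
      fam <- normal_family()
      th <- c(mu = rnorm(1, 0, 2), sigma2 = runif(1, 0.3, 4))
      y <- rnorm(1, th[["mu"]], 2 * sqrt(th[["sigma2"]]))
    } else {
      fam <- gamma_family()
      th <- c(alpha = runif(1, 0.8, 4), beta = runif(1, 0.5, 6))
      y <- rgamma(1, th[["alpha"]], rate = th[["beta"]]) + 0.05
    }
    list(family = fam, theta = th, y = y,
         gamma = sample(c(0, round(runif(1, 0.02, 0.6), 3)), 1,
                        prob = c(0.2, 0.8)))
  })
}

# two-stage dense grid search over (mu, sigma2), the estimation oracle
grid_search_normal <- function(spec, y, step_fine = 1e-3) {
  obj <- function(mu, s2)
    sum(div_objective(spec, y, c(mu = mu, sigma2 = s2)))
  stage <- function(mu_rng, s2_rng, step) {
    mus <- seq(mu_rng[1], mu_rng[2], by = step)
    s2s <- seq(max(s2_rng[1], step), s2_rng[2], by = step)
    vals <- outer(mus, s2s, Vectorize(obj))
    idx <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    c(mu = mus[idx[1]], sigma2 = s2s[idx[2]])
  }
  co <- stage(mean(y) + c(-2, 2), c(0.05, 3 * stats::var(y)), 0.02)
  stage(co[1] + c(-0.05, 0.05), co[2] + c(-0.05, 0.05), step_fine)
}

# maximizer of the ORIGINAL non-additive gamma-divergence form
fit_gamma_div_original <- function(family, y, gamma) {
  negobj <- function(phi) {
    th <- divtune:::from_internal(family, phi)
    if (any(!is.finite(th)) ||
        !gamma_admissible(family, th, gamma)) return(1e10)
    lf <- family_logdensity(family, y, th)
    m <- max(gamma * lf)
    lsum <- m + log(sum(exp(gamma * lf - m)))
    v <- -(lsum / gamma -
             power_integral(family, th, gamma, log = TRUE) / (1 + gamma))
    if (!is.finite(v)) 1e10 else v
  }
  phi0 <- divtune:::to_internal(family, divtune:::moment_init(family, y))
  opt <- stats::optim(phi0, negobj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  divtune:::from_internal(family, opt$par)
}

fixture_path <- function(name)
  system.file("extdata", name, package = "divtune", mustWork = TRUE)
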