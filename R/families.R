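#' Parametric model families
#'
#' A `div_family` bundles everything the divergence layer needs from a
#' parametric model: the density \eqn{f(y;\theta)}, its first and second
#' derivatives in the observation \eqn{y}, the power integral
#' \eqn{\int f(t;\theta)^{1+\gamma} dt} in closed form, and moment-based
#' starting values for optimization.
#'
#' Three families are provided:
#' \describe{
#'   \item{`normal_family()`}{\eqn{N(\mu, \sigma^2)}; parameters `mu`,
#'     `sigma2`.}
#'   \item{`gamma_family()`}{\eqn{Ga(\alpha, \beta)} with shape `alpha` and
#'     rate `beta` (mean \eqn{\alpha/\beta}); support \eqn{(0, \infty)}.}
#'   \item{`regression_family(p)`}{normal linear regression
#'     \eqn{y_i \sim N(x_i^\top\beta, \sigma^2)} with `p` covariates plus an
#'     intercept; parameters `beta0`, `beta1`, ..., `sigma2`. The covariate
#'     rows travel with the dataset (see [div_data()]), not the family.}
#' }
#'
#' Positivity-constrained parameters (`sigma2`, `alpha`, `beta`) are kept on
#' their natural scale in the public interface; optimizers work on an
#' internal log scale (see [div_fit()]).
#'
#' @param p number of covariates (excluding the intercept) for the
#'   regression family.
#' @return An object of class `div_family`.
#' @examples
#' fam <- normal_family()
#' family_density(fam, 0, c(mu = 0, sigma2 = 1))  # 1/sqrt(2*pi)
#' @export
normal_family <- function() {
  structure(
    list(id = "normal", d = 2L, param_names = c("mu", "sigma2"),
         positive = c(mu = FALSE, sigma2 = TRUE),
         support = "real line", has_covariates = FALSE),
    class = "div_family")
}

#' @rdname normal_family
#' @export
gamma_family <- function() {
  structure(
    list(id = "gamma", d = 2L, param_names = c("alpha", "beta"),
         positive = c(alpha = TRUE, beta = TRUE),
         support = "positive reals", has_covariates = FALSE),
    class = "div_family")
}

#' @rdname normal_family
#' @export
regression_family <- function(p) {
  p <- as.integer(p)
  stopifnot(p >= 1L)
  nm <- c(paste0("beta", 0:p), "sigma2")
  pos <- c(rep(FALSE, p + 1L), TRUE)
  names(pos) <- nm
  structure(
    list(id = "normal_regression", d = p + 2L, param_names = nm,
         positive = pos, support = "real line", has_covariates = TRUE,
         p = p),
    class = "div_family")
}

#' @export
print.div_family <- function(x, ...) {
  cat("Model family:", x$id, "\n")
  cat("  parameters (d =", x$d, "):", paste(x$param_names, collapse = ", "), "\n")
  cat("  support:", x$support, "\n")
  invisible(x)
}

check_params <- function(family, params) {
  if (length(params) != family$d)
    stop("parameter vector has length ", length(params),
         " but family '", family$id, "' has dimension ", family$d)
  if (is.null(names(params))) names(params) <- family$param_names
  if (any(!is.finite(params)))
    stop("non-finite parameter value in (",
         paste(names(params), collapse = ", "), ")")
  bad <- family$positive & params <= 0
  if (any(bad))
    stop("parameter(s) ", paste(names(params)[bad], collapse = ", "),
         " must be strictly positive")
  params
}

check_support <- function(family, y) {
  if (any(!is.finite(y))) stop("non-finite observation")
  if (family$id == "gamma" && any(y <= 0))
    stop("gamma family requires observations > 0; found y = ",
         signif(min(y), 4))
  invisible(y)
}

## Location vector: mu for normal, x_i' beta for regression. X excludes the
## intercept column.
location_of <- function(family, params, X = NULL) {
  switch(family$id,
    normal = rep_len(params[["mu"]], if (is.null(X)) 1L else nrow(X)),
    normal_regression = {
      if (is.null(X)) stop("regression family needs a covariate matrix")
      beta <- params[seq_len(family$p + 1L)]
      drop(beta[1L] + X %*% beta[-1L])
    },
    stop("family has no location parameter"))
}

#' Family density and its observation derivatives
#'
#' `family_density()` evaluates \eqn{f(y;\theta)}; `family_density_dy()` and
#' `family_density_d2y()` evaluate the exact analytic derivatives
#' \eqn{\partial f/\partial y} and \eqn{\partial^2 f/\partial y^2}. All three
#' are vectorized over `y` (and over rows of `X` for the regression family).
#'
#' For the gamma family the derivatives use the recursion
#' \deqn{f'(y) = ((\alpha-1)/y - \beta) f(y), \quad
#'       f''(y) = ((\alpha-1)/y - \beta) f'(y) - ((\alpha-1)/y^2) f(y).}
#'
#' @param family a [div_family][normal_family] object.
#' @param y numeric vector of observations (in the family's support).
#' @param params named parameter vector on the natural scale.
#' @param X covariate matrix (regression family only), one row per
#'   observation, without an intercept column.
#' @return numeric vector, one value per observation.
#' @export
family_density <- function(family, y, params, X = NULL) {
  exp(family_logdensity(family, y, params, X))
}

#' @rdname family_density
#' @export
family_logdensity <- function(family, y, params, X = NULL) {
  params <- check_params(family, params)
  check_support(family, y)
  switch(family$id,
    normal = stats::dnorm(y, params[["mu"]], sqrt(params[["sigma2"]]),
                          log = TRUE),
    gamma = stats::dgamma(y, shape = params[["alpha"]], rate = params[["beta"]],
                          log = TRUE),
    normal_regression = {
      mu <- location_of(family, params, X)
      stats::dnorm(y, mu, sqrt(params[["sigma2"]]), log = TRUE)
    })
}

#' @rdname family_density
#' @export
family_density_dy <- function(family, y, params, X = NULL) {
  f <- family_density(family, y, params, X)
  switch(family$id,
    normal = -(y - params[["mu"]]) / params[["sigma2"]] * f,
    gamma = ((params[["alpha"]] - 1) / y - params[["beta"]]) * f,
    normal_regression = {
      mu <- location_of(family, params, X)
      -(y - mu) / params[["sigma2"]] * f
    })
}

#' @rdname family_density
#' @export
family_density_d2y <- function(family, y, params, X = NULL) {
  f <- family_density(family, y, params, X)
  switch(family$id,
    normal = {
      z <- y - params[["mu"]]; s2 <- params[["sigma2"]]
      (z^2 / s2^2 - 1 / s2) * f
    },
    gamma = {
      a <- params[["alpha"]]; b <- params[["beta"]]
      g <- (a - 1) / y - b
      g * (g * f) - (a - 1) / y^2 * f
    },
    normal_regression = {
      mu <- location_of(family, params, X)
      z <- y - mu; s2 <- params[["sigma2"]]
      (z^2 / s2^2 - 1 / s2) * f
    })
}

#' Power integral of a family density
#'
#' Evaluates \eqn{\int f(t;\theta)^{1+\gamma}\,dt} in closed form:
#' \eqn{(2\pi\sigma^2)^{-\gamma/2}(1+\gamma)^{-1/2}} for the normal (and,
#' per observation, the regression) family, and
#' \eqn{\Gamma(\alpha(1+\gamma)-\gamma)\,\Gamma(\alpha)^{-(1+\gamma)}
#' \beta^{\gamma}(1+\gamma)^{-\alpha(1+\gamma)+\gamma}} for the gamma
#' family, which requires \eqn{\alpha(1+\gamma)-\gamma > 0} for the integral
#' to exist. At \eqn{\gamma = 0} the value is 1 for every family.
#'
#' @inheritParams family_density
#' @param gamma non-negative power parameter.
#' @param log logical; return the logarithm of the integral?
#' @return a positive scalar (or its log).
#' @export
power_integral <- function(family, params, gamma, log = FALSE) {
  params <- check_params(family, params)
  stopifnot(length(gamma) == 1L, is.finite(gamma), gamma >= 0)
  if (!gamma_admissible(family, params, gamma)) {
    a <- params[["alpha"]]
    stop("power integral does not exist: alpha*(1+gamma)-gamma = ",
         signif(a * (1 + gamma) - gamma, 4), " <= 0 at (alpha = ",
         signif(a, 4), ", gamma = ", signif(gamma, 4), ")")
  }
  lv <- switch(family$id,
    normal = ,
    normal_regression = {
      s2 <- params[["sigma2"]]
      -gamma / 2 * log(2 * pi * s2) - 0.5 * log1p(gamma)
    },
    gamma = {
      a <- params[["alpha"]]; b <- params[["beta"]]
      astar <- a * (1 + gamma) - gamma
      lgamma(astar) - (1 + gamma) * lgamma(a) + gamma * log(b) -
        astar * log1p(gamma)
    })
  if (log) lv else exp(lv)
}

#' @rdname power_integral
#' @export
gamma_admissible <- function(family, params, gamma) {
  if (family$id != "gamma") return(TRUE)
  params[["alpha"]] * (1 + gamma) - gamma > 0
}

## Gradient of log f(y_i; theta) in theta: n x d matrix.
logdensity_grad <- function(family, y, params, X = NULL) {
  switch(family$id,
    normal = {
      z <- y - params[["mu"]]; s2 <- params[["sigma2"]]
      cbind(mu = z / s2, sigma2 = (z^2 / s2 - 1) / (2 * s2))
    },
    gamma = {
      a <- params[["alpha"]]; b <- params[["beta"]]
      cbind(alpha = log(b) - digamma(a) + log(y), beta = a / b - y)
    },
    normal_regression = {
      mu <- location_of(family, params, X)
      z <- y - mu; s2 <- params[["sigma2"]]
      g <- cbind(1, X) * (z / s2)
      out <- cbind(g, (z^2 / s2 - 1) / (2 * s2))
      colnames(out) <- family$param_names
      out
    })
}

## Gradient of log of the power integral in theta: length-d vector.
log_power_integral_grad <- function(family, params, gamma) {
  switch(family$id,
    normal = c(mu = 0, sigma2 = -gamma / (2 * params[["sigma2"]])),
    gamma = {
      a <- params[["alpha"]]; b <- params[["beta"]]
      astar <- a * (1 + gamma) - gamma
      c(alpha = (1 + gamma) * (digamma(astar) - digamma(a) - log1p(gamma)),
        beta = gamma / b)
    },
    normal_regression = {
      out <- numeric(family$d)
      names(out) <- family$param_names
      out[family$d] <- -gamma / (2 * params[["sigma2"]])
      out
    })
}

## Moment-based starting values; trim > 0 uses the central (1 - trim)
## fraction of the data, the robust second start for contaminated samples.
moment_init <- function(family, y, X = NULL, trim = 0) {
  if (trim > 0) {
    qs <- stats::quantile(y, c(trim / 2, 1 - trim / 2), names = FALSE)
    keep <- y >= qs[1] & y <= qs[2]
    if (sum(keep) >= max(family$d + 1L, 3L)) {
      y <- y[keep]
      if (!is.null(X)) X <- X[keep, , drop = FALSE]
    }
  }
  switch(family$id,
    normal = c(mu = mean(y), sigma2 = max(stats::var(y), 1e-8)),
    gamma = {
      m <- mean(y); v <- max(stats::var(y), 1e-8)
      c(alpha = m^2 / v, beta = m / v)
    },
    normal_regression = {
      fit <- stats::lm.fit(cbind(1, X), y)
      s2 <- max(mean(fit$residuals^2), 1e-8)
      out <- c(fit$coefficients, s2)
      names(out) <- family$param_names
      out
    })
}

## Natural <-> internal (log for positive components) parameter scale.
to_internal <- function(family, params) {
  phi <- params
  phi[family$positive] <- log(params[family$positive])
  phi
}

from_internal <- function(family, phi) {
  params <- phi
  params[family$positive] <- exp(phi[family$positive])
  names(params) <- family$param_names
  params
}
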