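#' Divergence specification
#'
#' Binds a robust divergence kind — density power divergence (`"dpd"`) or
#' the transformed additive gamma-divergence (`"gamma_div"`) — to a model
#' family at a fixed tuning parameter \eqn{\gamma \ge 0}.
#'
#' The per-observation objectives (to be maximized over \eqn{\theta}) are
#' \deqn{D_\gamma(y_i;\theta) = \frac{1}{\gamma} f(y_i;\theta)^\gamma -
#'   \frac{1}{1+\gamma}\int f(t;\theta)^{1+\gamma} dt \quad \mathrm{(dpd)}}
#' \deqn{D_\gamma(y_i;\theta) = \frac{1}{\gamma}
#'   \frac{f(y_i;\theta)^\gamma}{C_\gamma(\theta)} \quad
#'   \mathrm{(gamma\_div)}, \qquad
#'   C_\gamma(\theta) = \Big(\int f^{1+\gamma}\Big)^{\gamma/(1+\gamma)}.}
#' \eqn{\gamma = 0} is a first-class value meaning maximum likelihood: the
#' objective is defined as \eqn{\log f(y_i;\theta)}, the \eqn{\gamma \to 0}
#' limit of the DPD up to the additive constant \eqn{1 - 1/\gamma}.
#'
#' @param kind `"dpd"` or `"gamma_div"`.
#' @param gamma tuning parameter, a single value \eqn{\ge 0}. Larger values
#'   are more outlier-resistant but less efficient.
#' @param family a [div_family][normal_family] object.
#' @return An object of class `div_spec`.
#' @examples
#' sp <- div_spec("dpd", 0.3, normal_family())
#' div_objective(sp, 0, c(mu = 0, sigma2 = 1))
#' @export
div_spec <- function(kind = c("dpd", "gamma_div"), gamma, family) {
  kind <- match.arg(kind)
  stopifnot(inherits(family, "div_family"),
            length(gamma) == 1L, is.finite(gamma), gamma >= 0)
  structure(list(kind = kind, gamma = gamma, family = family),
            class = "div_spec")
}

#' @export
print.div_spec <- function(x, ...) {
  cat(switch(x$kind, dpd = "Density power divergence",
             gamma_div = "Transformed gamma-divergence"),
      sprintf("(gamma = %g), family: %s\n", x$gamma, x$family$id))
  invisible(x)
}

#' Per-observation divergence objective and its observation derivatives
#'
#' `div_objective()` evaluates \eqn{D_\gamma(y_i;\theta)} for every
#' observation; `div_objective_dy()` and `div_objective_d2y()` evaluate the
#' analytic derivatives \eqn{D_\gamma'} and \eqn{D_\gamma''} in \eqn{y_i}
#' that enter the H-score. Powers of the density are computed as
#' \eqn{\exp(\gamma \log f)} so extreme (outlying) observations with tiny
#' densities do not underflow.
#'
#' For the DPD, \eqn{D' = f^{\gamma-1} f'} and
#' \eqn{D'' = (\gamma-1) f^{\gamma-2} (f')^2 + f^{\gamma-1} f''}; the
#' gamma-divergence derivatives are the same divided by
#' \eqn{C_\gamma(\theta)}. At \eqn{\gamma = 0} the derivatives of
#' \eqn{\log f} are used.
#'
#' @param spec a [div_spec()].
#' @param y numeric vector of observations.
#' @param params named parameter vector (natural scale).
#' @param X covariate matrix for the regression family.
#' @return numeric vector, one value per observation.
#' @export
div_objective <- function(spec, y, params, X = NULL) {
  fam <- spec$family; g <- spec$gamma
  lf <- family_logdensity(fam, y, params, X)
  if (g == 0) return(lf)
  switch(spec$kind,
    dpd = {
      lint <- power_integral(fam, params, g, log = TRUE)
      exp(g * lf) / g - exp(lint) / (1 + g)
    },
    gamma_div = {
      lint <- power_integral(fam, params, g, log = TRUE)
      exp(g * lf - g / (1 + g) * lint) / g
    })
}

#' @rdname div_objective
#' @export
div_objective_dy <- function(spec, y, params, X = NULL) {
  fam <- spec$family; g <- spec$gamma
  fp <- family_density_dy(fam, y, params, X)
  if (g == 0) return(fp / family_density(fam, y, params, X))
  lf <- family_logdensity(fam, y, params, X)
  out <- exp((g - 1) * lf) * fp
  if (spec$kind == "gamma_div") out <- out / c_gamma(spec, params)
  out
}

#' @rdname div_objective
#' @export
div_objective_d2y <- function(spec, y, params, X = NULL) {
  fam <- spec$family; g <- spec$gamma
  fp <- family_density_dy(fam, y, params, X)
  fpp <- family_density_d2y(fam, y, params, X)
  lf <- family_logdensity(fam, y, params, X)
  if (g == 0) {
    f <- exp(lf)
    return(fpp / f - (fp / f)^2)
  }
  out <- (g - 1) * exp((g - 2) * lf) * fp^2 + exp((g - 1) * lf) * fpp
  if (spec$kind == "gamma_div") out <- out / c_gamma(spec, params)
  out
}

#' Gamma-divergence normalizing factor
#'
#' \eqn{C_\gamma(\theta) = (\int f(t;\theta)^{1+\gamma} dt)^{\gamma/(1+\gamma)}},
#' the factor by which the transformed gamma-divergence rescales the DPD
#' kernel. For the normal and regression families it equals
#' \eqn{\{(1+\gamma)^{-1/2}(2\pi\sigma^2)^{-\gamma/2}\}^{\gamma/(1+\gamma)}}.
#'
#' @inheritParams div_objective
#' @return a positive scalar; 1 at \eqn{\gamma = 0}.
#' @export
c_gamma <- function(spec, params) {
  if (spec$kind != "gamma_div")
    stop("c_gamma is defined for gamma-divergence specs only")
  g <- spec$gamma
  if (g == 0) return(1)
  exp(g / (1 + g) * power_integral(spec$family, params, g, log = TRUE))
}

## theta-gradient of the summed objective sum_i D_gamma(y_i; theta):
## length-d vector on the natural parameter scale. Used by the optimizer
## and the sandwich covariance.
div_objective_grad_theta <- function(spec, y, params, X = NULL,
                                     per_observation = FALSE) {
  fam <- spec$family; g <- spec$gamma
  gl <- logdensity_grad(fam, y, params, X)
  if (g == 0) {
    return(if (per_observation) gl else colSums(gl))
  }
  lf <- family_logdensity(fam, y, params, X)
  w <- exp(g * lf)
  gint <- log_power_integral_grad(fam, params, g)
  if (spec$kind == "dpd") {
    lint <- power_integral(fam, params, g, log = TRUE)
    const_term <- exp(lint) / (1 + g) * gint
    gmat <- gl * w - matrix(const_term, nrow = length(y), ncol = fam$d,
                            byrow = TRUE)
  } else {
    lint <- power_integral(fam, params, g, log = TRUE)
    D <- exp(g * lf - g / (1 + g) * lint) / g
    ## dD_i/dtheta = D_i * gamma * (grad log f_i - grad log I /(1+gamma))
    gmat <- (D * g) * sweep(gl, 2L, gint / (1 + g), "-")
  }
  if (per_observation) gmat else colSums(gmat)
}
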