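#' H-score of a fitted robust divergence model
#'
#' Evaluates the Hyvarinen-score criterion
#' \deqn{H_n(\gamma) = \frac{1}{n}\sum_{i=1}^n \left\{ 2 D_\gamma''(y_i;
#'   \hat\theta_\gamma) + D_\gamma'(y_i;\hat\theta_\gamma)^2 \right\}}
#' at the M-estimate \eqn{\hat\theta_\gamma}. Treating
#' \eqn{\exp\{D_\gamma(y;\theta)\}} as an unnormalized model, this is the
#' large-sample approximation of the Hyvarinen score of its marginal
#' likelihood; it only needs derivatives of the objective in the
#' observations, so no normalizing constant and no asymptotic-variance
#' formula are required. Its grid argmin defines the selected tuning
#' parameter.
#'
#' `method = "closed"` dispatches to the per-family closed forms (normal
#' DPD, gamma DPD, normal/regression gamma-divergence); `"generic"` uses
#' the assembly from [div_objective_dy()] and [div_objective_d2y()];
#' `"auto"` uses a closed form when one exists. Both routes agree to
#' near machine precision.
#'
#' @param spec a [div_spec()] with the same `gamma` as the fit.
#' @param data a [div_data()] or numeric vector.
#' @param fit a converged [div_fit()].
#' @param method `"auto"`, `"closed"` or `"generic"`.
#' @return a single number; smaller is better.
#' @export
h_score <- function(spec, data, fit, method = c("auto", "closed", "generic")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "div_spec"), inherits(fit, "div_fit"))
  if (!isTRUE(fit$converged))
    stop("h_score requires a converged fit")
  if (!isTRUE(all.equal(spec$gamma, fit$gamma)))
    stop("spec has gamma = ", spec$gamma, " but fit has gamma = ", fit$gamma)
  data <- as_div_data(data)
  fam <- spec$family
  theta <- fit$params
  has_closed <- (fam$id %in% c("normal", "normal_regression")) ||
    (fam$id == "gamma" && spec$kind == "dpd")
  if (method == "closed" && !has_closed)
    stop("no closed form for family '", fam$id, "' with kind '",
         spec$kind, "'")
  use_closed <- method == "closed" || (method == "auto" && has_closed)
  if (!use_closed) {
    terms <- 2 * div_objective_d2y(spec, data$y, theta, data$X) +
      div_objective_dy(spec, data$y, theta, data$X)^2
    return(mean(terms))
  }
  g <- spec$gamma
  cc <- if (spec$kind == "gamma_div") c_gamma(spec, theta) else 1
  if (fam$id %in% c("normal", "normal_regression")) {
    mu <- if (fam$id == "normal") theta[["mu"]]
          else location_of(fam, theta, data$X)
    s2 <- theta[["sigma2"]]
    z <- data$y - mu
    lphi <- stats::dnorm(data$y, mu, sqrt(s2), log = TRUE)
    terms <- 2 * (g * z^2 - s2) / s2^2 * exp(g * lphi) / cc +
      z^2 / s2^2 * exp(2 * g * lphi) / cc^2
  } else {
    lf <- family_logdensity(fam, data$y, theta)
    fp <- family_density_dy(fam, data$y, theta)
    fpp <- family_density_d2y(fam, data$y, theta)
    terms <- (fp^2 * exp((g - 2) * lf) * (2 * (g - 1) + exp(g * lf)) +
                2 * exp((g - 1) * lf) * fpp) / cc
    if (spec$kind == "gamma_div")
      terms <- terms + fp^2 * exp((2 * g - 2) * lf) * (1 / cc^2 - 1 / cc)
  }
  mean(terms)
}

#' Select the robustness tuning parameter by the H-score criterion
#'
#' Fits the divergence M-estimator along a \eqn{\gamma} grid (warm-started,
#' see [div_fit_path()]), scores every converged admissible point with
#' [h_score()], and returns the grid argmin
#' \eqn{\gamma_{opt} = \arg\min_\gamma H_n(\gamma)}. Ties are broken toward
#' the smallest \eqn{\gamma}, the statistically more efficient choice when
#' fits are equally good. Grid points whose fit failed, did not converge,
#' or is inadmissible are skipped with a recorded reason rather than
#' aborting the search.
#'
#' For the regression family, supplying `lambda` selects \eqn{\gamma} for
#' the l1-penalized gamma-divergence estimator ([fit_l1_regression()]); the
#' H-score closed form is then evaluated at the penalized estimates.
#'
#' @param kind `"dpd"` or `"gamma_div"`.
#' @param family a [div_family][normal_family].
#' @param data a [div_data()] or numeric vector.
#' @param gamma_grid strictly increasing grid of values \eqn{\ge 0},
#'   e.g. `seq(0, 0.5, by = 0.01)`.
#' @param lambda optional l1 penalty level (regression family only).
#' @param control see [div_control()].
#' @return An object of class `div_select` with elements `gamma_grid`,
#'   `h_scores` (NA at skipped points), `fits`, `gamma_opt`, `fit_opt`,
#'   and `skipped` (reasons per grid point).
#' @examples
#' set.seed(1)
#' y <- c(rnorm(95, 2, 1), rnorm(5, 9, 1))
#' sel <- select_gamma("dpd", normal_family(), y, seq(0, 0.7, by = 0.05))
#' sel$gamma_opt
#' @export
select_gamma <- function(kind, family, data, gamma_grid, lambda = NULL,
                         control = div_control()) {
  data <- as_div_data(data)
  if (is.null(lambda)) {
    path <- div_fit_path(kind, family, data, gamma_grid, control)
    skipped <- attr(path, "skipped")
  } else {
    if (family$id != "normal_regression")
      stop("lambda is only meaningful for the regression family")
    if (kind != "gamma_div")
      stop("the penalized estimator is defined for the gamma-divergence")
    path <- vector("list", length(gamma_grid))
    skipped <- character(length(gamma_grid))
    prev <- NULL
    for (k in seq_along(gamma_grid)) {
      fit <- tryCatch(
        fit_l1_regression(gamma_grid[k], data, lambda, init = prev),
        error = function(e) conditionMessage(e))
      if (is.character(fit)) skipped[k] <- fit
      else {
        path[[k]] <- fit
        if (fit$converged) prev <- fit$params
      }
    }
  }
  hs <- rep(NA_real_, length(gamma_grid))
  for (k in seq_along(gamma_grid)) {
    fit <- path[[k]]
    if (is.null(fit)) next
    if (!fit$converged) {
      skipped[k] <- "fit did not converge"
      next
    }
    spec <- div_spec(kind, gamma_grid[k], family)
    hs[k] <- tryCatch(h_score(spec, data, fit),
                      error = function(e) {
                        skipped[k] <<- conditionMessage(e)
                        NA_real_
                      })
  }
  if (all(!is.finite(hs))) {
    stop("gamma selection failed at every grid point; reasons: ",
         paste(unique(skipped[nzchar(skipped)]), collapse = "; "))
  }
  opt <- which.min(replace(hs, !is.finite(hs), Inf))
  structure(list(kind = kind, family = family$id,
                 gamma_grid = gamma_grid, h_scores = hs,
                 fits = path, gamma_opt = gamma_grid[opt],
                 fit_opt = path[[opt]], skipped = skipped,
                 lambda = lambda),
            class = "div_select")
}

#' @export
print.div_select <- function(x, ...) {
  cat(sprintf("H-score selection (%s, family %s): gamma_opt = %g\n",
              x$kind, x$family, x$gamma_opt))
  cat(sprintf("  grid of %d points on [%g, %g]; H_n at optimum: %.6g\n",
              length(x$gamma_grid), min(x$gamma_grid), max(x$gamma_grid),
              min(x$h_scores, na.rm = TRUE)))
  ns <- sum(nzchar(x$skipped))
  if (ns > 0) cat("  skipped grid points:", ns, "\n")
  invisible(x)
}

#' @export
plot.div_select <- function(x, ...) {
  graphics::plot(x$gamma_grid, x$h_scores, type = "b", pch = 16, cex = 0.6,
                 xlab = expression(gamma), ylab = expression(H[n](gamma)),
                 ...)
  graphics::abline(v = x$gamma_opt, lty = 2, col = "grey40")
  invisible(x)
}
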