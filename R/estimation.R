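#' Dataset container
#'
#' Holds the observation vector `y` and, for regression, the covariate
#' matrix `X` (one row per observation, no intercept column). Missing
#' values are rejected; the minimum size is the model dimension plus one.
#'
#' @param y numeric response vector.
#' @param X optional covariate matrix.
#' @param note optional provenance note carried along with the data.
#' @return An object of class `div_data`.
#' @export
div_data <- function(y, X = NULL, note = NULL) {
  y <- as.numeric(y)
  if (length(y) == 0L) stop("empty dataset")
  if (any(!is.finite(y))) stop("dataset contains missing or non-finite y")
  if (!is.null(X)) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (nrow(X) != length(y))
      stop("X has ", nrow(X), " rows but y has length ", length(y))
    if (any(!is.finite(X))) stop("dataset contains missing covariate values")
  }
  structure(list(y = y, X = X, n = length(y),
                 p = if (is.null(X)) 0L else ncol(X), note = note),
            class = "div_data")
}

#' @export
print.div_data <- function(x, ...) {
  cat("Dataset: n =", x$n,
      if (x$p > 0) paste0(", p = ", x$p, " covariates"), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

as_div_data <- function(data) {
  if (inherits(data, "div_data")) data else div_data(data)
}

#' Fitting control parameters
#'
#' @param grad_tol convergence tolerance on the max-norm of the gradient of
#'   the mean objective.
#' @param maxit maximum quasi-Newton iterations.
#' @param reltol relative objective tolerance passed to [stats::optim()].
#' @param trim trimming fraction for the robust second starting value used
#'   by cold-started fits.
#' @return a list of control settings.
#' @export
div_control <- function(grad_tol = 1e-6, maxit = 500L, reltol = 1e-14,
                        trim = 0.2) {
  list(grad_tol = grad_tol, maxit = maxit, reltol = reltol, trim = trim)
}

## One quasi-Newton run from a given start (internal scale).
fit_from <- function(spec, data, start_params, control) {
  fam <- spec$family
  y <- data$y; X <- data$X; n <- data$n
  negobj <- function(phi) {
    params <- from_internal(fam, phi)
    if (any(!is.finite(params)) || any(params[fam$positive] <= 0) ||
        !gamma_admissible(fam, params, spec$gamma)) return(1e10)
    v <- -sum(div_objective(spec, y, params, X))
    if (!is.finite(v)) 1e10 else v
  }
  neggrad <- function(phi) {
    params <- from_internal(fam, phi)
    if (any(!is.finite(params)) || any(params[fam$positive] <= 0) ||
        !gamma_admissible(fam, params, spec$gamma))
      return(numeric(fam$d))
    gr <- -div_objective_grad_theta(spec, y, params, X)
    ## chain rule for log-scale components: d/dphi = theta * d/dtheta
    gr[fam$positive] <- gr[fam$positive] * params[fam$positive]
    if (any(!is.finite(gr))) numeric(fam$d) else gr
  }
  phi0 <- to_internal(fam, start_params)
  opt <- stats::optim(phi0, negobj, neggrad, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  params <- from_internal(fam, opt$par)
  gn <- if (all(is.finite(params)) && all(params[fam$positive] > 0) &&
            gamma_admissible(fam, params, spec$gamma)) {
    max(abs(div_objective_grad_theta(spec, y, params, X))) / n
  } else Inf
  list(params = params, value = -opt$value, grad_norm = gn,
       iterations = opt$counts[["function"]],
       converged = is.finite(gn) && gn < control$grad_tol)
}

#' Robust divergence M-estimation
#'
#' Maximizes \eqn{\sum_i D_\gamma(y_i;\theta)} by quasi-Newton (BFGS) with
#' analytic \eqn{\theta}-gradients, on an internal log scale for
#' positivity-constrained parameters. At \eqn{\gamma = 0} this is maximum
#' likelihood. Cold-started fits (no `init`) are run twice — once from
#' moment estimates and once from trimmed-moment estimates of the central
#' portion of the data — and the better objective is kept, guarding against
#' the multimodality that robust objectives can develop under heavy
#' contamination.
#'
#' @param spec a [div_spec()].
#' @param data a [div_data()] object or a bare numeric vector.
#' @param init optional named starting parameter vector (natural scale).
#' @param control see [div_control()].
#' @return An object of class `div_fit` with elements `params`, `gamma`,
#'   `kind`, `objective` (the maximized sum), `converged`, `grad_norm`,
#'   `iterations`. Non-convergence is reported through `converged = FALSE`,
#'   never silently.
#' @examples
#' fit <- div_fit(div_spec("dpd", 0, normal_family()), c(1, 2, 3))
#' coef(fit)  # mu = 2, sigma2 = 2/3
#' @export
div_fit <- function(spec, data, init = NULL, control = div_control()) {
  stopifnot(inherits(spec, "div_spec"))
  data <- as_div_data(data)
  fam <- spec$family
  if (data$n < fam$d + 1L)
    stop("need at least d + 1 = ", fam$d + 1L, " observations")
  check_support(fam, data$y)
  if (fam$has_covariates && (is.null(data$X) || data$p != fam$p))
    stop("regression family with p = ", fam$p,
         " needs a matching covariate matrix")
  runs <- if (is.null(init)) {
    starts <- list(moment_init(fam, data$y, data$X, trim = 0),
                   moment_init(fam, data$y, data$X, trim = control$trim))
    lapply(starts, function(s) fit_from(spec, data, s, control))
  } else {
    list(fit_from(spec, data, check_params(fam, init), control))
  }
  best <- runs[[which.max(vapply(runs, `[[`, 0, "value"))]]
  structure(list(gamma = spec$gamma, kind = spec$kind, family = fam$id,
                 params = best$params, objective = best$value,
                 converged = best$converged, grad_norm = best$grad_norm,
                 iterations = best$iterations, n = data$n,
                 covariance = NULL, lambda = NULL),
            class = "div_fit")
}

#' @export
print.div_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit (gamma = %g), family: %s\n",
              switch(x$kind, dpd = "DPD", gamma_div = "gamma-divergence",
                     x$kind),
              x$gamma, x$family))
  print(round(x$params, digits))
  cat(sprintf("objective %.6g, %sconverged (grad norm %.2e)\n",
              x$objective, if (x$converged) "" else "NOT ", x$grad_norm))
  if (!is.null(x$lambda)) cat("lambda =", x$lambda, "\n")
  invisible(x)
}

#' @export
coef.div_fit <- function(object, ...) object$params

#' Warm-started fits along a gamma grid
#'
#' Fits the divergence M-estimator at every point of an increasing
#' \eqn{\gamma} grid. The first grid point is cold-started (see
#' [div_fit()]); each subsequent point is warm-started from the previous
#' solution, which makes a dense grid cheap because the estimator deforms
#' continuously in \eqn{\gamma}. Grid points where the fit fails or the
#' power integral does not exist are flagged, not fatal.
#'
#' @param kind `"dpd"` or `"gamma_div"`.
#' @param family a [div_family][normal_family].
#' @param data a [div_data()] or numeric vector.
#' @param gamma_grid strictly increasing vector of values \eqn{\ge 0}.
#' @param control see [div_control()].
#' @return A list of class `div_path`: one [div_fit()] per grid point (or
#'   `NULL` with an attached reason where the point was skipped).
#' @export
div_fit_path <- function(kind, family, data, gamma_grid,
                         control = div_control()) {
  data <- as_div_data(data)
  stopifnot(length(gamma_grid) >= 1L, all(gamma_grid >= 0),
            !is.unsorted(gamma_grid, strictly = TRUE))
  fits <- vector("list", length(gamma_grid))
  reasons <- character(length(gamma_grid))
  prev <- NULL
  for (k in seq_along(gamma_grid)) {
    g <- gamma_grid[k]
    spec <- div_spec(kind, g, family)
    init <- if (!is.null(prev) && gamma_admissible(family, prev, g))
      prev else NULL
    fit <- tryCatch(div_fit(spec, data, init = init, control = control),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      reasons[k] <- fit
    } else {
      fits[[k]] <- fit
      if (fit$converged) prev <- fit$params
    }
  }
  structure(fits, gamma_grid = gamma_grid, skipped = reasons,
            class = "div_path")
}

#' Sandwich covariance and Wald intervals for a divergence fit
#'
#' Standard M-estimation sandwich \eqn{J^{-1} K J^{-1} / n} with
#' \eqn{J = -\frac{1}{n}\sum_i \nabla^2_\theta D_\gamma(y_i;\hat\theta)}
#' (computed by central differences of the analytic gradient) and
#' \eqn{K = \frac{1}{n}\sum_i \nabla_\theta D_\gamma
#' \nabla_\theta D_\gamma^\top} (analytic). At \eqn{\gamma = 0} this is the
#' usual robust (Huber) covariance of the MLE and reduces to the inverse
#' Fisher information under a correctly specified model.
#'
#' @param spec a [div_spec()] matching the fit.
#' @param data the data the fit was computed on.
#' @param fit a converged [div_fit()].
#' @param h relative finite-difference step for the Hessian.
#' @return symmetric positive semidefinite `d x d` matrix.
#' @export
sandwich_covariance <- function(spec, data, fit, h = 1e-6) {
  stopifnot(inherits(fit, "div_fit"))
  if (!fit$converged) stop("sandwich covariance requires a converged fit")
  data <- as_div_data(data)
  fam <- spec$family
  theta <- fit$params
  n <- data$n
  gmat <- div_objective_grad_theta(spec, data$y, theta, data$X,
                                   per_observation = TRUE)
  K <- crossprod(gmat) / n
  d <- fam$d
  J <- matrix(0, d, d)
  for (j in seq_len(d)) {
    step <- h * max(abs(theta[j]), 1)
    tp <- theta; tp[j] <- tp[j] + step
    tm <- theta; tm[j] <- tm[j] - step
    J[, j] <- -(div_objective_grad_theta(spec, data$y, tp, data$X) -
                  div_objective_grad_theta(spec, data$y, tm, data$X)) /
      (2 * step * n)
  }
  J <- (J + t(J)) / 2
  ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(abs(ev))) {
    worst <- which.min(eigen(J, symmetric = TRUE)$values)
    stop("singular or near-singular Hessian J; ill-conditioned direction ",
         "involves parameter '", fam$param_names[worst], "'")
  }
  Jinv <- solve(J)
  V <- Jinv %*% K %*% Jinv / n
  V <- (V + t(V)) / 2
  dimnames(V) <- list(fam$param_names, fam$param_names)
  V
}

#' @rdname sandwich_covariance
#' @param level confidence level for the Wald intervals.
#' @param covariance optionally, a precomputed covariance matrix.
#' @return `wald_interval()`: a matrix with columns `estimate`, `lower`,
#'   `upper`.
#' @export
wald_interval <- function(spec, data, fit, level = 0.95, covariance = NULL) {
  V <- if (is.null(covariance)) sandwich_covariance(spec, data, fit)
       else covariance
  se <- sqrt(pmax(diag(V), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(estimate = fit$params, lower = fit$params - z * se,
        upper = fit$params + z * se)
}
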