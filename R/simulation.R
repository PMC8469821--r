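#' Contamination scenario
#'
#' Describes one simulated contaminated-data condition: draw `n` i.i.d.
#' observations from the true family, then shift the first
#' \eqn{\lfloor n\omega \rfloor} of them upward by `shift`. This emulates
#' the contamination model \eqn{(1-\omega) f_{\theta^*} + \omega\,\delta}
#' with \eqn{\delta} a point-shifted copy of the clean distribution. The
#' study conditions used throughout are the normal study
#' (\eqn{\mu = 2, \sigma^2 = 1}, shift +7) and the gamma study
#' (\eqn{\alpha = 2, \beta = 4}, shift +5).
#'
#' @param family a [div_family][normal_family] (`normal_family()` or
#'   `gamma_family()`).
#' @param params true parameter vector (natural scale).
#' @param n sample size.
#' @param omega contamination fraction in `[0, 1)`.
#' @param shift positive amount added to contaminated observations.
#' @param seed optional seed making [generate_data()] deterministic.
#' @return An object of class `contamination_scenario`.
#' @examples
#' sc <- contamination_scenario(gamma_family(), c(alpha = 2, beta = 4),
#'                              n = 100, omega = 0.1, shift = 5, seed = 1)
#' d <- generate_data(sc)
#' @export
contamination_scenario <- function(family, params, n, omega = 0,
                                   shift = 5, seed = NULL) {
  stopifnot(inherits(family, "div_family"))
  if (family$has_covariates)
    stop("contamination scenarios cover the univariate families")
  params <- check_params(family, params)
  stopifnot(n >= family$d + 1L, omega >= 0, omega < 1, shift > 0)
  structure(list(family = family, params = params, n = as.integer(n),
                 omega = omega, shift = shift, seed = seed),
            class = "contamination_scenario")
}

#' @rdname contamination_scenario
#' @param scenario a `contamination_scenario`.
#' @param seed overrides the scenario's seed for this draw.
#' @return `generate_data()`: a [div_data()] of length `n` whose first
#'   `floor(n * omega)` entries carry the outlier shift.
#' @export
generate_data <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "contamination_scenario"))
  if (!is.null(seed)) set.seed(seed)
  p <- scenario$params
  y <- switch(scenario$family$id,
    normal = stats::rnorm(scenario$n, p[["mu"]], sqrt(p[["sigma2"]])),
    gamma = stats::rgamma(scenario$n, shape = p[["alpha"]],
                          rate = p[["beta"]]))
  k <- floor(scenario$n * scenario$omega)
  if (k > 0) y[seq_len(k)] <- y[seq_len(k)] + scenario$shift
  div_data(y, note = sprintf("%s scenario: n=%d, omega=%g, shift=%g",
                             scenario$family$id, scenario$n,
                             scenario$omega, scenario$shift))
}

#' Estimator descriptors for simulation studies
#'
#' `estimator_ml()` is maximum likelihood (\eqn{\gamma = 0});
#' `estimator_fixed(gamma)` fits the divergence at a fixed tuning value;
#' `estimator_hs(gamma_grid)` selects \eqn{\gamma} per dataset by the
#' H-score criterion and reports the selected fit.
#'
#' @param gamma fixed tuning value.
#' @param gamma_grid grid searched by the H-score criterion.
#' @param kind `"dpd"` or `"gamma_div"`.
#' @param label label used in study summaries.
#' @return a `div_estimator` descriptor for [run_study()].
#' @export
estimator_ml <- function(label = "ML") {
  structure(list(type = "ml", label = label), class = "div_estimator")
}

#' @rdname estimator_ml
#' @export
estimator_fixed <- function(gamma, kind = "dpd",
                            label = sprintf("gamma=%g", gamma)) {
  structure(list(type = "fixed", gamma = gamma, kind = kind, label = label),
            class = "div_estimator")
}

#' @rdname estimator_ml
#' @export
estimator_hs <- function(gamma_grid, kind = "dpd", label = "HS") {
  structure(list(type = "hs", gamma_grid = gamma_grid, kind = kind,
                 label = label),
            class = "div_estimator")
}

apply_estimator <- function(est, family, data, control) {
  switch(est$type,
    ml = list(fit = div_fit(div_spec("dpd", 0, family), data,
                            control = control),
              gamma = 0),
    fixed = list(fit = div_fit(div_spec(est$kind, est$gamma, family), data,
                               control = control),
                 gamma = est$gamma),
    hs = {
      sel <- select_gamma(est$kind, family, data, est$gamma_grid,
                          control = control)
      list(fit = sel$fit_opt, gamma = sel$gamma_opt)
    })
}

#' Monte-Carlo study over a contamination scenario
#'
#' Replicates a [contamination_scenario()] `R` times; on each replicate
#' every estimator is applied and its point estimates (and, optionally,
#' sandwich-based Wald intervals) are recorded. Summaries follow the usual
#' reporting of robust-divergence simulation studies: per-parameter
#' \eqn{RMSE = \sqrt{\mathrm{mean}((\hat\theta - \theta^*)^2)}}, coverage
#' probability (CP, percent) and average length (AL) of 95\% intervals, and
#' the mean selected \eqn{\gamma} for H-score estimators. Every summary
#' carries a Monte-Carlo standard error so scaled-down runs can be compared
#' with full-size results within sampling error.
#'
#' Replicate `r` draws its data under seed `seed + r` (a counter scheme),
#' so studies are reproducible and parallelizable deterministically.
#'
#' @param scenario a [contamination_scenario()].
#' @param estimators list of [estimator_ml()] / [estimator_fixed()] /
#'   [estimator_hs()] descriptors.
#' @param R number of Monte-Carlo replicates.
#' @param seed master seed.
#' @param intervals logical: compute Wald intervals (CP / AL)?
#' @param level confidence level for intervals.
#' @param scale multiplier applied to RMSE / AL when printing (e.g. 100 to
#'   match tables reported on a x100 scale); stored as metadata.
#' @param control see [div_control()].
#' @return An object of class `scenario_summary`.
#' @export
run_study <- function(scenario, estimators, R, seed = 1,
                      intervals = FALSE, level = 0.95, scale = 1,
                      control = div_control()) {
  stopifnot(R >= 1)
  if (inherits(estimators, "div_estimator")) estimators <- list(estimators)
  fam <- scenario$family
  truth <- scenario$params
  d <- fam$d
  E <- length(estimators)
  labels <- vapply(estimators, `[[`, "", "label")
  est_arr <- array(NA_real_, c(R, E, d),
                   dimnames = list(NULL, labels, fam$param_names))
  gam_arr <- matrix(NA_real_, R, E, dimnames = list(NULL, labels))
  cov_arr <- len_arr <- if (intervals)
    array(NA_real_, c(R, E, d), dimnames = dimnames(est_arr)) else NULL
  failures <- integer(E)
  for (r in seq_len(R)) {
    data <- generate_data(scenario, seed = seed + r)
    for (e in seq_len(E)) {
      res <- tryCatch(
        apply_estimator(estimators[[e]], fam, data, control),
        error = function(err) NULL)
      if (is.null(res) || is.null(res$fit) || !res$fit$converged) {
        failures[e] <- failures[e] + 1L
        next
      }
      est_arr[r, e, ] <- res$fit$params
      gam_arr[r, e] <- res$gamma
      if (intervals) {
        spec <- div_spec(if (estimators[[e]]$type == "ml") "dpd"
                         else estimators[[e]]$kind,
                         res$gamma, fam)
        ci <- tryCatch(wald_interval(spec, data, res$fit, level = level),
                       error = function(err) NULL)
        if (!is.null(ci)) {
          cov_arr[r, e, ] <- truth >= ci[, "lower"] & truth <= ci[, "upper"]
          len_arr[r, e, ] <- ci[, "upper"] - ci[, "lower"]
        }
      }
    }
  }
  per_est <- lapply(seq_len(E), function(e) {
    est_mat <- matrix(est_arr[, e, ], ncol = d)
    err2 <- (est_mat - matrix(truth, nrow = R, ncol = d, byrow = TRUE))^2
    ok <- stats::complete.cases(err2)
    mse <- colMeans(err2[ok, , drop = FALSE])
    mse_se <- apply(err2[ok, , drop = FALSE], 2L, stats::sd) / sqrt(sum(ok))
    rmse <- sqrt(mse)
    out <- list(label = labels[e], R_effective = sum(ok),
                rmse = stats::setNames(rmse, fam$param_names),
                rmse_se = stats::setNames(mse_se / (2 * rmse),
                                          fam$param_names))
    if (estimators[[e]]$type == "hs") {
      g <- gam_arr[, e]
      out$mean_gamma <- mean(g, na.rm = TRUE)
      out$mean_gamma_se <- stats::sd(g, na.rm = TRUE) /
        sqrt(sum(is.finite(g)))
    }
    if (intervals) {
      cv <- matrix(cov_arr[, e, ], ncol = d)
      ln <- matrix(len_arr[, e, ], ncol = d)
      out$cp <- 100 * colMeans(cv, na.rm = TRUE)
      out$cp_se <- 100 * apply(cv, 2L, stats::sd, na.rm = TRUE) /
        sqrt(colSums(is.finite(cv)))
      out$al <- colMeans(ln, na.rm = TRUE)
      out$al_se <- apply(ln, 2L, stats::sd, na.rm = TRUE) /
        sqrt(colSums(is.finite(ln)))
      names(out$cp) <- names(out$al) <- fam$param_names
    }
    out
  })
  names(per_est) <- labels
  structure(list(scenario = scenario, estimators = per_est, R = R,
                 failures = stats::setNames(failures, labels),
                 seed = seed, level = level, scale = scale,
                 selected_gamma = gam_arr),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, digits = 3, ...) {
  sc <- x$scenario
  cat(sprintf(
    "Monte-Carlo study: %s family, n = %d, omega = %g, shift = +%g, R = %d\n",
    sc$family$id, sc$n, sc$omega, sc$shift, x$R))
  if (x$scale != 1) cat("  (RMSE/AL reported on a x", x$scale,
                        " scale)\n", sep = "")
  for (e in x$estimators) {
    cat(sprintf("  %s (R_eff = %d):\n", e$label, e$R_effective))
    cat("    RMSE: ",
        paste(sprintf("%s %.*g (se %.1e)", names(e$rmse),
                      digits, e$rmse * x$scale, e$rmse_se * x$scale),
              collapse = ", "), "\n", sep = "")
    if (!is.null(e$mean_gamma))
      cat(sprintf("    mean selected gamma: %.3f (se %.1e)\n",
                  e$mean_gamma, e$mean_gamma_se))
    if (!is.null(e$cp))
      cat("    CP%: ", paste(sprintf("%s %.1f", names(e$cp), e$cp),
                             collapse = ", "),
          "; AL: ", paste(sprintf("%s %.*g", names(e$al), digits,
                                  e$al * x$scale), collapse = ", "),
          "\n", sep = "")
  }
  if (any(x$failures > 0))
    cat("  replicate failures:",
        paste(sprintf("%s %d", names(x$failures), x$failures),
              collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate study summaries
#'
#' Collapses one or more [run_study()] summaries into a tidy data frame,
#' one row per (scenario, estimator, parameter), convenient for laying out
#' RMSE tables across contamination fractions.
#'
#' @param ... `scenario_summary` objects.
#' @return a data.frame with columns `family`, `n`, `omega`, `estimator`,
#'   `parameter`, `rmse`, `rmse_se`, `mean_gamma`, `cp`, `al`.
#' @export
study_table <- function(...) {
  summaries <- list(...)
  if (length(summaries) == 1L && !inherits(summaries[[1]],
                                           "scenario_summary"))
    summaries <- summaries[[1]]
  rows <- lapply(summaries, function(s) {
    sc <- s$scenario
    do.call(rbind, lapply(s$estimators, function(e) {
      data.frame(family = sc$family$id, n = sc$n, omega = sc$omega,
                 estimator = e$label, parameter = names(e$rmse),
                 rmse = unname(e$rmse * s$scale),
                 rmse_se = unname(e$rmse_se * s$scale),
                 mean_gamma = if (is.null(e$mean_gamma)) NA_real_
                              else e$mean_gamma,
                 cp = if (is.null(e$cp)) NA_real_ else unname(e$cp),
                 al = if (is.null(e$al)) NA_real_
                      else unname(e$al * s$scale),
                 row.names = NULL)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
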