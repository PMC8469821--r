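#' Exact H-score of the marginal unnormalized model (small-n oracle)
#'
#' Computes the exact Hyvarinen score
#' \deqn{H_n^*(\gamma) = \frac{1}{n}\sum_i \left\{ 2 \frac{\partial^2}{
#'   \partial y_i^2} \log L^{(m)}_\gamma(y) + \Big(\frac{\partial}{\partial
#'   y_i} \log L^{(m)}_\gamma(y)\Big)^2 \right\}}
#' of the marginal likelihood \eqn{L^{(m)}_\gamma(y) = \int \pi(\theta)
#' \prod_i \exp\{D_\gamma(y_i;\theta)\}\, d\theta} by deterministic tensor
#' quadrature over the two-dimensional parameter, with the observation
#' derivatives taken by central finite differences of the log marginal.
#'
#' This is a test oracle, not an estimator: the grid argmin criterion
#' [h_score()] is its large-sample approximation, and the two agree as
#' \eqn{n} grows. The prior \eqn{\pi} is an independent wide normal on the
#' internal (location / log-scale) parameter coordinates; the approximation
#' is prior-free to first order, so the choice only matters at very small
#' \eqn{n}. Limited to two-parameter families and \eqn{n \le 50}.
#'
#' @param kind `"dpd"` or `"gamma_div"`.
#' @param family a two-parameter [div_family][normal_family].
#' @param data a [div_data()] or numeric vector with at most 50 points.
#' @param gamma tuning parameter value.
#' @param prior_sd standard deviation of the normal prior on each internal
#'   coordinate.
#' @param grid_points odd number of Simpson nodes per dimension.
#' @param width half-width of the integration box in posterior standard
#'   deviations around the M-estimate.
#' @param h finite-difference step in the observations.
#' @return the exact score \eqn{H_n^*(\gamma)}.
#' @export
exact_h_score_oracle <- function(kind, family, data, gamma, prior_sd = 10,
                                 grid_points = 101L, width = 10, h = 1e-3) {
  data <- as_div_data(data)
  if (family$d != 2L)
    stop("the exact-score oracle handles two-parameter families only")
  if (data$n > 50L)
    stop("the exact-score oracle is limited to n <= 50 (got n = ",
         data$n, ")")
  if (grid_points %% 2L == 0L) grid_points <- grid_points + 1L
  spec <- div_spec(kind, gamma, family)
  fit <- div_fit(spec, data)
  phi_hat <- to_internal(family, fit$params)

  ## posterior curvature on the internal scale, for the integration box
  d <- 2L
  H <- matrix(0, d, d)
  gr_phi <- function(phi) {
    params <- from_internal(family, phi)
    if (!gamma_admissible(family, params, gamma)) return(rep(NA_real_, d))
    g <- div_objective_grad_theta(spec, data$y, params, data$X)
    g[family$positive] <- g[family$positive] * params[family$positive]
    g
  }
  for (j in 1:d) {
    st <- 1e-5 * max(abs(phi_hat[j]), 1)
    pp <- phi_hat; pp[j] <- pp[j] + st
    pm <- phi_hat; pm[j] <- pm[j] - st
    H[, j] <- -(gr_phi(pp) - gr_phi(pm)) / (2 * st)
  }
  H <- (H + t(H)) / 2
  sds <- sqrt(pmax(diag(solve(H)), 1e-12))

  grids <- lapply(1:d, function(j)
    seq(phi_hat[j] - width * sds[j], phi_hat[j] + width * sds[j],
        length.out = grid_points))
  simpson_w <- function(x) {
    m <- length(x)
    w <- c(1, rep(c(4, 2), length.out = m - 2L), 1)
    w * (x[2] - x[1]) / 3
  }
  w2 <- as.vector(outer(simpson_w(grids[[1]]), simpson_w(grids[[2]])))
  th_grid <- as.matrix(expand.grid(grids[[1]], grids[[2]]))
  G <- nrow(th_grid)
  logprior <- stats::dnorm(th_grid[, 1], 0, prior_sd, log = TRUE) +
    stats::dnorm(th_grid[, 2], 0, prior_sd, log = TRUE)

  ## n x G matrices of per-observation objective contributions at each node
  eval_rows <- function(yv) {
    out <- matrix(-Inf, length(yv), G)
    for (g in seq_len(G)) {
      params <- from_internal(family, stats::setNames(th_grid[g, ],
                                                      family$param_names))
      if (!gamma_admissible(family, params, gamma)) next
      out[, g] <- div_objective(spec, yv, params)
    }
    out
  }
  D0 <- eval_rows(data$y)
  Dp <- eval_rows(data$y + h)
  Dm <- eval_rows(data$y - h)

  logmarg <- function(colsum) {
    v <- colsum + logprior
    m <- max(v)
    m + log(sum(w2 * exp(v - m)))
  }
  base_colsum <- colSums(D0)
  lm0 <- logmarg(base_colsum)
  score <- numeric(data$n)
  for (i in seq_len(data$n)) {
    lp <- logmarg(base_colsum - D0[i, ] + Dp[i, ])
    lm <- logmarg(base_colsum - D0[i, ] + Dm[i, ])
    d1 <- (lp - lm) / (2 * h)
    d2 <- (lp - 2 * lm0 + lm) / h^2
    score[i] <- 2 * d2 + d1^2
  }
  mean(score)
}
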