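#' One-way random-intercept REML profile
#'
#' Restricted log-likelihood machinery for the variance-components model
#' x_ig = mu + u_g + e_ig with u_g ~ N(0, s2_u), e_ig ~ N(0, s2_e). The
#' likelihood is profiled over the variance ratio lambda = s2_u / s2_e:
#' with w_g = n_g / (1 + n_g * lambda), the GLS mean is
#' mu(lambda) = sum w_g xbar_g / sum w_g, the weighted residual sum is
#' Q(lambda) = SSW + sum w_g (xbar_g - mu)^2, and (up to a constant not
#' involving lambda)
#' -2 lR(lambda) = (N-1) log Q + sum log(1 + n_g lambda) + log(sum w_g).
#' Everything reduces to the group sizes, group means and the pooled
#' within-group sum of squares, so one evaluation is O(G).
#'
#' @param x Numeric vector of individual-level values.
#' @param group Group id per element of `x`.
#' @return List with `lambda` (REML estimate of the variance ratio),
#'   `sigma2_e`, `sigma2_u`, `rlrt` (restricted likelihood-ratio
#'   statistic for H0: s2_u = 0, >= 0), and `criterion(lambda)` pieces.
#' @keywords internal
reml_one_way <- function(x, group) {
  f <- factor(group)
  n_g <- as.numeric(table(f))
  xbar <- tapply(x, f, mean)
  N <- length(x)
  ssw <- sum((x - xbar[as.integer(f)])^2)
  crit <- function(lambda) {
    w <- n_g / (1 + n_g * lambda)
    mu <- sum(w * xbar) / sum(w)
    Q <- ssw + sum(w * (xbar - mu)^2)
    (N - 1) * log(Q) + sum(log1p(n_g * lambda)) + log(sum(w))
  }
  c0 <- crit(0)
  # coarse log-spaced grid, then local refinement around the best point
  grid <- c(0, exp(seq(log(1e-8), log(1e6), length.out = 61)))
  vals <- vapply(grid, crit, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(crit, c(lo, hi), tol = 1e-10)
  if (opt$objective <= vals[i]) {
    lambda <- opt$minimum; cmin <- opt$objective
  } else {
    lambda <- grid[i]; cmin <- vals[i]
  }
  if (cmin >= c0) { lambda <- 0; cmin <- c0 }
  w <- n_g / (1 + n_g * lambda)
  mu <- sum(w * xbar) / sum(w)
  Q <- ssw + sum(w * (xbar - mu)^2)
  s2e <- Q / (N - 1)
  list(lambda = lambda, sigma2_e = s2e, sigma2_u = lambda * s2e,
       rlrt = max(0, c0 - cmin), crit = crit, n_g = n_g, N = N)
}

#' Simulation-based test of zero between-group variance
#'
#' Tests whether an individual-level variable varies between groups at
#' all: fits the random-intercept model x_ig = mu + u_g + e_ig by
#' restricted maximum likelihood and computes the restricted
#' likelihood-ratio statistic for H0: Var(u_g) = 0. Because the null
#' value lies on the boundary of the parameter space the chi-squared
#' reference fails, so the null distribution is obtained by parametric
#' simulation: `n_sim` datasets are drawn under H0 (i.i.d. Gaussian on
#' the same group design — the statistic is invariant to the location
#' and scale of the data, so unit normals suffice) and the p-value is
#' the exceedance proportion (1 + #\{sim >= observed\}) / (n_sim + 1).
#'
#' A significant result supports aggregating the variable to group
#' level: its group means carry real between-group signal rather than
#' pure within-group noise.
#'
#' @param x Numeric individual-level values.
#' @param group Group id per element (>= 3 groups).
#' @param n_sim Number of null simulations, default 1000.
#' @param seed Optional integer seed.
#' @return List of class `"zero_variance_test"`: `statistic` (RLRT),
#'   `p_value`, `sigma2_u`, `sigma2_e`, `icc`, `n_sim`.
#' @export
zero_variance_test <- function(x, group, n_sim = 1000, seed = NULL) {
  x <- as.numeric(x)
  f <- factor(group)
  if (nlevels(f) < 3) stop("need at least 3 groups")
  if (length(x) != length(f)) stop("x and group lengths differ")
  if (!is.null(seed)) set.seed(seed)
  if (stats::sd(x) < 1e-14) {
    return(structure(list(statistic = 0, p_value = 1,
                          sigma2_u = 0, sigma2_e = 0, icc = 0,
                          n_sim = n_sim),
                     class = "zero_variance_test"))
  }
  obs <- reml_one_way(x, f)
  N <- length(x)
  sims <- vapply(seq_len(n_sim), function(b) {
    reml_one_way(stats::rnorm(N), f)$rlrt
  }, numeric(1))
  p <- (1 + sum(sims >= obs$rlrt)) / (n_sim + 1)
  icc <- obs$sigma2_u / (obs$sigma2_u + obs$sigma2_e)
  structure(list(statistic = obs$rlrt, p_value = p,
                 sigma2_u = obs$sigma2_u, sigma2_e = obs$sigma2_e,
                 icc = icc, n_sim = n_sim),
            class = "zero_variance_test")
}

#' @export
print.zero_variance_test <- function(x, ...) {
  cat("Restricted LRT of zero between-group variance\n",
      "  RLRT = ", signif(x$statistic, 5),
      ",  simulated p = ", signif(x$p_value, 4),
      "  (", x$n_sim, " null draws)\n",
      "  sigma2_u = ", signif(x$sigma2_u, 4),
      ", sigma2_e = ", signif(x$sigma2_e, 4),
      ", ICC = ", signif(x$icc, 3), "\n", sep = "")
  invisible(x)
}
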