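# Independent oracles and small data builders used across tests.
# Oracle code deliberately avoids the package's own computational paths:
# explicit summation loops and naive lm() enumeration only.

# Explicit-summation one-way MANOVA decomposition (brute force).
oracle_moments <- function(X, g) {
  g <- as.character(g)
  ids <- unique(g)
  G <- length(ids)
  N <- nrow(X)
  p <- ncol(X)
  mu <- rep(0, p)
  for (i in seq_len(N)) mu <- mu + X[i, ]
  mu <- mu / N
  xbar <- matrix(0, G, p)
  n_g <- integer(G)
  for (k in seq_len(G)) {
    rows <- which(g == ids[k])
    n_g[k] <- length(rows)
    for (i in rows) xbar[k, ] <- xbar[k, ] + X[i, ]
    xbar[k, ] <- xbar[k, ] / n_g[k]
  }
  SW <- matrix(0, p, p)
  for (k in seq_len(G)) for (i in which(g == ids[k])) {
    d <- X[i, ] - xbar[k, ]
    SW <- SW + outer(d, d)
  }
  SW <- SW / (N - G)
  SB <- matrix(0, p, p)
  for (k in seq_len(G)) {
    d <- xbar[k, ] - mu
    SB <- SB + n_g[k] * outer(d, d)
  }
  SB <- SB / (G - 1)
  c_anova <- (N - sum(n_g^2) / N) / (G - 1)
  list(mu = mu, xbar = xbar, n_g = n_g, SW = SW, SB = SB,
       c_anova = c_anova, Sigma_xi = (SB - SW) / c_anova)
}

# Independent exhaustive best-subset search using lm() and the Gaussian
# AIC G*log(RSS/G) + 2(k+1), looping over all subsets of candidates.
oracle_best_subset <- function(y, X, blocks) {
  cand <- unique(blocks)
  p <- length(cand)
  G <- length(y)
  best_aic <- Inf
  best <- NULL
  for (m in 0:(2^p - 1)) {
    sel <- cand[bitwAnd(m, 2^(seq_len(p) - 1)) > 0]
    cols <- which(blocks %in% sel)
    d <- data.frame(y = y)
    if (length(cols)) d <- cbind(d, as.data.frame(X[, cols, drop = FALSE]))
    f <- stats::lm(y ~ ., data = d)
    rss <- sum(stats::residuals(f)^2)
    k <- length(cols)
    aic <- G * log(rss / G) + 2 * (k + 1)
    if (aic < best_aic - 1e-12 ||
        (abs(aic - best_aic) <= 1e-12 && length(sel) < length(best))) {
      best_aic <- aic
      best <- sel
    }
  }
  list(best = sort(best), aic = best_aic)
}

# Two-predictor-per-level scenario used in several tests.
toy_scenario <- function(...) {
  simulation_scenario(G = 30, group_size = 10,
                      sigma_xi = sqrt(0.3), sigma_upsilon = sqrt(0.7),
                      replicates = 10, seed = 42, ...)
}

# Plain quantitative two-level dataset with planted variable blocks,
# used by the clustering tests: variables within a block share a latent
# factor, blocks are independent.
blocky_data <- function(n = 120, block_sizes = c(3, 3), noise = 0.3,
                        seed = 11) {
  set.seed(seed)
  cols <- list()
  for (b in seq_along(block_sizes)) {
    f <- rnorm(n)
    for (j in seq_len(block_sizes[b])) {
      cols[[paste0("v", b, "_", j)]] <- f + rnorm(n, 0, noise)
    }
  }
  as.data.frame(cols)
}

quant_specs <- function(df, level = "individual") {
  lapply(names(df), variable_spec, level = level, type = "quantitative")
}
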