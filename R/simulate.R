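#' Define a micro-macro simulation scenario
#'
#' Describes one data-generating condition for the model
#' y_g = b0 + b1' z_g + b2' xi_g + eps_g with x_ig = xi_g + ups_ig.
#' Latent standardized scores for all predictors are drawn jointly
#' Gaussian, with correlation `rho_z_xi` between every group-level and
#' every individual-level latent score. Quantitative individual
#' predictors are xi_g = sigma_xi * latent plus N(0, sigma_upsilon)
#' within-group noise, so their intraclass correlation is
#' sigma_xi^2 / (sigma_xi^2 + sigma_upsilon^2). Binary predictors are
#' produced by probit-style thresholding of the latent scale at
#' prevalence 1/2: a binary group predictor is 1\{latent > 0\}; a binary
#' individual predictor has group-level success probability
#' p_g = Phi(gamma * latent_g), with gamma chosen in closed form
#' (gamma^2/(1+gamma^2) = sin(pi * icc / 2)) so that the observed binary
#' responses have intraclass correlation exactly `icc`; its latent
#' group score entering the outcome is p_g itself, and the Bernoulli
#' residual plays the role of ups_ig.
#'
#' @param G Number of groups.
#' @param group_size Either a single fixed group size or a length-2
#'   vector `(low, high)` sampled uniformly per group.
#' @param beta Named list or vector of true coefficients: intercept
#'   first, then one per predictor in `z_types` and `x_types` order.
#' @param z_types Character vector of group-level predictor types from
#'   `{"quantitative", "binary"}`; may be empty for a no-Z model.
#' @param x_types Character vector of individual-level predictor types.
#' @param sigma_xi SD of the latent group score of quantitative
#'   individual predictors.
#' @param sigma_upsilon Within-group SD of quantitative individual
#'   predictors.
#' @param sigma_eps SD of the group-level disturbance eps_g.
#' @param rho_z_xi Correlation between group-level and individual-level
#'   latent scores (|rho| < 1).
#' @param replicates Number of Monte-Carlo replicates for bias studies.
#' @param seed Root seed; replicate r uses an independent stream derived
#'   from `(seed, r)` so replicates are order-insensitive.
#' @param label Optional scenario label for reports.
#' @return An object of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(G = 30,
                                group_size = 10,
                                beta = c(0.2, 0.1, -0.1, 0.1, -0.05),
                                z_types = c("quantitative", "binary"),
                                x_types = c("quantitative", "binary"),
                                sigma_xi = sqrt(0.3),
                                sigma_upsilon = sqrt(0.7),
                                sigma_eps = 0.02,
                                rho_z_xi = 0,
                                replicates = 200,
                                seed = 1,
                                label = NULL) {
  stopifnot(G >= 3, sigma_xi >= 0, sigma_upsilon >= 0, sigma_eps >= 0,
            abs(rho_z_xi) < 1,
            length(group_size) %in% 1:2, all(group_size >= 1))
  z_types <- as.character(z_types)
  x_types <- as.character(x_types)
  stopifnot(all(c(z_types, x_types) %in% c("quantitative", "binary")),
            length(x_types) >= 1)
  npred <- length(z_types) + length(x_types)
  beta <- as.numeric(beta)
  if (length(beta) != npred + 1)
    stop("beta must have length 1 + #predictors = ", npred + 1)
  icc <- sigma_xi^2 / (sigma_xi^2 + sigma_upsilon^2)
  if (is.null(label))
    label <- sprintf("G%d_n%s_icc%.2f_rho%.1f", G,
                     paste(group_size, collapse = "-"), icc, rho_z_xi)
  structure(list(G = G, group_size = group_size, beta = beta,
                 z_types = z_types, x_types = x_types,
                 sigma_xi = sigma_xi, sigma_upsilon = sigma_upsilon,
                 sigma_eps = sigma_eps, rho_z_xi = rho_z_xi, icc = icc,
                 replicates = replicates, seed = seed, label = label),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat("<simulation_scenario> ", x$label, ": G=", x$G,
      ", n_g=", paste(x$group_size, collapse = "-"),
      ", ICC=", round(x$icc, 3), ", rho=", x$rho_z_xi,
      ", R=", x$replicates, "\n", sep = "")
  invisible(x)
}

# Independent per-replicate RNG stream: a deterministic 32-bit mix of the
# root seed and the replicate counter.
replicate_seed <- function(seed, replicate_index) {
  s <- (as.double(seed) * 48271 + as.double(replicate_index) * 16807) %%
    2147483629
  as.integer(s)
}

# gamma for the binary individual predictor: Var(Phi(gamma*U)) = icc/4.
binary_gamma <- function(icc) {
  if (icc <= 0) return(0)
  rho_star <- sin(pi * icc / 2)
  sqrt(rho_star / (1 - rho_star))
}

#' Simulate one micro-macro dataset
#'
#' Draws one dataset from a [simulation_scenario()]: latent group scores
#' and group predictors, individual-level measurements, and the
#' group-level outcome. Deterministic given `(scenario$seed,
#' replicate_index)`.
#'
#' @param scenario A `"simulation_scenario"`.
#' @param replicate_index Positive integer replicate counter.
#' @return A `"two_level_data"` pair whose macro table carries the
#'   outcome `outcome`, plus attribute `truth`: list with the true
#'   `beta` (named), the latent group scores `xi` used to build the
#'   outcome, and the coefficient `level` map.
#' @export
simulate_dataset <- function(scenario, replicate_index = 1) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(replicate_seed(scenario$seed, replicate_index))
  G <- scenario$G
  qz <- length(scenario$z_types)
  px <- length(scenario$x_types)
  d <- qz + px
  rho <- scenario$rho_z_xi

  # latent standardized scores: within-level independent, cross-level rho
  Sig <- diag(d)
  if (qz > 0 && px > 0)
    Sig[seq_len(qz), qz + seq_len(px)] <-
      Sig[qz + seq_len(px), seq_len(qz)] <- rho
  L <- chol(Sig)
  U <- matrix(stats::rnorm(G * d), G, d) %*% L

  n_g <- if (length(scenario$group_size) == 1)
    rep(scenario$group_size, G)
  else sample(seq(scenario$group_size[1], scenario$group_size[2]),
              G, replace = TRUE)
  gid <- sprintf("g%03d", seq_len(G))

  # group-level predictors
  zmat <- NULL
  if (qz > 0) {
    zmat <- sapply(seq_len(qz), function(j) {
      if (scenario$z_types[j] == "quantitative") U[, j]
      else as.numeric(U[, j] > 0)
    })
    zmat <- matrix(zmat, G, qz,
                   dimnames = list(NULL, paste0("z", seq_len(qz))))
  }

  # individual-level predictors and their latent group scores
  xi <- matrix(NA_real_, G, px,
               dimnames = list(NULL, paste0("x", seq_len(px))))
  micro_cols <- vector("list", px)
  gindex <- rep(seq_len(G), n_g)
  for (j in seq_len(px)) {
    u <- U[, qz + j]
    if (scenario$x_types[j] == "quantitative") {
      xi[, j] <- scenario$sigma_xi * u
      micro_cols[[j]] <- xi[gindex, j] +
        stats::rnorm(sum(n_g), 0, scenario$sigma_upsilon)
    } else {
      p_g <- stats::pnorm(binary_gamma(scenario$icc) * u)
      xi[, j] <- p_g
      micro_cols[[j]] <- as.numeric(stats::runif(sum(n_g)) < p_g[gindex])
    }
  }

  pred <- cbind(zmat, xi)
  beta <- scenario$beta
  y <- beta[1] + drop(pred %*% beta[-1]) +
    stats::rnorm(G, 0, scenario$sigma_eps)

  micro_df <- data.frame(group_id = gid[gindex],
                         stats::setNames(micro_cols, colnames(xi)),
                         check.names = FALSE)
  macro_df <- data.frame(group_id = gid, outcome = y, check.names = FALSE)
  if (qz > 0) macro_df <- cbind(macro_df, as.data.frame(zmat))

  specs <- c(
    lapply(seq_len(qz), function(j) variable_spec(
      paste0("z", j), "group", "quantitative")),
    lapply(seq_len(px), function(j) variable_spec(
      paste0("x", j), "individual", "quantitative"))
  )
  td <- two_level_data(
    micro_table(micro_df, specs),
    macro_table(macro_df, specs, outcome_col = "outcome")
  )
  names(beta) <- c("(Intercept)", colnames(pred))
  attr(td, "truth") <- list(
    beta = beta, xi = xi,
    level = stats::setNames(
      c(rep("group", qz), rep("individual", px)), colnames(pred))
  )
  td
}
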