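#' Observed group means of encoded individual-level predictors
#'
#' @param micro_enc An individual-level `"encoded_matrix"`.
#' @param group_ids Character vector of group ids, one per row of the
#'   encoded matrix.
#' @param group_order Optional character vector fixing the output order
#'   (typically the macro table's group order). Defaults to order of
#'   first appearance.
#' @return An object of class `"group_summaries"`: list with `group_id`,
#'   `n_g` (integer vector) and `xbar` (G x p matrix of group means).
#' @export
group_summaries <- function(micro_enc, group_ids, group_order = NULL) {
  X <- if (inherits(micro_enc, "encoded_matrix")) micro_enc$values else
    as.matrix(micro_enc)
  group_ids <- as.character(group_ids)
  stopifnot(nrow(X) == length(group_ids))
  if (is.null(group_order)) group_order <- unique(group_ids)
  if (!all(group_ids %in% group_order))
    stop("group ids not covered by group_order")
  f <- factor(group_ids, levels = group_order)
  n_g <- as.integer(table(f))
  if (any(n_g < 1)) stop("every group needs at least one row")
  xbar <- apply(X, 2, function(col) tapply(col, f, mean))
  xbar <- matrix(xbar, nrow = length(group_order),
                 dimnames = list(group_order, colnames(X)))
  structure(list(group_id = group_order, n_g = n_g, xbar = xbar),
            class = "group_summaries")
}

#' @export
print.group_summaries <- function(x, ...) {
  cat("<group_summaries> ", length(x$group_id), " groups, ",
      ncol(x$xbar), " predictors\n", sep = "")
  invisible(x)
}

#' Project a symmetric matrix onto the positive semidefinite cone
#'
#' Eigenvalue truncation at zero: negative eigenvalues are set to 0.
#' Moment-difference estimates of between-group covariance can be
#' indefinite in small samples; this repair keeps them usable as a
#' covariance.
#'
#' @param m Symmetric matrix.
#' @return The nearest-PSD truncation of `m` (same eigenvectors).
#' @export
psd_truncate <- function(m) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values >= 0)) return(m)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

#' ANOVA-type moment estimates for the micro-macro model
#'
#' Decomposes the encoded individual-level predictors into within-group
#' and latent between-group covariance components under the measurement
#' model x_ig = xi_g + upsilon_ig, and estimates the covariance of the
#' group-level predictors Z and their cross-covariance with the latent
#' group scores xi.
#'
#' The estimators are the classical one-way MANOVA moments:
#' \itemize{
#' \item `Sigma_within` = pooled within-group covariance,
#'   sum_g sum_i (x_ig - xbar_g)(x_ig - xbar_g)' / (N - G), estimating
#'   Var(upsilon).
#' \item `S_between` = sum_g n_g (xbar_g - mu_x)(xbar_g - mu_x)' / (G - 1).
#' \item `c_anova` = (N - sum_g n_g^2 / N) / (G - 1), the unbalanced-design
#'   scaling constant (equal to n for balanced designs).
#' \item `Sigma_between_latent` = (S_between - Sigma_within) / c_anova,
#'   PSD-repaired by [psd_truncate()], estimating Var(xi).
#' }
#' The grand mean `mu_x` is individual-weighted (sum x_ig / N), matching
#' these moment identities. The Z/xi cross-covariance is the group-level
#' sample covariance of z_g with xbar_g (valid because upsilon is
#' independent of Z); each group counts once by default, with optional
#' n_g weighting.
#'
#' @param summaries A `"group_summaries"` object.
#' @param micro_enc The individual-level `"encoded_matrix"` the summaries
#'   were computed from.
#' @param group_ids Group id per row of `micro_enc`.
#' @param macro_z Optional group-level `"encoded_matrix"` (rows in the
#'   order of `summaries$group_id`), or `NULL` for a no-Z model.
#' @param weight_cross If `TRUE`, weight groups by n_g in the Z moments.
#' @return An object of class `"moment_estimates"`.
#' @export
estimate_moments <- function(summaries, micro_enc, group_ids,
                             macro_z = NULL, weight_cross = FALSE) {
  X <- if (inherits(micro_enc, "encoded_matrix")) micro_enc$values else
    as.matrix(micro_enc)
  G <- length(summaries$group_id)
  n_g <- summaries$n_g
  N <- sum(n_g)
  if (G < 3) stop("insufficient data: need at least 3 groups")
  if (N - G < 1) stop("insufficient data: no within-group replication (N = G)")
  f <- factor(as.character(group_ids), levels = summaries$group_id)
  mu_x <- colMeans(X)

  centered_within <- X - summaries$xbar[as.integer(f), , drop = FALSE]
  Sigma_within <- crossprod(centered_within) / (N - G)

  dev <- sweep(summaries$xbar, 2, mu_x)
  S_between <- crossprod(sweep(dev, 1, sqrt(n_g), `*`)) / (G - 1)
  c_anova <- (N - sum(n_g^2) / N) / (G - 1)
  Sigma_between_latent <- psd_truncate((S_between - Sigma_within) / c_anova)

  mu_z <- NULL; Sigma_z <- NULL; Sigma_z_xi <- NULL
  if (!is.null(macro_z)) {
    Z <- if (inherits(macro_z, "encoded_matrix")) macro_z$values else
      as.matrix(macro_z)
    stopifnot(nrow(Z) == G)
    w <- if (weight_cross) n_g / sum(n_g) * G else rep(1, G)
    mu_z <- colSums(Z * w) / sum(w)
    zc <- sweep(Z, 2, mu_z)
    Sigma_z <- crossprod(zc * sqrt(w)) / (sum(w) - 1)
    # cross-covariance of z_g with xbar_g estimates Cov(z, xi)
    xc <- sweep(summaries$xbar, 2, colMeans(summaries$xbar))
    Sigma_z_xi <- crossprod(zc * w, xc) / (sum(w) - 1)
  }

  structure(
    list(mu_x = mu_x, mu_z = mu_z,
         Sigma_within = Sigma_within,
         S_between = S_between,
         Sigma_between_latent = Sigma_between_latent,
         Sigma_z = Sigma_z, Sigma_z_xi = Sigma_z_xi,
         c_anova = c_anova, G = G, N = N, n_g = n_g),
    class = "moment_estimates"
  )
}

#' @export
print.moment_estimates <- function(x, ...) {
  cat("<moment_estimates> G=", x$G, " N=", x$N,
      " c_anova=", signif(x$c_anova, 5), "\n", sep = "")
  cat("  tr(Sigma_within)=", signif(sum(diag(x$Sigma_within)), 5),
      " tr(Sigma_xi)=", signif(sum(diag(x$Sigma_between_latent)), 5),
      "\n", sep = "")
  invisible(x)
}
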