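#' Latent-variable-adjusted group means
#'
#' Replaces each observed group mean xbar_g by the best linear predictor
#' of the latent group score xi_g given all observed group-level
#' information (z_g, xbar_g):
#' \deqn{\tilde x_g = \hat\mu_x + [\hat\Sigma_{\xi z}\;\hat\Sigma_\xi]\,
#'   V_g^{-1} \begin{pmatrix} z_g - \hat\mu_z \\ \bar x_g - \hat\mu_x
#'   \end{pmatrix}}
#' where V_g is the joint covariance of (z_g, xbar_g), with lower-right
#' block \eqn{\hat\Sigma_\xi + \hat\Sigma_\upsilon / n_g} and
#' off-diagonal blocks \eqn{\hat\Sigma_{z\xi}}. With no Z this reduces to
#' shrinkage of xbar_g toward the grand mean with weight
#' \eqn{W_g = \hat\Sigma_\xi(\hat\Sigma_\xi + \hat\Sigma_\upsilon/n_g)^{-1}},
#' so small groups are shrunk more. The adjusted mean is the expected
#' value of the latent group score given the data, and substituting it
#' for the observed mean removes the attenuation bias of naive
#' group-mean regression.
#'
#' @param moments A `"moment_estimates"` object.
#' @param summaries The `"group_summaries"` the moments were built from.
#' @param macro_z Optional group-level `"encoded_matrix"` (same row
#'   order); `NULL` for a no-Z model.
#' @return An object of class `"adjusted_means"`: list with `group_id`,
#'   `xtilde` (G x p matrix), and `shrinkage` (per-group singular values
#'   of the weight on the xbar block, a diagnostic of how strongly each
#'   group is shrunk; values near 1 mean little shrinkage).
#' @export
adjust_means <- function(moments, summaries, macro_z = NULL) {
  xbar <- summaries$xbar
  n_g <- summaries$n_g
  G <- nrow(xbar)
  p <- ncol(xbar)
  Sxi <- moments$Sigma_between_latent
  Sw <- moments$Sigma_within
  mu_x <- moments$mu_x

  has_z <- !is.null(macro_z)
  if (has_z) {
    Z <- if (inherits(macro_z, "encoded_matrix")) macro_z$values else
      as.matrix(macro_z)
    stopifnot(nrow(Z) == G)
    q <- ncol(Z)
    Szz <- moments$Sigma_z
    Szxi <- moments$Sigma_z_xi            # q x p
    mu_z <- moments$mu_z
    A <- cbind(t(Szxi), Sxi)              # p x (q + p)
  } else {
    q <- 0L
    A <- Sxi
  }

  xtilde <- matrix(NA_real_, G, p, dimnames = dimnames(xbar))
  shrinkage <- matrix(NA_real_, G, p)
  warned <- FALSE
  for (g in seq_len(G)) {
    Vxx <- Sxi + Sw / n_g[g]
    if (has_z) {
      V <- rbind(cbind(Szz, Szxi), cbind(t(Szxi), Vxx))
      d <- c(Z[g, ] - mu_z, xbar[g, ] - mu_x)
    } else {
      V <- Vxx
      d <- xbar[g, ] - mu_x
    }
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(Vi) || !all(is.finite(Vi))) {
      eps <- 1e-8 * sum(diag(V)) / nrow(V)
      Vi <- solve(V + diag(eps, nrow(V)))
      if (!warned) {
        warning("singular joint covariance V_g; ridge fallback applied")
        warned <- TRUE
      }
    }
    W <- A %*% Vi                          # p x (q + p)
    xtilde[g, ] <- mu_x + drop(W %*% d)
    Wx <- W[, q + seq_len(p), drop = FALSE]
    shrinkage[g, ] <- svd(Wx, nu = 0, nv = 0)$d
  }
  structure(list(group_id = summaries$group_id, xtilde = xtilde,
                 shrinkage = shrinkage),
            class = "adjusted_means")
}

#' @export
print.adjusted_means <- function(x, ...) {
  cat("<adjusted_means> ", nrow(x$xtilde), " groups, ",
      ncol(x$xtilde), " predictors; median shrinkage weight ",
      signif(stats::median(x$shrinkage), 3), "\n", sep = "")
  invisible(x)
}
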