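#' Exhaustive best-subset regression by AIC
#'
#' Enumerates subsets of the candidate predictors (including the empty,
#' intercept-only model), fits each by ordinary least squares with an
#' intercept, and returns the subset minimizing
#' `AIC = G * log(RSS / G) + 2 * (k + 1)` where G is the number of
#' groups and k the number of regressors in the subset. Additive
#' constants of the Gaussian log-likelihood are dropped consistently, so
#' only AIC differences matter. Dummy columns originating from one
#' source variable enter and leave together, so a qualitative predictor
#' is selected as a whole. Subsets whose regressor count leaves no
#' residual degree of freedom (k + 1 >= G - 1) are never examined: their
#' residual sum of squares is degenerate and their AIC meaningless.
#' Ties are broken toward fewer candidates, then lexicographically —
#' the search is deterministic.
#'
#' @param y Numeric outcome vector (one value per group).
#' @param design Numeric matrix of candidate columns (e.g. the encoded Z
#'   block cbind-ed with adjusted individual-level means), or an
#'   `"encoded_matrix"`.
#' @param blocks Character vector, one entry per design column, naming
#'   the source variable of each column. Columns sharing a name move as
#'   one candidate. Defaults to the encoded column map when `design` is
#'   an `"encoded_matrix"`, else to one candidate per column.
#' @param max_size Optional cap on the number of candidates per subset.
#'   Required when more than 25 candidates would otherwise be
#'   enumerated exhaustively.
#' @param keep Number of best subsets retained in the returned AIC
#'   table (the search itself always covers every examined subset).
#' @return An object of class `"subset_selection"`: list with
#'   `candidates`, `best_subset` (character vector of selected candidate
#'   names), `aic_best`, `n_examined`, and `aic_table` (data frame of
#'   the `keep` best subsets with their AIC, ordered by AIC).
#' @export
best_subset <- function(y, design, blocks = NULL, max_size = NULL,
                        keep = 100) {
  if (inherits(design, "encoded_matrix")) {
    if (is.null(blocks)) blocks <- design$column_map$variable
    design <- design$values
  }
  design <- as.matrix(design)
  y <- as.numeric(y)
  G <- length(y)
  stopifnot(nrow(design) == G)
  if (is.null(blocks)) {
    blocks <- colnames(design)
    if (is.null(blocks)) blocks <- paste0("v", seq_len(ncol(design)))
  }
  stopifnot(length(blocks) == ncol(design))
  candidates <- unique(blocks)
  p <- length(candidates)
  if (p > 25 && is.null(max_size))
    stop("refusing exhaustive search over ", p,
         " candidates (2^p too large); supply max_size")
  col_of <- lapply(candidates, function(v) which(blocks == v))
  ncols <- lengths(col_of)
  max_k <- if (is.null(max_size)) p else min(max_size, p)

  subsets <- list()
  aic <- numeric()
  nvar <- integer()
  for (k in 0:max_k) {
    combos <- if (k == 0) list(integer(0)) else
      utils::combn(p, k, simplify = FALSE)
    for (sel in combos) {
      cols <- unlist(col_of[sel], use.names = FALSE)
      if (length(cols) + 1 >= G - 1) next  # no residual df
      Xs <- cbind(1, design[, cols, drop = FALSE])
      fit <- stats::lm.fit(Xs, y)
      rss <- sum(fit$residuals^2)
      kk <- ncol(Xs) - 1L
      subsets[[length(subsets) + 1L]] <- sel
      aic[length(aic) + 1L] <- G * log(rss / G) + 2 * (kk + 1)
      nvar[length(nvar) + 1L] <- length(sel)
    }
  }
  if (!length(aic))
    stop("no admissible subset (too few groups for any candidate)")
  labs <- vapply(subsets, function(sel)
    paste(candidates[sel], collapse = "+"), character(1))
  ord <- order(aic, nvar, labs)
  best_idx <- ord[1]
  top <- utils::head(ord, keep)
  tab <- data.frame(subset = labs[top], n_candidates = nvar[top],
                    aic = aic[top], stringsAsFactors = FALSE)
  best_subset <- candidates[subsets[[best_idx]]]
  structure(list(candidates = candidates, best_subset = best_subset,
                 aic_best = aic[best_idx], n_examined = length(aic),
                 aic_table = tab),
            class = "subset_selection")
}

#' @export
print.subset_selection <- function(x, ...) {
  cat("<subset_selection> ", length(x$candidates), " candidates, ",
      x$n_examined, " subsets examined, best AIC ",
      signif(x$aic_best, 6), "\n  selected: ",
      if (length(x$best_subset)) paste(x$best_subset, collapse = ", ")
      else "(intercept only)", "\n", sep = "")
  invisible(x)
}
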