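#' Bootstrap stability of variable-cluster partitions
#'
#' Resamples observations with replacement, rebuilds the variable-cluster
#' tree on each bootstrap sample, and scores the agreement between the
#' original K-cluster partition and each replicate's K-cluster partition
#' with the adjusted Rand index (corrected for chance, so 0 is the
#' chance level and 1 is identity). The recommended number of clusters
#' is the K with the highest mean agreement, ties broken toward the
#' smallest K. K = 1 is a degenerate single-cluster partition whose
#' agreement is 1 by convention, so the default range starts at 2.
#'
#' @param table A `micro_table`, `macro_table`, or data frame.
#' @param specs Variable specs; default taken from the table.
#' @param level `"individual"` or `"group"` (inferred when possible).
#' @param K_range Integer vector of cluster counts to score; default
#'   `2:(p - 1)`.
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Integer seed for the resampling.
#' @return An object of class `"stability_curve"`: list with `K_range`,
#'   `mean_agreement` (per K), `agreement` (B x |K_range| matrix),
#'   `recommended_K`, `B`, `seed`, and `skipped` (replicates dropped
#'   because a variable was constant in the resample).
#' @export
stability <- function(table, specs = attr(table, "specs"), level = NULL,
                      K_range = NULL, B = 50, seed = 1) {
  stopifnot(B >= 2)
  if (is.null(level)) {
    level <- if (inherits(table, "micro_table")) "individual"
             else if (inherits(table, "macro_table")) "group"
             else stop("supply level for a plain data frame")
  }
  sp <- specs_at_level(specs, level)
  p <- length(sp)
  if (is.null(K_range)) K_range <- seq(2L, max(2L, p - 1L))
  K_range <- sort(unique(as.integer(K_range)))
  stopifnot(all(K_range >= 1), all(K_range <= p))

  base_tree <- cluster_variables(table, specs, level)
  base_parts <- lapply(K_range, function(K)
    cut_tree(base_tree, K)$assignment[base_tree$labels])

  df <- as.data.frame(table)
  n <- nrow(df)
  agreement <- matrix(NA_real_, B, length(K_range),
                      dimnames = list(NULL, paste0("K", K_range)))
  skipped <- 0L
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- df[idx, , drop = FALSE]
    tree_b <- tryCatch(
      withCallingHandlers(
        cluster_variables(boot, specs, level),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(tree_b) || length(tree_b$labels) != p) {
      skipped <- skipped + 1L
      next
    }
    for (j in seq_along(K_range)) {
      K <- K_range[j]
      if (K == 1) { agreement[b, j] <- 1; next }
      part_b <- cut_tree(tree_b, K)$assignment[base_tree$labels]
      agreement[b, j] <- mclust::adjustedRandIndex(base_parts[[j]], part_b)
    }
  }
  if (skipped) message(skipped, " degenerate bootstrap replicate(s) skipped")
  mean_agreement <- colMeans(agreement, na.rm = TRUE)
  recommended_K <- K_range[which.max(mean_agreement)]
  structure(list(K_range = K_range, mean_agreement = mean_agreement,
                 agreement = agreement, recommended_K = recommended_K,
                 B = B, seed = seed, skipped = skipped),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat("<stability_curve> B=", x$B, ", recommended K=", x$recommended_K,
      "\n", sep = "")
  print(round(x$mean_agreement, 3))
  invisible(x)
}
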