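#' Full micro-macro analysis pipeline
#'
#' Orchestrates the complete workflow on a validated two-level dataset:
#' \enumerate{
#' \item cluster the variables of each level into correlated groups
#'   ([cluster_variables()]), choosing the number of clusters by
#'   bootstrap stability ([stability()]) unless fixed by the caller;
#' \item keep one representative variable per cluster
#'   ([pick_representatives()]), honoring substantive overrides;
#' \item encode the representatives ([encode()]), estimate the
#'   within/between moments ([estimate_moments()]) and replace observed
#'   group means by latent-adjusted means ([adjust_means()]);
#' \item search all predictor subsets by AIC ([best_subset()]);
#' \item fit the final group-level regression with
#'   heteroscedasticity-consistent inference ([fit_micro_macro()]).
#' }
#'
#' @param data A `"two_level_data"` object (see [read_two_level()]).
#' @param specs Variable specs for both levels; defaults to the specs
#'   attached to the tables.
#' @param K_individual,K_group Fixed cluster counts per level; `NULL`
#'   (default) picks them by bootstrap stability.
#' @param B Bootstrap replicates for the stability curves.
#' @param overrides Character vector of variable names forced as
#'   cluster representatives (any level).
#' @param hc_type,reference Passed to [fit_micro_macro()].
#' @param max_size Optional cap on subset size in the AIC search.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `"micro_macro_analysis"`: list with
#'   `trees`, `stability`, `partitions`, `representatives`, `moments`,
#'   `adjusted`, `selection`, `fit` (final `"micro_macro_fit"`),
#'   `naive_fit`, and `config`.
#' @export
run_pipeline <- function(data, specs = NULL,
                         K_individual = NULL, K_group = NULL,
                         B = 50, overrides = NULL,
                         hc_type = "HC3", reference = "t",
                         max_size = NULL, seed = 1) {
  stopifnot(inherits(data, "two_level_data"))
  micro <- data$micro
  macro <- data$macro
  if (is.null(specs))
    specs <- c(attr(micro, "specs"), attr(macro, "specs"))

  pick_level <- function(table, level, K_fixed) {
    tree <- cluster_variables(table, specs, level)
    p <- length(tree$labels)
    stab <- NULL
    K <- K_fixed
    if (is.null(K)) {
      if (p <= 2) {
        K <- p
      } else {
        stab <- stability(table, specs, level, B = B, seed = seed)
        K <- stab$recommended_K
      }
    }
    part <- cut_tree(tree, K)
    reps <- pick_representatives(part, overrides = intersect(
      if (is.null(overrides)) character(0) else overrides,
      tree$labels))
    list(tree = tree, stability = stab, partition = part, reps = reps)
  }

  ind <- pick_level(micro, "individual", K_individual)
  grp <- pick_level(macro, "group", K_group)

  specs_ind <- specs[spec_names(specs) %in% ind$reps &
                       vapply(specs, `[[`, character(1), "level") ==
                       "individual"]
  specs_grp <- specs[spec_names(specs) %in% grp$reps &
                       vapply(specs, `[[`, character(1), "level") == "group"]

  menc <- encode(micro, specs_ind)
  zenc <- encode(macro, specs_grp)
  gcol <- attr(micro, "group_col")
  gs <- group_summaries(menc, micro[[gcol]],
                        macro[[attr(macro, "group_col")]])
  mom <- estimate_moments(gs, menc, micro[[gcol]], macro_z = zenc)
  adj <- adjust_means(mom, gs, macro_z = zenc)
  y <- macro[[attr(macro, "outcome_col")]]

  candidate <- cbind(zenc$values, adj$xtilde)
  blocks <- c(zenc$column_map$variable,
              menc$column_map$variable)
  # with G groups, models beyond ~G/3 predictors are essentially
  # saturated; cap the exhaustive search there (and at a bounded number
  # of examined subsets) unless the caller says otherwise
  if (is.null(max_size)) {
    p_cand <- length(unique(blocks))
    max_size <- max(2L, min(p_cand, floor(length(y) / 3)))
    while (max_size > 2 &&
           sum(choose(p_cand, 0:max_size)) > 2e5)
      max_size <- max_size - 1L
  }
  sel <- best_subset(y, candidate, blocks = blocks, max_size = max_size)

  zsel <- zenc$column_map$variable %in% sel$best_subset
  xsel <- menc$column_map$variable %in% sel$best_subset
  fit <- fit_micro_macro(
    y,
    macro_z = if (any(zsel)) zenc$values[, zsel, drop = FALSE] else NULL,
    adjusted = if (any(xsel)) adj$xtilde[, xsel, drop = FALSE] else NULL,
    hc_type = hc_type, reference = reference)
  nfit <- fit_micro_macro(
    y,
    macro_z = if (any(zsel)) zenc$values[, zsel, drop = FALSE] else NULL,
    adjusted = if (any(xsel)) gs$xbar[, xsel, drop = FALSE] else NULL,
    hc_type = hc_type, reference = reference)

  structure(
    list(trees = list(individual = ind$tree, group = grp$tree),
         stability = list(individual = ind$stability, group = grp$stability),
         partitions = list(individual = ind$partition,
                           group = grp$partition),
         representatives = list(individual = ind$reps, group = grp$reps),
         moments = mom, adjusted = adj, summaries = gs,
         selection = sel, fit = fit, naive_fit = nfit,
         config = list(K_individual = ind$partition$K,
                       K_group = grp$partition$K, B = B,
                       overrides = overrides, hc_type = hc_type,
                       reference = reference, seed = seed)),
    class = "micro_macro_analysis"
  )
}

#' @export
print.micro_macro_analysis <- function(x, ...) {
  cat("Micro-macro analysis\n")
  cat("  clusters: ", x$config$K_individual, " individual-level, ",
      x$config$K_group, " group-level\n", sep = "")
  cat("  selected: ", paste(x$selection$best_subset, collapse = ", "),
      "\n\n", sep = "")
  print(x$fit)
  invisible(x)
}

# stable short checksum of the configuration, written into reports so
# two runs are comparable at a glance
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write pipeline reports as delimited text
#'
#' Emits the coefficient table (estimate, 95% CI, p, classical and
#' corrected SE), the examined-subset AIC table, the cluster
#' assignments and Newick dendrograms, the stability curves, and a run
#' log carrying the seed and a configuration checksum.
#'
#' @param analysis A `"micro_macro_analysis"`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_reports <- function(analysis, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[name] <<- p
  }
  w(coef_table(analysis$fit), "coefficients.csv")
  w(utils::head(analysis$selection$aic_table, 50), "selection_aic.csv")
  for (lvl in c("individual", "group")) {
    part <- analysis$partitions[[lvl]]
    w(data.frame(variable = names(part$assignment),
                 cluster = unname(part$assignment),
                 representative = names(part$assignment) %in%
                   analysis$representatives[[lvl]]),
      paste0("clusters_", lvl, ".csv"))
    nw <- file.path(out_dir, paste0("dendrogram_", lvl, ".nwk"))
    writeLines(to_newick(analysis$trees[[lvl]]), nw)
    paths[basename(nw)] <- nw
    st <- analysis$stability[[lvl]]
    if (!is.null(st))
      w(data.frame(K = st$K_range, mean_agreement = st$mean_agreement),
        paste0("stability_", lvl, ".csv"))
  }
  log <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste("config_hash:", config_hash(analysis$config)),
    paste("seed:", analysis$config$seed),
    paste("r_version:", R.version.string),
    paste("selected:", paste(analysis$selection$best_subset,
                             collapse = ", ")),
    paste("r_squared:", format(analysis$fit$r_squared, digits = 6))
  ), log)
  paths["run_log.txt"] <- log
  invisible(paths)
}
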