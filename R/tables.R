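#' Two-level tables
#'
#' `micro_table()` and `macro_table()` validate plain data frames as the
#' individual-level and group-level halves of a micro-macro dataset, and
#' [read_two_level()] builds the validated pair from two delimited files.
#'
#' @name two_level
NULL

#' Validate an individual-level table
#'
#' @param data Data frame, one row per individual.
#' @param specs List of [variable_spec()]s; only `level = "individual"`
#'   entries are used.
#' @param group_col Name of the group-identifier column.
#' @return `data`, classed `"micro_table"`, with attributes `group_col`
#'   and `specs`. Rows with missing values in declared covariates are
#'   dropped listwise with a warning stating the count.
#' @export
micro_table <- function(data, specs, group_col = "group_id") {
  specs <- specs_at_level(specs, "individual")
  data <- as.data.frame(data)
  if (!group_col %in% names(data))
    stop("group column '", group_col, "' not found in individual table")
  data[[group_col]] <- trimws(as.character(data[[group_col]]))
  check_spec_columns(data, specs, "individual")
  keep <- stats::complete.cases(data[spec_names(specs)])
  if (!all(keep)) {
    warning(sum(!keep), " individual row(s) with missing covariate values ",
            "dropped (listwise deletion)")
    data <- data[keep, , drop = FALSE]
  }
  validate_values(data, specs, "individual")
  small <- table(data[[group_col]])
  if (any(small < 2))
    warning("group(s) reduced to fewer than 2 individuals: ",
            paste(names(small)[small < 2], collapse = ", "))
  rownames(data) <- NULL
  structure(data, group_col = group_col, specs = specs,
            class = c("micro_table", "data.frame"))
}

#' Validate a group-level table
#'
#' @param data Data frame, one row per group.
#' @param specs List of [variable_spec()]s; only `level = "group"`
#'   entries are used.
#' @param group_col Name of the group-identifier column (must be unique).
#' @param outcome_col Name of the quantitative outcome column.
#' @return `data`, classed `"macro_table"`, with attributes `group_col`,
#'   `outcome_col` and `specs`.
#' @export
macro_table <- function(data, specs, group_col = "group_id",
                        outcome_col = "outcome") {
  specs <- specs_at_level(specs, "group")
  data <- as.data.frame(data)
  for (col in c(group_col, outcome_col))
    if (!col %in% names(data))
      stop("column '", col, "' not found in group table")
  data[[group_col]] <- trimws(as.character(data[[group_col]]))
  if (anyDuplicated(data[[group_col]]))
    stop("duplicate group identifiers in group table: ",
         paste(unique(data[[group_col]][duplicated(data[[group_col]])]),
               collapse = ", "))
  y <- data[[outcome_col]]
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("outcome '", outcome_col, "' must be finite and numeric for every group")
  if (nrow(data) < 3) stop("need at least 3 groups")
  check_spec_columns(data, specs, "group")
  validate_values(data, specs, "group")
  rownames(data) <- NULL
  structure(data, group_col = group_col, outcome_col = outcome_col,
            specs = specs, class = c("macro_table", "data.frame"))
}

check_spec_columns <- function(data, specs, level) {
  missing_cols <- setdiff(spec_names(specs), names(data))
  if (length(missing_cols))
    stop("schema error: ", level, "-level spec column(s) not in table: ",
         paste(missing_cols, collapse = ", "))
  invisible(TRUE)
}

validate_values <- function(data, specs, level) {
  for (s in specs) {
    v <- data[[s$name]]
    if (is_quantitative(s)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop("parse error: non-numeric value in quantitative column '",
             s$name, "' at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    } else {
      lab <- as.character(v)
      unseen <- setdiff(unique(lab[!is.na(lab)]), s$categories)
      if (length(unseen))
        stop("encoding error: value(s) not in categories of '", s$name,
             "': ", paste(unseen, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Read and pair individual- and group-level tables
#'
#' Reads two delimited text files (header row mandatory), validates them
#' against the variable specs, and cross-checks the group key: every
#' individual must belong to a listed group, and groups without any
#' individuals are dropped from the group table with a warning. Group
#' keys are matched by exact string equality after whitespace trimming.
#'
#' @param individual_path,group_path Paths to delimited files.
#' @param specs List of [variable_spec()]s covering both levels.
#' @param group_col Name of the shared group-key column.
#' @param outcome_col Name of the outcome column in the group file.
#' @param sep Field delimiter, default comma.
#' @return An object of class `"two_level_data"`: a list with elements
#'   `micro` (a `micro_table`), `macro` (a `macro_table`), and `n_g`
#'   (named integer vector of group sizes, in macro row order).
#' @export
read_two_level <- function(individual_path, group_path, specs,
                           group_col = "group_id", outcome_col = "outcome",
                           sep = ",") {
  for (p in c(individual_path, group_path))
    if (!file.exists(p)) stop("file not found: ", p)
  ind <- utils::read.table(individual_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  grp <- utils::read.table(group_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  micro <- micro_table(ind, specs, group_col = group_col)
  macro <- macro_table(grp, specs, group_col = group_col,
                       outcome_col = outcome_col)
  two_level_data(micro, macro)
}

#' Pair validated micro and macro tables
#'
#' @param micro A `micro_table`.
#' @param macro A `macro_table`.
#' @return A `"two_level_data"` list; see [read_two_level()].
#' @export
two_level_data <- function(micro, macro) {
  gcol_i <- attr(micro, "group_col")
  gcol_g <- attr(macro, "group_col")
  gi <- micro[[gcol_i]]
  gg <- macro[[gcol_g]]
  orphan <- setdiff(gi, gg)
  if (length(orphan))
    stop("individual rows reference unknown group(s): ",
         paste(orphan, collapse = ", "))
  empty <- setdiff(gg, gi)
  if (length(empty)) {
    warning("dropping ", length(empty), " group(s) with no individuals: ",
            paste(empty, collapse = ", "))
    at <- attributes(macro)[c("group_col", "outcome_col", "specs", "class")]
    macro <- macro[!(gg %in% empty), , drop = FALSE]
    rownames(macro) <- NULL
    attributes(macro)[names(at)] <- at
    gg <- macro[[gcol_g]]
  }
  if (nrow(macro) < 2) stop("need at least 2 non-empty groups")
  n_g <- as.integer(table(factor(gi, levels = gg)))
  names(n_g) <- gg
  structure(list(micro = micro, macro = macro, n_g = n_g),
            class = "two_level_data")
}

#' @export
print.two_level_data <- function(x, ...) {
  cat("<two_level_data> ", nrow(x$micro), " individuals in ",
      nrow(x$macro), " groups (sizes ", min(x$n_g), "-", max(x$n_g),
      ")\n", sep = "")
  invisible(x)
}

#' @export
print.micro_table <- function(x, ...) {
  cat("<micro_table> ", nrow(x), " rows, ",
      length(attr(x, "specs")), " declared covariates\n", sep = "")
  NextMethod()
}

#' @export
print.macro_table <- function(x, ...) {
  cat("<macro_table> ", nrow(x), " groups, outcome '",
      attr(x, "outcome_col"), "'\n", sep = "")
  NextMethod()
}
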