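#' Dummy-code a two-level table into a numeric design block
#'
#' Quantitative columns pass through unchanged. A binary variable becomes
#' one 0/1 indicator (reference category coded 0). A nominal or ordinal
#' variable with n modalities becomes n-1 indicator columns, omitting the
#' reference category. The mapping back to source variables is retained so
#' the encoding is invertible and so downstream selection can keep the
#' dummy block of one variable together.
#'
#' @param table A `micro_table` or `macro_table` (or plain data frame).
#' @param specs List of [variable_spec()]s; defaults to the specs stored
#'   on the table. Only specs matching the table's level are used when
#'   the table carries a level.
#' @return An object of class `"encoded_matrix"`: list with `values`
#'   (numeric matrix, one row per input row), `column_map` (data frame
#'   with columns `column`, `variable`, `category`; `category` is `NA`
#'   for passed-through quantitative columns), and `level`.
#' @examples
#' sp <- list(variable_spec("skip", "individual", "binary",
#'                          categories = c("no", "yes")))
#' d <- data.frame(group_id = c("a", "a", "b"), skip = c("no", "yes", "yes"))
#' encode(micro_table(d, sp))$values
#' @export
encode <- function(table, specs = attr(table, "specs")) {
  if (is.null(specs)) stop("no variable specs supplied or attached")
  level <- if (inherits(table, "micro_table")) "individual"
           else if (inherits(table, "macro_table")) "group"
           else unique(vapply(specs, `[[`, character(1), "level"))
  if (length(level) != 1L)
    stop("cannot infer level: supply specs from a single level")
  specs <- specs_at_level(specs, level)
  if (!length(specs)) stop("no ", level, "-level specs to encode")
  check_spec_columns(table, specs, level)
  validate_values(table, specs, level)

  cols <- list()
  map <- list()
  for (s in specs) {
    v <- table[[s$name]]
    if (is_quantitative(s)) {
      cols[[length(cols) + 1L]] <- as.numeric(v)
      map[[length(map) + 1L]] <- data.frame(
        column = s$name, variable = s$name, category = NA_character_,
        stringsAsFactors = FALSE)
    } else {
      lab <- as.character(v)
      for (cat in setdiff(s$categories, s$reference)) {
        cols[[length(cols) + 1L]] <- as.numeric(lab == cat)
        cname <- if (s$type == "binary") s$name else paste0(s$name, ".", cat)
        map[[length(map) + 1L]] <- data.frame(
          column = cname, variable = s$name, category = cat,
          stringsAsFactors = FALSE)
      }
    }
  }
  column_map <- do.call(rbind, map)
  values <- do.call(cbind, cols)
  colnames(values) <- column_map$column
  structure(list(values = values, column_map = column_map, level = level,
                 specs = specs),
            class = "encoded_matrix")
}

#' Invert an encoding back to source variables
#'
#' Reconstructs the original columns (numeric for quantitative variables,
#' character labels for qualitative ones) from an encoded matrix.
#'
#' @param encoded An `"encoded_matrix"`.
#' @return A data frame with one column per source variable.
#' @export
decode <- function(encoded) {
  stopifnot(inherits(encoded, "encoded_matrix"))
  out <- list()
  for (s in encoded$specs) {
    if (is_quantitative(s)) {
      out[[s$name]] <- encoded$values[, s$name]
    } else {
      idx <- which(encoded$column_map$variable == s$name)
      block <- encoded$values[, idx, drop = FALSE]
      cats <- encoded$column_map$category[idx]
      lab <- rep(s$reference, nrow(block))
      for (j in seq_along(idx)) lab[block[, j] == 1] <- cats[j]
      out[[s$name]] <- lab
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat("<encoded_matrix> ", nrow(x$values), " x ", ncol(x$values),
      " (", x$level, " level)\n", sep = "")
  invisible(x)
}
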