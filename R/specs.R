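#' Declare a variable for two-level analysis
#'
#' A variable spec records where a covariate lives (individual or group
#' level), how it is typed, and — for qualitative variables — its category
#' labels and reference category. Specs drive validation on ingestion and
#' dummy coding in [encode()].
#'
#' @param name Column name in the individual- or group-level table.
#' @param level `"individual"` or `"group"`.
#' @param type One of `"quantitative"`, `"binary"`, `"nominal"`,
#'   `"ordinal"`. Ordinal items scored with small integer codes (e.g. a
#'   0-3 never/very-often item) may equally be declared `"quantitative"`
#'   to enter the model through their codes.
#' @param categories Character vector of category labels, in order.
#'   Required for qualitative types, must be empty for quantitative.
#' @param reference Reference category (qualitative only). Defaults to
#'   the first category.
#' @return An object of class `"variable_spec"`.
#' @examples
#' variable_spec("stress", "individual", "quantitative")
#' variable_spec("icu_type", "group", "nominal",
#'               categories = c("medical", "surgical", "polyvalent"))
#' @export
variable_spec <- function(name,
                          level = c("individual", "group"),
                          type = c("quantitative", "binary", "nominal", "ordinal"),
                          categories = character(),
                          reference = NULL) {
  level <- match.arg(level)
  type <- match.arg(type)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  categories <- as.character(categories)
  if (type == "quantitative") {
    if (length(categories) > 0L)
      stop("quantitative variable '", name, "' must not declare categories")
    reference <- NULL
  } else {
    if (type == "binary" && length(categories) != 2L)
      stop("binary variable '", name, "' needs exactly 2 categories")
    if (type != "binary" && length(categories) < 2L)
      stop(type, " variable '", name, "' needs at least 2 categories")
    if (anyDuplicated(categories))
      stop("duplicate categories for '", name, "'")
    if (is.null(reference)) reference <- categories[1L]
    if (!reference %in% categories)
      stop("reference category '", reference, "' of '", name,
           "' is not among its categories")
  }
  structure(
    list(name = name, level = level, type = type,
         categories = categories, reference = reference),
    class = "variable_spec"
  )
}

#' @export
print.variable_spec <- function(x, ...) {
  cat("<variable_spec> ", x$name, " [", x$level, ", ", x$type, "]", sep = "")
  if (length(x$categories))
    cat(" {", paste(x$categories, collapse = ", "), "} ref=", x$reference,
        sep = "")
  cat("\n")
  invisible(x)
}

is_quantitative <- function(spec) spec$type == "quantitative"

spec_names <- function(specs) vapply(specs, `[[`, character(1), "name")

specs_at_level <- function(specs, level) {
  specs[vapply(specs, function(s) s$level == level, logical(1))]
}

#' Read variable specs from a YAML dictionary
#'
#' The file plays the role of a data dictionary: a top-level `variables`
#' sequence, each entry with fields `name`, `level`, `type` and, for
#' qualitative variables, `categories` and optional `reference`.
#'
#' @param path Path to a YAML file.
#' @return A list of [variable_spec()] objects.
#' @export
read_variable_specs <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path)
  raw <- yaml::read_yaml(path)
  entries <- if (!is.null(raw$variables)) raw$variables else raw
  lapply(entries, function(e) {
    variable_spec(
      name = e$name, level = e$level, type = e$type,
      categories = if (is.null(e$categories)) character() else
        as.character(e$categories),
      reference = e$reference
    )
  })
}

#' Write variable specs to a YAML dictionary
#'
#' @param specs List of [variable_spec()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variable_specs <- function(specs, path) {
  entries <- lapply(specs, function(s) {
    e <- list(name = s$name, level = s$level, type = s$type)
    if (length(s$categories)) {
      e$categories <- as.list(s$categories)
      e$reference <- s$reference
    }
    e
  })
  yaml::write_yaml(list(variables = entries), path)
  invisible(path)
}
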