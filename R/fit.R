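#' Group-level regression with adjusted means and robust inference
#'
#' Fits the micro-macro regression y_g = b0 + b1' z_g + b2' xi_g + eps_g
#' by ordinary least squares on the intercept, the encoded group-level
#' predictors and the latent-adjusted group means from [adjust_means()].
#' Classical standard errors assume homoscedastic eps_g; because group
#' sizes differ (and the adjusted means carry group-size-dependent
#' sampling noise), the reported inference uses a
#' heteroscedasticity-consistent sandwich covariance (HC3 by default).
#' Confidence intervals and p-values use a t reference with G - k - 1
#' degrees of freedom by default, appropriate for small numbers of
#' groups; a normal reference is available.
#'
#' @param y Numeric outcome vector, one value per group, or a
#'   `macro_table` (its outcome column is used).
#' @param macro_z Group-level `"encoded_matrix"` (or numeric matrix), or
#'   `NULL` for a model with individual-level predictors only.
#' @param adjusted An `"adjusted_means"` object (or numeric matrix of
#'   group-level predictors derived from individual data).
#' @param hc_type Sandwich flavor: `"HC3"` (default), `"HC0"`, `"HC1"`,
#'   `"HC2"`.
#' @param reference `"t"` (default) or `"normal"` reference distribution
#'   for CIs and p-values.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `"micro_macro_fit"` with components
#'   `beta`, `se_classical`, `se_corrected`, `ci_lower`, `ci_upper`,
#'   `p_values`, `residuals`, `sigma_eps2`, `r_squared`, `vcov_classical`,
#'   `vcov_corrected`, `df`, and the underlying `lm` fit.
#' @seealso [naive_fit()] for the uncorrected group-mean regression.
#' @export
fit_micro_macro <- function(y, macro_z = NULL, adjusted = NULL,
                            hc_type = c("HC3", "HC0", "HC1", "HC2"),
                            reference = c("t", "normal"),
                            conf_level = 0.95) {
  hc_type <- match.arg(hc_type)
  reference <- match.arg(reference)
  if (inherits(y, "macro_table")) y <- y[[attr(y, "outcome_col")]]
  y <- as.numeric(y)

  blocks <- list()
  level_map <- character()
  if (!is.null(macro_z)) {
    Z <- if (inherits(macro_z, "encoded_matrix")) macro_z$values else
      as.matrix(macro_z)
    if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
    blocks$z <- Z
    level_map <- c(level_map, stats::setNames(rep("group", ncol(Z)),
                                              colnames(Z)))
  }
  if (!is.null(adjusted)) {
    Xt <- if (inherits(adjusted, "adjusted_means")) adjusted$xtilde else
      as.matrix(adjusted)
    if (is.null(colnames(Xt))) colnames(Xt) <- paste0("x", seq_len(ncol(Xt)))
    blocks$x <- Xt
    level_map <- c(level_map, stats::setNames(rep("individual", ncol(Xt)),
                                              colnames(Xt)))
  }
  if (!length(blocks)) stop("supply at least one predictor block")
  X <- do.call(cbind, unname(blocks))
  G <- length(y)
  stopifnot(nrow(X) == G)
  k <- ncol(X)
  if (G <= k + 1)
    stop("need more groups (", G, ") than regressors + 1 (", k + 1, ")")

  dat <- data.frame(.y = y, X, check.names = FALSE)
  fm <- stats::as.formula(paste0("`.y` ~ ",
    paste0("`", colnames(X), "`", collapse = " + ")))
  lmfit <- stats::lm(fm, data = dat)
  cf <- stats::coef(lmfit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear column(s): ",
         paste(gsub("`", "", names(cf)[is.na(cf)]), collapse = ", "))
  names(cf) <- gsub("`", "", names(cf))
  df_resid <- G - k - 1

  vc_classical <- stats::vcov(lmfit)
  vc_corrected <- sandwich::vcovHC(lmfit, type = hc_type)
  dimnames(vc_classical) <- dimnames(vc_corrected) <-
    list(names(cf), names(cf))
  se_cl <- sqrt(diag(vc_classical))
  se_hc <- sqrt(diag(vc_corrected))

  crit <- if (reference == "t")
    stats::qt(1 - (1 - conf_level) / 2, df_resid)
  else stats::qnorm(1 - (1 - conf_level) / 2)
  tval <- cf / se_hc
  p <- if (reference == "t") 2 * stats::pt(-abs(tval), df_resid)
       else 2 * stats::pnorm(-abs(tval))
  res <- stats::residuals(lmfit)
  rss <- sum(res^2)
  r2 <- summary(lmfit)$r.squared

  structure(
    list(beta = cf,
         se_classical = se_cl, se_corrected = se_hc,
         ci_lower = cf - crit * se_hc, ci_upper = cf + crit * se_hc,
         p_values = p,
         residuals = res, sigma_eps2 = rss / df_resid,
         r_squared = r2,
         vcov_classical = vc_classical, vcov_corrected = vc_corrected,
         df = df_resid, hc_type = hc_type, reference = reference,
         conf_level = conf_level, level_map = level_map,
         lm_fit = lmfit, n_groups = G),
    class = "micro_macro_fit"
  )
}

#' Naive group-mean regression (no latent adjustment)
#'
#' Identical regression machinery to [fit_micro_macro()] but with the
#' observed group means xbar_g in place of the adjusted means. Retained
#' as the biased comparator: its coefficients on individual-level
#' predictors are attenuated by roughly
#' Sigma_xi / (Sigma_xi + Sigma_upsilon / n_g) in the univariate case.
#'
#' @param y Outcome vector or `macro_table`.
#' @param macro_z Group-level `"encoded_matrix"` or `NULL`.
#' @param summaries A `"group_summaries"` object (its `xbar` is used).
#' @param ... Passed to [fit_micro_macro()] (`hc_type`, `reference`, ...).
#' @return A `"micro_macro_fit"`.
#' @export
naive_fit <- function(y, macro_z = NULL, summaries = NULL, ...) {
  stopifnot(inherits(summaries, "group_summaries"))
  fit_micro_macro(y, macro_z = macro_z, adjusted = summaries$xbar, ...)
}

#' @export
coef.micro_macro_fit <- function(object, ...) object$beta

#' @export
vcov.micro_macro_fit <- function(object, type = c("corrected", "classical"),
                                 ...) {
  type <- match.arg(type)
  if (type == "corrected") object$vcov_corrected else object$vcov_classical
}

#' @export
confint.micro_macro_fit <- function(object, parm, level = NULL, ...) {
  ci <- cbind(lower = object$ci_lower, upper = object$ci_upper)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.micro_macro_fit <- function(x, digits = 3, ...) {
  cat("Micro-macro group-level regression (", x$n_groups, " groups, ",
      x$hc_type, " corrected SEs, ", x$reference, " reference)\n\n",
      sep = "")
  print(coef_table(x), digits = digits)
  cat("\nResidual variance ", signif(x$sigma_eps2, digits),
      " on ", x$df, " df;  R-squared ", signif(x$r_squared, digits),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.micro_macro_fit <- function(object, ...) object

#' Coefficient table in reporting layout
#'
#' One row per model term: estimate, 95% CI, p-value, classical and
#' corrected standard errors, and the level (individual/group) of the
#' source predictor.
#'
#' @param fit A `"micro_macro_fit"`.
#' @return A data frame.
#' @export
coef_table <- function(fit) {
  nm <- names(fit$beta)
  lvl <- c("(intercept)", unname(fit$level_map[nm[-1]]))
  data.frame(
    factor = nm,
    level = lvl,
    beta = unname(fit$beta),
    ci_lower = unname(fit$ci_lower),
    ci_upper = unname(fit$ci_upper),
    p = unname(fit$p_values),
    se = unname(fit$se_classical),
    se_corr = unname(fit$se_corrected),
    stringsAsFactors = FALSE
  )
}
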