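#' Sex-stratified association models
#'
#' Ordinary least-squares models of embedding scores (or change scores) on
#' one predictor of interest with covariates of no interest, stratified by
#' sex; per-predictor effect sizes as partial eta-squared and Bonferroni
#' control over the analysis family.
#'
#' @name association
NULL

#' Partial eta-squared from a t statistic
#'
#' `t^2 / (t^2 + df_residual)`, the single-predictor equivalent of
#' `SS_effect / (SS_effect + SS_residual)`.
#'
#' @param t_stat t statistic of the predictor of interest.
#' @param df_residual residual degrees of freedom (>= 1).
#' @return effect size in `[0, 1]`.
#' @export
partial_eta_squared <- function(t_stat, df_residual) {
  if (df_residual < 1) stop("df_residual must be >= 1")
  t_stat ^ 2 / (t_stat ^ 2 + df_residual)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha_family family-wise alpha.
#' @param m number of models in the family (>= 1).
#' @return `alpha_family / m`.
#' @export
bonferroni_threshold <- function(alpha_family, m) {
  if (m < 1) stop("family size m must be >= 1")
  alpha_family / m
}

#' Fit one stratified linear association model
#'
#' OLS of `dv ~ iv + covariates` on one sex stratum with listwise deletion.
#' Site (or any character/factor covariate) enters as dummy indicators with
#' the alphabetically first level as reference. Reports the unstandardized
#' coefficient, two-sided p and partial eta-squared for the predictor of
#' interest, and whether it passes the family's Bonferroni threshold.
#'
#' @param data data frame holding all referenced columns.
#' @param dv,iv column names of the dependent variable and the predictor of
#'   interest.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param stratum optional value of the `sex` column to restrict to.
#' @param interaction optional column name; adds `iv:interaction` next to
#'   both main effects.
#' @param alpha_family,m family-wise alpha and family size for the
#'   Bonferroni flag.
#' @return list of class `association_result`: `b`, `p`, `eta_sq_partial`,
#'   `n`, `passed_bonferroni`, plus the fitted model spec.
#' @export
fit_linear_model <- function(data, dv, iv, covariates = character(),
                             stratum = NULL, interaction = NULL,
                             alpha_family = 0.05, m = 1L) {
  if (!is.null(stratum)) data <- data[data$sex == stratum, , drop = FALSE]
  vars <- c(dv, iv, covariates, interaction)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
               drop = FALSE]
  if (nrow(data) < 10L) stop("fewer than 10 observations after deletion")
  for (v in c(iv, covariates)) {
    if (is.character(data[[v]]))
      data[[v]] <- factor(data[[v]], levels = sort(unique(data[[v]])))
  }
  rhs <- c(iv, covariates)
  if (!is.null(interaction))
    rhs <- c(rhs, interaction, paste0(iv, ":", interaction))
  fml <- stats::reformulate(rhs, response = dv)
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased: ", paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)
  row <- which(rownames(sm$coefficients) == iv)
  if (!length(row)) stop("predictor of interest not found in fit")
  b <- sm$coefficients[row, "Estimate"]
  t_stat <- sm$coefficients[row, "t value"]
  p <- sm$coefficients[row, "Pr(>|t|)"]
  eta <- partial_eta_squared(t_stat, fit$df.residual)
  structure(list(dv = dv, iv = iv, stratum = stratum,
                 b = unname(b), p = unname(p),
                 eta_sq_partial = unname(eta),
                 n = nrow(data),
                 passed_bonferroni = p < bonferroni_threshold(alpha_family, m),
                 fit = fit),
            class = "association_result")
}

#' Run a set of association models
#'
#' @param data data frame.
#' @param models list of model specs, each a list with fields accepted by
#'   [fit_linear_model()] (`dv`, `iv`, `covariates`, `stratum`,
#'   `interaction`).
#' @param alpha_family family-wise alpha shared by the set.
#' @return tidy data frame, one row per model.
#' @export
run_associations <- function(data, models, alpha_family = 0.05) {
  m <- length(models)
  rows <- lapply(models, function(sp) {
    res <- fit_linear_model(data,
                            dv = sp$dv, iv = sp$iv,
                            covariates = sp$covariates %||% character(),
                            stratum = sp$stratum,
                            interaction = sp$interaction,
                            alpha_family = alpha_family, m = m)
    data.frame(dv = res$dv, iv = res$iv,
               stratum = res$stratum %||% "all",
               b = res$b, p = res$p,
               eta_sq_partial = res$eta_sq_partial, n = res$n,
               passed_bonferroni = res$passed_bonferroni,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
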