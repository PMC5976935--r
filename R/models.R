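# Mortality models on the matched cohort: multivariate logistic
# regression (odds ratios), Cox proportional hazards (hazard ratios),
# Welch group comparisons, and stratified comparisons.

#' Model specification for the mortality analyses
#'
#' The default covariate set is muscle area, fat attenuation, emphysema
#' fraction, CAC grade (three indicators against the "none" reference),
#' tumour stage, age, gender, and height.  With the default ordinal
#' stage coding (a single linear term over stages I-IV) this gives ten
#' coefficient terms, so the model chi-square has 10 degrees of freedom;
#' `stage_coding = "indicator"` expands stage to indicators against
#' stage I instead (11 terms on a three-stage cohort).  Emphysema enters
#' as a fraction in `[0, 1]`, so its ratio is per unit fraction (hence
#' numerically large).
#'
#' @param outcome column holding the binary nonsurvivor indicator
#'   (logistic model).
#' @param time,event columns holding survival time (days) and the event
#'   indicator (Cox model).
#' @param covariates right-hand-side terms; factors expand to
#'   indicators.
#' @param stage_coding `"ordinal"` (single linear term, the default) or
#'   `"indicator"` (stage II/III/IV indicators against stage I).
#' @return An `analysis_spec` list.
#' @export
analysis_spec <- function(outcome = "nonsurvivor",
                          time = "survival_time", event = "event",
                          covariates = c("muscle_area",
                                         "fat_attenuation", "emphysema",
                                         "cac_grade", "stage", "age",
                                         "gender", "height"),
                          stage_coding = c("ordinal", "indicator")) {
  structure(list(outcome = outcome, time = time, event = event,
                 covariates = covariates,
                 stage_coding = match.arg(stage_coding)),
            class = "analysis_spec")
}

# Coerce the factor covariates to their reference coding.
.prep_model_data <- function(data, spec) {
  df <- as.data.frame(data)
  if ("cac_grade" %in% spec$covariates && "cac_grade" %in% names(df) &&
      !is.factor(df$cac_grade)) {
    labs <- cac_grade_labels()
    df$cac_grade <- factor(labs[as.character(df$cac_grade)],
                           levels = unname(labs))
  }
  if ("stage" %in% spec$covariates && "stage" %in% names(df)) {
    coding <- spec$stage_coding %||% "ordinal"
    if (coding == "ordinal") {
      df$stage <- as.numeric(factor(as.character(df$stage),
                                    levels = c("I", "II", "III", "IV")))
    } else if (!is.factor(df$stage)) {
      df$stage <- factor(df$stage, levels = intersect(
        c("I", "II", "III", "IV"), unique(as.character(df$stage))))
    }
  }
  if ("gender" %in% spec$covariates && "gender" %in% names(df) &&
      !is.factor(df$gender))
    df$gender <- factor(df$gender, levels = intersect(
      c("female", "male"), unique(as.character(df$gender))))
  df
}

.model_result <- function(terms, coefs, ses, chisq, df_model, n,
                          model = c("logistic", "cox")) {
  model <- match.arg(model)
  z <- coefs / ses
  p <- 2 * pnorm(-abs(z))
  q <- qnorm(0.975)
  res <- data.frame(
    term = terms,
    coefficient = unname(coefs),
    ratio = exp(unname(coefs)),
    ci_lo = exp(unname(coefs - q * ses)),
    ci_hi = exp(unname(coefs + q * ses)),
    se = unname(ses),
    p_value = unname(p),
    stringsAsFactors = FALSE)
  structure(res, class = c("model_result", "data.frame"),
            model = model, model_chisq = chisq, model_df = df_model,
            model_p = pchisq(chisq, df_model, lower.tail = FALSE),
            n = n)
}

#' @export
print.model_result <- function(x, digits = 3, ...) {
  kind <- attr(x, "model")
  cat(sprintf("<model_result: %s> n = %d, chi-square(%d) = %.2f, p = %.3g\n",
              kind, attr(x, "n"), attr(x, "model_df"),
              attr(x, "model_chisq"), attr(x, "model_p")))
  df <- as.data.frame(x)
  df$ratio_ci <- sprintf(paste0("%.", digits, "g (%.", digits,
                                "g-%.", digits, "g)"),
                         df$ratio, df$ci_lo, df$ci_hi)
  print(df[, c("term", "coefficient", "ratio_ci", "p_value")],
        row.names = FALSE)
  invisible(x)
}

.check_full_rank <- function(fit) {
  aliased <- is.na(coef(fit))
  if (any(aliased))
    stop2("design matrix is rank deficient; aliased terms: ",
          paste(names(coef(fit))[aliased], collapse = ", "))
}

#' Multivariate binary logistic regression
#'
#' Maximum-likelihood logistic fit of the nonsurvivor indicator on the
#' specified covariates.  Reports per-term coefficients, odds ratios
#' with Wald 95% confidence intervals, Wald p-values, and the
#' likelihood-ratio model chi-square against the intercept-only model
#' (df = number of coefficient terms).
#'
#' @param data data frame with the outcome and covariates.
#' @param spec an [analysis_spec()].
#' @return A `model_result` data frame; model-level statistics in
#'   attributes `model_chisq`, `model_df`, `model_p`, `n`.
#' @examples
#' d <- data.frame(y = rep(c(0, 1), each = 50),
#'                 x = rep(c(0, 1, 0, 1), c(40, 10, 20, 30)))
#' fit <- fit_logistic(d, analysis_spec(outcome = "y", covariates = "x"))
#' fit$ratio  # cross-product odds ratio (30*40)/(20*10) = 6
#' @export
fit_logistic <- function(data, spec = analysis_spec()) {
  stopifnot(inherits(spec, "analysis_spec"))
  df <- .prep_model_data(data, spec)
  y <- df[[spec$outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y[!is.na(y)])) != 2)
    stop2("outcome must be binary with both classes present")
  df$.y <- y
  form <- reformulate(spec$covariates, ".y")
  fit <- withCallingHandlers(
    glm(form, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        stop2("separation detected: some covariate perfectly predicts ",
              "the outcome (", conditionMessage(w), ")")
      invokeRestart("muffleWarning")
    })
  .check_full_rank(fit)
  bad <- abs(coef(fit)) > 15 & names(coef(fit)) != "(Intercept)"
  if (any(bad, na.rm = TRUE))
    stop2("separation detected: diverged coefficient(s) for ",
          paste(names(coef(fit))[which(bad)], collapse = ", "),
          "; these terms perfectly predict the outcome")
  sm <- summary(fit)
  keep <- rownames(sm$coefficients) != "(Intercept)"
  .model_result(rownames(sm$coefficients)[keep],
                sm$coefficients[keep, "Estimate"],
                sm$coefficients[keep, "Std. Error"],
                chisq = fit$null.deviance - fit$deviance,
                df_model = fit$df.null - fit$df.residual,
                n = nrow(fit$model), model = "logistic")
}

#' Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling.  Reports hazard
#' ratios with Wald 95% confidence intervals and the likelihood-ratio
#' model chi-square against the null model.
#'
#' @inheritParams fit_logistic
#' @return A `model_result` data frame (ratios are hazard ratios).
#' @export
fit_cox <- function(data, spec = analysis_spec()) {
  stopifnot(inherits(spec, "analysis_spec"))
  df <- .prep_model_data(data, spec)
  time <- df[[spec$time]]
  event <- df[[spec$event]]
  if (any(time < 0, na.rm = TRUE)) stop2("survival times must be >= 0")
  if (sum(event, na.rm = TRUE) == 0)
    stop2("no events in the data; the Cox model is undefined")
  form <- stats::as.formula(paste0(
    "survival::Surv(", spec$time, ", ", spec$event, ") ~ ",
    paste(spec$covariates, collapse = " + ")))
  fit <- survival::coxph(form, data = df, ties = "efron")
  .check_full_rank(fit)
  sm <- summary(fit)
  .model_result(rownames(sm$coefficients),
                sm$coefficients[, "coef"],
                sm$coefficients[, "se(coef)"],
                chisq = 2 * diff(fit$loglik),
                df_model = sum(!is.na(coef(fit))),
                n = fit$n, model = "cox")
}

#' Two-group comparison with descriptive statistics
#'
#' Welch (unequal-variance) two-sample t-test with group means and
#' standard deviations, the comparison used for all survivor-versus-
#' nonsurvivor biomarker contrasts.
#'
#' @param values_a,values_b numeric vectors, each with at least two
#'   observations.
#' @return list: `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `mean_diff`, `p_value`.
#' @export
group_compare <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2)
    stop2("each group needs at least 2 observations")
  tt <- t.test(a, b)
  list(mean_a = mean(a), sd_a = sd(a), n_a = length(a),
       mean_b = mean(b), sd_b = sd(b), n_b = length(b),
       mean_diff = mean(a) - mean(b), p_value = tt$p.value)
}

#' Stratified group comparisons
#'
#' Applies [group_compare()] within each stratum of a stratifier: lung
#' cancer stage, smoking history dichotomised at 50 pack-years (a
#' subject at exactly 50 goes to the "<=50" stratum; only strictly
#' greater values reach ">50"), or COPD history.  A stratum missing one
#' group is flagged, not dropped.
#'
#' @param data data frame holding the value, group and stratifier
#'   columns.
#' @param value column with the quantity compared (e.g. muscle area).
#' @param group column with the two-level group (e.g. survivor flag).
#' @param stratifier `"stage"`, `"pkyr50"`, or `"copd"` - or any column
#'   name in `data`.
#' @return data frame, one row per stratum: group means/sds/sizes,
#'   p-value (`NA` with `note` set when a group is absent).
#' @export
stratified_analysis <- function(data, value, group,
                                stratifier = c("stage", "pkyr50",
                                               "copd")) {
  stratifier <- stratifier[1]
  df <- as.data.frame(data)
  strat <- if (stratifier == "pkyr50") {
    factor(ifelse(df$pkyr > 50, ">50", "<=50"),
           levels = c("<=50", ">50"))
  } else df[[stratifier]]
  if (is.null(strat)) stop2("stratifier column not found: ", stratifier)
  if (any(is.na(strat))) stop2("stratifier must be defined for all rows")
  glev <- sort(unique(as.character(df[[group]])))
  if (length(glev) != 2) stop2("group column must have exactly 2 levels")
  rows <- lapply(sort(unique(as.character(strat))), function(s) {
    sub <- df[as.character(strat) == s, , drop = FALSE]
    a <- sub[[value]][sub[[group]] == glev[1]]
    b <- sub[[value]][sub[[group]] == glev[2]]
    if (length(a[!is.na(a)]) < 2 || length(b[!is.na(b)]) < 2) {
      return(data.frame(stratum = s, n_a = length(a), mean_a = NA,
                        sd_a = NA, n_b = length(b), mean_b = NA,
                        sd_b = NA, p_value = NA,
                        note = "group absent or too small",
                        stringsAsFactors = FALSE))
    }
    gc <- group_compare(a, b)
    data.frame(stratum = s, n_a = gc$n_a, mean_a = gc$mean_a,
               sd_a = gc$sd_a, n_b = gc$n_b, mean_b = gc$mean_b,
               sd_b = gc$sd_b, p_value = gc$p_value, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- glev
  out
}
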