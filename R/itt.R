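#' Baseline covariates entering adjusted ITT models
#'
#' The adjusted specification controls for maternal baseline self-report
#' covariates (age, schooling, household income, net worth, general and
#' mental health, race/ethnicity, marital status, adults in household, other
#' children, smoking and alcohol during pregnancy, father in household),
#' child covariates (sex, birth weight, gestational age), child age at the
#' visit, and the number of usable EEG epochs.
#'
#' @return Character vector of cohort column names.
#' @export
itt_covariates <- function() {
  c("mother_age", "mother_edu_years", "hh_income", "net_worth",
    "mother_health", "mother_mental_health", "race", "married",
    "n_adults", "n_other_children", "smoked_pregnancy", "alcohol_pregnancy",
    "father_in_home", "child_female", "birth_weight_g", "gestational_age_wk",
    "child_age_months", "n_usable_epochs")
}

#' Mean-impute missing covariates using the analytic sample
#'
#' Each missing numeric covariate cell is replaced by the mean of that
#' covariate over the analytic sample (not the full cohort); missing
#' categorical values become an explicit `"(missing)"` level. Outcome columns
#' are never touched.
#'
#' @param cohort Cohort data frame.
#' @param analytic_ids Ids of the analytic (EEG) sample; imputation means are
#'   computed over these rows only.
#' @param covariates Covariate columns to impute.
#' @return The cohort with covariate missingness resolved.
#' @export
impute_covariates <- function(cohort, analytic_ids,
                              covariates = intersect(itt_covariates(), names(cohort))) {
  stopifnot(all(analytic_ids %in% cohort$id))
  an <- cohort$id %in% analytic_ids
  for (v in covariates) {
    x <- cohort[[v]]
    if (!anyNA(x)) next
    if (is.numeric(x) || is.logical(x)) {
      m <- mean(x[an], na.rm = TRUE)
      if (is.nan(m)) stopf("covariate '%s' entirely missing in the analytic sample", v)
      if (is.logical(x)) x <- as.numeric(x)
      x[is.na(x)] <- m
    } else {
      x <- factor(x)
      levels(x) <- c(levels(x), "(missing)")
      x[is.na(x)] <- "(missing)"
    }
    cohort[[v]] <- x
  }
  cohort
}

#' Fit an intent-to-treat regression for one outcome
#'
#' Ordinary least squares of the outcome on the treatment indicator and site
#' fixed effects, optionally plus the baseline covariate list, with
#' heteroskedasticity-consistent standard errors. The reported p-value for
#' the treatment coefficient comes from the robust t statistic, by default
#' using the normal approximation.
#'
#' @param outcome Numeric vector, one value per row of `data` (no missing
#'   values: outcomes are never imputed).
#' @param data Analytic-sample cohort rows (already imputed via
#'   [impute_covariates()] when `covariates = TRUE`).
#' @param covariates Logical: adjust for [itt_covariates()]?
#' @param hc_type Robust covariance flavor passed to [sandwich::vcovHC()]
#'   (`"HC0"`-`"HC3"`; default `"HC1"`).
#' @param df_method `"normal"` (default) or `"t"` (residual df).
#' @param outcome_name Label stored on the estimate.
#' @return Object of class `itt_estimate`: `coef`, `se`, `t`, `p`, `n`,
#'   `covariates`, `hc_type`, `outcome`, and `sd_low` when `data` carries an
#'   `arm` column (SD of the outcome among low-cash analytic children, the
#'   denominator of the standardized effect size).
#' @export
fit_itt <- function(outcome, data, covariates = TRUE, hc_type = "HC1",
                    df_method = c("normal", "t"),
                    outcome_name = deparse(substitute(outcome))) {
  df_method <- match.arg(df_method)
  stopifnot(length(outcome) == nrow(data))
  if (anyNA(outcome)) stopf("outcome has missing values; outcomes are never imputed")
  d <- droplevels(as.data.frame(data))
  d$.y <- outcome
  d$.treat <- as.integer(as.character(d$arm) == "high")
  rhs <- ".treat + factor(site)"
  if (covariates) {
    covs <- intersect(itt_covariates(), names(d))
    if (anyNA(d[covs])) stopf("covariates contain missing values; run impute_covariates() first")
    rhs <- paste(c(rhs, covs), collapse = " + ")
  }
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  if (anyNA(stats::coef(fit))) {
    stopf("collinear design; aliased column(s): %s",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  V <- sandwich::vcovHC(fit, type = hc_type)
  co <- stats::coef(fit)[[".treat"]]
  se <- sqrt(V[".treat", ".treat"])
  tstat <- co / se
  p <- if (df_method == "normal") 2 * stats::pnorm(-abs(tstat)) else
    2 * stats::pt(-abs(tstat), df = fit$df.residual)
  sd_low <- if ("arm" %in% names(d)) stats::sd(outcome[as.character(d$arm) == "low"]) else NA_real_
  structure(list(outcome = outcome_name, coef = co, se = se, t = tstat, p = p,
                 n = nrow(d), covariates = covariates, hc_type = hc_type,
                 df_method = df_method, sd_low = sd_low),
            class = "itt_estimate")
}

#' @export
print.itt_estimate <- function(x, ...) {
  cat(sprintf("ITT %s: coef %.4g (robust SE %.4g), p = %.3g, n = %d%s\n",
              x$outcome, x$coef, x$se, x$p, x$n,
              if (x$covariates) ", covariate-adjusted" else ""))
  invisible(x)
}

#' Standardized effect size
#'
#' Divides the (covariate-adjusted) treatment coefficient by the SD of the
#' outcome within the low-cash analytic sample. Tables display it rounded to
#' two decimals; the returned value is full precision.
#'
#' @param est An `itt_estimate` or a bare numeric coefficient.
#' @param sd_low SD of the outcome among low-cash analytic children; defaults
#'   to the value stored on the estimate.
#' @return Numeric standardized effect.
#' @export
effect_size <- function(est, sd_low = NULL) {
  co <- if (inherits(est, "itt_estimate")) est$coef else est
  if (is.null(sd_low) && inherits(est, "itt_estimate")) sd_low <- est$sd_low
  if (is.null(sd_low) || is.na(sd_low) || sd_low <= 0) {
    stopf("sd_low must be a positive number")
  }
  co / sd_low
}

#' Baseline balance table
#'
#' Per-arm means (SD) for continuous variables or percentages for binary
#' ones, with per-arm n and an unadjusted two-sided p-value for the group
#' difference: Welch t-test for continuous variables and a two-proportion
#' z-test (chi-square without continuity correction) for binary ones.
#' Factor variables are expanded into one indicator per level.
#'
#' @param cohort Cohort data frame.
#' @param analytic_ids Ids defining the sample being balanced (default: the
#'   EEG analytic sample).
#' @param variables Columns to tabulate.
#' @return Data frame: `variable`, `mean_low`, `sd_low`, `n_low`,
#'   `mean_high`, `sd_high`, `n_high`, `p`. Binary rows report percentages in
#'   the mean columns and `NA` SDs.
#' @export
balance_table <- function(cohort,
                          analytic_ids = cohort$id[cohort$in_eeg_sample],
                          variables = c("child_female", "child_age_months",
                                        "mother_edu_years", "race", "hh_income",
                                        "n_usable_epochs")) {
  missing_v <- setdiff(variables, names(cohort))
  if (length(missing_v)) stopf("variable(s) not in cohort: %s", paste(missing_v, collapse = ", "))
  d <- cohort[cohort$id %in% analytic_ids, ]
  arm <- factor(as.character(d$arm), levels = c("low", "high"))

  one_row <- function(name, x) {
    lo <- x[arm == "low"]; hi <- x[arm == "high"]
    n_lo <- sum(!is.na(lo)); n_hi <- sum(!is.na(hi))
    if (is_binary(x)) {
      x_lo <- sum(lo, na.rm = TRUE); x_hi <- sum(hi, na.rm = TRUE)
      p <- if ((x_lo + x_hi) %in% c(0, n_lo + n_hi)) 1 else
        stats::prop.test(c(x_lo, x_hi), c(n_lo, n_hi), correct = FALSE)$p.value
      data.frame(variable = name,
                 mean_low = 100 * x_lo / n_lo, sd_low = NA_real_, n_low = n_lo,
                 mean_high = 100 * x_hi / n_hi, sd_high = NA_real_, n_high = n_hi,
                 p = p, stringsAsFactors = FALSE)
    } else {
      p <- if (stats::sd(lo, na.rm = TRUE) == 0 && stats::sd(hi, na.rm = TRUE) == 0) 1 else
        stats::t.test(lo, hi)$p.value
      data.frame(variable = name,
                 mean_low = mean(lo, na.rm = TRUE), sd_low = stats::sd(lo, na.rm = TRUE),
                 n_low = n_lo,
                 mean_high = mean(hi, na.rm = TRUE), sd_high = stats::sd(hi, na.rm = TRUE),
                 n_high = n_hi, p = p, stringsAsFactors = FALSE)
    }
  }

  rows <- lapply(variables, function(v) {
    x <- d[[v]]
    if (is.factor(x) || is.character(x)) {
      x <- factor(x)
      do.call(rbind, lapply(levels(x), function(lv) {
        one_row(paste0(v, ": ", lv), as.numeric(x == lv))
      }))
    } else {
      one_row(v, if (is.logical(x)) as.numeric(x) else x)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
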