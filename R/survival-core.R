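#' Assemble survival data from a clinical table
#'
#' @param time event/censoring times in months (finite, positive).
#' @param event 1 = event observed, 0 = right-censored.
#' @param group optional categorical label per subject.
#' @param strata optional categorical stratification variable.
#' @return A data.frame of class `survival_data`.
#' @export
survival_data <- function(time, event, group = NULL, strata = NULL) {
  if (length(time) < 1L) stop("need >= 1 subject")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("`time` must be finite and positive (months)")
  if (!all(event %in% c(0L, 1L))) stop("`event` must be 0 (censored) or 1 (event)")
  df <- data.frame(time = as.numeric(time), event = as.integer(event))
  if (!is.null(group)) df$group <- as.character(group)
  if (!is.null(strata)) df$strata <- as.character(strata)
  class(df) <- c("survival_data", "data.frame")
  df
}

#' @rdname survival_data
#' @param clinical a clinical table with columns `time_months` and `event`
#'   (the schema written by [write_cohort()]).
#' @param group_col,strata_col optional column names to carry along.
#' @export
survival_from_clinical <- function(clinical, group_col = NULL, strata_col = NULL) {
  survival_data(clinical$time_months, clinical$event,
                group = if (!is.null(group_col)) clinical[[group_col]],
                strata = if (!is.null(strata_col)) clinical[[strata_col]])
}

#' Kaplan-Meier curve and median survival
#'
#' Product-limit estimate of the survival function. The median is the
#' earliest observed time at which the estimate drops to 0.5 or below;
#' when the curve never reaches 0.5 the median is reported as the token
#' `"not reached"` (field `median_reached = FALSE`), never as infinity.
#'
#' @param data a [survival_data()].
#' @return List with `time`, `surv` (step-function values at event
#'   times), `n_risk`, `n_event`, `median` (numeric or NA), and
#'   `median_reached`.
#' @export
km_curve <- function(data) {
  if (nrow(data) < 1L) stop("need >= 1 subject")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  med <- unname(summary(fit)$table["median"])
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk, n_event = fit$n.event,
       median = if (is.na(med)) NA_real_ else med,
       median_reached = !is.na(med),
       median_label = if (is.na(med)) "not reached" else format(med))
}

#' (Stratified) log-rank test
#'
#' Standard log-rank chi-square comparing survival between groups, with
#' `df = groups - 1`; when `strata` is present in the data, the
#' observed-minus-expected contributions are summed over strata before
#' squaring (the stratified test).
#'
#' @param data a [survival_data()] with a `group` column (>= 2 groups).
#' @return List with `statistic`, `df`, `p`.
#' @export
logrank <- function(data) {
  if (is.null(data$group)) stop("`data` must carry a group label")
  counts <- table(data$group)
  if (length(counts) < 2L) stop("need >= 2 groups")
  if (any(counts == 0L)) stop("a group has zero subjects")
  fml <- if (!is.null(data$strata))
    survival::Surv(time, event) ~ group + survival::strata(strata)
  else
    survival::Surv(time, event) ~ group
  sd <- survival::survdiff(fml, data = data)
  df <- length(counts) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling. In
#' `univariate = TRUE` mode each covariate is fit singly; otherwise all
#' covariates enter one model. Per covariate the result carries the
#' coefficient (log hazard per unit), the hazard ratio, a Wald 95% CI,
#' the two-sided Wald p, and the coefficient sign.
#'
#' @param data a [survival_data()].
#' @param covariates data.frame (or named list) of per-sample numeric
#'   covariates, row-matched to `data`.
#' @param univariate fit each covariate separately (default TRUE).
#' @return data.frame with one row per covariate: `covariate`,
#'   `coefficient`, `hr`, `ci_low`, `ci_high`, `p`, `sign`.
#' @export
cox_fit <- function(data, covariates, univariate = TRUE) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(data))
    stop("covariates must be row-matched to the survival data")
  if (sum(data$event) < 1L) stop("need >= 1 observed event")
  const <- vapply(covariates, function(v) stats::var(as.numeric(v)) == 0, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(covariates)[const], collapse = ", "))
  one_model <- function(df_cov) {
    dd <- cbind(data.frame(time = data$time, event = data$event), df_cov)
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(sprintf("`%s`", names(df_cov)), collapse = " + ")))
    fit <- survival::coxph(fml, data = dd, ties = "efron")
    s <- summary(fit)
    data.frame(covariate = names(df_cov),
               coefficient = unname(s$coefficients[, "coef"]),
               hr = unname(s$coefficients[, "exp(coef)"]),
               ci_low = unname(s$conf.int[, "lower .95"]),
               ci_high = unname(s$conf.int[, "upper .95"]),
               p = unname(s$coefficients[, "Pr(>|z|)"]),
               sign = sign(unname(s$coefficients[, "coef"])),
               stringsAsFactors = FALSE)
  }
  if (univariate) {
    out <- do.call(rbind, lapply(names(covariates), function(nm) one_model(covariates[nm])))
  } else {
    out <- one_model(covariates)
  }
  rownames(out) <- NULL
  out
}

# Univariate Cox score-test p-value for one numeric covariate; constant
# covariates are flagged and given p = 1 rather than an error (degenerate
# genes are common in filtered expression matrices).
cox_score_p <- function(time, event, x) {
  if (stats::var(x) == 0) return(c(p = 1, flagged = 1))
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  s <- summary(fit)
  c(p = unname(s$sctest["pvalue"]), flagged = 0)
}
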