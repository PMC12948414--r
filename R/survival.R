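# Survival association of microenvironmental features with local
# progression-free survival: dichotomization, Kaplan-Meier estimation and
# the two-group log-rank test. Estimation and testing are delegated to the
# survival package; this module fixes the stratification rules and the
# result contract.

#' Dichotomize a clinical covariate
#'
#' Three stratification rules: `median_split` (ties at the median go to the
#' low group), `positive_vs_zero` (present when the value exceeds a small
#' epsilon — the CD8 present-vs-absent rule), and `threshold` (high when the
#' value exceeds `t`).
#'
#' @param values finite numeric vector, length >= 2.
#' @param rule one of `"median_split"`, `"positive_vs_zero"`, `"threshold"`.
#' @param t cut point for `rule = "threshold"`.
#' @param eps positivity tolerance for `positive_vs_zero`.
#' @return factor of group labels (`low`/`high` or `absent`/`present`).
#' @export
dichotomize <- function(values,
                        rule = c("median_split", "positive_vs_zero",
                                 "threshold"),
                        t = NULL, eps = 1e-6) {
  rule <- match.arg(rule)
  if (length(values) < 2L || any(!is.finite(values)))
    stop("need >= 2 finite values to dichotomize", call. = FALSE)
  switch(rule,
    median_split = {
      med <- stats::median(values)
      if (all(values == values[1L]))
        stop("degenerate median split: all values identical", call. = FALSE)
      factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
    },
    positive_vs_zero =
      factor(ifelse(values > eps, "present", "absent"),
             levels = c("absent", "present")),
    threshold = {
      if (is.null(t)) stop("rule 'threshold' needs a cut point t",
                           call. = FALSE)
      factor(ifelse(values > t, "high", "low"), levels = c("low", "high"))
    })
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator; the curve starts at 1 and deaths
#' precede censorings at tied times (the standard convention).
#'
#' @param times positive event/censoring times.
#' @param events event indicator (1/TRUE = event, 0/FALSE = censored).
#' @return data.frame with one row per observed time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("times must be positive", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison of two survival curves,
#' 1 degree of freedom, p from the upper chi-square tail.
#'
#' @param times positive times for all patients.
#' @param events event indicators.
#' @param groups two-level grouping factor/vector.
#' @return list with `chi_square`, `df` and `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) != 2L)
    stop("log-rank test needs exactly two non-empty groups", call. = FALSE)
  if (any(table(groups) == 0L))
    stop("both groups must be non-empty", call. = FALSE)
  sd <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ groups)
  chi <- unname(sd$chisq)
  list(chi_square = chi, df = 1L,
       p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE))
}

#' Survival association of a clinical feature
#'
#' Dichotomizes one covariate of a clinical table, estimates a Kaplan-Meier
#' curve per stratum of local progression-free survival, and compares the
#' strata by log-rank test.
#'
#' @param clinical clinical data.frame with `time`, `event` and the feature
#'   column.
#' @param feature column name to stratify on (e.g. `"purity"`,
#'   `"cd8_fraction"`).
#' @param rule,t passed to [dichotomize()].
#' @return a `survival_result` list: `feature`, `rule`, `groups` (labels per
#'   patient), `km` (named list of KM data.frames), `chi_square`, `df`,
#'   `p_value`.
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(seed = 7))
#' res <- survival_association(cohort$clinical, "cd8_fraction",
#'                             rule = "positive_vs_zero")
#' res$p_value
#' @export
survival_association <- function(clinical, feature,
                                 rule = "median_split", t = NULL) {
  validate_clinical(clinical)
  if (!feature %in% names(clinical))
    stop("feature column not found: ", feature, call. = FALSE)
  groups <- dichotomize(clinical[[feature]], rule = rule, t = t)
  if (any(table(groups) == 0L))
    stop("stratification produced an empty group", call. = FALSE)
  km <- lapply(split(seq_len(nrow(clinical)), groups), function(i) {
    km_estimate(clinical$time[i], clinical$event[i])
  })
  lr <- logrank_test(clinical$time, clinical$event, groups)
  structure(list(feature = feature, rule = rule, groups = groups, km = km,
                 chi_square = lr$chi_square, df = lr$df,
                 p_value = lr$p_value),
            class = "survival_result")
}
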