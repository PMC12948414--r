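#' Configuration for a simulated clinical cohort
#'
#' Emulates a ~30-patient retrospective radiotherapy cohort with local
#' progression-free survival (months), right censoring, and two
#' microenvironmental covariates consumed as inputs by the association
#' module: tumor purity (low purity = more microenvironment) and a
#' deconvolution-style CD8 T-cell fraction. Event times are exponential with
#' a group-specific hazard: the "good-response" group has hazard
#' `baseline_hazard * hazard_ratio` and is simulated with lower purity and a
#' nonzero CD8 fraction; the "poor-response" group has the baseline hazard,
#' higher purity, and mostly zero CD8.
#'
#' @param n_per_group patients per response group (cohort size is twice
#'   this; default 15, i.e. n = 30).
#' @param hazard_ratio good-response vs poor-response hazard ratio (< 1 for
#'   a protective microenvironment).
#' @param baseline_hazard poor-response event rate (events/month).
#' @param censor_rate independent exponential censoring rate (events/month).
#' @param seed integer seed.
#' @return a validated `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_per_group = 15, hazard_ratio = 0.25,
                              baseline_hazard = 0.05, censor_rate = 0.02,
                              seed = 1) {
  assert_number(n_per_group, "n_per_group", lower = 1, integer = TRUE)
  assert_number(hazard_ratio, "hazard_ratio", lower = 1e-12)
  assert_number(baseline_hazard, "baseline_hazard", lower = 1e-12)
  assert_number(censor_rate, "censor_rate", lower = 1e-12)
  assert_number(seed, "seed", integer = TRUE)
  structure(list(n_per_group = as.integer(n_per_group),
                 hazard_ratio = hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a clinical cohort
#'
#' @param config a [cohort_sim_config()].
#' @return a `cohort_sim` list: `clinical` (data.frame `id`, `group`,
#'   `time`, `event`, `purity`, `cd8_fraction`), `truth` (per-group true
#'   hazards) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n_per_group
  hazards <- c(poor_response = config$baseline_hazard,
               good_response = config$baseline_hazard * config$hazard_ratio)
  clinical <- with_seed(derive_seed(config$seed, 9L), {
    group <- rep(names(hazards), each = n)
    t_event <- stats::rexp(2 * n, rate = rep(hazards, each = n))
    t_cens <- stats::rexp(2 * n, rate = config$censor_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    # purity: high in tumor-rich poor responders, low with infiltration
    purity <- c(stats::rbeta(n, 8, 3), stats::rbeta(n, 4, 6))
    # CD8: mostly absent in poor responders, present in good responders
    cd8_poor <- ifelse(stats::runif(n) < 0.7, 0, stats::runif(n, 0, 0.02))
    cd8_good <- stats::runif(n, 0.01, 0.10)
    data.frame(id = sprintf("PT%03d", seq_len(2 * n)), group = group,
               time = time, event = event, purity = purity,
               cd8_fraction = c(cd8_poor, cd8_good),
               stringsAsFactors = FALSE)
  })
  structure(list(clinical = clinical,
                 truth = data.frame(group = names(hazards),
                                    hazard = unname(hazards)),
                 config = config),
            class = "cohort_sim")
}
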