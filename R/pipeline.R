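# Orchestration: schema-checked configuration, staged execution from
# simulation through scored outputs, and a machine-readable run report.

pipeline_schema <- list(
  seed = NULL, out_dir = NULL, stages = NULL,
  screen = c("n_genes", "n_ntc", "n_replicates", "mean_depth",
             "abundance_sd_log", "dispersion", "doublings_untreated",
             "doublings_rt", "frac_growth_hits", "frac_rt_hits",
             "effect_size_gamma", "effect_size_rho", "barcode_length",
             "contrast", "threshold", "pseudocount", "alpha",
             "dispersion_pool"),
  cnv = c("n_bins", "bin_size", "noise_sd", "chrom", "spikes", "mode",
          "alpha", "n_perm", "mean_thr", "z_thr", "genes_bed"),
  survival = c("n_per_group", "hazard_ratio", "baseline_hazard",
               "censor_rate", "feature", "rule", "threshold_t"))

check_config_keys <- function(config) {
  unknown <- setdiff(names(config), names(pipeline_schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (blk in c("screen", "cnv", "survival")) {
    if (is.null(config[[blk]])) next
    bad <- setdiff(names(config[[blk]]), pipeline_schema[[blk]])
    if (length(bad))
      stop("unknown configuration key(s) in '", blk, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

take <- function(lst, keys) lst[intersect(names(lst), keys)]

#' Run the simulation-to-results pipeline
#'
#' Executes the requested stages in dependency order — screen simulation and
#' phenotype scoring, copy-number simulation and gene-level deletion
#' calling, cohort simulation and survival association — writing versioned
#' TSV/CSV outputs and a machine-readable YAML report (filter accounting,
#' hit counts, deletion calls, survival p-values) into `out_dir`. The same
#' configuration and seed produce byte-identical outputs. If a stage fails,
#' outputs written so far are retained next to a `FAILED` marker file
#' naming the stage and error.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Top-level keys: `seed`, `out_dir`, `stages` (subset of
#'   `c("screen", "cnv", "survival")`), and per-stage blocks `screen`,
#'   `cnv`, `survival` mirroring the simulator/scoring arguments. Unknown
#'   keys are rejected.
#' @param out_dir output directory (overrides the config entry).
#' @param seed root seed (overrides the config entry).
#' @return the run report, invisibly (also written as `report.yaml`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  check_config_keys(config)
  seed <- seed %||% config$seed %||% 0L
  assert_number(seed, "seed", integer = TRUE)
  seed <- as.integer(seed)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("screen", "cnv", "survival")
  bad <- setdiff(stages, c("screen", "cnv", "survival"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  report <- list(seed = seed, stages = stages)

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(c(paste("stage:", name), paste("error:", conditionMessage(e))),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("screen" %in% stages) run_stage("screen", function() {
    sc <- config$screen %||% list()
    sim_args <- take(sc, setdiff(pipeline_schema$screen,
                                 c("contrast", "threshold", "pseudocount",
                                   "alpha", "dispersion_pool")))
    cfg <- do.call(screen_sim_config, c(sim_args, list(seed = seed)))
    sim <- simulate_screen(cfg)
    write_screen_sim(sim, out_dir)
    tab <- score_screen(sim$counts, sim$sample_sheet,
                        contrast = sc$contrast %||% "rt_vs_untreated",
                        threshold = sc$threshold %||% 50,
                        pseudocount = sc$pseudocount %||% 1,
                        alpha = sc$alpha %||% 0.05,
                        seed = seed,
                        dispersion_pool = sc$dispersion_pool %||% "global")
    write_tsv(tab, file.path(out_dir, "phenotypes.tsv"))
    hits <- call_hits(tab, alpha = sc$alpha %||% 0.05)
    report$screen <<- list(
      contrast = attr(tab, "contrast")$name,
      elements_in = nrow(tab),
      elements_retained = sum(tab$passes_filter),
      elements_filtered = sum(!tab$passes_filter),
      n_enriched = length(hits$enriched),
      n_depleted = length(hits$depleted),
      dispersion = as.numeric(attr(tab, "dispersion")))
  })

  if ("cnv" %in% stages) run_stage("cnv", function() {
    cc <- config$cnv %||% list()
    spikes <- cc$spikes
    if (!is.null(spikes) && !is.data.frame(spikes))
      spikes <- do.call(rbind, lapply(spikes, as.data.frame))
    sim_args <- take(cc, c("n_bins", "bin_size", "noise_sd", "chrom"))
    cfg <- do.call(cnv_sim_config,
                   c(sim_args, list(spikes = spikes, seed = seed)))
    sim <- simulate_cnv_profile(cfg)
    write_bins(sim$bins, file.path(out_dir, "cnv_bins.tsv"))
    genes <- if (is.null(cc$genes_bed)) genes_9p21(targets_only = FALSE)
             else read_bed_genes(cc$genes_bed)
    mode <- cc$mode %||% "detail"
    rep_cnv <- list(mode = mode, n_bins = nrow(sim$bins))
    if (mode %in% c("detail", "both")) {
      det <- gene_detail_score(sim$bins, genes,
                               mean_thr = cc$mean_thr %||% -1,
                               z_thr = cc$z_thr %||% -3,
                               alpha = cc$alpha %||% 0.05)
      write_tsv(det, file.path(out_dir, "cnv_gene_detail.tsv"))
      rep_cnv$detail_deleted <- det$name[det$deleted]
    }
    if (mode %in% c("segment", "both")) {
      segs <- segment_bins(sim$bins, n_perm = cc$n_perm %||% 1000,
                           seed = seed)
      write_tsv(segs, file.path(out_dir, "cnv_segments.tsv"))
      calls <- call_deletions_segment(segs, genes,
                                      mean_thr = cc$mean_thr %||% -1)
      write_tsv(calls, file.path(out_dir, "cnv_segment_calls.tsv"))
      rep_cnv$segment_deleted <- calls$name[calls$deleted]
    }
    report$cnv <<- rep_cnv
  })

  if ("survival" %in% stages) run_stage("survival", function() {
    sv <- config$survival %||% list()
    cfg <- do.call(cohort_sim_config,
                   c(take(sv, c("n_per_group", "hazard_ratio",
                                "baseline_hazard", "censor_rate")),
                     list(seed = seed)))
    sim <- simulate_cohort(cfg)
    write_clinical(sim$clinical, file.path(out_dir, "clinical.csv"))
    feature <- sv$feature %||% "cd8_fraction"
    rule <- sv$rule %||%
      if (feature == "cd8_fraction") "positive_vs_zero" else "median_split"
    res <- survival_association(sim$clinical, feature, rule = rule,
                                t = sv$threshold_t)
    surv_tab <- do.call(rbind, lapply(names(res$km), function(g) {
      cbind(group = g, res$km[[g]])
    }))
    write_tsv(surv_tab, file.path(out_dir, "survival_km.tsv"))
    report$survival <<- list(feature = feature, rule = rule,
                             chi_square = res$chi_square,
                             p_value = res$p_value,
                             n_per_group = as.list(table(res$groups)))
  })

  yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  invisible(report)
}
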