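#' Configuration for a simulated dual-sgRNA CRISPRi screen
#'
#' Describes a pooled screen with three arms (T0 baseline, untreated T14,
#' irradiated T14) run in biologic replicate. Each library element is one
#' barcoded dual-sgRNA construct against a single gene (or a non-targeting
#' control pair). Per-element fitness (`gamma`, doublings^-1) and
#' radiation-response (`rho`, doublings^-1) phenotypes act multiplicatively
#' on expected abundance as `2^(phenotype * doublings)`, after which expected
#' counts are renormalized to the sample's sequencing depth; counts are drawn
#' negative-binomially with `variance = mu + dispersion * mu^2` and a
#' dispersion shared across elements.
#'
#' Arm-specific cumulative population doublings over the 14-day screen are
#' simulator conventions (irradiated cells divide more slowly), defaulting to
#' 10 for the untreated arm and 7 for the irradiated arm.
#'
#' @param n_genes number of gene-targeting elements (one dual-sgRNA element
#'   per gene).
#' @param n_ntc number of non-targeting control elements.
#' @param n_replicates biologic replicates per arm.
#' @param mean_depth expected reads per element per sample.
#' @param abundance_sd_log SD of log baseline element abundance (log-normal
#'   plasmid-pool skew).
#' @param dispersion negative-binomial overdispersion alpha
#'   (`variance = mu + alpha * mu^2`), shared across elements.
#' @param doublings_untreated,doublings_rt cumulative population doublings of
#'   the untreated and irradiated arms at T14.
#' @param frac_growth_hits,frac_rt_hits fraction of genes carrying a true
#'   fitness / radiation-response phenotype.
#' @param effect_size_gamma,effect_size_rho phenotype assigned to those hit
#'   genes (doublings^-1; sign sets direction of selection).
#' @param rho_sign `"balanced"` (default) gives half the radiation-response
#'   hits `+|effect_size_rho|` and half `-|effect_size_rho|`, mirroring the
#'   roughly equal numbers of radio-protective and radio-sensitizing genes a
#'   genome-wide screen detects (a strongly one-sided spike would also shift
#'   the relative abundance of every null element after depth
#'   renormalization); `"fixed"` assigns `effect_size_rho` as given to all.
#' @param barcode_length barcode length in nt.
#' @param seed integer root seed; per-sample counts are drawn from
#'   independent sub-streams derived from it.
#' @return a validated `screen_sim_config` list.
#' @seealso [simulate_screen()], [full_scale_config()]
#' @export
screen_sim_config <- function(n_genes = 2000, n_ntc = 100, n_replicates = 3,
                              mean_depth = 500, abundance_sd_log = 0.5,
                              dispersion = 0.05,
                              doublings_untreated = 10, doublings_rt = 7,
                              frac_growth_hits = 0.05, frac_rt_hits = 0.05,
                              effect_size_gamma = -0.3, effect_size_rho = 0.3,
                              rho_sign = c("balanced", "fixed"),
                              barcode_length = 20, seed = 1) {
  rho_sign <- match.arg(rho_sign)
  assert_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  assert_number(n_ntc, "n_ntc", lower = 0, integer = TRUE)
  assert_number(n_replicates, "n_replicates", lower = 1, integer = TRUE)
  assert_number(mean_depth, "mean_depth", lower = 1e-9)
  assert_number(abundance_sd_log, "abundance_sd_log", lower = 0)
  assert_number(dispersion, "dispersion", lower = 1e-12)
  assert_number(doublings_untreated, "doublings_untreated", lower = 1e-9)
  assert_number(doublings_rt, "doublings_rt", lower = 1e-9)
  assert_number(frac_growth_hits, "frac_growth_hits", lower = 0, upper = 1)
  assert_number(frac_rt_hits, "frac_rt_hits", lower = 0, upper = 1)
  assert_number(effect_size_gamma, "effect_size_gamma")
  assert_number(effect_size_rho, "effect_size_rho")
  assert_number(barcode_length, "barcode_length", lower = 8, integer = TRUE)
  assert_number(seed, "seed", integer = TRUE)
  structure(list(n_genes = as.integer(n_genes), n_ntc = as.integer(n_ntc),
                 n_replicates = as.integer(n_replicates),
                 mean_depth = mean_depth, abundance_sd_log = abundance_sd_log,
                 dispersion = dispersion,
                 doublings_untreated = doublings_untreated,
                 doublings_rt = doublings_rt,
                 frac_growth_hits = frac_growth_hits,
                 frac_rt_hits = frac_rt_hits,
                 effect_size_gamma = effect_size_gamma,
                 effect_size_rho = effect_size_rho, rho_sign = rho_sign,
                 barcode_length = as.integer(barcode_length),
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Full-scale library preset
#'
#' The genome-wide dual-sgRNA library: the top 2 on-target guides per gene for
#' 23,483 genes packaged as one element per gene, plus 1,137 non-targeting
#' control pairs.
#'
#' @param ... overrides passed to [screen_sim_config()] (all but `n_genes`
#'   and `n_ntc`).
#' @return a `screen_sim_config` with `n_genes = 23483`, `n_ntc = 1137`.
#' @export
full_scale_config <- function(...) {
  screen_sim_config(n_genes = 23483L, n_ntc = 1137L, ...)
}

#' Reference recovery preset
#'
#' The parameter-recovery benchmark: 2,000 genes, 100 of them spiked with a
#' radiation-response phenotype of magnitude 0.3 doublings^-1 (no fitness
#' effects), triplicates at 500x per-element depth, dispersion 0.05,
#' doublings 10 (untreated) / 7 (irradiated).
#'
#' @param seed integer root seed.
#' @param effect_size_rho spiked radiation-response phenotype.
#' @return a `screen_sim_config`.
#' @export
reference_recovery_config <- function(seed = 1, effect_size_rho = 0.3) {
  screen_sim_config(n_genes = 2000, n_ntc = 100, n_replicates = 3,
                    mean_depth = 500, dispersion = 0.05,
                    doublings_untreated = 10, doublings_rt = 7,
                    frac_growth_hits = 0, frac_rt_hits = 0.05,
                    effect_size_rho = effect_size_rho, seed = seed)
}

# Build the element catalogue for a config: unique ids and barcodes,
# random 20-nt protospacers. Barcode uniqueness is enforced by redraw.
make_manifest <- function(config) {
  n_g <- config$n_genes; n_n <- config$n_ntc
  genes <- sprintf("GENE%05d", seq_len(n_g))
  element_id <- c(paste0(genes, "_ds"), sprintf("NTC%04d", seq_len(n_n)))
  gene <- c(genes, rep("NTC", n_n))
  n <- n_g + n_n
  bc <- random_dna(n, config$barcode_length)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- random_dna(length(dup), config$barcode_length)
  }
  data.frame(element_id = element_id, gene = gene,
             protospacer_a = random_dna(n, 20L),
             protospacer_b = random_dna(n, 20L),
             barcode = bc,
             is_ntc = gene == "NTC",
             stringsAsFactors = FALSE)
}

#' Simulate a pooled CRISPRi radiotherapy screen
#'
#' Draws a library manifest, per-element true phenotypes, and an
#' element-by-sample count matrix for a three-arm screen (T0, untreated T14,
#' irradiated T14; `n_replicates` biologic replicates each). Expected
#' abundance of element e in a sample with cumulative doublings d is
#' `baseline_e * 2^(effect_e * d)` with `effect = gamma` in the untreated arm,
#' `gamma + rho` in the irradiated arm and 0 at T0, renormalized so every
#' sample has the same expected depth; counts are negative-binomial with
#' shared dispersion. Non-targeting controls always have zero true effects.
#'
#' @param config a [screen_sim_config()].
#' @return a `screen_sim` list: `manifest` (data.frame), `counts` (integer
#'   matrix, elements x samples), `sample_sheet` (data.frame), `truth`
#'   (data.frame `element_id`, `true_gamma`, `true_rho`) and the `config`.
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 50, n_ntc = 5, seed = 1))
#' dim(sim$counts)
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  manifest <- with_seed(derive_seed(config$seed, 1L), make_manifest(config))
  n <- nrow(manifest)
  is_gene <- !manifest$is_ntc

  truth <- with_seed(derive_seed(config$seed, 2L), {
    g <- numeric(n); r <- numeric(n)
    gene_idx <- which(is_gene)
    n_gh <- round(config$frac_growth_hits * length(gene_idx))
    n_rh <- round(config$frac_rt_hits * length(gene_idx))
    if (n_gh > 0) g[sample(gene_idx, n_gh)] <- config$effect_size_gamma
    if (n_rh > 0) {
      rt_idx <- sample(gene_idx, n_rh)
      if (config$rho_sign == "balanced") {
        half <- n_rh %/% 2L
        sgn <- rep(c(1, -1), c(n_rh - half, half))
        r[rt_idx] <- sgn * abs(config$effect_size_rho)
      } else {
        r[rt_idx] <- config$effect_size_rho
      }
    }
    data.frame(element_id = manifest$element_id, true_gamma = g, true_rho = r,
               stringsAsFactors = FALSE)
  })

  baseline <- with_seed(derive_seed(config$seed, 3L),
                        exp(stats::rnorm(n, 0, config$abundance_sd_log)))
  baseline <- baseline / sum(baseline)

  arms <- c(rep("T0", config$n_replicates),
            rep("T14_untreated", config$n_replicates),
            rep("T14_RT", config$n_replicates))
  reps <- rep(seq_len(config$n_replicates), 3L)
  sheet <- data.frame(
    sample_id = paste0(sub("T14_", "", arms), "_", reps),
    arm = arms, replicate = reps,
    doublings = c(rep(0, config$n_replicates),
                  rep(config$doublings_untreated, config$n_replicates),
                  rep(config$doublings_rt, config$n_replicates)),
    stringsAsFactors = FALSE)

  effect <- cbind(T0 = rep(0, n),
                  T14_untreated = truth$true_gamma,
                  T14_RT = truth$true_gamma + truth$true_rho)
  depth_total <- config$mean_depth * n
  counts <- matrix(0L, nrow = n, ncol = nrow(sheet),
                   dimnames = list(manifest$element_id, sheet$sample_id))
  for (s in seq_len(nrow(sheet))) {
    w <- baseline * 2^(effect[, sheet$arm[s]] * sheet$doublings[s])
    mu <- depth_total * w / sum(w)
    counts[, s] <- with_seed(derive_seed(config$seed, 10L + s),
                             stats::rnbinom(n, mu = mu,
                                            size = 1 / config$dispersion))
  }
  storage.mode(counts) <- "integer"

  structure(list(manifest = manifest, counts = counts, sample_sheet = sheet,
                 truth = truth, config = config),
            class = "screen_sim")
}

#' Write all tables of a simulated screen
#'
#' @param sim a `screen_sim` from [simulate_screen()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_screen_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "screen_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(manifest = file.path(dir, "manifest.tsv"),
             counts = file.path(dir, "counts.tsv"),
             sample_sheet = file.path(dir, "sample_sheet.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_manifest(sim$manifest, paths[["manifest"]])
  write_counts(sim$counts, paths[["counts"]])
  write_sample_sheet(sim$sample_sheet, paths[["sample_sheet"]])
  write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}
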