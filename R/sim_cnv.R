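#' Configuration for a simulated copy-number bin profile
#'
#' Emulates bin-level log2 copy-number ratios as produced by methylation-array
#' CNV callers: Gaussian noise around zero, with focal "spikes" (deletions or
#' gains) of a given log2 level over stated intervals. The simulated genome
#' is a single chromosome (default `chr9`) tiled by `n_bins` bins of
#' `bin_size` bp.
#'
#' @param n_bins number of bins.
#' @param bin_size bin width in bp.
#' @param noise_sd SD of the per-bin Gaussian noise (log2 units).
#' @param spikes data.frame with columns `chrom`, `start`, `end`,
#'   `log2_level` (0-based half-open bp coordinates), or NULL for a flat
#'   profile. Spikes must not overlap and must lie within the genome.
#' @param chrom chromosome name for the tiled genome.
#' @param seed integer seed.
#' @return a validated `cnv_sim_config` list.
#' @export
cnv_sim_config <- function(n_bins = 10000, bin_size = 10000, noise_sd = 0.2,
                           spikes = NULL, chrom = "chr9", seed = 1) {
  assert_number(n_bins, "n_bins", lower = 1, integer = TRUE)
  assert_number(bin_size, "bin_size", lower = 1, integer = TRUE)
  assert_number(noise_sd, "noise_sd", lower = 1e-12)
  assert_number(seed, "seed", integer = TRUE)
  genome_len <- as.double(n_bins) * bin_size
  if (!is.null(spikes)) {
    need <- c("chrom", "start", "end", "log2_level")
    miss <- setdiff(need, names(spikes))
    if (length(miss))
      stop("spikes missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (any(spikes$chrom != chrom) ||
        any(spikes$start < 0) || any(spikes$end > genome_len))
      stop("spike intervals must lie within the simulated genome",
           call. = FALSE)
    if (any(spikes$end <= spikes$start))
      stop("spike intervals must have end > start", call. = FALSE)
    sp <- spikes[order(spikes$start), , drop = FALSE]
    if (nrow(sp) > 1L && any(sp$start[-1] < sp$end[-nrow(sp)]))
      stop("spike intervals must not overlap", call. = FALSE)
  }
  structure(list(n_bins = as.integer(n_bins), bin_size = as.integer(bin_size),
                 noise_sd = noise_sd, spikes = spikes, chrom = chrom,
                 seed = as.integer(seed)),
            class = "cnv_sim_config")
}

#' Simulate a bin-level copy-number profile
#'
#' Bin log2 ratios are `spike level + N(0, noise_sd)` inside spike intervals
#' and `N(0, noise_sd)` elsewhere. A bin is "inside" a spike if it overlaps
#' it by at least 1 bp; the spike level applied to a partially overlapping
#' bin is weighted by the overlapped fraction.
#'
#' @param config a [cnv_sim_config()].
#' @return a `cnv_sim` list: `bins` (data.frame `chrom`, `start`, `end`,
#'   `log2ratio`), `truth` (the spike table, possibly NULL) and `config`.
#' @export
simulate_cnv_profile <- function(config) {
  stopifnot(inherits(config, "cnv_sim_config"))
  start <- (seq_len(config$n_bins) - 1) * as.double(config$bin_size)
  end <- start + config$bin_size
  level <- numeric(config$n_bins)
  if (!is.null(config$spikes)) {
    for (i in seq_len(nrow(config$spikes))) {
      sp <- config$spikes[i, ]
      ov <- pmin(end, sp$end) - pmax(start, sp$start)
      w <- pmax(ov, 0) / config$bin_size
      level <- level + w * sp$log2_level
    }
  }
  log2ratio <- level + with_seed(derive_seed(config$seed, 5L),
                                 stats::rnorm(config$n_bins, 0,
                                              config$noise_sd))
  bins <- data.frame(chrom = config$chrom, start = start, end = end,
                     log2ratio = log2ratio, stringsAsFactors = FALSE)
  structure(list(bins = bins, truth = config$spikes, config = config),
            class = "cnv_sim")
}
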