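# Gene-level focal-deletion calling at 9p21.3 from bin-level copy-number
# log2 ratios: (a) circular binary segmentation plus segment-overlap
# thresholds, (b) the genome-wide z-score "detail" statistic.
# Coordinates are 0-based half-open throughout; overlap means >= 1 bp.

#' @useDynLib radscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Bundled chromosome 9p gene intervals
#'
#' Approximate hg19 intervals (0-based half-open) for the 9p21.3 focal
#' deletion targets — `CDKN2A`, `CDKN2B`, `MTAP` and an `IFN_cluster`
#' interval covering the type I interferon gene cluster (the exact extent of
#' "the IFN locus" is a documented convention here and user-overridable) —
#' plus six other 9p genes used as off-target controls.
#'
#' @param targets_only if TRUE (default) return only the four deletion
#'   targets.
#' @return data.frame with columns `name`, `chrom`, `start`, `end`.
#' @export
genes_9p21 <- function(targets_only = TRUE) {
  g <- read_bed_genes(system.file("extdata", "genes_chr9p_hg19.bed",
                                  package = "radscreen", mustWork = TRUE))
  if (targets_only)
    g <- g[g$name %in% c("CDKN2A", "CDKN2B", "MTAP", "IFN_cluster"), ]
  rownames(g) <- NULL
  g
}

# Recursive CBS on one chromosome's bin values. Each emitted segment carries
# the permutation p of the split that created it (1 for a never-split
# chromosome, whose best candidate split was rejected). Returns a matrix of
# (first bin, last bin, p).
cbs_segment_chrom <- function(x, alpha, n_perm, seed) {
  n <- length(x)
  segs <- list()
  recurse <- function(lo, hi, creation_p, depth) {
    m <- hi - lo + 1L
    if (m >= 4L) {
      xs <- x[lo:hi]
      obs <- cbs_max_t(xs)
      perm_t <- with_seed(derive_seed(seed, 1000L + lo * 7L + hi + depth), {
        vapply(seq_len(n_perm),
               function(i) cbs_max_t_stat(sample(xs)), numeric(1))
      })
      p <- (1 + sum(perm_t >= obs$t)) / (n_perm + 1)
      if (!is.na(obs$i) && p < alpha) {
        i <- lo + obs$i - 1L
        j <- lo + obs$j - 1L
        if (i > lo) recurse(lo, i - 1L, p, depth + 1L)
        recurse(i, j, p, depth + 1L)
        if (j < hi) recurse(j + 1L, hi, p, depth + 1L)
        return(invisible())
      }
      if (depth == 0L) creation_p <- p  # unsplit chromosome: rejected-split p
    }
    segs[[length(segs) + 1L]] <<- c(lo, hi, creation_p)
    invisible()
  }
  recurse(1L, n, 1, 0L)
  out <- do.call(rbind, segs)
  out[order(out[, 1L]), , drop = FALSE]
}

#' Segment a bin profile by circular binary segmentation
#'
#' Recursive CBS: at each step the arc of bins maximizing the pooled-variance
#' |t| between member and non-member bins is found by exhaustive scan; the
#' split is accepted if its permutation p-value (bin values permuted within
#' the segment) is below `alpha`, and the flanks and the arc are then
#' segmented recursively (flanks and the arc alike). Every emitted segment
#' carries the permutation p of the split that created it, so the deletion
#' caller sees the significance of the change-points delimiting the segment;
#' a never-split chromosome reports its rejected best split's p (1 for a
#' constant profile). The scan is O(n^2) per segment and `n_perm` permutations
#' rescan each; profiles of up to a few thousand bins per chromosome are
#' practical.
#'
#' @param profile bin data.frame (`chrom`, `start`, `end`, `log2ratio`),
#'   sorted, non-overlapping (validated).
#' @param alpha permutation significance level for accepting a split.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @return a `segment_table` data.frame: `chrom`, `start`, `end`, `n_bins`,
#'   `seg_mean` (mean log2 of member bins), `p_value`.
#' @export
segment_bins <- function(profile, alpha = 0.01, n_perm = 1000, seed = 1) {
  validate_bins(profile)
  assert_number(alpha, "alpha", lower = 0, upper = 1)
  assert_number(n_perm, "n_perm", lower = 1, integer = TRUE)
  assert_number(seed, "seed", integer = TRUE)
  res <- list()
  for (ch in unique(profile$chrom)) {
    b <- profile[profile$chrom == ch, , drop = FALSE]
    if (nrow(b) < 2L)
      stop("need >= 2 bins per chromosome to segment (", ch, ")",
           call. = FALSE)
    bounds <- cbs_segment_chrom(b$log2ratio, alpha, n_perm, seed)
    res[[ch]] <- data.frame(
      chrom = ch,
      start = b$start[bounds[, 1L]],
      end = b$end[bounds[, 2L]],
      n_bins = as.integer(bounds[, 2L] - bounds[, 1L] + 1L),
      seg_mean = vapply(seq_len(nrow(bounds)), function(k) {
        mean(b$log2ratio[bounds[k, 1L]:bounds[k, 2L]])
      }, numeric(1)),
      p_value = bounds[, 3L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("segment_table", "data.frame")
  out
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(start = genes$start + 1L,
                                          end = genes$end))
}

#' Call gene deletions from a segment table
#'
#' A gene is called deleted when at least one segment overlapping it by
#' >= 1 bp has `seg_mean < mean_thr` and `p_value < p_thr`
#' (defaults: log2 segment mean < -1, p < 0.01).
#'
#' @param segments a `segment_table` (from [segment_bins()] or read from an
#'   external segmentation) with `chrom`, `start`, `end`, `seg_mean`,
#'   `p_value`.
#' @param genes gene intervals data.frame (`name`, `chrom`, `start`, `end`),
#'   e.g. [genes_9p21()].
#' @param mean_thr segment-mean threshold (log2 units).
#' @param p_thr segment p-value threshold.
#' @return data.frame per gene: `name`, `deleted`, `min_seg_mean`,
#'   `min_seg_p` (over overlapping segments; NA when none overlap).
#' @export
call_deletions_segment <- function(segments, genes, mean_thr = -1,
                                   p_thr = 0.01) {
  need <- c("chrom", "start", "end", "seg_mean", "p_value")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop("segment table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  unmatched <- setdiff(unique(genes$chrom), unique(segments$chrom))
  if (length(unmatched))
    stop("gene chromosome(s) absent from segment table: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(start = segments$start + 1L,
                                     end = segments$end))
  ov <- GenomicRanges::findOverlaps(genes_to_granges(genes), seg_gr)
  out <- data.frame(name = genes$name, deleted = FALSE,
                    min_seg_mean = NA_real_, min_seg_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in seq_len(nrow(genes))) {
    hit <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == g]
    if (!length(hit)) next
    out$min_seg_mean[g] <- min(segments$seg_mean[hit])
    out$min_seg_p[g] <- min(segments$p_value[hit])
    out$deleted[g] <- any(segments$seg_mean[hit] < mean_thr &
                            segments$p_value[hit] < p_thr)
  }
  out
}

#' Gene-level detail (z-score) deletion statistic
#'
#' For each gene, the mean log2 ratio `r_g` of bins overlapping it (>= 1 bp)
#' is compared against the distribution of bin values across the whole
#' genome: `z_g = (r_g - mu) / sigma` with `mu`, `sigma` the mean and
#' population SD of all bins. The p-value is the lower-tail normal
#' probability of `z_g` (deletions are the target; `two_sided = TRUE` doubles
#' the tail), BH-adjusted across scored genes. A gene is called deleted when
#' `r_g < -1`, `z_g < -3` and adjusted p < 0.05.
#'
#' Genes on sex chromosomes are dropped by default (array probes on X/Y are
#' conventionally removed upstream). A gene overlapping no bin gets NA
#' statistics, with a warning.
#'
#' @param profile bin data.frame (`chrom`, `start`, `end`, `log2ratio`).
#' @param genes gene intervals data.frame, e.g. [genes_9p21()].
#' @param mean_thr,z_thr,alpha the three deletion-call thresholds.
#' @param two_sided use a two-sided p-value.
#' @param exclude_sex drop genes on chrX/chrY/X/Y.
#' @return a `gene_detail_table` data.frame: `name`, `n_bins`, `mean_log2`,
#'   `z_score`, `p_value`, `p_adj`, `deleted`.
#' @export
gene_detail_score <- function(profile, genes, mean_thr = -1, z_thr = -3,
                              alpha = 0.05, two_sided = FALSE,
                              exclude_sex = TRUE) {
  validate_bins(profile)
  if (exclude_sex)
    genes <- genes[!genes$chrom %in% c("chrX", "chrY", "X", "Y"), ,
                   drop = FALSE]
  if (nrow(genes) == 0L) stop("no genes to score", call. = FALSE)
  mu <- mean(profile$log2ratio)
  n <- nrow(profile)
  sigma <- sqrt(sum((profile$log2ratio - mu)^2) / n)  # population SD
  bin_gr <- GenomicRanges::GRanges(
    profile$chrom, IRanges::IRanges(start = profile$start + 1L,
                                    end = profile$end))
  ov <- GenomicRanges::findOverlaps(genes_to_granges(genes), bin_gr)
  r <- rep(NA_real_, nrow(genes))
  nb <- integer(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    hit <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == g]
    nb[g] <- length(hit)
    if (length(hit)) r[g] <- mean(profile$log2ratio[hit])
  }
  if (any(nb == 0L))
    warning("gene(s) with no overlapping bins: ",
            paste(genes$name[nb == 0L], collapse = ", "), call. = FALSE)
  z <- (r - mu) / sigma
  p <- stats::pnorm(z)
  if (two_sided) p <- 2 * pmin(p, 1 - p)
  p_adj <- adjust_bh(p)
  out <- data.frame(name = genes$name, n_bins = nb, mean_log2 = r,
                    z_score = z, p_value = p, p_adj = p_adj,
                    deleted = !is.na(r) & r < mean_thr & z < z_thr &
                      p_adj < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_detail_table", "data.frame")
  out
}

#' Reference 9p21.3 deletion fixture configuration
#'
#' A chr9p-like profile (4,000 bins of 10 kb, 40 Mb) with one focal -1.5
#' deletion spanning 21.0-22.2 Mb — covering the `IFN_cluster`, `MTAP`,
#' `CDKN2A` and `CDKN2B` intervals of [genes_9p21()] — at the stated noise.
#'
#' @param seed integer seed.
#' @param noise_sd per-bin noise SD (log2 units).
#' @param level deletion log2 level.
#' @return a `cnv_sim_config`.
#' @export
cnv_deletion_config <- function(seed = 1, noise_sd = 0.2, level = -1.5) {
  cnv_sim_config(n_bins = 4000, bin_size = 10000, noise_sd = noise_sd,
                 spikes = data.frame(chrom = "chr9", start = 21.0e6,
                                     end = 22.2e6, log2_level = level),
                 chrom = "chr9", seed = seed)
}
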