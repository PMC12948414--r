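# Copy-number segmentation and the two gene-level deletion callers.

test_that("constant profile yields one segment per chromosome with p 1", {
  bins <- data.frame(chrom = "chr9", start = seq(0, 99) * 1000,
                     end = seq(1, 100) * 1000, log2ratio = 0.3)
  segs <- segment_bins(bins, n_perm = 200, seed = 1)
  expect_identical(nrow(segs), 1L)
  expect_equal(segs$p_value, 1)
  expect_equal(segs$seg_mean, 0.3)
  expect_identical(segs$n_bins, 100L)
})

test_that("step profile breakpoint is recovered within 2 bins", {
  sim <- simulate_cnv_profile(cnv_sim_config(
    n_bins = 400, bin_size = 10000, noise_sd = 0.2,
    spikes = data.frame(chrom = "chr9", start = 2e6, end = 4e6,
                        log2_level = -1.5), seed = 17))
  segs <- segment_bins(sim$bins, n_perm = 500, seed = 2)
  # the -1.5 segment's boundaries should sit at 2 Mb and 4 Mb (+- 2 bins)
  del <- segs[segs$seg_mean < -1, ]
  expect_identical(nrow(del), 1L)
  expect_lte(abs(del$start - 2e6), 2 * 10000)
  expect_lte(abs(del$end - 4e6), 2 * 10000)
  expect_lt(del$p_value, 0.01)
})

test_that("segments partition the bins and seg_mean is the member mean", {
  sim <- simulate_cnv_profile(cnv_sim_config(
    n_bins = 300, bin_size = 5000, noise_sd = 0.25,
    spikes = data.frame(chrom = "chr9", start = c(2e5, 9e5),
                        end = c(4e5, 1.05e6), log2_level = c(-1.2, 0.9)),
    seed = 23))
  segs <- segment_bins(sim$bins, n_perm = 300, seed = 3)
  expect_identical(sum(segs$n_bins), 300L)
  expect_equal(segs$start[1], 0)
  expect_equal(segs$end[nrow(segs)], 300 * 5000)
  expect_true(all(segs$start[-1] == segs$end[-nrow(segs)]))
  for (k in seq_len(nrow(segs))) {
    member <- sim$bins$start >= segs$start[k] & sim$bins$end <= segs$end[k]
    expect_lt(abs(segs$seg_mean[k] - mean(sim$bins$log2ratio[member])), 1e-9)
  }
  expect_error(segment_bins(sim$bins[c(2, 1, 3:300), ]), "sorted")
})

test_that("segment-overlap deletion calls follow both thresholds", {
  segs <- data.frame(
    chrom = "chr9",
    start = c(0, 21.5e6, 23e6),
    end = c(21.5e6, 23e6, 40e6),
    n_bins = c(100, 10, 100),
    seg_mean = c(0.01, -1.4, -1.4),
    p_value = c(1, 0.001, 0.05))
  genes <- genes_9p21()
  calls <- call_deletions_segment(segs, genes)
  # the significant deep segment spans MTAP/CDKN2A/CDKN2B but not the
  # IFN cluster (ends at 21.48 Mb < 21.5 Mb)
  expect_identical(calls$deleted[calls$name == "CDKN2A"], TRUE)
  expect_identical(calls$deleted[calls$name == "CDKN2B"], TRUE)
  expect_identical(calls$deleted[calls$name == "MTAP"], TRUE)
  expect_identical(calls$deleted[calls$name == "IFN_cluster"], FALSE)
  # deep but non-significant segment (p = 0.05) never calls
  segs2 <- segs; segs2$p_value[2] <- 0.05
  expect_true(!any(call_deletions_segment(segs2, genes)$deleted))
  # shallow segments never call
  segs3 <- segs; segs3$seg_mean[2] <- -0.9
  expect_true(!any(call_deletions_segment(segs3, genes)$deleted))
  # chromosome naming mismatch is an explicit error
  genes_bad <- genes; genes_bad$chrom <- "9"
  expect_error(call_deletions_segment(segs, genes_bad), "9")
})

test_that("detail z-scores follow their definition and the 3-part call rule", {
  # genome of 1000 bins: 996 background at +-0.1, 4 gene bins at -1.5
  n <- 1000
  vals <- rep(c(0.1, -0.1), length.out = n)
  vals[501:504] <- -1.5
  bins <- data.frame(chrom = "chr9", start = (0:(n - 1)) * 1000,
                     end = (1:n) * 1000, log2ratio = vals)
  genes <- data.frame(name = c("DEL", "FLAT"),
                      chrom = "chr9",
                      start = c(500000, 100000),
                      end = c(504000, 110000))
  det <- gene_detail_score(bins, genes)
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))
  expect_equal(det$mean_log2[det$name == "DEL"], -1.5)
  expect_equal(det$z_score[det$name == "DEL"], (-1.5 - mu) / sigma,
               tolerance = 1e-12)
  expect_equal(det$p_value, pnorm(det$z_score), tolerance = 1e-12)
  expect_identical(det$deleted[det$name == "DEL"], TRUE)
  expect_identical(det$deleted[det$name == "FLAT"], FALSE)
  expect_true(all(det$deleted == (det$mean_log2 < -1 & det$z_score < -3 &
                                    det$p_adj < 0.05)))
})

test_that("flat profiles produce no deletion calls and near-zero z", {
  sim <- simulate_cnv_profile(cnv_sim_config(n_bins = 4000, bin_size = 10000,
                                             noise_sd = 0.2, seed = 31))
  det <- gene_detail_score(sim$bins, genes_9p21(targets_only = FALSE))
  expect_true(!any(det$deleted))
  expect_lt(max(abs(det$z_score[det$n_bins >= 10])), 1.5)
})

test_that("genes without bins get NA with a warning; sex chromosomes drop", {
  bins <- data.frame(chrom = "chr9", start = (0:99) * 1000,
                     end = (1:100) * 1000, log2ratio = 0)
  genes <- data.frame(name = c("IN", "OUT", "XG"),
                      chrom = c("chr9", "chr9", "chrX"),
                      start = c(1000, 2e6, 0), end = c(5000, 2.1e6, 1e4))
  expect_warning(det <- gene_detail_score(bins, genes), "OUT")
  expect_identical(det$name, c("IN", "OUT"))
  expect_true(is.na(det$mean_log2[det$name == "OUT"]))
})

test_that("deeper spikes never shrink the called set", {
  call_at <- function(level) {
    sim <- simulate_cnv_profile(cnv_deletion_config(seed = 11, level = level))
    det <- gene_detail_score(sim$bins, genes_9p21(targets_only = FALSE))
    det$name[det$deleted]
  }
  shallow <- call_at(-1.2)
  deep <- call_at(-2.5)
  expect_true(all(shallow %in% deep))
})

test_that("segment and detail callers agree on an unambiguous deletion", {
  sim <- simulate_cnv_profile(cnv_sim_config(
    n_bins = 400, bin_size = 100000, noise_sd = 0.05,
    spikes = data.frame(chrom = "chr9", start = 21.0e6, end = 22.2e6,
                        log2_level = -2), seed = 13))
  genes <- genes_9p21(targets_only = FALSE)
  det <- gene_detail_score(sim$bins, genes)
  segs <- segment_bins(sim$bins, n_perm = 500, seed = 4)
  seg_calls <- call_deletions_segment(segs, genes)
  targets <- c("CDKN2A", "CDKN2B", "MTAP", "IFN_cluster")
  expect_setequal(det$name[det$deleted], targets)
  expect_setequal(seg_calls$name[seg_calls$deleted], targets)
})
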