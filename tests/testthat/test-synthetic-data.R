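# Screen, copy-number and cohort simulators: determinism, null behavior,
# spike expectations, and config validation.

test_that("screen simulator is deterministic and structurally sound", {
  cfg <- screen_sim_config(n_genes = 50, n_ntc = 5, seed = 3)
  sim1 <- simulate_screen(cfg)
  sim2 <- simulate_screen(cfg)
  expect_identical(sim1, sim2)
  expect_identical(nrow(sim1$manifest), 55L)
  expect_identical(dim(sim1$counts), c(55L, 9L))
  # truth covers every element; NTCs have zero effects
  expect_identical(sim1$truth$element_id, sim1$manifest$element_id)
  ntc <- sim1$manifest$is_ntc
  expect_true(all(sim1$truth$true_gamma[ntc] == 0))
  expect_true(all(sim1$truth$true_rho[ntc] == 0))
  expect_true(all(sim1$counts >= 0L))
})

test_that("null screen is symmetric: mean RT vs untreated log2 ratio ~ 0", {
  cfg <- screen_sim_config(n_genes = 2000, n_ntc = 0, n_replicates = 3,
                           frac_growth_hits = 0, frac_rt_hits = 0, seed = 1)
  sim <- simulate_screen(cfg)
  contrast <- make_contrast("rt_vs_untreated", sim$sample_sheet)
  l2fc <- log2_ratio(downsample_counts(sim$counts, seed = 0), contrast,
                     sim$sample_sheet)
  expect_lt(abs(mean(l2fc)), 0.02)
})

test_that("spiked rho shows up as l2fc ~ rho * doublings over the null", {
  # equal doublings in both T14 arms so the realized RT/untreated log2
  # ratio of a spiked element has expectation rho * d = 0.3 * 5 = 1.5
  cfg <- screen_sim_config(n_genes = 2000, n_ntc = 0,
                           doublings_untreated = 5, doublings_rt = 5,
                           frac_growth_hits = 0, frac_rt_hits = 0.05,
                           effect_size_rho = 0.3, rho_sign = "fixed",
                           seed = 7)
  sim <- simulate_screen(cfg)
  contrast <- make_contrast("rt_vs_untreated", sim$sample_sheet)
  l2fc <- log2_ratio(downsample_counts(sim$counts, seed = 0), contrast,
                     sim$sample_sheet)
  spiked <- sim$truth$true_rho != 0
  expect_identical(sum(spiked), 100L)
  # measured against the null median, which absorbs the (small) common
  # depth-renormalization offset
  expect_lt(abs(mean(l2fc[spiked]) - median(l2fc[!spiked]) - 1.5), 0.1)
})

test_that("invalid screen configs are rejected", {
  expect_error(screen_sim_config(n_genes = 0), "n_genes")
  expect_error(screen_sim_config(dispersion = -1), "dispersion")
  expect_error(screen_sim_config(frac_rt_hits = 1.2), "frac_rt_hits")
  expect_error(screen_sim_config(mean_depth = Inf), "mean_depth")
})

test_that("fastq emission and error-free counting round-trip exactly", {
  sim <- simulate_screen(screen_sim_config(n_genes = 30, n_ntc = 3,
                                           mean_depth = 40, seed = 4))
  d <- withr::local_tempdir()
  sheet <- simulate_reads(sim, error_rate = 0, seed = 5, dir = d)
  bc <- count_barcodes(sheet, sim$manifest, tolerance = 0)
  expect_identical(bc$counts, sim$counts)
  expect_true(all(bc$unassigned == 0L))
})

test_that("substitution errors are recovered at tolerance 1 near the binomial rate", {
  sim <- simulate_screen(screen_sim_config(n_genes = 40, n_ntc = 4,
                                           mean_depth = 60, seed = 6))
  d <- withr::local_tempdir()
  sheet <- simulate_reads(sim, error_rate = 0.02, seed = 8, dir = d)
  bc <- count_barcodes(sheet, sim$manifest, tolerance = 1)
  # P(<= 1 substitution in 20 nt at 2%) = 0.98^20 + 20 * 0.02 * 0.98^19
  p_keep <- 0.98^20 + 20 * 0.02 * 0.98^19
  frac <- sum(bc$counts) / sum(sim$counts)
  expect_gt(frac, p_keep - 0.02)
  expect_lte(frac, 1)
  # read conservation holds with errors too
  expect_true(all(colSums(bc$counts) + bc$unassigned == bc$total))
})

test_that("an all-zero count matrix emits zero reads", {
  sim <- simulate_screen(screen_sim_config(n_genes = 5, n_ntc = 1,
                                           mean_depth = 10, seed = 9))
  sim$counts[] <- 0L
  d <- withr::local_tempdir()
  sheet <- simulate_reads(sim, error_rate = 0, seed = 1, dir = d)
  expect_true(all(file.size(sheet$fastq_path) == 0))
  bc <- count_barcodes(sheet, sim$manifest, tolerance = 0)
  expect_true(all(bc$counts == 0L))
  expect_true(all(bc$total == 0L))
})

test_that("cnv simulator: zero-mean noise, spike level, determinism", {
  cfg <- cnv_sim_config(n_bins = 10000, bin_size = 10000, noise_sd = 0.2,
                        seed = 7)
  sim <- simulate_cnv_profile(cfg)
  expect_lt(abs(mean(sim$bins$log2ratio)), 0.01)
  expect_identical(sim, simulate_cnv_profile(cfg))

  spike <- data.frame(chrom = "chr9", start = 21.0e6, end = 22.2e6,
                      log2_level = -1.5)
  sim2 <- simulate_cnv_profile(cnv_sim_config(n_bins = 10000,
                                              bin_size = 10000,
                                              noise_sd = 0.2, spikes = spike,
                                              seed = 7))
  inside <- sim2$bins$start >= 21.0e6 & sim2$bins$end <= 22.2e6
  expect_lt(abs(mean(sim2$bins$log2ratio[inside]) + 1.5), 0.05)
})

test_that("overlapping or out-of-genome spikes are rejected", {
  sp <- data.frame(chrom = "chr9", start = c(1e6, 1.5e6), end = c(2e6, 2.5e6),
                   log2_level = -1)
  expect_error(cnv_sim_config(n_bins = 1000, bin_size = 10000, spikes = sp),
               "overlap")
  sp2 <- data.frame(chrom = "chr9", start = 9e6, end = 11e6, log2_level = -1)
  expect_error(cnv_sim_config(n_bins = 1000, bin_size = 10000, spikes = sp2),
               "within")
})

test_that("cohort simulator: determinism and microenvironment structure", {
  cfg <- cohort_sim_config(seed = 5)
  sim <- simulate_cohort(cfg)
  expect_identical(sim, simulate_cohort(cfg))
  cl <- sim$clinical
  expect_identical(nrow(cl), 30L)
  good <- cl$group == "good_response"
  expect_true(all(cl$cd8_fraction[good] > 0))
  expect_lt(mean(cl$purity[good]), mean(cl$purity[!good]))
  expect_true(all(cl$time > 0))
  expect_true(all(cl$event %in% 0:1))
})

test_that("cohort log-rank power is adequate at the design hazard ratio", {
  # HR 0.25, 15/group: Monte-Carlo power at alpha 0.05 over 200 cohorts
  rej <- vapply(1:200, function(s) {
    cl <- simulate_cohort(cohort_sim_config(hazard_ratio = 0.25,
                                            seed = s))$clinical
    logrank_test(cl$time, cl$event, cl$group)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.5)
})
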