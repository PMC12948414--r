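# Phenotype scoring chain: downsampling, filtering, ratios, doubling
# normalization, NB Wald test, BH, hit calling.

test_that("downsampling equalizes column totals exactly and is seeded", {
  m <- matrix(c(10L, 30L, 60L, 5L, 20L, 25L), ncol = 2,
              dimnames = list(paste0("e", 1:3), c("a", "b")))
  out <- downsample_counts(m, seed = 1)
  expect_identical(colSums(out), c(a = 50, b = 50))
  expect_true(all(out <= m))
  expect_identical(out[, "b"], m[, "b"])  # already at the minimum
  expect_identical(out, downsample_counts(m, seed = 1))
  # equal totals: identity
  eq <- matrix(c(5L, 5L, 4L, 6L), ncol = 2,
               dimnames = list(c("x", "y"), c("a", "b")))
  expect_identical(downsample_counts(eq, seed = 3), eq)
  # single sample: unchanged
  single <- m[, 1, drop = FALSE]
  expect_identical(downsample_counts(single, seed = 2), single)
  # zero-total sample is an error naming the sample
  z <- m; z[, 2] <- 0L
  expect_error(downsample_counts(z), "b")
})

test_that("low-count filter applies the >=50-in-every-sample rule", {
  counts <- rbind(a = c(49L, 60L, 70L), b = c(0L, 0L, 0L),
                  c = c(50L, 50L, 50L), d = c(51L, 200L, 80L))
  colnames(counts) <- paste0("s", 1:3)
  mask <- filter_low_counts(counts, threshold = 50)
  expect_identical(unname(mask), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(filter_low_counts(counts, threshold = -1), "threshold")
})

test_that("log2 ratio: identity, hand arithmetic, antisymmetry", {
  sheet <- tiny_sheet(n = 2)
  counts <- tiny_counts(t0 = cbind(c(99L, 120L), c(99L, 120L)),
                        untreated = cbind(c(99L, 80L), c(99L, 80L)),
                        rt = cbind(c(198L, 80L), c(200L, 80L)),
                        sheet = sheet)
  fwd <- make_contrast("rt_vs_untreated", sheet)
  l2 <- log2_ratio(counts, fwd, sheet, pseudocount = 1)
  expect_equal(unname(l2[1]), 1)          # (199+1)/(99+1) = 2
  expect_equal(unname(l2[2]), 0)          # identical arm means
  # swapping arms negates the ratio
  rev <- fwd
  rev[c("numerator_arm", "denominator_arm")] <-
    rev[c("denominator_arm", "numerator_arm")]
  expect_equal(log2_ratio(counts, rev, sheet), -l2)
})

test_that("doubling normalization scales as stated", {
  sheet <- tiny_sheet(n = 2, du = 8)
  contrast <- make_contrast("untreated_vs_t0", sheet)
  expect_equal(doubling_normalize(c(0, 2), contrast), c(0, 0.25))
  contrast1 <- make_contrast("untreated_vs_t0", sheet,
                             doubling_normalizer = 1)
  expect_equal(doubling_normalize(c(-1.3, 2), contrast1), c(-1.3, 2))
  contrast$doubling_normalizer <- 0
  expect_error(doubling_normalize(1, contrast), "positive")
})

test_that("Wald test: null identity and agreement with an NB LR oracle", {
  sheet <- tiny_sheet(n = 3)
  counts <- tiny_counts(
    t0 = matrix(100L, 2, 3),
    untreated = rbind(c(100L, 110L, 95L), c(500L, 500L, 500L)),
    rt = rbind(c(1000L, 1010L, 990L), c(500L, 500L, 500L)),
    sheet = sheet)
  contrast <- make_contrast("rt_vs_untreated", sheet)
  wt <- wald_test(counts, contrast, sheet)
  # identical counts in both arms -> stat 0, p 1
  expect_identical(wt$wald_stat[2], 0)
  expect_identical(wt$p_value[2], 1)
  # strong 10x enrichment is overwhelmingly significant
  expect_lt(wt$p_value[1], 1e-4)
  # oracle: NB likelihood ratio at the same fitted dispersion
  alpha <- attr(wt, "dispersion")
  y1 <- counts[1, sheet$sample_id[sheet$arm == "T14_RT"]]
  y2 <- counts[1, sheet$sample_id[sheet$arm == "T14_untreated"]]
  ll <- function(y, mu) sum(stats::dnbinom(y, mu = mu, size = 1 / alpha,
                                           log = TRUE))
  lr <- 2 * (ll(y1, mean(y1)) + ll(y2, mean(y2)) -
               ll(c(y1, y2), mean(c(y1, y2))))
  p_lr <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  expect_lt(p_lr, 1e-4)
  # the two routes agree on the log-p scale for this clear-cut case
  # (floored to dodge underflow of doubles at extreme significance)
  expect_lt(abs(log10(pmax(p_lr, 1e-300)) -
                  log10(pmax(wt$p_value[1], 1e-300))), 20)
  keep <- setdiff(sheet$sample_id, c("RT_1", "RT_2"))
  expect_error(wald_test(counts[, keep], contrast,
                         sheet[sheet$sample_id %in% keep, ]), ">= 2")
})

test_that("per-element dispersion pooling is available and distinct", {
  sheet <- tiny_sheet(n = 3)
  set.seed(33)
  counts <- tiny_counts(
    t0 = matrix(rpois(30, 100), 10, 3),
    untreated = matrix(rnbinom(30, mu = 200, size = 10), 10, 3),
    rt = matrix(rnbinom(30, mu = 260, size = 10), 10, 3),
    sheet = sheet)
  contrast <- make_contrast("rt_vs_untreated", sheet)
  wt_g <- wald_test(counts, contrast, sheet, dispersion_pool = "global")
  wt_e <- wald_test(counts, contrast, sheet, dispersion_pool = "element")
  expect_false(isTRUE(all.equal(wt_g$wald_stat, wt_e$wald_stat)))
  expect_true(all(is.finite(wt_g$wald_stat)))
})

test_that("BH adjustment matches hand computation and handles NA", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
  p <- c(0.001, 0.2, 0.03, NA, 0.9)
  expect_true(all(adjust_bh(p) >= p, na.rm = TRUE))
})

test_that("hit calling follows the adjusted-p / sign rule", {
  tab <- data.frame(
    element_id = paste0("e", 1:5),
    phenotype = c(0.2, -0.1, 0.3, -0.4, 0.5),
    p_adj = c(0.04, 0.04, 0.2, 0.01, NA),
    passes_filter = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  hits <- call_hits(tab, alpha = 0.05)
  expect_identical(hits$enriched, "e1")
  expect_identical(hits$depleted, c("e2", "e4"))
  empty <- call_hits(tab[0, ])
  expect_length(empty$enriched, 0)
  expect_length(empty$depleted, 0)
})

test_that("score_screen output satisfies its contract", {
  sim <- simulate_screen(screen_sim_config(n_genes = 300, n_ntc = 30,
                                           seed = 21))
  tab <- score_screen(sim$counts, sim$sample_sheet, "rt_vs_untreated")
  expect_s3_class(tab, "phenotype_table")
  expect_identical(tab$element_id, sim$manifest$element_id)
  ok <- tab$passes_filter
  expect_true(all(tab$p_adj[ok] >= tab$p_value[ok]))
  expect_identical(tab$call == "filtered", !tab$passes_filter)
  nz <- ok & tab$l2fc != 0
  expect_true(all(sign(tab$phenotype[nz]) == sign(tab$l2fc[nz])))
  expect_true(all(is.na(tab$p_value[!ok])))
})

test_that("reversing a contrast negates phenotypes and keeps p-values", {
  sim <- simulate_screen(screen_sim_config(n_genes = 200, n_ntc = 20,
                                           seed = 31))
  sheet <- sim$sample_sheet
  counts <- downsample_counts(sim$counts, seed = 0)
  fwd <- make_contrast("rt_vs_untreated", sheet)
  rev <- fwd
  rev[c("numerator_arm", "denominator_arm")] <-
    rev[c("denominator_arm", "numerator_arm")]
  mask <- filter_low_counts(counts)
  p_f <- doubling_normalize(log2_ratio(counts, fwd, sheet), fwd)
  p_r <- doubling_normalize(log2_ratio(counts, rev, sheet), rev)
  expect_equal(p_r, -p_f)
  w_f <- wald_test(counts, fwd, sheet, mask = mask)
  w_r <- wald_test(counts, rev, sheet, mask = mask)
  expect_equal(w_r$p_value, w_f$p_value, tolerance = 1e-12)
  expect_equal(w_r$wald_stat, -w_f$wald_stat, tolerance = 1e-12)
})

test_that("NTC elements behave as nulls in a null screen", {
  sim <- simulate_screen(screen_sim_config(n_genes = 1000, n_ntc = 200,
                                           frac_growth_hits = 0,
                                           frac_rt_hits = 0, seed = 41))
  tab <- score_screen(sim$counts, sim$sample_sheet, "rt_vs_untreated")
  ntc <- grepl("^NTC", tab$element_id) & tab$passes_filter
  expect_lt(abs(median(tab$phenotype[ntc])), 0.02)
  n_tested <- sum(!is.na(tab$p_adj))
  se <- sqrt(0.05 * 0.95 / n_tested)
  expect_lte(mean(tab$p_adj < 0.05, na.rm = TRUE), 0.05 + 2 * se)
})

test_that("gene-level aggregation applies min-p with Bonferroni", {
  tab <- data.frame(
    element_id = c("e1", "e2", "e3", "e4"),
    phenotype = c(0.3, 0.1, -0.2, 0.4),
    p_value = c(0.001, 0.5, 0.04, NA),
    p_adj = c(0.004, 0.6, 0.08, NA),
    passes_filter = c(TRUE, TRUE, TRUE, FALSE))
  manifest <- data.frame(element_id = paste0("e", 1:4),
                         gene = c("G1", "G1", "G2", "G2"))
  g <- gene_level_table(tab, manifest)
  # G1: min p 0.001 over 2 tested elements -> 0.002, phenotype of e1
  expect_equal(g$p_value[g$gene == "G1"], 0.002)
  expect_equal(g$phenotype[g$gene == "G1"], 0.3)
  expect_identical(g$n_elements[g$gene == "G1"], 2L)
  # G2: e4 filtered, single tested element -> p unchanged
  expect_equal(g$p_value[g$gene == "G2"], 0.04)
  expect_identical(g$n_elements[g$gene == "G2"], 1L)
  expect_equal(g$p_adj, adjust_bh(g$p_value))
})
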