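# Screen phenotype scoring: depth-equalizing downsampling, low-count
# filtering, log2 ratio contrasts, population-doubling normalization,
# negative-binomial Wald testing, BH correction and hit calling.

#' Define a scoring contrast
#'
#' Three contrasts are scored in a radiotherapy screen: irradiated vs
#' untreated at T14 (the radiation-response phenotype, rho-type), untreated
#' T14 vs T0 (the fitness phenotype, gamma-type) and irradiated T14 vs T0
#' (the combined phenotype, tau-type). The doubling normalizer defaults to
#' the untreated arm's cumulative population doublings for every contrast
#' (one screen-wide doubling count); pass `doubling_normalizer` to use an
#' arm-specific value instead.
#'
#' @param name one of `"rt_vs_untreated"`, `"untreated_vs_t0"`, `"rt_vs_t0"`.
#' @param sample_sheet sample sheet data.frame (used to locate arm samples
#'   and the default normalizer).
#' @param doubling_normalizer positive real; population doublings used to
#'   convert log2 ratios to doublings^-1 phenotypes.
#' @return a `screen_contrast` list with `name`, `numerator_arm`,
#'   `denominator_arm`, `doubling_normalizer`.
#' @export
make_contrast <- function(name = c("rt_vs_untreated", "untreated_vs_t0",
                                   "rt_vs_t0"),
                          sample_sheet, doubling_normalizer = NULL) {
  name <- match.arg(name)
  validate_sample_sheet(sample_sheet)
  arms <- switch(name,
                 rt_vs_untreated = c("T14_RT", "T14_untreated"),
                 untreated_vs_t0 = c("T14_untreated", "T0"),
                 rt_vs_t0 = c("T14_RT", "T0"))
  for (a in arms)
    if (!a %in% sample_sheet$arm)
      stop("arm absent from sample sheet: ", a, call. = FALSE)
  if (is.null(doubling_normalizer)) {
    d <- unique(sample_sheet$doublings[sample_sheet$arm == "T14_untreated"])
    if (length(d) != 1L)
      stop("untreated arm doublings not unique; pass doubling_normalizer",
           call. = FALSE)
    doubling_normalizer <- d
  }
  assert_number(doubling_normalizer, "doubling_normalizer", lower = 1e-12)
  structure(list(name = name, numerator_arm = arms[1L],
                 denominator_arm = arms[2L],
                 doubling_normalizer = doubling_normalizer),
            class = "screen_contrast")
}

contrast_samples <- function(contrast, sample_sheet, counts) {
  num <- sample_sheet$sample_id[sample_sheet$arm == contrast$numerator_arm]
  den <- sample_sheet$sample_id[sample_sheet$arm == contrast$denominator_arm]
  miss <- setdiff(c(num, den), colnames(counts))
  if (length(miss))
    stop("sample(s) missing from count matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  list(num = num, den = den)
}

#' Downsample counts to equal per-sample depth
#'
#' Trims every sample (column) to the minimum input column total by sampling
#' reads without replacement (multivariate hypergeometric), so all column
#' totals are exactly equal afterwards. Columns already at the minimum are
#' returned unchanged.
#'
#' @param counts integer element x sample matrix.
#' @param seed integer seed (per-column sub-streams derived from it).
#' @return an integer matrix of the same shape with equal column totals.
#' @export
downsample_counts <- function(counts, seed = 0) {
  assert_number(seed, "seed", integer = TRUE)
  storage.mode(counts) <- "double"
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero))
    stop("sample(s) with zero total reads cannot be downsampled: ",
         paste(zero, collapse = ", "), call. = FALSE)
  target <- min(totals)
  out <- counts
  for (s in seq_len(ncol(counts))) {
    if (totals[s] == target) next
    out[, s] <- with_seed(derive_seed(seed, s),
                          rmv_hypergeom(counts[, s], target))
  }
  storage.mode(out) <- "integer"
  out
}

# Multivariate hypergeometric draw: k balls without replacement from urns
# with sizes `m`, by sequential conditional univariate draws.
rmv_hypergeom <- function(m, k) {
  n <- length(m)
  out <- numeric(n)
  remaining <- sum(m)
  for (i in seq_len(n)) {
    if (k == 0) break
    out[i] <- stats::rhyper(1L, m[i], remaining - m[i], k)
    k <- k - out[i]
    remaining <- remaining - m[i]
  }
  out
}

#' Low-representation filter
#'
#' An element is retained only if it carries at least `threshold` normalized
#' (downsampled) reads in every sample considered — the strict reading of
#' requiring representation across all replicates.
#'
#' @param counts downsampled count matrix.
#' @param threshold minimum reads per sample (default 50).
#' @param samples optional character vector restricting the check to the
#'   samples of a contrast; default all columns.
#' @return logical vector, one entry per element (TRUE = retained).
#' @export
filter_low_counts <- function(counts, threshold = 50, samples = NULL) {
  assert_number(threshold, "threshold", lower = 0, integer = TRUE)
  sub <- if (is.null(samples)) counts else counts[, samples, drop = FALSE]
  apply(sub, 1L, min) >= threshold
}

#' Log2 abundance ratio of a contrast
#'
#' `l2fc_e = log2((mean numerator counts + pc) / (mean denominator counts
#' + pc))`, with arm means over unpaired replicates and a pseudocount to keep
#' the ratio defined at zero counts.
#'
#' @param counts downsampled count matrix.
#' @param contrast a [make_contrast()] object.
#' @param sample_sheet sample sheet data.frame.
#' @param pseudocount positive real added to both arm means (default 1).
#' @return numeric vector of per-element log2 ratios.
#' @export
log2_ratio <- function(counts, contrast, sample_sheet, pseudocount = 1) {
  assert_number(pseudocount, "pseudocount", lower = 1e-12)
  ss <- contrast_samples(contrast, sample_sheet, counts)
  m_num <- rowMeans(counts[, ss$num, drop = FALSE])
  m_den <- rowMeans(counts[, ss$den, drop = FALSE])
  log2((m_num + pseudocount) / (m_den + pseudocount))
}

#' Population-doubling normalization
#'
#' Converts a log2 ratio to a phenotype in doublings^-1 by dividing by the
#' contrast's cumulative population doublings, making selection strength
#' comparable across arms that divided at different rates.
#'
#' @param l2fc numeric vector of log2 ratios.
#' @param contrast a [make_contrast()] object.
#' @return numeric vector of phenotypes (doublings^-1).
#' @export
doubling_normalize <- function(l2fc, contrast) {
  d <- contrast$doubling_normalizer
  if (!is.numeric(d) || d <= 0)
    stop("doubling normalizer must be positive", call. = FALSE)
  l2fc / d
}

#' Per-element negative-binomial Wald test
#'
#' Fits, per element, a log-link negative-binomial model with a single arm
#' coefficient beta (log mean ratio numerator/denominator) and tests
#' `beta = 0` with `wald_stat = beta_hat / SE(beta_hat)` against the
#' standard normal (two-sided). For this saturated two-group design the
#' maximum-likelihood arm means are the sample means, so the IRLS fit has a
#' closed form; the overdispersion alpha (`variance = mu + alpha * mu^2`) is
#' estimated by method of moments from within-arm residuals and, by default,
#' pooled across all tested elements (it is a property of the assay, not of
#' one element; with three replicates a per-element estimate is far too
#' unstable to calibrate the test). `dispersion_pool = "element"` keeps the
#' per-element estimate, pooled across the two arms.
#'
#' @param counts downsampled count matrix.
#' @param contrast a [make_contrast()] object.
#' @param sample_sheet sample sheet data.frame.
#' @param mask optional logical vector from [filter_low_counts()]; elements
#'   failing it get `NA` statistics and are excluded from dispersion
#'   estimation.
#' @param dispersion_pool `"global"` (default) or `"element"`.
#' @param dispersion_floor lower bound for the dispersion estimate.
#' @return data.frame with `wald_stat`, `p_value` and the `dispersion`
#'   attribute.
#' @export
wald_test <- function(counts, contrast, sample_sheet, mask = NULL,
                      dispersion_pool = c("global", "element"),
                      dispersion_floor = 1e-8) {
  dispersion_pool <- match.arg(dispersion_pool)
  ss <- contrast_samples(contrast, sample_sheet, counts)
  n1 <- length(ss$num); n2 <- length(ss$den)
  if (n1 < 2L || n2 < 2L)
    stop("each arm needs >= 2 replicates for the Wald test", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, nrow(counts))

  y1 <- counts[, ss$num, drop = FALSE]
  y2 <- counts[, ss$den, drop = FALSE]
  m1 <- rowMeans(y1); m2 <- rowMeans(y2)
  v1 <- apply(y1, 1L, stats::var)
  v2 <- apply(y2, 1L, stats::var)

  if (dispersion_pool == "global") {
    num <- sum((v1 - m1)[mask]) + sum((v2 - m2)[mask])
    den <- sum(m1[mask]^2) + sum(m2[mask]^2)
    alpha <- max(num / den, dispersion_floor)
    alpha_e <- rep(alpha, nrow(counts))
  } else {
    alpha_e <- pmax((v1 - m1 + v2 - m2) / (m1^2 + m2^2), dispersion_floor)
    alpha <- stats::median(alpha_e[mask], na.rm = TRUE)
  }

  # Fisher information of the log mean per arm: n * mu / (1 + alpha * mu)
  se <- sqrt((1 + alpha_e * m1) / (n1 * m1) + (1 + alpha_e * m2) / (n2 * m2))
  beta <- log(m1) - log(m2)
  stat <- beta / se
  stat[m1 == m2] <- 0           # includes the all-equal-counts case
  stat[(m1 == 0 | m2 == 0) & m1 != m2] <- NA_real_  # undefined log ratio
  p <- 2 * stats::pnorm(-abs(stat))
  stat[!mask] <- NA_real_
  p[!mask] <- NA_real_
  out <- data.frame(wald_stat = stat, p_value = p, row.names = rownames(counts))
  attr(out, "dispersion") <- alpha
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement. `NA` entries
#' (filtered elements) are excluded from the number of tests and returned
#' as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Score a screen contrast end to end
#'
#' Runs the full element-level scoring chain on a raw count matrix:
#' depth-equalizing downsampling, the >= `threshold`-reads-in-every-sample
#' filter, pseudocounted log2 ratios, population-doubling normalization,
#' negative-binomial Wald test, BH correction and hit calls.
#'
#' @param counts raw integer count matrix (elements x samples).
#' @param sample_sheet sample sheet data.frame.
#' @param contrast a [make_contrast()] object or a contrast name.
#' @param threshold low-count filter threshold (reads per sample).
#' @param pseudocount pseudocount for the log2 ratio.
#' @param alpha BH-adjusted significance level for hit calls.
#' @param seed downsampling seed.
#' @param downsample set FALSE if `counts` are already depth-equalized.
#' @param dispersion_pool passed to [wald_test()].
#' @return a `phenotype_table` data.frame with one row per element:
#'   `element_id`, `mean_num`, `mean_den`, `l2fc`, `phenotype`, `wald_stat`,
#'   `p_value`, `p_adj`, `passes_filter`, `call` (one of `enriched`,
#'   `depleted`, `ns`, `filtered`).
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 100, n_ntc = 10,
#'                                          mean_depth = 300, seed = 2))
#' tab <- score_screen(sim$counts, sim$sample_sheet, "rt_vs_untreated")
#' table(tab$call)
#' @export
score_screen <- function(counts, sample_sheet, contrast = "rt_vs_untreated",
                         threshold = 50, pseudocount = 1, alpha = 0.05,
                         seed = 0, downsample = TRUE,
                         dispersion_pool = "global") {
  validate_sample_sheet(sample_sheet)
  if (is.character(contrast))
    contrast <- make_contrast(contrast, sample_sheet)
  if (downsample) counts <- downsample_counts(counts, seed = seed)
  ss <- contrast_samples(contrast, sample_sheet, counts)
  mask <- filter_low_counts(counts, threshold = threshold,
                            samples = c(ss$num, ss$den))
  l2fc <- log2_ratio(counts, contrast, sample_sheet,
                     pseudocount = pseudocount)
  phenotype <- doubling_normalize(l2fc, contrast)
  wt <- wald_test(counts, contrast, sample_sheet, mask = mask,
                  dispersion_pool = dispersion_pool)
  p_adj <- adjust_bh(wt$p_value)
  call <- rep("ns", nrow(counts))
  call[!mask] <- "filtered"
  call[mask & !is.na(p_adj) & p_adj < alpha & phenotype > 0] <- "enriched"
  call[mask & !is.na(p_adj) & p_adj < alpha & phenotype < 0] <- "depleted"
  out <- data.frame(
    element_id = rownames(counts),
    mean_num = rowMeans(counts[, ss$num, drop = FALSE]),
    mean_den = rowMeans(counts[, ss$den, drop = FALSE]),
    l2fc = l2fc, phenotype = phenotype,
    wald_stat = wt$wald_stat, p_value = wt$p_value, p_adj = p_adj,
    passes_filter = mask, call = call,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- contrast
  attr(out, "dispersion") <- attr(wt, "dispersion")
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Extract enriched and depleted hits
#'
#' @param table a `phenotype_table` from [score_screen()], or any data.frame
#'   with `element_id`, `p_adj`, `phenotype` and `passes_filter` columns.
#' @param alpha adjusted-p significance level (default 0.05).
#' @return list with character vectors `enriched` and `depleted`.
#' @export
call_hits <- function(table, alpha = 0.05) {
  assert_number(alpha, "alpha", lower = 0, upper = 1)
  ok <- table$passes_filter & !is.na(table$p_adj) & table$p_adj < alpha
  list(enriched = table$element_id[ok & table$phenotype > 0],
       depleted = table$element_id[ok & table$phenotype < 0])
}

#' Aggregate element-level results to gene level
#'
#' The simulated library carries one dual-sgRNA element per gene, so element
#' and gene calls coincide; for manifests with several elements per gene the
#' convention here is: gene p = minimum element p, Bonferroni-corrected by
#' the number of tested elements of that gene, with the phenotype of the
#' minimum-p element; BH is then reapplied across genes.
#'
#' @param table a `phenotype_table` from [score_screen()].
#' @param manifest library manifest mapping `element_id` to `gene`.
#' @param alpha BH-adjusted significance level for gene calls.
#' @return data.frame per gene: `gene`, `n_elements`, `phenotype`,
#'   `p_value`, `p_adj`, `call`.
#' @export
gene_level_table <- function(table, manifest, alpha = 0.05) {
  gene <- manifest$gene[match(table$element_id, manifest$element_id)]
  if (anyNA(gene))
    stop("element(s) missing from manifest", call. = FALSE)
  keep <- table$passes_filter & !is.na(table$p_value)
  rows <- lapply(split(which(keep), gene[keep]), function(i) {
    best <- i[which.min(table$p_value[i])]
    data.frame(gene = gene[best], n_elements = length(i),
               phenotype = table$phenotype[best],
               p_value = min(table$p_value[best] * length(i), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- adjust_bh(out$p_value)
  out$call <- ifelse(out$p_adj < alpha,
                     ifelse(out$phenotype > 0, "enriched", "depleted"), "ns")
  out
}
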