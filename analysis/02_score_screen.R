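#!/usr/bin/env Rscript
# Score the simulated screen: radiation-response (RT vs untreated T14) and
# fitness (untreated T14 vs T0) contrasts, hit calls, recovery against the
# known truth, and a demonstration gene-set overrepresentation test.

library(radscreen)

dat <- "results/data"
out <- "results/screen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

counts <- read_counts(file.path(dat, "counts.tsv"))
sheet <- read_sample_sheet(file.path(dat, "sample_sheet.tsv"))
truth <- read.delim(file.path(dat, "truth.tsv"))

for (ctr in c("rt_vs_untreated", "untreated_vs_t0")) {
  tab <- score_screen(counts, sheet, ctr, threshold = 50, alpha = 0.05,
                      seed = 0)
  write.table(tab, file.path(out, paste0("phenotypes_", ctr, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- call_hits(tab)
  message(sprintf(
    "%s: %d/%d retained; %d enriched, %d depleted (BH < 0.05)",
    ctr, sum(tab$passes_filter), nrow(tab),
    length(hits$enriched), length(hits$depleted)))
  if (ctr == "rt_vs_untreated") {
    retained <- tab$passes_filter
    spiked <- truth$true_rho != 0
    called <- unlist(hits)
    message(sprintf(
      "  recovery: r = %.3f; sensitivity %.2f (tested) / %.2f (all); FDR %.3f",
      cor(truth$true_rho[retained], tab$phenotype[retained]),
      mean(truth$element_id[spiked & retained] %in% called),
      mean(truth$element_id[spiked] %in% called),
      mean(!called %in% truth$element_id[spiked])))
    if (requireNamespace("ggplot2", quietly = TRUE))
      ggplot2::ggsave(file.path(out, "volcano_rt_vs_untreated.pdf"),
                      plot_volcano(tab), width = 6, height = 4)
    # overrepresentation of the spiked genes among the called hits
    universe <- tab$element_id[retained]
    sets <- list(spiked_rho = truth$element_id[spiked],
                 random_decoy = truth$element_id[seq(1, 2000, by = 20)])
    enr <- overrepresentation_test(intersect(called, universe), sets,
                                   universe)
    write.table(enr, file.path(out, "overrepresentation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    message(sprintf("  overrepresentation: spiked set p = %.3g, decoy p = %.3g",
                    enr$p_value[enr$set == "spiked_rho"],
                    enr$p_value[enr$set == "random_decoy"]))
  }
}
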