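#!/usr/bin/env Rscript
# Call gene-level 9p21.3 deletions on the simulated bin profile with both
# callers: CBS segmentation + segment thresholds, and the genome-wide
# z-score detail statistic.

library(radscreen)

dat <- "results/data"
out <- "results/cnv"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

bins <- read_bins(file.path(dat, "cnv_bins.tsv"))
genes <- genes_9p21(targets_only = FALSE)

det <- gene_detail_score(bins, genes)
write.table(det, file.path(out, "gene_detail.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("detail caller deleted: ",
        paste(det$name[det$deleted], collapse = ", "))

# segmentation on a 10x coarsened profile (CBS arc scan is O(n^2) per
# segment; 400 bins of 100 kb keep the full 40 Mb span)
coarse_idx <- (seq_len(nrow(bins)) - 1) %/% 10
coarse <- data.frame(
  chrom = bins$chrom[!duplicated(coarse_idx)],
  start = tapply(bins$start, coarse_idx, min),
  end = tapply(bins$end, coarse_idx, max),
  log2ratio = as.numeric(tapply(bins$log2ratio, coarse_idx, mean)))
segs <- segment_bins(coarse, alpha = 0.01, n_perm = 1000, seed = 1)
write.table(segs, file.path(out, "segments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
calls <- call_deletions_segment(segs, genes)
write.table(calls, file.path(out, "segment_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("segmentation: %d segments; deleted: %s", nrow(segs),
                paste(calls$name[calls$deleted], collapse = ", ")))
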