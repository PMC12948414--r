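#!/usr/bin/env Rscript
# Generate the three synthetic datasets all downstream analyses consume:
# a reference CRISPRi radiotherapy screen with 100 spiked radiation-response
# genes, a chr9p copy-number profile carrying a focal 9p21.3 deletion, and a
# 30-patient clinical cohort with a protective microenvironment group.

library(radscreen)

seed <- 20260927L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

screen <- simulate_screen(reference_recovery_config(seed = seed))
write_screen_sim(screen, out)
message(sprintf("screen: %d elements x %d samples; %d spiked rho genes",
                nrow(screen$counts), ncol(screen$counts),
                sum(screen$truth$true_rho != 0)))

cnv <- simulate_cnv_profile(cnv_deletion_config(seed = seed))
write_bins(cnv$bins, file.path(out, "cnv_bins.tsv"))
write.table(cnv$truth, file.path(out, "cnv_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("cnv: %d bins, deletion %.1f-%.1f Mb at log2 %.1f",
                nrow(cnv$bins), cnv$truth$start / 1e6, cnv$truth$end / 1e6,
                cnv$truth$log2_level))

cohort <- simulate_cohort(cohort_sim_config(seed = seed))
write_clinical(cohort$clinical, file.path(out, "clinical.csv"))
message(sprintf("cohort: %d patients, %d events, true HR %.2f",
                nrow(cohort$clinical), sum(cohort$clinical$event),
                cohort$config$hazard_ratio))
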