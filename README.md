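# radscreen

Malignant peripheral nerve sheath tumors (MPNSTs) are aggressive,
radioresistant sarcomas. A line of work dissecting their radiotherapy
response combines three computational pieces: phenotype scoring of a pooled
genome-wide dual-sgRNA CRISPRi screen comparing irradiated and untreated
cells, gene-level focal copy-number deletion calling at chromosome 9p21.3
(CDKN2A/B, MTAP, the type I IFN gene cluster) from methylation-array style
bin profiles, and Kaplan-Meier / log-rank association of microenvironmental
features (tumor purity, CD8 T-cell presence) with local progression-free
survival after radiotherapy. **radscreen** implements those three tracks as
a tested R package, driven end to end by a synthetic-data generator with
known ground truth, for analysts who want the screen/CNV/survival
statistics without any wet-lab or array preprocessing machinery.

## The statistics at the core

**Screen scoring.** For element *e* and contrast arms with counts
*c<sub>es</sub>*: samples are downsampled without replacement to exactly
equal totals; elements with < 50 reads in any contrast sample are excluded;
`l2fc_e = log2((mean_num + 1)/(mean_den + 1))`; the phenotype is
`l2fc_e / d` (doublings⁻¹) with *d* the screen's population doublings;
significance is a per-element negative-binomial Wald test
(`z = beta / SE(beta)`, dispersion pooled across elements by method of
moments), BH-corrected, with hits at adjusted p < 0.05 split by sign.
One-sided Fisher overrepresentation (hypergeometric upper tail) runs
against user gene sets (GMT).

**Focal deletions.** Circular binary segmentation (max-|t| arc scan,
permutation p) calls a gene deleted when an overlapping segment has mean
log2 < −1 and p < 0.01; the "detail" route standardizes each gene's mean
bin ratio against all genome bins and requires log2 < −1, z < −3 and
BH-adjusted p < 0.05.

**Survival.** Product-limit curves and the two-group log-rank test on local
PFS, with stratification by median-split purity or present-vs-absent CD8
fraction.

## Worked example

```r
library(radscreen)

# a 2,000-gene screen with 100 spiked radiation-response genes (|rho| = 0.3)
sim <- simulate_screen(reference_recovery_config(seed = 20260927))
tab <- score_screen(sim$counts, sim$sample_sheet, "rt_vs_untreated")
table(tab$call)
#> depleted enriched filtered       ns
#>       39       51       19     1991

hits <- call_hits(tab)
res <- overrepresentation_test(
  hits = intersect(unlist(hits), tab$element_id[tab$passes_filter]),
  gene_sets = list(spiked = sim$truth$element_id[sim$truth$true_rho != 0]),
  universe = tab$element_id[tab$passes_filter])
res$p_value   # 5.9e-141: the called hits are the spiked genes
```

Of the 2,100 library elements, 19 fall under the 50-read representation
rule; 90 of the remaining elements are called at BH-adjusted p < 0.05, and
they are overwhelmingly the spiked radiation-response genes (51 enriched =
radio-protective knockdowns, 39 depleted = radio-sensitizing).

```r
# focal 9p21.3 deletion on a simulated chr9p profile
cnv <- simulate_cnv_profile(cnv_deletion_config(seed = 20260927))
det <- gene_detail_score(cnv$bins, genes_9p21(targets_only = FALSE))
det$name[det$deleted]
#> "IFN_cluster" "MTAP" "CDKN2A" "CDKN2B"

# microenvironment vs local PFS in a simulated 30-patient cohort
cohort <- simulate_cohort(cohort_sim_config(seed = 20260927))
sv <- survival_association(cohort$clinical, "cd8_fraction",
                           rule = "positive_vs_zero")
c(chi_square = sv$chi_square, p = sv$p_value)
#> chi_square          p
#>      7.445     0.0064
```

The numbered drivers under `analysis/` run these three tracks as a
narrated workflow (`01_simulate_data.R` → `04_survival.R`), writing tables
under `results/`; `run_pipeline()` does the same programmatically from one
seeded YAML/list configuration.

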