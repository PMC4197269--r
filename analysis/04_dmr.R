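#!/usr/bin/env Rscript
# Extract regions uniquely differentially methylated in the inv(16) group:
# every subgroup sample at least 0.2 away from the CD34+ control with one
# sign, every other patient within 0.1 of it. Reports the hypomethylation
# tendency and recovery of the planted truth.

library(methylpanel)

cohort <- readRDS("scratch/cohort.rds")
rmeans <- readRDS("scratch/matrix.rds")$region_means

groups <- setNames(cohort$metadata$group, cohort$metadata$sample_id)
groups <- groups[cohort$metadata$role == "case"]
control <- cohort$metadata$sample_id[cohort$metadata$role == "control"]

dmrs <- call_unique_dmrs(rmeans, groups, control, "inv16",
                         params = dmr_params(), regions = cohort$regions)
write_dmrs(dmrs, tsv_path = "results/dmrs.tsv", bed_path = "results/dmrs.bed")

hf <- hypomethylation_fraction(dmrs)
cat("unique DMRs called:", hf$n_total, "\n")
cat(sprintf("hypomethylated: %d of %d (%.0f%%)\n",
            hf$n_hypo, hf$n_total, 100 * hf$fraction))

truth <- cohort$truth$planted_dmrs$region_id
cat(sprintf("sensitivity vs planted truth: %.2f  (false positives: %d)\n",
            mean(truth %in% dmrs$region_id),
            sum(!dmrs$region_id %in% truth)))
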