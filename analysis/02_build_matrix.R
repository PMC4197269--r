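#!/usr/bin/env Rscript
# Build the filtered CpG x sample methylation matrix: autosomal positions
# with coverage >= 10 available in all samples, and the region x sample
# mean methylation table used by all downstream steps.

library(methylpanel)

cohort <- readRDS("scratch/cohort.rds")
mat <- build_matrix(cohort$calls, matrix_filter_params(min_coverage = 10))
rmeans <- region_sample_means(mat, cohort$regions)

dir.create("results", showWarnings = FALSE)
write_tsv_deterministic(
  data.frame(site = sprintf("%s:%d", mat$sites$chrom, mat$sites$pos),
             as.data.frame(mat$ratio, check.names = FALSE)),
  "results/matrix.tsv")
write_tsv_deterministic(
  data.frame(region_id = rownames(rmeans),
             as.data.frame(rmeans, check.names = FALSE)),
  "results/region_means.tsv")
saveRDS(list(matrix = mat, region_means = rmeans), "scratch/matrix.rds")

cat("retained sites:", mat$n_retained, "of", sum(cohort$regions$n_cpgs), "\n")
cat("regions with defined means:",
    sum(rowSums(!is.na(rmeans)) == ncol(rmeans)), "of", nrow(rmeans), "\n")
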