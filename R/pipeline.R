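#' Write a data.frame as a byte-deterministic TSV
#'
#' Numeric columns are formatted with a fixed significant-digit rule so
#' repeated runs on the same data produce identical bytes.
#'
#' @param df data.frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns.
#' @return \code{path}, invisibly.
#' @export
write_tsv_deterministic <- function(df, path, digits = 8) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], format = "g", digits = digits)
      out[[j]][out[[j]] == "NA"] <- "NA"
    }
  }
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(paste, c(unname(out), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

matrix_to_df <- function(m, id_col) {
  df <- data.frame(rownames(m), as.data.frame(m, stringsAsFactors = FALSE),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1L] <- id_col
  rownames(df) <- NULL
  df
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort in the pipeline's external formats: one Bismark-style
#' coverage file per sample (\code{<sample>.cov}), region intervals as
#' BED3+name (0-based half-open), a gene table, expression and detection
#' matrices, sample metadata, and the ground truth as JSON. Identical
#' cohorts give byte-identical files.
#'
#' @param cohort A \code{sim_cohort} from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort$calls)) {
    write_coverage_file(cohort$calls[[s]], file.path(dir, paste0(s, ".cov")))
  }
  reg <- cohort$regions
  writeLines(sprintf("%s\t%d\t%d\t%s", reg$chrom, reg$start, reg$end,
                     reg$region_id),
             file.path(dir, "regions.bed"))
  write_tsv_deterministic(cohort$genes, file.path(dir, "genes.tsv"))
  write_tsv_deterministic(matrix_to_df(cohort$expression, "gene_id"),
                          file.path(dir, "expression.tsv"))
  write_tsv_deterministic(matrix_to_df(cohort$detection, "gene_id"),
                          file.path(dir, "detection.tsv"))
  write_tsv_deterministic(cohort$metadata, file.path(dir, "metadata.tsv"))
  truth <- list(planted_dmrs = cohort$truth$planted_dmrs,
                planted_pairs = cohort$truth$planted_pairs)
  writeLines(jsonlite::toJSON(truth, dataframe = "rows", digits = NA,
                              pretty = TRUE),
             file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read region intervals from a BED3+name file
#'
#' @param path BED file (0-based half-open, fourth column = region id).
#' @return data.frame \code{region_id}, \code{chrom}, \code{start},
#'   \code{end}.
#' @export
read_regions_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(region_id = bed[[4L]], chrom = bed[[1L]],
             start = as.integer(bed[[2L]]), end = as.integer(bed[[3L]]),
             stringsAsFactors = FALSE)
}

#' Run the full targeted-methylation analysis on a cohort
#'
#' Chains the pipeline stages: matrix building with coverage/completeness
#' filters, region averaging, subgroup-unique DMR calling, TSS-window
#' assignment and the anti-correlation integration filter. When \code{dir}
#' is given, writes the intermediate tables (methylation matrix, region
#' means, DMR calls, integration hits) as deterministic TSVs.
#'
#' @param cohort A \code{sim_cohort}, or any list with the same components.
#' @param subgroup Case group whose unique methylation signature is sought.
#' @param filter_params [matrix_filter_params()] for matrix assembly.
#' @param dmr_params [dmr_params()] for the DMR caller.
#' @param integration_params [integration_params()] for the integration.
#' @param dir Optional output directory for result TSVs.
#' @return List with \code{matrix}, \code{region_means}, \code{dmrs},
#'   \code{hypo} (hypomethylation fraction summary), \code{pairs},
#'   \code{hits}.
#' @export
run_pipeline <- function(cohort, subgroup = "inv16",
                         filter_params = matrix_filter_params(),
                         dmr_params = methylpanel::dmr_params(),
                         integration_params = methylpanel::integration_params(),
                         dir = NULL) {
  control <- cohort$metadata$sample_id[cohort$metadata$role == "control"]
  groups <- setNames(cohort$metadata$group, cohort$metadata$sample_id)
  groups <- groups[cohort$metadata$role == "case"]

  mat <- build_matrix(cohort$calls, filter_params)
  rmeans <- region_sample_means(mat, cohort$regions)
  dmrs <- call_unique_dmrs(rmeans, groups, control, subgroup,
                           params = dmr_params, regions = cohort$regions)
  hypo <- hypomethylation_fraction(dmrs)
  pairs <- assign_regions(cohort$regions, cohort$genes, integration_params)
  hits <- integration_filter(pairs, rmeans, cohort$expression,
                             control_sample = control[1L],
                             params = integration_params)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ratio_df <- matrix_to_df(cohort_ratio_table(mat), "site")
    write_tsv_deterministic(ratio_df, file.path(dir, "matrix.tsv"))
    write_tsv_deterministic(matrix_to_df(rmeans, "region_id"),
                            file.path(dir, "region_means.tsv"))
    write_dmrs(dmrs, tsv_path = file.path(dir, "dmrs.tsv"),
               bed_path = file.path(dir, "dmrs.bed"))
    write_tsv_deterministic(hits, file.path(dir, "hits.tsv"))
  }
  list(matrix = mat, region_means = rmeans, dmrs = dmrs, hypo = hypo,
       pairs = pairs, hits = hits)
}

cohort_ratio_table <- function(mat) {
  m <- mat$ratio
  rownames(m) <- paste0(mat$sites$chrom, ":", mat$sites$pos)
  m
}
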