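#' Read a Bismark-style coverage file
#'
#' Parses a 6-column tab-separated methylation count file in the Bismark
#' coverage dialect: chromosome, start (1-based), end (1-based inclusive),
#' percent methylation, count methylated, count unmethylated. Positions are
#' converted to 0-based on read; all internal coordinates in this package are
#' 0-based half-open and conversion happens only at I/O boundaries.
#'
#' Rows with a wrong field count or non-numeric coordinates/counts are
#' rejected with a warning naming their row numbers. Negative counts are an
#' error (they violate the count model rather than the file format). The
#' percent column is cross-checked against \code{100 * meth / (meth + unmeth)}
#' with a tolerance of 0.1; mismatches are reported but the counts are kept,
#' as the counts are authoritative. Duplicate positions within one file have
#' their counts summed, with a warning.
#'
#' @param path Path to the coverage file.
#' @return A data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{n_meth}, \code{n_unmeth}, sorted by (chrom, pos). Zero-coverage
#'   rows are kept; their methylation ratio is undefined downstream.
#' @seealso [write_coverage_file()], [methylation_ratio()], [build_matrix()]
#' @export
read_coverage_file <- function(path) {
  if (!file.exists(path)) {
    stop("coverage file not found: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      n_meth = integer(), n_unmeth = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield != 6L)
  ok <- which(nfield == 6L)
  mat <- if (length(ok)) do.call(rbind, fields[ok]) else
    matrix(character(), 0L, 6L)
  suppressWarnings({
    start <- as.numeric(mat[, 2L])
    pct <- as.numeric(mat[, 4L])
    n_meth <- as.numeric(mat[, 5L])
    n_unmeth <- as.numeric(mat[, 6L])
  })
  malformed <- !is.finite(start) | !is.finite(n_meth) | !is.finite(n_unmeth) |
    n_meth != round(n_meth) | n_unmeth != round(n_unmeth)
  bad <- sort(c(bad, ok[malformed]))
  if (length(bad)) {
    warning("rejected ", length(bad), " malformed row(s): ",
            paste(head(bad, 20L), collapse = ", "),
            if (length(bad) > 20L) ", ..." else "")
  }
  keep <- !malformed
  chrom <- mat[keep, 1L]
  start <- start[keep]
  pct <- pct[keep]
  n_meth <- as.integer(n_meth[keep])
  n_unmeth <- as.integer(n_unmeth[keep])
  if (any(n_meth < 0L) || any(n_unmeth < 0L)) {
    stop("negative methylation counts in ", path)
  }
  cov <- n_meth + n_unmeth
  expected <- ifelse(cov > 0L, 100 * n_meth / cov, NA_real_)
  mism <- which(is.finite(pct) & is.finite(expected) &
                  abs(pct - expected) > 0.1)
  if (length(mism)) {
    warning(length(mism), " row(s) with percent column inconsistent with ",
            "counts (tolerance 0.1); counts taken as authoritative")
  }
  out <- data.frame(chrom = chrom, pos = as.integer(start - 1L),
                    n_meth = n_meth, n_unmeth = n_unmeth,
                    stringsAsFactors = FALSE)
  key <- paste(out$chrom, out$pos)
  if (anyDuplicated(key)) {
    warning("duplicate positions in ", path, "; counts summed")
    out <- aggregate_counts(out, key)
  }
  out[order(out$chrom, out$pos), , drop = FALSE]
}

aggregate_counts <- function(calls, key) {
  first <- !duplicated(key)
  agg <- data.frame(
    chrom = calls$chrom[first],
    pos = calls$pos[first],
    n_meth = as.integer(rowsum(calls$n_meth, key)[unique(key), 1L]),
    n_unmeth = as.integer(rowsum(calls$n_unmeth, key)[unique(key), 1L]),
    stringsAsFactors = FALSE)
  agg
}

#' Write methylation calls as a Bismark-style coverage file
#'
#' Inverse of [read_coverage_file()]: emits 1-based inclusive coordinates and
#' a percent column computed from the counts. Output is byte-deterministic
#' for a given input.
#'
#' @param calls data.frame with \code{chrom}, \code{pos} (0-based),
#'   \code{n_meth}, \code{n_unmeth}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_coverage_file <- function(calls, path) {
  cov <- calls$n_meth + calls$n_unmeth
  pct <- ifelse(cov > 0L, 100 * calls$n_meth / cov, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   calls$chrom, calls$pos + 1L, calls$pos + 1L,
                   formatC(pct, format = "g", digits = 8),
                   calls$n_meth, calls$n_unmeth)
  writeLines(lines, path)
  invisible(path)
}

#' Per-CpG methylation ratio
#'
#' \code{n_meth / (n_meth + n_unmeth)}, or \code{NA} when coverage is zero.
#' Missingness is explicit and never encoded as 0.
#'
#' @param n_meth,n_unmeth Non-negative count vectors.
#' @return Numeric vector in \[0, 1\] with \code{NA} at zero coverage.
#' @export
methylation_ratio <- function(n_meth, n_unmeth) {
  cov <- n_meth + n_unmeth
  ifelse(cov > 0, n_meth / cov, NA_real_)
}

#' Matrix filter parameters
#'
#' Filters applied when assembling the CpG-by-sample matrix: minimum per-site
#' coverage (default 10), autosome-only restriction (default on; drops sex
#' chromosomes and mitochondria), and completeness (default on: a site must
#' pass the coverage threshold in every sample).
#'
#' @param min_coverage Minimum coverage per site and sample, >= 1.
#' @param autosomes_only Keep only chromosomes in \code{autosome_names}.
#' @param require_complete Require the coverage threshold in every sample.
#' @param autosome_names Chromosome names treated as autosomes.
#' @return A list of class \code{matrix_filter_params}.
#' @export
matrix_filter_params <- function(min_coverage = 10L, autosomes_only = TRUE,
                                 require_complete = TRUE,
                                 autosome_names = paste0("chr", 1:22)) {
  stopifnot(min_coverage >= 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 autosomes_only = isTRUE(autosomes_only),
                 require_complete = isTRUE(require_complete),
                 autosome_names = autosome_names),
            class = "matrix_filter_params")
}

#' Build a filtered CpG-by-sample methylation matrix
#'
#' Aligns per-sample methylation calls on genomic position and applies the
#' coverage/completeness/autosome filters. With \code{require_complete} on
#' (the default), exactly the sites with coverage at least
#' \code{min_coverage} in every sample are retained; with it off, sites
#' passing in at least one sample are kept and entries below the threshold
#' are set to missing.
#'
#' @param calls_by_sample Named list of call data.frames as returned by
#'   [read_coverage_file()]; at least two samples.
#' @param params A [matrix_filter_params()] object.
#' @return An object of class \code{methylation_matrix}: list with
#'   \code{sites} (data.frame chrom, pos, sorted, no duplicates),
#'   \code{samples}, \code{ratio} (site x sample, NA where undefined),
#'   \code{coverage} (site x sample) and \code{n_retained}. Zero retained
#'   sites yields a valid empty matrix, not an error.
#' @export
build_matrix <- function(calls_by_sample, params = matrix_filter_params()) {
  if (length(calls_by_sample) < 2L) {
    stop("need at least 2 samples, got ", length(calls_by_sample))
  }
  samples <- names(calls_by_sample)
  if (is.null(samples) || anyDuplicated(samples)) {
    stop("calls_by_sample must be a uniquely named list")
  }
  keys <- lapply(calls_by_sample, function(d) paste0(d$chrom, ":", d$pos))
  all_keys <- sort(unique(unlist(keys, use.names = FALSE)))
  n <- length(all_keys)
  cov <- matrix(0L, n, length(samples), dimnames = list(all_keys, samples))
  meth <- matrix(0L, n, length(samples), dimnames = list(all_keys, samples))
  for (s in seq_along(samples)) {
    idx <- match(keys[[s]], all_keys)
    d <- calls_by_sample[[s]]
    cov[idx, s] <- d$n_meth + d$n_unmeth
    meth[idx, s] <- d$n_meth
  }
  split_keys <- strsplit(all_keys, ":", fixed = TRUE)
  chrom <- vapply(split_keys, `[[`, character(1), 1L)
  pos <- as.integer(vapply(split_keys, `[[`, character(1), 2L))
  keep <- rep(TRUE, n)
  if (params$autosomes_only) {
    keep <- keep & chrom %in% params$autosome_names
  }
  pass <- cov >= params$min_coverage
  keep <- keep & if (params$require_complete) {
    rowSums(pass) == length(samples)
  } else {
    rowSums(pass) > 0L
  }
  ord <- order(chrom[keep], pos[keep])
  cov <- cov[keep, , drop = FALSE][ord, , drop = FALSE]
  meth <- meth[keep, , drop = FALSE][ord, , drop = FALSE]
  ratio <- ifelse(cov > 0L, meth / cov, NA_real_)
  if (!params$require_complete) {
    ratio[cov < params$min_coverage] <- NA_real_
  }
  out <- structure(list(
    sites = data.frame(chrom = chrom[keep][ord], pos = pos[keep][ord],
                       stringsAsFactors = FALSE),
    samples = samples,
    ratio = ratio,
    coverage = cov,
    n_retained = sum(keep)), class = "methylation_matrix")
  if (out$n_retained == 0L) {
    message("no sites retained after filtering")
  }
  out
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("methylation_matrix:", x$n_retained, "sites x",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Mean methylation of a region for one sample
#'
#' Unweighted mean of the defined per-CpG ratios of \code{sample} at sites
#' with \code{start <= pos < end} on the region's chromosome (0-based
#' half-open). Returns \code{NA} when the region contains no CpG with a
#' defined ratio.
#'
#' @param mat A \code{methylation_matrix}.
#' @param region List or one-row data.frame with \code{chrom}, \code{start},
#'   \code{end}.
#' @param sample Sample identifier.
#' @return Numeric scalar in \[0, 1\] or \code{NA}.
#' @export
region_mean_methylation <- function(mat, region, sample) {
  in_region <- mat$sites$chrom == region$chrom &
    mat$sites$pos >= region$start & mat$sites$pos < region$end
  r <- mat$ratio[in_region, sample]
  if (!length(r) || all(is.na(r))) return(NA_real_)
  mean(r, na.rm = TRUE)
}

#' Region-by-sample mean methylation matrix
#'
#' Applies [region_mean_methylation()] over a region table and all samples.
#' The number of matrix CpGs falling in each region is attached as attribute
#' \code{n_cpgs}, used by the DMR caller's minimum-CpG filter.
#'
#' @param mat A \code{methylation_matrix}.
#' @param regions data.frame with \code{region_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @return Numeric matrix (regions x samples) with attribute \code{n_cpgs}.
#' @export
region_sample_means <- function(mat, regions) {
  out <- matrix(NA_real_, nrow(regions), length(mat$samples),
                dimnames = list(regions$region_id, mat$samples))
  n_cpgs <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    in_region <- mat$sites$chrom == regions$chrom[i] &
      mat$sites$pos >= regions$start[i] & mat$sites$pos < regions$end[i]
    n_cpgs[i] <- sum(in_region)
    if (n_cpgs[i] > 0L) {
      sub <- mat$ratio[in_region, , drop = FALSE]
      m <- colMeans(sub, na.rm = TRUE)
      m[colSums(!is.na(sub)) == 0L] <- NA_real_
      out[i, ] <- m
    }
  }
  attr(out, "n_cpgs") <- setNames(n_cpgs, regions$region_id)
  out
}

#' Cross-platform correlation of two methylation matrices
#'
#' Pearson correlation of methylation ratios over the sites shared by two
#' matrices, where both have coverage at least \code{min_coverage}. Used to
#' compare measurements of the same material on two platforms or from two
#' tissues (e.g. peripheral blood vs bone marrow of one patient).
#'
#' @param matA,matB \code{methylation_matrix} objects with a single sample
#'   each, or a sample chosen via \code{sampleA}/\code{sampleB}.
#' @param min_coverage Minimum coverage required in both matrices.
#' @param sampleA,sampleB Sample to use from each matrix (default: first).
#' @return List with \code{r} (Pearson correlation) and \code{n_shared}.
#' @export
cross_platform_correlation <- function(matA, matB, min_coverage = 10L,
                                       sampleA = matA$samples[1L],
                                       sampleB = matB$samples[1L]) {
  keyA <- paste0(matA$sites$chrom, ":", matA$sites$pos)
  keyB <- paste0(matB$sites$chrom, ":", matB$sites$pos)
  shared <- intersect(keyA, keyB)
  ia <- match(shared, keyA)
  ib <- match(shared, keyB)
  ok <- matA$coverage[ia, sampleA] >= min_coverage &
    matB$coverage[ib, sampleB] >= min_coverage
  n <- sum(ok)
  if (n < 3L) {
    stop("only ", n, " shared site(s) pass coverage ", min_coverage,
         "; need at least 3")
  }
  list(r = cor(matA$ratio[ia[ok], sampleA], matB$ratio[ib[ok], sampleB]),
       n_shared = n)
}
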