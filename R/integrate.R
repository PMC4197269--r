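#' Parameters for methylation-expression integration
#'
#' Regions are assigned to genes whose TSS window (default 5 kb upstream to
#' 1 kb downstream, strand-aware) they overlap; assigned pairs are kept when
#' region methylation and gene expression are strongly anti-correlated
#' (Spearman rho at or below \code{rho_max}) and the methylation change
#' between control and at least one case is at least \code{fold_min}-fold,
#' with some sample (control included) reaching methylation ratio
#' \code{ratio_min}. Fold changes of ratios near zero are stabilised with a
#' pseudocount.
#'
#' @param upstream_bp,downstream_bp Window extent around the TSS, bp >= 0.
#' @param rho_max Spearman threshold in \[-1, 0); pairs with rho <= rho_max
#'   pass.
#' @param fold_min Minimum methylation fold change, > 1.
#' @param ratio_min Minimum methylation ratio some sample must reach, (0,1).
#' @param pseudocount Stabiliser added to both ratios in the fold change.
#' @return A list of class \code{integration_params}.
#' @export
integration_params <- function(upstream_bp = 5000L, downstream_bp = 1000L,
                               rho_max = -0.7, fold_min = 2,
                               ratio_min = 0.3, pseudocount = 0.01) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0,
            rho_max >= -1, rho_max < 0, fold_min > 1,
            ratio_min > 0, ratio_min < 1, pseudocount >= 0)
  structure(list(upstream_bp = as.integer(upstream_bp),
                 downstream_bp = as.integer(downstream_bp),
                 rho_max = rho_max, fold_min = fold_min,
                 ratio_min = ratio_min, pseudocount = pseudocount),
            class = "integration_params")
}

#' Strand-aware TSS windows
#'
#' For a plus-strand gene the window is \code{[tss - upstream, tss +
#' downstream)}; for a minus-strand gene it is mirrored to \code{[tss -
#' downstream, tss + upstream)}. Coordinates are 0-based half-open and
#' clipped at zero.
#'
#' @param genes data.frame with \code{gene_id}, \code{chrom}, \code{strand}
#'   ("+"/"-") and \code{tss} (0-based).
#' @param params An [integration_params()] object.
#' @return data.frame \code{gene_id}, \code{chrom}, \code{start}, \code{end}.
#' @export
tss_window <- function(genes, params = integration_params()) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - params$upstream_bp,
                  genes$tss - params$downstream_bp)
  end <- ifelse(plus, genes$tss + params$downstream_bp,
                genes$tss + params$upstream_bp)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0L, as.integer(start)), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Assign targeted regions to genes by TSS-window overlap
#'
#' A (region, gene) pair is emitted when the region overlaps the gene's TSS
#' window by at least one base on the same chromosome. A region may pair
#' with several genes and vice versa.
#'
#' @param regions data.frame with \code{region_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open).
#' @param genes Gene table as in [tss_window()].
#' @param params An [integration_params()] object.
#' @return data.frame \code{region_id}, \code{gene_id}, one row per pair,
#'   sorted.
#' @export
assign_regions <- function(regions, genes, params = integration_params()) {
  win <- tss_window(genes, params)
  # 0-based half-open -> 1-based inclusive IRanges
  gr_regions <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  gr_win <- GenomicRanges::GRanges(
    win$chrom, IRanges::IRanges(win$start + 1L, pmax(win$start + 1L, win$end)))
  # zero-width windows (upstream = downstream = 0 at tss 0) cannot overlap
  ok_win <- win$end > win$start
  hits <- GenomicRanges::findOverlaps(gr_regions, gr_win, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  keep <- ok_win[si]
  out <- unique(data.frame(region_id = regions$region_id[qi[keep]],
                           gene_id = win$gene_id[si[keep]],
                           stringsAsFactors = FALSE))
  out <- out[order(out$region_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-tie ranks, after pairwise deletion of
#' missing values. Returns \code{NA} (an explicit undefined signal) when a
#' vector is constant after deletion, rather than an arbitrary number.
#'
#' @param x,y Numeric vectors of equal length; at least 3 complete pairs.
#' @return Correlation in \[-1, 1\], or \code{NA} when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs, got ", sum(ok))
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Methylation-expression anti-correlation filter
#'
#' For each assigned (region, gene) pair, computes the Spearman correlation
#' between region mean methylation and gene expression across samples
#' (control included by default, so n patients + 1 profiles enter the
#' correlation), the maximum methylation fold change between control and any
#' case, and the maximum methylation ratio over all samples. A pair is kept
#' when rho <= \code{rho_max}, the fold change is at least \code{fold_min}
#' (in either direction: \code{fold(a, b) = max(a + eps, b + eps) / min(a +
#' eps, b + eps)}), and the maximum ratio reaches \code{ratio_min}. Pairs
#' with undefined rho (a constant vector) are skipped and counted in a log
#' message.
#'
#' @param pairs data.frame \code{region_id}, \code{gene_id} (e.g. from
#'   [assign_regions()]).
#' @param region_means Regions-by-samples methylation matrix.
#' @param expression Genes-by-samples expression matrix.
#' @param control_sample Control column name.
#' @param params An [integration_params()] object.
#' @param include_control Include the control in the correlation (default
#'   TRUE).
#' @return data.frame \code{region_id}, \code{gene_id}, \code{rho},
#'   \code{max_fold_change}, \code{max_ratio}, sorted by rho ascending.
#' @export
integration_filter <- function(pairs, region_means, expression,
                               control_sample,
                               params = integration_params(),
                               include_control = TRUE) {
  samples <- intersect(colnames(region_means), colnames(expression))
  if (!control_sample %in% samples) {
    stop("control sample absent from shared samples")
  }
  cases <- setdiff(samples, control_sample)
  corr_samples <- if (include_control) samples else cases
  if (length(corr_samples) < 3L) {
    stop("need at least 3 samples with both measurements")
  }
  eps <- params$pseudocount
  n_skipped <- 0L
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    rid <- pairs$region_id[i]
    gid <- pairs$gene_id[i]
    if (!rid %in% rownames(region_means) || !gid %in% rownames(expression)) {
      next
    }
    m <- region_means[rid, samples]
    e <- expression[gid, samples]
    ok <- !is.na(m[corr_samples]) & !is.na(e[corr_samples])
    if (sum(ok) < 3L) { n_skipped <- n_skipped + 1L; next }
    rho <- spearman_rho(m[corr_samples][ok], e[corr_samples][ok])
    if (is.na(rho)) { n_skipped <- n_skipped + 1L; next }
    m_ctrl <- m[control_sample]
    m_case <- m[cases]
    folds <- pmax(m_case + eps, m_ctrl + eps) / pmin(m_case + eps, m_ctrl + eps)
    max_fold <- suppressWarnings(max(folds, na.rm = TRUE))
    max_ratio <- suppressWarnings(max(m, na.rm = TRUE))
    if (!is.finite(max_fold) || !is.finite(max_ratio)) {
      n_skipped <- n_skipped + 1L; next
    }
    if (rho <= params$rho_max && max_fold >= params$fold_min &&
        max_ratio >= params$ratio_min) {
      rows[[i]] <- data.frame(region_id = rid, gene_id = gid, rho = rho,
                              max_fold_change = max_fold,
                              max_ratio = max_ratio,
                              stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0L) {
    message(n_skipped, " pair(s) skipped (undefined correlation or missing data)")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(region_id = character(), gene_id = character(),
                      rho = numeric(), max_fold_change = numeric(),
                      max_ratio = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$rho, out$region_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
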