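#' Parameters for unique-DMR calling
#'
#' The uniqueness criterion: every subgroup sample must differ from the
#' control by at least \code{delta_subgroup_min} with a common sign, while
#' every other case sample stays within \code{delta_others_max} of the
#' control, and the region must contain at least \code{min_cpgs_per_region}
#' CpGs with defined ratios.
#'
#' @param delta_subgroup_min Minimum absolute methylation difference from
#'   control required of every subgroup sample, in (0, 1\].
#' @param delta_others_max Maximum absolute difference tolerated in every
#'   non-subgroup case sample, in \[0, 1); must be below
#'   \code{delta_subgroup_min}.
#' @param min_cpgs_per_region Minimum number of defined CpGs per region.
#' @return A list of class \code{dmr_params}.
#' @export
dmr_params <- function(delta_subgroup_min = 0.2, delta_others_max = 0.1,
                       min_cpgs_per_region = 3L) {
  stopifnot(delta_subgroup_min > 0, delta_subgroup_min <= 1,
            delta_others_max >= 0, delta_others_max < 1,
            min_cpgs_per_region >= 0)
  if (delta_others_max >= delta_subgroup_min) {
    stop("delta_others_max must be smaller than delta_subgroup_min")
  }
  structure(list(delta_subgroup_min = delta_subgroup_min,
                 delta_others_max = delta_others_max,
                 min_cpgs_per_region = as.integer(min_cpgs_per_region)),
            class = "dmr_params")
}

#' Call regions uniquely differentially methylated in one subgroup
#'
#' A region is reported when (a) every sample of the designated subgroup
#' differs from the control by at least \code{delta_subgroup_min} with a
#' common sign, (b) every non-subgroup, non-control case sample differs by
#' less than \code{delta_others_max}, and (c) the region has at least
#' \code{min_cpgs_per_region} defined CpGs. The direction is the sign of the
#' subgroup shift (hypo when below control). Regions with a missing control
#' value, or missing values in any tested sample, are skipped and counted in
#' a log message.
#'
#' @param region_means Regions-by-samples matrix of mean methylation (e.g.
#'   from [region_sample_means()]); row names are region ids. An attribute
#'   \code{n_cpgs} (named vector) supplies the per-region CpG counts.
#' @param groups Named character vector mapping case sample ids to group
#'   labels. Samples absent from \code{groups} (other than the control) are
#'   ignored.
#' @param control_sample Control column name(s); several controls are
#'   averaged.
#' @param subgroup Group label whose unique signature is sought.
#' @param params A [dmr_params()] object.
#' @param n_cpgs Optional named vector of defined-CpG counts per region,
#'   overriding the matrix attribute. If neither is available the CpG filter
#'   is skipped.
#' @param regions Optional region table (\code{region_id}, \code{chrom},
#'   \code{start}, \code{end}) merged into the output.
#' @return data.frame with one row per reported region: \code{region_id},
#'   \code{subgroup}, \code{direction} ("hypo"/"hyper"),
#'   \code{subgroup_mean}, \code{control_value}, \code{delta} (subgroup mean
#'   minus control) and \code{max_abs_delta_others}; sorted by region id so
#'   the result does not depend on input row order.
#' @export
call_unique_dmrs <- function(region_means, groups, control_sample, subgroup,
                             params = dmr_params(), n_cpgs = NULL,
                             regions = NULL) {
  if (!subgroup %in% groups) stop("unknown subgroup label: ", subgroup)
  if (!all(control_sample %in% colnames(region_means))) {
    stop("control sample(s) not in region_means columns")
  }
  sub_samples <- names(groups)[groups == subgroup]
  other_samples <- setdiff(names(groups)[groups != subgroup], control_sample)
  sub_samples <- intersect(sub_samples, colnames(region_means))
  other_samples <- intersect(other_samples, colnames(region_means))
  if (length(sub_samples) == 0L) stop("subgroup has no samples in the matrix")
  if (is.null(n_cpgs)) n_cpgs <- attr(region_means, "n_cpgs")

  ctrl <- if (length(control_sample) > 1L) {
    rowMeans(region_means[, control_sample, drop = FALSE])
  } else {
    region_means[, control_sample]
  }
  n_skipped <- 0L
  rows <- vector("list", nrow(region_means))
  for (i in seq_len(nrow(region_means))) {
    rid <- rownames(region_means)[i]
    m_ctrl <- ctrl[i]
    m_sub <- region_means[i, sub_samples]
    m_oth <- region_means[i, other_samples]
    if (is.na(m_ctrl) || anyNA(m_sub) || anyNA(m_oth)) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (!is.null(n_cpgs) && !is.na(n_cpgs[rid]) &&
        n_cpgs[rid] < params$min_cpgs_per_region) next
    d_sub <- m_sub - m_ctrl
    d_oth <- m_oth - m_ctrl
    signs <- unique(sign(d_sub))
    if (length(signs) != 1L || signs == 0) next
    if (!all(abs(d_sub) >= params$delta_subgroup_min)) next
    if (length(d_oth) && !all(abs(d_oth) < params$delta_others_max)) next
    rows[[i]] <- data.frame(
      region_id = rid,
      subgroup = subgroup,
      direction = if (signs < 0) "hypo" else "hyper",
      subgroup_mean = mean(m_sub),
      control_value = m_ctrl,
      delta = mean(m_sub) - m_ctrl,
      max_abs_delta_others = if (length(d_oth)) max(abs(d_oth)) else 0,
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L) {
    message(n_skipped, " region(s) skipped for missing values")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(region_id = character(), subgroup = character(),
                      direction = character(), subgroup_mean = numeric(),
                      control_value = numeric(), delta = numeric(),
                      max_abs_delta_others = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(regions)) {
    out <- merge(regions[, c("region_id", "chrom", "start", "end")], out,
                 by = "region_id", sort = TRUE)
  }
  out
}

#' Fraction of hypomethylated regions in a DMR set
#'
#' @param dmrs data.frame with a \code{direction} column, as from
#'   [call_unique_dmrs()].
#' @return List with \code{n_hypo}, \code{n_total} and \code{fraction}
#'   (\code{NA} for an empty set: the fraction of nothing is undefined, not
#'   zero).
#' @export
hypomethylation_fraction <- function(dmrs) {
  n_total <- nrow(dmrs)
  n_hypo <- sum(dmrs$direction == "hypo")
  list(n_hypo = n_hypo, n_total = n_total,
       fraction = if (n_total == 0L) NA_real_ else n_hypo / n_total)
}

#' Write DMR calls as TSV and BED6
#'
#' The BED name field carries \code{region_id|direction}; scores are
#' 1000 * |delta| rounded.
#'
#' @param dmrs DMR table including \code{chrom}, \code{start}, \code{end}.
#' @param tsv_path,bed_path Output paths (either may be NULL to skip).
#' @return Invisibly, the DMR table.
#' @export
write_dmrs <- function(dmrs, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) write_tsv_deterministic(dmrs, tsv_path)
  if (!is.null(bed_path)) {
    lines <- sprintf("%s\t%d\t%d\t%s|%s\t%d\t.",
                     dmrs$chrom, as.integer(dmrs$start),
                     as.integer(dmrs$end),
                     dmrs$region_id, dmrs$direction,
                     as.integer(round(pmin(1000, 1000 * abs(dmrs$delta)))))
    writeLines(lines, bed_path)
  }
  invisible(dmrs)
}
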