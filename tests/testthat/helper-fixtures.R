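# Shared fixtures and independent oracles for the test suite.

# Small cohort reused across module tests (memoized per test run).
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(sim_config(
        n_case_groups = 4L, samples_per_group = 2L, n_regions = 80L,
        cpgs_per_region = c(3L, 6L), n_planted_dmrs = 10L,
        n_planted_pairs = 8L, seed = 42L))
    }
    cache
  }
})

# Random per-sample call tables on a shared site grid.
random_calls <- function(n_sites, n_samples, chroms = c("chr1", "chr2", "chrX"),
                         max_cov = 30L) {
  pos <- sort(sample.int(10000L, n_sites))
  chrom <- sample(chroms, n_sites, replace = TRUE)
  out <- lapply(seq_len(n_samples), function(s) {
    cov <- sample(0:max_cov, n_sites, replace = TRUE)
    meth <- rbinom(n_sites, cov, runif(1, 0.2, 0.8))
    data.frame(chrom = chrom, pos = pos, n_meth = meth,
               n_unmeth = cov - meth, stringsAsFactors = FALSE)
  })
  names(out) <- paste0("S", seq_len(n_samples))
  out
}

# Brute-force site filter: scan every site against the criterion directly.
bf_retained_sites <- function(calls, params) {
  keys <- unique(do.call(rbind, lapply(calls, function(d)
    data.frame(chrom = d$chrom, pos = d$pos, stringsAsFactors = FALSE))))
  kept <- character()
  for (i in seq_len(nrow(keys))) {
    ch <- keys$chrom[i]; p <- keys$pos[i]
    if (params$autosomes_only && !ch %in% params$autosome_names) next
    covs <- vapply(calls, function(d) {
      j <- which(d$chrom == ch & d$pos == p)
      if (length(j)) d$n_meth[j] + d$n_unmeth[j] else 0L
    }, integer(1))
    ok <- if (params$require_complete) all(covs >= params$min_coverage)
          else any(covs >= params$min_coverage)
    if (ok) kept <- c(kept, paste0(ch, ":", p))
  }
  sort(kept)
}

# Brute-force unique-DMR criterion, clause by clause.
bf_unique_dmrs <- function(region_means, groups, control, subgroup, params,
                           n_cpgs = attr(region_means, "n_cpgs")) {
  sub_s <- intersect(names(groups)[groups == subgroup], colnames(region_means))
  oth_s <- intersect(setdiff(names(groups)[groups != subgroup], control),
                     colnames(region_means))
  out <- character()
  for (rid in rownames(region_means)) {
    ctrl <- mean(region_means[rid, control])
    ms <- region_means[rid, sub_s]; mo <- region_means[rid, oth_s]
    if (is.na(ctrl) || anyNA(ms) || anyNA(mo)) next
    if (!is.null(n_cpgs) && !is.na(n_cpgs[rid]) &&
        n_cpgs[rid] < params$min_cpgs_per_region) next
    d <- ms - ctrl
    if (all(d >= params$delta_subgroup_min) ||
        all(d <= -params$delta_subgroup_min)) {
      if (all(abs(mo - ctrl) < params$delta_others_max)) out <- c(out, rid)
    }
  }
  sort(out)
}

# Independent Spearman: average-tie ranks + explicit Pearson formula.
bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Two-sided Fisher p by explicit hypergeometric enumeration.
bf_fisher_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force Mann-Whitney U: pairwise comparison count with half ties.
bf_U <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
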