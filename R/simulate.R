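#' Configuration of the synthetic targeted-panel cohort
#'
#' Defaults emulate the study design the pipeline targets: 7 molecular case
#' groups of 2 patients (14 AML samples) plus one pooled CD34+ healthy
#' control, a 500-region targeted panel with 5-15 CpGs per region, mean
#' per-CpG coverage 83x (negative binomial), 50 regions planted as uniquely
#' differentially methylated in the first case group (effect 0.4 on the
#' methylation scale, 69% of them hypomethylated), and 30 genes whose log10
#' expression is anti-coupled to the methylation of their promoter-window
#' region.
#'
#' Region baselines are drawn from context-specific Beta distributions
#' (CpG island Beta(1,9), shore Beta(3,3), open sea Beta(9,1)) to mimic the
#' panel's CpG-context mix. Regions are laid out on chr1-chr22 plus chrX so
#' that autosome filtering is exercised.
#'
#' @param n_case_groups Number of molecular case groups.
#' @param samples_per_group Patients per group.
#' @param n_controls Pooled healthy control samples.
#' @param n_regions Targeted regions on the panel.
#' @param cpgs_per_region Length-2 integer range of CpGs per region.
#' @param coverage_mean Mean per-CpG read coverage.
#' @param coverage_dispersion Negative-binomial size parameter.
#' @param baseline_beta_params Named list of Beta(a, b) parameter pairs for
#'   the island / shore / open_sea region classes.
#' @param n_planted_dmrs Regions planted as subgroup-unique DMRs.
#' @param dmr_effect Planted methylation shift in (0, 1\].
#' @param hypo_fraction Fraction of planted DMRs that are hypomethylated.
#' @param n_planted_pairs Genes anti-coupled to their region's methylation.
#' @param coupling_strength Coupling in \[0, 1\]; 0 decouples entirely.
#' @param coupling_slope log10-expression drop per unit methylation at full
#'   coupling.
#' @param expression_noise_sd Gaussian noise of log10 expression.
#' @param level_jitter_sd Small per-sample biological wobble of region
#'   methylation levels.
#' @param seed Master seed; component streams (layout, methylation,
#'   expression) derive from it by fixed offsets.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_case_groups = 7L, samples_per_group = 2L,
                       n_controls = 1L, n_regions = 500L,
                       cpgs_per_region = c(5L, 15L),
                       coverage_mean = 83, coverage_dispersion = 10,
                       baseline_beta_params = list(island = c(1, 9),
                                                   shore = c(3, 3),
                                                   open_sea = c(9, 1)),
                       n_planted_dmrs = 50L, dmr_effect = 0.4,
                       hypo_fraction = 0.69,
                       n_planted_pairs = 30L, coupling_strength = 0.9,
                       coupling_slope = 2,
                       expression_noise_sd = 0.2,
                       level_jitter_sd = 0.02,
                       seed = 1L) {
  stopifnot(n_case_groups >= 1, samples_per_group >= 1, n_controls >= 1,
            n_regions >= 1, length(cpgs_per_region) == 2L,
            cpgs_per_region[1] >= 1,
            cpgs_per_region[2] >= cpgs_per_region[1],
            coverage_mean >= 1, coverage_dispersion > 0,
            n_planted_dmrs >= 0, n_planted_dmrs <= n_regions,
            dmr_effect >= 0, dmr_effect <= 1,
            hypo_fraction >= 0, hypo_fraction <= 1,
            n_planted_pairs >= 0,
            n_planted_pairs <= n_regions - n_planted_dmrs,
            coupling_strength >= 0, coupling_strength <= 1,
            expression_noise_sd >= 0, level_jitter_sd >= 0)
  stopifnot(all(c("island", "shore", "open_sea") %in%
                  names(baseline_beta_params)))
  structure(as.list(environment()), class = "sim_config")
}

sim_chromosomes <- c(paste0("chr", 1:22), "chrX")

clamp01 <- function(x) pmin(1, pmax(0, x))

# Draw a region baseline compatible with a planted shift: hypomethylation
# needs headroom below, hypermethylation above. Bounded retries, then error.
draw_representable_baseline <- function(ab, effect, direction,
                                        margin = 0.02, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    b <- rbeta(1, ab[1], ab[2])
    if (direction == "hypo" && b - effect >= margin) return(b)
    if (direction == "hyper" && b + effect <= 1 - margin) return(b)
  }
  stop("could not draw a baseline representable for a ", direction,
       " shift of ", effect, " after ", max_tries, " tries")
}

#' Generate a synthetic targeted bisulfite cohort
#'
#' Produces per-sample per-CpG methylation counts, a genes-by-samples
#' expression matrix with detection p-values, region and gene annotation,
#' sample metadata and the ground truth of planted signals. Coverage is
#' negative binomial around \code{coverage_mean}; methylated counts are
#' binomial in the sample's region methylation level. A region's baseline
#' level is drawn once and shared by all samples (plus a small per-sample
#' jitter); planted DMR regions shift the designated subgroup by
#' \code{dmr_effect} (clamped to \[0, 1\]), and planted anti-correlated pair
#' regions instead vary per sample (Beta(2, 2)) so that an expression
#' correlation across samples is measurable. For planted pairs, log10
#' expression is \code{a - slope * level * coupling_strength + noise}.
#'
#' Identical seeds give identical cohorts; [write_cohort()] then emits
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @return List of class \code{sim_cohort}: \code{config}, \code{metadata},
#'   \code{regions}, \code{genes}, \code{calls} (named list of per-sample
#'   call data.frames), \code{expression}, \code{detection}, \code{truth}
#'   (with \code{planted_dmrs}, \code{planted_pairs} data.frames and the
#'   true \code{region_levels} matrix).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_cases <- config$n_case_groups * config$samples_per_group
  case_ids <- paste0("AML_", seq_len(n_cases))
  ctrl_ids <- if (config$n_controls == 1L) "CD34_pool" else
    paste0("CD34_pool_", seq_len(config$n_controls))
  samples <- c(case_ids, ctrl_ids)
  group_labels <- c("inv16", paste0("G", 2:max(2, config$n_case_groups)))
  groups <- rep(group_labels[seq_len(config$n_case_groups)],
                each = config$samples_per_group)

  ## -- layout stream ---------------------------------------------------
  set.seed(config$seed)
  n_reg <- config$n_regions
  chrom <- sim_chromosomes[((seq_len(n_reg) - 1L) %% length(sim_chromosomes)) + 1L]
  slot <- (seq_len(n_reg) - 1L) %/% length(sim_chromosomes)
  n_cpg <- sample(seq(config$cpgs_per_region[1], config$cpgs_per_region[2]),
                  n_reg, replace = TRUE)
  region_len <- n_cpg * 40L
  start <- 100000L + slot * 100000L
  regions <- data.frame(region_id = sprintf("R%04d", seq_len(n_reg)),
                        chrom = chrom, start = start,
                        end = start + region_len,
                        class = sample(c("island", "shore", "open_sea"),
                                       n_reg, replace = TRUE),
                        n_cpgs = n_cpg, stringsAsFactors = FALSE)
  cpg_pos <- lapply(seq_len(n_reg), function(i) {
    start[i] + sort(sample.int(region_len[i], n_cpg[i]) - 1L)
  })
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n_reg)),
                      chrom = chrom,
                      strand = sample(c("+", "-"), n_reg, replace = TRUE),
                      tss = start + region_len %/% 2L,
                      stringsAsFactors = FALSE)
  # planted signals go on autosomes: the analysis is autosome-restricted,
  # so chrX regions serve as filter-exercising nulls
  auto_idx <- which(regions$chrom != "chrX")
  if (config$n_planted_dmrs + config$n_planted_pairs > length(auto_idx)) {
    stop("not enough autosomal regions to plant all signals")
  }
  dmr_idx <- if (config$n_planted_dmrs > 0L)
    sort(sample(auto_idx, config$n_planted_dmrs)) else integer()
  pair_pool <- setdiff(auto_idx, dmr_idx)
  pair_idx <- if (config$n_planted_pairs > 0L)
    sort(sample(pair_pool, config$n_planted_pairs)) else integer()
  dmr_dir <- if (length(dmr_idx))
    ifelse(runif(length(dmr_idx)) < config$hypo_fraction, "hypo", "hyper")
  else character()

  ## -- methylation stream ----------------------------------------------
  set.seed(config$seed + 1L)
  base <- numeric(n_reg)
  for (i in seq_len(n_reg)) {
    ab <- config$baseline_beta_params[[regions$class[i]]]
    k <- match(i, dmr_idx)
    base[i] <- if (!is.na(k) && config$dmr_effect > 0) {
      draw_representable_baseline(ab, config$dmr_effect, dmr_dir[k])
    } else {
      rbeta(1, ab[1], ab[2])
    }
  }
  subgroup_samples <- case_ids[groups == "inv16"]
  levels_mat <- matrix(NA_real_, n_reg, length(samples),
                       dimnames = list(regions$region_id, samples))
  for (i in seq_len(n_reg)) {
    if (i %in% pair_idx) {
      levels_mat[i, ] <- rbeta(length(samples), 2, 2)
      next
    }
    lv <- base[i] + rnorm(length(samples), 0, config$level_jitter_sd)
    k <- match(i, dmr_idx)
    if (!is.na(k) && config$dmr_effect > 0) {
      shift <- if (dmr_dir[k] == "hypo") -config$dmr_effect else config$dmr_effect
      lv[samples %in% subgroup_samples] <-
        lv[samples %in% subgroup_samples] + shift
    }
    levels_mat[i, ] <- clamp01(lv)
  }
  calls <- vector("list", length(samples))
  names(calls) <- samples
  all_chrom <- rep(regions$chrom, regions$n_cpgs)
  all_pos <- unlist(cpg_pos, use.names = FALSE)
  reg_of_cpg <- rep(seq_len(n_reg), regions$n_cpgs)
  for (s in seq_along(samples)) {
    cov <- rnbinom(length(all_pos), size = config$coverage_dispersion,
                   mu = config$coverage_mean)
    p <- levels_mat[reg_of_cpg, s]
    n_meth <- rbinom(length(all_pos), cov, p)
    calls[[s]] <- data.frame(chrom = all_chrom, pos = all_pos,
                             n_meth = n_meth, n_unmeth = cov - n_meth,
                             stringsAsFactors = FALSE)
  }

  ## -- expression stream -----------------------------------------------
  set.seed(config$seed + 2L)
  a <- rnorm(n_reg, 2, 0.5)
  log_expr <- matrix(rnorm(n_reg * length(samples), 0,
                           config$expression_noise_sd),
                     n_reg, length(samples),
                     dimnames = list(genes$gene_id, samples))
  log_expr <- log_expr + a
  for (i in pair_idx) {
    log_expr[i, ] <- log_expr[i, ] + config$coupling_slope *
      config$coupling_strength * (0.5 - levels_mat[i, ])
  }
  expression <- 10^log_expr
  detection <- matrix(runif(n_reg * length(samples), 0, 0.04),
                      n_reg, length(samples),
                      dimnames = list(genes$gene_id, samples))
  # a few undetected gene-sample entries exercise the detection filter
  n_undet <- max(1L, round(0.02 * n_reg))
  undet_genes <- sample(setdiff(seq_len(n_reg), pair_idx), n_undet)
  detection[undet_genes, sample(length(samples), 1L)] <-
    runif(n_undet, 0.06, 0.5)

  metadata <- data.frame(
    sample_id = samples,
    role = c(rep("case", n_cases), rep("control", config$n_controls)),
    group = c(groups, rep("control", config$n_controls)),
    material = sample(c("BM", "PB"), length(samples), replace = TRUE),
    stringsAsFactors = FALSE)

  truth <- list(
    planted_dmrs = data.frame(
      region_id = regions$region_id[dmr_idx],
      subgroup = rep("inv16", length(dmr_idx)),
      direction = dmr_dir,
      true_delta = ifelse(dmr_dir == "hypo", -1, 1) *
        rep(config$dmr_effect, length(dmr_idx)),
      stringsAsFactors = FALSE),
    planted_pairs = data.frame(
      region_id = regions$region_id[pair_idx],
      gene_id = genes$gene_id[pair_idx],
      coupling_sign = rep(if (config$coupling_strength > 0) -1L else 0L,
                          length(pair_idx)),
      stringsAsFactors = FALSE),
    region_levels = levels_mat)
  if (config$dmr_effect == 0) {
    truth$planted_dmrs <- truth$planted_dmrs[0, , drop = FALSE]
  }

  structure(list(config = config, metadata = metadata, regions = regions,
                 genes = genes, calls = calls, expression = expression,
                 detection = detection, truth = truth),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$metadata), "samples,", nrow(x$regions),
      "regions,", sum(x$regions$n_cpgs), "CpGs\n")
  invisible(x)
}

#' Attach simulated survival outcomes to sample metadata
#'
#' Event times are exponential; patients in the "up" expression category
#' have their relapse hazard multiplied by \code{relapse_rate_ratio}.
#' Death (without relapse) acts as a competing event for relapse-free
#' survival, and all follow-up is administratively censored at
#' \code{horizon} days.
#'
#' @param metadata data.frame with an \code{expression_category} column.
#' @param relapse_rate_ratio Positive hazard multiplier for the
#'   high-expression category; 1 is the null.
#' @param seed Integer seed.
#' @param relapse_hazard Baseline daily relapse hazard.
#' @param death_hazard Daily hazard of death without relapse.
#' @param horizon Administrative censoring horizon, days.
#' @return \code{metadata} with columns \code{os_time}, \code{os_event},
#'   \code{rfs_time}, \code{rfs_event}, \code{relapse_event},
#'   \code{death_event} appended.
#' @export
generate_survival <- function(metadata, relapse_rate_ratio, seed = 1L,
                              relapse_hazard = log(2) / 500,
                              death_hazard = log(2) / 1500,
                              horizon = 1825) {
  if (!"expression_category" %in% names(metadata)) {
    stop("metadata must have an expression_category column")
  }
  if (relapse_rate_ratio <= 0) stop("relapse_rate_ratio must be positive")
  set.seed(seed + 3L)
  n <- nrow(metadata)
  hr <- ifelse(metadata$expression_category == "up", relapse_rate_ratio, 1)
  t_relapse <- rexp(n, relapse_hazard * hr)
  t_death <- rexp(n, death_hazard)
  rfs_time <- pmin(t_relapse, t_death, horizon)
  relapse_event <- as.integer(t_relapse <= t_death & t_relapse < horizon)
  death_event <- as.integer(t_death < t_relapse & t_death < horizon)
  os_time <- pmin(t_death, horizon)
  os_event <- as.integer(t_death < horizon)
  cbind(metadata,
        data.frame(os_time = os_time, os_event = os_event,
                   rfs_time = rfs_time,
                   rfs_event = as.integer(relapse_event | death_event),
                   relapse_event = relapse_event,
                   death_event = death_event))
}
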