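#' Correlation distance between sample profiles
#'
#' \code{d(i, j) = 1 - r(profile_i, profile_j)} with \code{r} the Pearson
#' correlation across features. Profiles must be complete: features with
#' missing values are expected to be dropped upstream (the matrix filters
#' already enforce availability in all samples).
#'
#' @param profiles Numeric matrix, samples in rows, features in columns;
#'   at least 2 samples and 2 features, no missing values.
#' @return Symmetric samples-by-samples distance matrix with zero diagonal.
#' @export
correlation_distance <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L || ncol(profiles) < 2L) {
    stop("need at least 2 samples and 2 features")
  }
  if (anyNA(profiles)) {
    stop("profiles contain missing values; drop incomplete features first")
  }
  sds <- apply(profiles, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(profiles)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance sample(s): ", paste(bad, collapse = ", "))
  }
  d <- 1 - cor(t(profiles))
  diag(d) <- 0
  # correlation can exceed 1 by rounding error; distances are non-negative
  d[d < 0] <- 0
  d
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under the Ward.D2 convention (Lance-Williams
#' update on squared distances). The merge sequence is deterministic; ties
#' resolve to the lowest pair of node indices.
#'
#' @param d Symmetric non-negative distance matrix (or \code{dist}).
#' @return An \code{hclust} object.
#' @export
ward_cluster <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
    if (any(d < 0)) stop("distance matrix has negative entries")
    d <- as.dist(d)
  } else if (any(d < 0)) {
    stop("distance matrix has negative entries")
  }
  hclust(d, method = "ward.D2")
}

# Leaf-label set of every internal node, as canonical sorted strings.
node_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    members <- function(id) {
      if (id < 0L) return(hc$labels[-id])
      c(sets[[id]])
    }
    sets[[k]] <- sort(c(members(hc$merge[k, 1L]), members(hc$merge[k, 2L])))
  }
  vapply(sets, paste, character(1), collapse = "\r")
}

#' Bootstrap support for hierarchical cluster nodes
#'
#' Ordinary (bootstrap probability) cluster support: features are resampled
#' with replacement \code{n_boot} times, the tree is recomputed with
#' correlation distance and Ward linkage, and the support of each internal
#' node of the full-data tree is the fraction of bootstrap trees containing
#' the same leaf set. The root always has support 1. Multiscale (AU)
#' corrections are deliberately not applied; see the package vignette.
#'
#' @param profiles Samples-by-features matrix as in [correlation_distance()].
#' @param n_boot Number of bootstrap replicates, >= 1.
#' @param seed Integer seed; results are reproducible given the seed.
#' @return List with \code{hclust} (full-data tree), \code{support} (numeric
#'   vector, one entry per internal node in merge order, in \[0, 1\]) and
#'   \code{n_boot}.
#' @export
bootstrap_support <- function(profiles, n_boot = 1000L, seed = 1L) {
  stopifnot(n_boot >= 1L)
  profiles <- as.matrix(profiles)
  hc <- ward_cluster(correlation_distance(profiles))
  target <- node_leaf_sets(hc)
  hits <- numeric(length(target))
  n_eff <- 0L
  set.seed(seed)
  p <- ncol(profiles)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(p, p, replace = TRUE)
    bp <- profiles[, cols, drop = FALSE]
    if (any(apply(bp, 1L, stats::sd) == 0)) next  # degenerate resample
    bhc <- ward_cluster(correlation_distance(bp))
    hits <- hits + (target %in% node_leaf_sets(bhc))
    n_eff <- n_eff + 1L
  }
  if (n_eff == 0L) stop("all bootstrap resamples were degenerate")
  list(hclust = hc, support = hits / n_eff, n_boot = n_eff)
}

#' Support of the node joining a given set of leaves
#'
#' Convenience accessor: returns the bootstrap support of the internal node
#' whose leaf set is exactly \code{leaves}, or \code{NA} if no such node
#' exists in the tree.
#'
#' @param boot Result of [bootstrap_support()].
#' @param leaves Character vector of leaf labels.
#' @return Support in \[0, 1\] or \code{NA}.
#' @export
node_support <- function(boot, leaves) {
  key <- paste(sort(leaves), collapse = "\r")
  sets <- node_leaf_sets(boot$hclust)
  i <- match(key, sets)
  if (is.na(i)) NA_real_ else boot$support[i]
}

#' Filter expression matrix by detection p-values
#'
#' Keeps the genes detected above background in every sample, i.e. with a
#' detection p-value at or below \code{alpha} (inclusive threshold) in all
#' columns.
#'
#' @param values Genes-by-samples expression matrix.
#' @param detection Matrix of detection p-values, same dimensions.
#' @param alpha Detection threshold in (0, 1\].
#' @return The row-subset of \code{values} for detected genes.
#' @export
detection_filter <- function(values, detection, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]")
  }
  if (!all(dim(values) == dim(detection))) {
    stop("values and detection must have identical dimensions")
  }
  keep <- rowSums(detection <= alpha) == ncol(detection)
  values[keep, , drop = FALSE]
}

#' Quantile normalization of an expression matrix
#'
#' Standard quantile normalization: each column's sorted values are replaced
#' by the cross-column means of the order statistics; ties receive the mean
#' of their rank range. Delegates to \code{limma::normalizeQuantiles}.
#'
#' @param values Complete genes-by-samples numeric matrix.
#' @return Matrix of the same dimensions; all columns share the same sorted
#'   values afterwards.
#' @export
quantile_normalize <- function(values) {
  if (anyNA(values)) stop("quantile normalization requires a complete matrix")
  out <- limma::normalizeQuantiles(as.matrix(values), ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Export a supported dendrogram as Newick
#'
#' Writes the tree with bootstrap supports as internal-node labels, readable
#' by standard phylogenetics software.
#'
#' @param boot Result of [bootstrap_support()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
export_dendrogram_newick <- function(boot, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export")
  }
  phy <- ape::as.phylo(boot$hclust)
  # hclust merge order k corresponds to phylo internal node (n + 1) ... (2n-1)
  # via ape's conversion: match on leaf sets to be safe.
  sets <- node_leaf_sets(boot$hclust)
  n <- length(boot$hclust$labels)
  lab <- character(phy$Nnode)
  for (node in seq_len(phy$Nnode)) {
    tips <- ape::extract.clade(phy, n + node)$tip.label
    i <- match(paste(sort(tips), collapse = "\r"), sets)
    lab[node] <- if (is.na(i)) "" else formatC(boot$support[i], digits = 3, format = "f")
  }
  phy$node.label <- lab
  ape::write.tree(phy, file = path)
  invisible(path)
}
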