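# Independent Ward.D2 oracle: naive Lance-Williams agglomeration on squared
# distances, ties broken by lowest pair of cluster indices.
naive_ward <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  active <- seq_len(n)
  sizes <- rep(1L, n)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1L)
  merged_sets <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); best_val <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      v <- d2[active[ii], active[jj]]
      if (v < best_val - 1e-12) { best_val <- v; best <- c(ii, jj) }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights[step] <- sqrt(best_val)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      v <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
      d2[i, k] <- d2[k, i] <- v
    }
    sizes[i] <- ni + nj
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    merged_sets[[step]] <- members[[i]]
    active <- setdiff(active, j)
  }
  list(heights = heights, sets = merged_sets)
}

test_that("correlation distance is 1 minus Pearson, with affine invariance", {
  p <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(3, 5, 7, 9))
  d <- correlation_distance(p)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0)  # c is an increasing affine map of a
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  set.seed(3)
  q <- matrix(rnorm(3 * 50), 3, 50, dimnames = list(c("x", "y", "z"), NULL))
  dq <- correlation_distance(q)
  manual <- function(u, v) {
    1 - sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(dq["x", "y"], manual(q[1, ], q[2, ]), tolerance = 1e-12)
  expect_equal(dq["y", "z"], manual(q[2, ], q[3, ]), tolerance = 1e-12)
  flat <- rbind(ok = c(1, 2, 3), flat_sample = c(5, 5, 5))
  expect_error(correlation_distance(flat), "flat_sample")
})

test_that("Ward clustering matches an independent Lance-Williams oracle", {
  # two leaves merge at their distance under the Ward.D2 convention
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc <- ward_cluster(d)
  expect_equal(hc$height, 0.4)
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    x <- matrix(rnorm(n * 4), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    hc <- ward_cluster(d)
    oracle <- naive_ward(as.dist(d))
    expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-8)
    # compare partitions instead of raw merge tables: same trees induce the
    # same k-cluster memberships for every k
    for (k in 2:min(4, n)) {
      part_impl <- cutree(hc, k)
      sets_impl <- sort(vapply(split(names(part_impl), part_impl),
                               function(s) paste(sort(s), collapse = ","),
                               character(1)))
      # reconstruct oracle partition at k clusters from its merge sequence
      memb <- as.list(paste0("s", 1:n))
      for (step in seq_len(n - k)) {
        set <- paste0("s", oracle$sets[[step]])
        memb <- memb[!vapply(memb, function(m) all(m %in% set), logical(1))]
        memb <- c(memb, list(set))
      }
      sets_oracle <- sort(vapply(memb, function(s) paste(sort(s), collapse = ","),
                                 character(1)))
      expect_identical(unname(sets_impl), sets_oracle)
    }
  }
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(ward_cluster(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

test_that("two well-separated groups split at the root", {
  set.seed(5)
  # each group shares a common feature pattern plus noise
  pat1 <- rnorm(100); pat2 <- rnorm(100)
  prof <- rbind(t(replicate(4, pat1 + rnorm(100, 0, 0.3))),
                t(replicate(4, pat2 + rnorm(100, 0, 0.3))))
  rownames(prof) <- paste0("s", 1:8)
  hc <- ward_cluster(correlation_distance(prof))
  part <- cutree(hc, 2)
  expect_equal(length(unique(part[1:4])), 1L)
  expect_equal(length(unique(part[5:8])), 1L)
  expect_true(part[1] != part[5])
})

test_that("clustering is invariant to sample and feature order", {
  set.seed(9)
  prof <- matrix(rnorm(6 * 40), 6, 40, dimnames = list(paste0("s", 1:6), NULL))
  hc1 <- ward_cluster(correlation_distance(prof))
  perm_s <- sample(6); perm_f <- sample(40)
  hc2 <- ward_cluster(correlation_distance(prof[perm_s, perm_f]))
  coph1 <- as.matrix(cophenetic(hc1))
  coph2 <- as.matrix(cophenetic(hc2))[rownames(coph1), colnames(coph1)]
  expect_equal(coph1, coph2, tolerance = 1e-10)
})

test_that("Ward heights are non-negative and non-decreasing", {
  set.seed(13)
  prof <- matrix(rnorm(7 * 30), 7, 30, dimnames = list(paste0("s", 1:7), NULL))
  hc <- ward_cluster(correlation_distance(prof))
  expect_true(all(hc$height >= 0))
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("bootstrap supports are valid probabilities with root support 1", {
  set.seed(17)
  prof <- matrix(rnorm(5 * 30), 5, 30, dimnames = list(paste0("s", 1:5), NULL))
  b1 <- bootstrap_support(prof, n_boot = 1, seed = 4)
  expect_true(all(b1$support %in% c(0, 1)))
  b <- bootstrap_support(prof, n_boot = 25, seed = 4)
  expect_true(all(b$support >= 0 & b$support <= 1))
  expect_equal(b$support[length(b$support)], 1)  # root leaf set always present
  expect_equal(node_support(b, paste0("s", 1:5)), 1)
  # reproducible given the seed
  b2 <- bootstrap_support(prof, n_boot = 25, seed = 4)
  expect_identical(b$support, b2$support)
  expect_error(bootstrap_support(prof, n_boot = 0), "n_boot")
})

test_that("pure-noise profiles do not earn confident cluster support", {
  set.seed(19)
  prof <- matrix(rnorm(8 * 150), 8, 150, dimnames = list(paste0("s", 1:8), NULL))
  b <- bootstrap_support(prof, n_boot = 100, seed = 2)
  nontrivial <- head(b$support, -1L)  # all but the root
  expect_lt(mean(nontrivial), 0.95)
})

test_that("detection filter keeps genes detected in every sample", {
  values <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
  det <- matrix(c(0.05, 0.06, 0.01, 0.01, 0.02, 0.03), 3, 2)
  kept <- detection_filter(values, det, alpha = 0.05)
  # p = 0.05 is kept (inclusive); p = 0.06 drops the gene
  expect_identical(rownames(kept), c("g1", "g3"))
  expect_error(detection_filter(values, det, alpha = 0), "alpha")
  expect_error(detection_filter(values, det, alpha = 1.5), "alpha")
  set.seed(23)
  det_r <- matrix(runif(200, 0, 0.1), 50, 4)
  vals_r <- matrix(rnorm(200), 50, 4, dimnames = list(paste0("g", 1:50), NULL))
  kept_r <- detection_filter(vals_r, det_r, alpha = 0.05)
  bf <- vapply(seq_len(50), function(i) all(det_r[i, ] <= 0.05), logical(1))
  expect_identical(rownames(kept_r), paste0("g", which(bf)))
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(c(1, 3), c(2, 4))  # rank means (1+2)/2 = 1.5 and (3+4)/2 = 3.5
  qn <- quantile_normalize(m)
  expect_equal(qn, cbind(c(1.5, 3.5), c(1.5, 3.5)), ignore_attr = TRUE)
  set.seed(29)
  m2 <- matrix(rexp(60), 12, 5)
  qn2 <- quantile_normalize(m2)
  sorted_cols <- apply(qn2, 2, sort)
  expect_true(all(abs(sorted_cols - sorted_cols[, 1]) < 1e-12))
  # within-column order preserved
  expect_equal(apply(qn2, 2, order), apply(m2, 2, order))
  # identical distributions are a fixed point
  m3 <- cbind(c(1, 5, 9), c(9, 1, 5))
  expect_equal(quantile_normalize(m3), m3[, ], ignore_attr = TRUE)
})
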