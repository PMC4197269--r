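test_that("coverage file parsing converts coordinates and validates rows", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t1001\t1001\t75.0\t3\t1",
               "chr2\t51\t51\t0\t0\t0"), f)
  calls <- read_coverage_file(f)
  expect_equal(calls$chrom, c("chr1", "chr2"))
  expect_equal(calls$pos, c(1000L, 50L))
  expect_equal(calls$n_meth, c(3L, 0L))
  expect_equal(calls$n_unmeth, c(1L, 0L))
  # zero-coverage row kept, ratio undefined downstream
  expect_true(is.na(methylation_ratio(0, 0)))

  writeLines(c("chr1\t10\t10\t50\t1\t1",
               "chr1\tnot_a_number\t10\t50\t1\t1",
               "chr1\t20\t20\t50\t1"), f)
  expect_warning(calls <- read_coverage_file(f), "malformed row")
  expect_equal(nrow(calls), 1L)

  writeLines("chr1\t10\t10\t50\t-1\t3", f)
  expect_error(read_coverage_file(f), "negative")
  expect_error(read_coverage_file(file.path(tempdir(), "nope.cov")),
               "not found")

  writeLines("chr1\t10\t10\t99.0\t1\t1", f)  # percent disagrees with counts
  expect_warning(read_coverage_file(f), "percent")

  writeLines(c("chr1\t10\t10\t50\t2\t2", "chr1\t10\t10\t100\t3\t0"), f)
  expect_warning(calls <- read_coverage_file(f), "duplicate")
  expect_equal(calls$n_meth, 5L)
  expect_equal(calls$n_unmeth, 2L)
})

test_that("methylation ratio is the count fraction with explicit missingness", {
  expect_equal(methylation_ratio(3, 1), 0.75)
  expect_equal(methylation_ratio(0, 10), 0)
  expect_equal(methylation_ratio(c(3, 0, 0), c(1, 10, 0)),
               c(0.75, 0, NA))
})

test_that("coverage files round-trip exactly through write and read", {
  co <- tiny_cohort()
  f <- withr::local_tempfile()
  orig <- co$calls[[1]]
  write_coverage_file(orig, f)
  back <- read_coverage_file(f)
  orig <- orig[order(orig$chrom, orig$pos), ]
  rownames(orig) <- rownames(back) <- NULL
  expect_equal(back, orig)
})

test_that("matrix filter retains exactly the qualifying sites", {
  mk <- function(chrom, pos, cov) data.frame(
    chrom = chrom, pos = pos, n_meth = cov, n_unmeth = 0L,
    stringsAsFactors = FALSE)
  # site covered 12x and 9x with min_coverage 10 and completeness: dropped
  calls <- list(A = mk("chr1", c(100L, 200L), c(12L, 15L)),
                B = mk("chr1", c(100L, 200L), c(9L, 20L)))
  mat <- build_matrix(calls, matrix_filter_params(min_coverage = 10))
  expect_equal(mat$n_retained, 1L)
  expect_equal(mat$sites$pos, 200L)
  # chrX dropped under autosomes_only
  calls <- list(A = mk(c("chr1", "chrX"), c(1L, 2L), c(30L, 30L)),
                B = mk(c("chr1", "chrX"), c(1L, 2L), c(30L, 30L)))
  expect_equal(build_matrix(calls)$sites$chrom, "chr1")
  expect_equal(build_matrix(
    calls, matrix_filter_params(autosomes_only = FALSE))$n_retained, 2L)
  expect_error(build_matrix(calls[1]), "at least 2 samples")
})

test_that("matrix filter matches a brute-force scan on random cohorts", {
  set.seed(7)
  for (rep in 1:20) {
    calls <- random_calls(n_sites = 25L, n_samples = 3L)
    params <- matrix_filter_params(
      min_coverage = sample(5:15, 1),
      autosomes_only = sample(c(TRUE, FALSE), 1),
      require_complete = sample(c(TRUE, FALSE), 1))
    mat <- suppressMessages(build_matrix(calls, params))
    got <- sort(sprintf("%s:%d", mat$sites$chrom, mat$sites$pos))
    expect_identical(got, bf_retained_sites(calls, params))
  }
})

test_that("raising the coverage threshold never gains sites", {
  set.seed(11)
  calls <- random_calls(n_sites = 60L, n_samples = 4L)
  counts <- vapply(c(1L, 5L, 10L, 20L, 31L), function(mc) {
    suppressMessages(
      build_matrix(calls, matrix_filter_params(min_coverage = mc)))$n_retained
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("ratios stay in [0,1] and missingness is explicit", {
  co <- tiny_cohort()
  mat <- build_matrix(co$calls)
  r <- mat$ratio[!is.na(mat$ratio)]
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(is.na(mat$ratio) == (mat$coverage == 0)))
  expect_false(is.unsorted(order(mat$sites$chrom, mat$sites$pos)))
})

test_that("region mean methylation averages defined CpGs only", {
  mat <- structure(list(
    sites = data.frame(chrom = "chr1", pos = c(10L, 20L, 30L)),
    samples = c("A", "B"),
    ratio = matrix(c(0.2, 0.4, NA, 0.1, 0.5, 0.9), 3, 2,
                   dimnames = list(NULL, c("A", "B"))),
    coverage = matrix(10L, 3, 2), n_retained = 3L),
    class = "methylation_matrix")
  reg <- list(chrom = "chr1", start = 0L, end = 25L)
  expect_equal(region_mean_methylation(mat, reg, "A"), 0.3)
  expect_true(is.na(region_mean_methylation(
    mat, list(chrom = "chr1", start = 100L, end = 200L), "A")))
  # half-open: pos 30 excluded by end = 30
  expect_equal(region_mean_methylation(
    mat, list(chrom = "chr1", start = 20L, end = 30L), "B"), 0.5)
})

test_that("region means equal brute-force site enumeration and ignore order", {
  co <- tiny_cohort()
  mat <- build_matrix(co$calls)
  rm1 <- region_sample_means(mat, co$regions)
  for (i in sample(nrow(co$regions), 10)) {
    reg <- co$regions[i, ]
    idx <- which(mat$sites$chrom == reg$chrom &
                   mat$sites$pos >= reg$start & mat$sites$pos < reg$end)
    for (s in c("AML_1", "CD34_pool")) {
      expected <- if (length(idx)) mean(mat$ratio[idx, s]) else NA_real_
      expect_equal(unname(rm1[reg$region_id, s]), expected)
    }
  }
  shuffled <- co$regions[sample(nrow(co$regions)), ]
  rm2 <- region_sample_means(mat, shuffled)
  expect_equal(rm2[rownames(rm1), ], rm1[, ], ignore_attr = TRUE)
})

test_that("cross-platform correlation matches the textbook formula", {
  co <- tiny_cohort()
  matA <- build_matrix(co$calls[c("AML_1", "AML_2")])
  expect_equal(cross_platform_correlation(matA, matA)$r, 1.0)
  # flipping counts turns every ratio into 1 - ratio: perfect anticorrelation
  flipped <- lapply(co$calls[c("AML_1", "AML_2")], function(d) {
    data.frame(chrom = d$chrom, pos = d$pos, n_meth = d$n_unmeth,
               n_unmeth = d$n_meth, stringsAsFactors = FALSE)
  })
  matB <- build_matrix(flipped)
  expect_equal(cross_platform_correlation(matA, matB)$r, -1.0)
  # independent textbook Pearson on the shared passing sites
  matC <- build_matrix(co$calls[c("AML_3", "AML_4")])
  res <- cross_platform_correlation(matA, matC, min_coverage = 10)
  keyA <- paste0(matA$sites$chrom, ":", matA$sites$pos)
  keyC <- paste0(matC$sites$chrom, ":", matC$sites$pos)
  shared <- intersect(keyA, keyC)
  ia <- match(shared, keyA); ic <- match(shared, keyC)
  ok <- matA$coverage[ia, "AML_1"] >= 10 & matC$coverage[ic, "AML_3"] >= 10
  x <- matA$ratio[ia[ok], "AML_1"]; y <- matC$ratio[ic[ok], "AML_3"]
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_manual, tolerance = 1e-12)
  expect_equal(res$n_shared, sum(ok))
  # too few shared sites: error names the count
  tiny <- lapply(co$calls[c("AML_1", "AML_2")], function(d) head(d, 2))
  matT <- build_matrix(tiny)
  expect_error(cross_platform_correlation(matA, matT), "2 shared")
})
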