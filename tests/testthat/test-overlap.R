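test_that("jaccard obeys its definition, symmetry and missing-value rule", {
  a <- array(FALSE, c(3, 3, 2)); b <- a
  a[1:2, 1, 1] <- TRUE
  expect_equal(jaccard(a, a), 1)
  b[3, 3, 2] <- TRUE
  expect_equal(jaccard(a, b), 0)
  x <- array(FALSE, c(4, 1, 1)); y <- x
  x[1:2, 1, 1] <- TRUE; y[2:4, 1, 1] <- TRUE
  expect_equal(jaccard(x, y), 0.25)  # |intersection| 1, |union| 4
  expect_equal(jaccard(x, y), jaccard(y, x))
  empty <- array(FALSE, c(4, 1, 1))
  expect_true(is.na(jaccard(empty, empty)))
  expect_error(jaccard(a, x), "grid")
  set.seed(3)
  for (rep in 1:30) {
    u <- array(runif(24) < 0.4, c(4, 3, 2))
    v <- array(runif(24) < 0.4, c(4, 3, 2))
    j <- jaccard(u, v)
    if (!is.na(j)) {
      expect_gte(j, 0); expect_lte(j, 1)
      expect_equal(j, sum(u & v) / sum(u | v))
    }
  }
})

# minimal abnormality_result stand-in for overlap bookkeeping
fake_result <- function(subject, analysis, timepoint, vox, dm = c(5, 5, 2),
                        p2 = NULL) {
  mask <- array(TRUE, dm)
  abn <- rep(FALSE, prod(dm)); abn[vox] <- TRUE
  if (is.null(p2)) { p2 <- runif(prod(dm), 0.2, 1); p2[vox] <- 1e-5 }
  structure(list(subject_id = subject, modality = "FA", analysis = analysis,
                 timepoint = timepoint, p2 = p2,
                 p = ifelse(p2 / 2 < 0.5, 1 - p2 / 2, 0.5),
                 abnormal = abn, mask = mask, dim = dm),
            class = "abnormality_result")
}

test_that("overlap tables pool correctly and contrasts respect symmetry", {
  set.seed(8)
  res <- list()
  for (s in sprintf("S%d", 1:6)) {
    vox <- sample(50, 5)
    for (an in c("CS", "LNG")) for (tp in c("SYM", "RTP"))
      res[[length(res) + 1]] <- fake_result(s, an, tp, vox)
  }
  ot <- overlap_table(res)
  # identical maps everywhere: all overlaps 1, symmetric contrasts p = 1
  expect_true(all(ot$records$jaccard == 1))
  expect_true(all(ot$pooled$median == 1))
  expect_true(all(ot$contrasts$p == 1))
  expect_true(all(ot$contrasts$pooled))

  # Wilcoxon p agrees with exact sign-pattern enumeration on random pairs
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    a <- runif(n); b <- runif(n)
    got <- suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
    expect_equal(got, wilcox_enum_oracle(a - b), tolerance = 1e-12)
  }
})

test_that("threshold sweeps re-threshold faithfully under all three schemes", {
  dm <- c(10, 10, 6)
  nv <- prod(dm)
  set.seed(12)
  res <- list()
  blob <- as.vector(outer(outer(3:5, (2:3 - 1) * 10, "+"),
                          (2:3 - 1) * 100, "+"))  # 3x2x2 contiguous block
  for (s in sprintf("S%d", 1:5)) {
    p2 <- runif(nv, 0.2, 1)
    p2[blob] <- seq(1e-6, 1e-4, length.out = length(blob))
    # identical CS and LNG probability maps with a detectable cluster
    res[[length(res) + 1]] <- fake_result(s, "CS", "SYM", integer(0), dm, p2)
    res[[length(res) + 1]] <- fake_result(s, "LNG", "SYM", integer(0), dm, p2)
  }
  sw <- threshold_sweep(res, "percentile", grid = c(99, 98))
  expect_true(all(sw$median == 1))  # identical maps: constant curve at 1
  sw_f <- threshold_sweep(res, "fdr", grid = c(0.01, 0.05))
  expect_true(all(sw_f$median == 1))
  # percentile 95 keeps 5% of voxels per map (up to ties)
  b <- voxnorm:::apply_scheme(res[[1]]$p2, "percentile", 95)
  expect_equal(sum(b), ceiling(0.05 * nv), tolerance = 1)
  # uncorrected-p detections grow monotonically with alpha
  p2 <- res[[1]]$p2
  d1 <- voxnorm:::apply_scheme(p2, "p", 0.01)
  d2 <- voxnorm:::apply_scheme(p2, "p", 0.05)
  expect_true(all(which(d1) %in% which(d2)))
  # and FDR scheme equals the BH oracle
  expect_identical(voxnorm:::apply_scheme(p2, "fdr", 0.05),
                   bh_oracle(p2, 0.05))
  expect_error(threshold_sweep(res, "fdr", grid = numeric(0)), "empty")
})

test_that("independent uniform maps at the 99th percentile overlap near k/(2m - k)", {
  dm <- c(10, 10, 10)
  nv <- prod(dm)
  set.seed(33)
  js <- replicate(60, {
    x <- voxnorm:::apply_scheme(runif(nv), "percentile", 99)
    y <- voxnorm:::apply_scheme(runif(nv), "percentile", 99)
    sum(x & y) / sum(x | y)
  })
  k <- ceiling(0.01 * nv)
  # expected Jaccard of two random equal-size subsets: ~ (k^2/m) / (2k - k^2/m)
  exp_j <- (k^2 / nv) / (2 * k - k^2 / nv)
  expect_lt(abs(mean(js) - exp_j), 0.006)
})

test_that("time correlations recover monotone association and handle degeneracy", {
  x <- c(1, 3, 5, 9, 11)
  expect_equal(correlate_with_time(x, x^2)$rho, 1)
  expect_equal(correlate_with_time(x, -x)$rho, -1)
  expect_true(is.na(correlate_with_time(rep(2, 5), x)$rho))
  expect_error(correlate_with_time(c(1, 2), c(1, 2)), "3 complete pairs")
  # agreement with a manual rank-Pearson + t-approximation oracle
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- correlate_with_time(a, b)
    rho <- cor(rank(a), rank(b))
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    expect_equal(got$rho, rho, tolerance = 1e-10)
    expect_equal(got$p, 2 * min(pt(tt, n - 2), pt(tt, n - 2, lower.tail = FALSE)),
                 tolerance = 1e-10)
  }
})
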