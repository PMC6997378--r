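test_that("the closed-form CV score matches numerical quadrature", {
  set.seed(101)
  for (rep in 1:5) {
    x <- rnorm(5, sd = runif(1, 0.5, 2))
    h <- runif(1, 0.2, 1.5) * sd(x)
    expect_equal(kde_cv(x, h), cv_quad_oracle(x, h), tolerance = 1e-6)
  }
  # and the C++ grid search agrees with the R closed form at every candidate
  x <- rnorm(20)
  grid <- voxnorm:::bandwidth_grid(c(0.05, 5), 25L)
  scores <- vapply(grid * sd(x), function(h) kde_cv(x, h), numeric(1))
  expect_equal(select_bandwidth(x, range = c(0.05, 5), n_candidates = 25L),
               (grid * sd(x))[which.min(scores)], tolerance = 1e-12)
})

test_that("selected bandwidths are sane for Gaussian samples and degenerate data errors", {
  set.seed(7)
  hits <- 0
  for (rep in 1:5) {
    x <- rnorm(500)
    h <- select_bandwidth(x)
    ref <- 1.06 * sd(x) * 500^(-1 / 5)
    if (h > ref / 2 && h < ref * 2) hits <- hits + 1
  }
  expect_gte(hits, 3)  # majority over seeds
  expect_error(select_bandwidth(c(2, 2, 2, 2)), "degenerate")
  expect_error(select_bandwidth(3), "at least 2")
})

test_that("robust weights keep inliers near-uniform and down-weight gross outliers", {
  expect_equal(fit_robust_weights(5, 1), 1, ignore_attr = TRUE)
  set.seed(55)
  ratio_ok <- 0; outlier_ok <- 0
  for (rep in 1:20) {
    x <- rnorm(40)
    h <- select_bandwidth(x)
    w <- fit_robust_weights(x, h)
    expect_equal(sum(w), 1, tolerance = 1e-10)
    expect_true(all(w >= 0))
    if (max(w) / min(w) < 1.5) ratio_ok <- ratio_ok + 1
    xo <- c(rnorm(19), 10)
    ho <- select_bandwidth(xo)
    wo <- fit_robust_weights(xo, ho)
    if (wo[20] < min(wo[1:19])) outlier_ok <- outlier_ok + 1
  }
  expect_gte(ratio_ok, 15)   # contamination-free: near-uniform weights
  expect_gte(outlier_ok, 15) # outlier gets the smallest weight (majority)
})

test_that("kde_cdf matches quadrature, is monotone, and honors symmetry", {
  # single center: P(center) = 1/2; symmetric two-center model at midpoint
  expect_equal(kde_cdf(3, 3, 1, 0.7), 0.5)
  expect_equal(kde_cdf(1, c(0, 2), c(0.5, 0.5), 1), 0.5)
  set.seed(17)
  for (rep in 1:5) {
    centers <- rnorm(4, sd = 2)
    w <- runif(4); w <- w / sum(w)
    h <- runif(1, 0.3, 1.2)
    x <- rnorm(1, sd = 2)
    expect_equal(kde_cdf(x, centers, w, h),
                 cdf_quad_oracle(x, centers, w, h), tolerance = 1e-8)
    # monotone with limits 0 and 1
    xs <- seq(min(centers) - 6 * h, max(centers) + 6 * h, length.out = 80)
    ps <- kde_cdf(xs, centers, w, h)
    expect_true(all(diff(ps) >= 0))
    expect_lt(ps[1], 1e-6)
    expect_gt(ps[80], 1 - 1e-6)
  }
})

test_that("two-tailed conversion follows P' = 2 min(P, 1 - P)", {
  expect_equal(two_tailed(0.5), 1)
  expect_equal(two_tailed(0.975), 0.05)
  expect_equal(two_tailed(0), 0)
  expect_equal(two_tailed(c(0.1, 0.9)), c(0.2, 0.2))
  expect_error(two_tailed(1.2))
})

test_that("per-voxel fits normalize weights, flag degenerate voxels, and round-trip", {
  set.seed(23)
  vals <- matrix(rnorm(44 * 100, mean = 10), 44, 100)
  vals[, 37] <- 2  # one constant voxel
  stk <- toy_stack(vals, dim = c(10, 10, 1))
  model <- normative_kde(stk, "CS")
  expect_s3_class(model, "normative_kde")
  expect_equal(sum(model$valid), 99)
  expect_false(model$valid[37])
  expect_true(all(abs(rowSums(model$weights[model$valid, ]) - 1) < 1e-10))
  expect_true(all(model$h[model$valid] > 0))
  expect_true(is.na(model$h[37]))

  # serialize + reload: identical probabilities for random queries
  path <- withr::local_tempfile(fileext = ".rds")
  write_normative(model, path)
  back <- read_normative(path)
  set.seed(4)
  q <- matrix(rnorm(10 * 100, mean = 10), 10, 100)
  expect_identical(predict(model, q), predict(back, q))

  expect_error(normative_kde(toy_stack(matrix(1, 1, 4)), "CS"), "at least 2")
})

test_that("uniform-weight models reduce to the plain Parzen CDF", {
  set.seed(71)
  vals <- matrix(rnorm(20 * 30), 20, 30)
  stk <- toy_stack(vals, dim = c(6, 5, 1))
  model <- normative_kde(stk, "CS", robust = FALSE)
  x <- rnorm(30)
  p <- predict(model, x)[1, ]
  parzen <- vapply(seq_len(30), function(v)
    mean(pnorm(x[v], mean = vals[, v], sd = model$h[v])), numeric(1))
  expect_equal(unname(p), parzen, tolerance = 1e-12)
})

test_that("under contamination the robust fit is better calibrated and more powerful", {
  set.seed(29)
  ks_rob <- ks_unif <- pow_rob <- pow_unif <- numeric(0)
  for (rep in 1:10) {
    x <- c(rnorm(40), sample(c(-8, 8), 4, replace = TRUE))  # 10% gross
    stk <- toy_stack(matrix(x, ncol = 1), dim = c(1, 1, 1))
    mr <- suppressWarnings(normative_kde(stk, "CS", robust = TRUE))
    mu <- normative_kde(stk, "CS", robust = FALSE)
    clean <- rnorm(400)
    pr <- two_tailed(predict(mr, matrix(clean, ncol = 1))[, 1])
    pu <- two_tailed(predict(mu, matrix(clean, ncol = 1))[, 1])
    ks <- function(p) max(abs(sort(p) - seq_along(p) / length(p)))
    ks_rob <- c(ks_rob, ks(pr)); ks_unif <- c(ks_unif, ks(pu))
    abn <- sample(c(-4, 4), 200, replace = TRUE)  # genuine 4-SD abnormalities
    pow_rob <- c(pow_rob,
                 mean(two_tailed(predict(mr, matrix(abn, ncol = 1))[, 1]) < 0.05))
    pow_unif <- c(pow_unif,
                  mean(two_tailed(predict(mu, matrix(abn, ncol = 1))[, 1]) < 0.05))
  }
  expect_lt(mean(ks_rob), mean(ks_unif))     # closer to uniform P'
  expect_gte(mean(pow_rob), mean(pow_unif))  # detection never worse
})

test_that("simulated draws follow the fitted mixture", {
  set.seed(83)
  vals <- matrix(rnorm(30 * 4, mean = 5), 30, 4)
  model <- normative_kde(toy_stack(vals, dim = c(2, 2, 1)), "CS")
  sims <- simulate(model, nsim = 4000, seed = 11, voxels = 2)
  p <- kde_cdf(sims[, 1], model$centers[2, ], model$weights[2, ], model$h[2])
  expect_lt(max(abs(sort(p) - seq_along(p) / length(p))), 0.03)
})
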