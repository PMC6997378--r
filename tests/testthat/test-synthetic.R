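test_that("cohort generation is seed-deterministic and degenerates to the mean field", {
  spec <- cohort_spec("FA", dim = c(6, 6, 4), n_controls = 4, n_concussed = 2,
                      seed = 21)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$controls$baseline$values, b$controls$baseline$values)
  expect_identical(a$concussed$RTP$values, b$concussed$RTP$values)

  # zero noise, zero offsets, zero drift: every map equals mu(v)
  spec0 <- cohort_spec("FA", dim = c(5, 5, 2), n_controls = 3, n_concussed = 1,
                       cov_field = 0, drift_pct = 0, skew_fraction = 0,
                       seed = 3)
  coh0 <- generate_cohort(spec0)
  expect_true(all(coh0$controls$baseline$values == coh0$mu[1]))
  expect_true(all(coh0$concussed$SYM$values == coh0$mu[1]))

  # enlarging the control group leaves earlier controls untouched
  s1 <- cohort_spec("FA", dim = c(5, 5, 2), n_controls = 3, n_concussed = 0,
                    seed = 8)
  s2 <- cohort_spec("FA", dim = c(5, 5, 2), n_controls = 5, n_concussed = 0,
                    seed = 8)
  c1 <- generate_cohort(s1)
  c2 <- generate_cohort(s2)
  expect_identical(c1$controls$baseline$values[1:3, ],
                   c2$controls$baseline$values[1:3, ])
})

test_that("generated voxel-wise CoV tracks the requested CoV field", {
  # Monte-Carlo check of the generator against its own parameters
  spec <- cohort_spec("FA", dim = c(10, 10, 5), n_controls = 200,
                      n_concussed = 0, cov_field = 0.06, skew_fraction = 0,
                      seed = 12)
  coh <- generate_cohort(spec)
  cv <- voxelwise_cov(coh$controls$baseline)
  expect_lt(abs(cv$median - 0.06) / 0.06, 0.05)
  # longitudinal change has far larger relative variability than baseline
  chg <- change_stack(coh$controls$baseline, coh$controls$postseason)
  cv_chg <- apply(chg$values, 2, sd) / abs(colMeans(chg$values))
  expect_gt(median(cv_chg) / cv$median, 10)
})

test_that("injections shift exactly the truth voxels by the requested amount", {
  spec <- cohort_spec("CBF", dim = c(8, 8, 6), n_controls = 3, n_concussed = 2,
                      cov_field = 0.1, skew_fraction = 0, seed = 5)
  coh <- generate_cohort(spec)
  stack <- coh$controls$baseline
  sdf <- coh$sd_baseline

  # effect = 0 leaves values identical but still records the truth mask
  inj0 <- injection(c(4, 4, 3), effect = 0, n_voxels = 5, mode = "value")
  r0 <- inject_abnormalities(stack, list(inj0), sdf)
  expect_identical(r0$stack$values, stack$values)
  expect_equal(sum(r0$truth), 5)

  # radius 0 marks exactly the center voxel
  inj1 <- injection(c(4, 4, 3), effect = 2, radius = 0)
  r1 <- inject_abnormalities(stack, list(inj1), sdf)
  expect_equal(sum(r1$truth), 1)
  expect_true(r1$truth[4, 4, 3])

  # 6-SD effect on a 30-voxel cluster: difference equals 6 * SD(v) exactly
  inj6 <- injection(c(4, 4, 3), effect = 6, n_voxels = 30, mode = "value")
  r6 <- inject_abnormalities(stack, list(inj6), sdf)
  pos <- match(which(r6$truth), which(spec$mask))
  diff <- r6$stack$values[1, pos] - stack$values[1, pos]
  expect_equal(unname(diff), 6 * sdf[pos], tolerance = 1e-12)
  untouched <- setdiff(seq_len(ncol(stack$values)), pos)
  expect_identical(r6$stack$values[, untouched], stack$values[, untouched])

  # clusters outside the mask are an error
  mask <- array(TRUE, c(8, 8, 6)); mask[1, 1, 1] <- FALSE
  stk2 <- map_stack(stack$values[, -1, drop = FALSE], mask, "CBF", "baseline")
  expect_error(inject_abnormalities(
    stk2, list(injection(c(1, 1, 1), effect = 1, radius = 0)), sdf[-1]),
    "outside")
})

test_that("value-mode injections cancel in change maps; change-mode do not", {
  spec <- cohort_spec("FA", dim = c(8, 8, 6), n_controls = 4, n_concussed = 2,
                      seed = 77)
  spec$injections <- list(
    injection(c(3, 3, 3), effect = 6, n_voxels = 7, mode = "value"),
    injection(c(6, 6, 4), effect = 6, n_voxels = 7, mode = "change"))
  coh <- generate_cohort(spec)
  spec_clean <- spec; spec_clean$injections <- list()
  clean <- generate_cohort(spec_clean)
  midx <- which(spec$mask)
  a <- match(which(coh$truth$CS$SYM), midx)
  b <- match(which(coh$truth$LNG$SYM), midx)
  chg <- coh$concussed$SYM$values - coh$concussed$baseline$values
  chg_clean <- clean$concussed$SYM$values - clean$concussed$baseline$values
  # value-mode shift present at baseline and SYM alike: change unchanged
  expect_equal(chg[, a], chg_clean[, a], tolerance = 1e-12)
  # change-mode shift appears only post-injury: change shifted by 6 SD_chg
  expect_equal(unname(chg[1, b] - chg_clean[1, b]), 6 * coh$sd_change[b],
               tolerance = 1e-12)
  # and the baseline scan itself is shifted only at value-mode loci
  expect_false(isTRUE(all.equal(coh$concussed$baseline$values[, a],
                                clean$concussed$baseline$values[, a])))
  expect_equal(coh$concussed$baseline$values[, b],
               clean$concussed$baseline$values[, b], tolerance = 1e-12)
})

test_that("at value-injection-free voxels, concussed and control changes share one law", {
  spec <- cohort_spec("FA", dim = c(8, 8, 6), n_controls = 24, n_concussed = 24,
                      seed = 13)
  spec$injections <- list(
    injection(c(4, 4, 3), effect = 6, n_voxels = 10, mode = "value"))
  coh <- generate_cohort(spec)
  midx <- which(spec$mask)
  clean_vox <- setdiff(seq_along(midx), match(which(coh$truth$CS$SYM), midx))
  ctl_chg <- coh$controls$postseason$values - coh$controls$baseline$values
  con_chg <- coh$concussed$SYM$values - coh$concussed$baseline$values
  set.seed(2)
  vox <- sample(clean_vox, 100)
  pvals <- vapply(vox, function(v)
    suppressWarnings(wilcox.test(ctl_chg[, v], con_chg[, v])$p.value),
    numeric(1))
  # p-values behave like a null sample: no enrichment of small p
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_gt(median(pvals), 0.25)
})

test_that("toy atlases partition the mask with correct centers of mass", {
  mask <- array(TRUE, c(7, 6, 5))
  atlas <- generate_toy_atlas(mask, 6, seed = 2)
  lab <- atlas$labels
  expect_equal(sort(unique(lab[mask])), 1:6)
  expect_equal(sum(tabulate(lab[mask])), sum(mask))
  expect_true(all(tabulate(lab[mask]) > 0))

  # single region: center of mass equals the mask centroid
  a1 <- generate_toy_atlas(mask, 1, seed = 1)
  expect_equal(unname(a1$com[1, ]), colMeans(arrayInd(which(mask), dim(mask))))

  # hand-built two-box atlas: centroids by hand arithmetic
  lab2 <- array(0L, c(4, 2, 1))
  lab2[1:2, , 1] <- 1L
  lab2[3:4, , 1] <- 2L
  a2 <- atlas_parcellation(lab2)
  expect_equal(unname(a2$com["1", ]), c(1.5, 1.5, 1))
  expect_equal(unname(a2$com["2", ]), c(3.5, 1.5, 1))

  expect_error(generate_toy_atlas(array(TRUE, c(2, 2, 1)), 10), "partition")
})
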