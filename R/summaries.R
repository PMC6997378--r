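#' Voxel-wise coefficient of variation of a control stack
#'
#' `CoV = sd(X) / |mean(X)|` per voxel (sample SD, N - 1 denominator),
#' summarized by the median and quartiles over valid voxels. Voxels with
#' zero mean are excluded and counted.
#'
#' @param stack a [map_stack()] with at least 2 subjects.
#' @return list with `cov` (masked vector, `NA` at excluded voxels),
#'   `median`, `q1`, `q3`, `n_voxels`, `n_excluded`, `modality`,
#'   `session`.
#' @export
voxelwise_cov <- function(stack) {
  stopifnot(inherits(stack, "map_stack"))
  if (nrow(stack$values) < 2) stop("CoV requires at least 2 subjects")
  m <- colMeans(stack$values)
  s <- apply(stack$values, 2, sd)
  cov <- ifelse(m == 0, NA_real_, s / abs(m))
  ok <- !is.na(cov)
  if (!any(ok)) stop("all voxels excluded (zero mean); nothing to summarize")
  q <- quantile(cov[ok], c(0.25, 0.5, 0.75))
  list(cov = cov, median = unname(q[2]), q1 = unname(q[1]), q3 = unname(q[3]),
       n_voxels = sum(ok), n_excluded = sum(!ok),
       modality = stack$modality, session = stack$session)
}

#' Voxel-wise median percent signal change
#'
#' `CHG = 100 * (post - baseline) / baseline` per subject and voxel,
#' reduced to the per-voxel median over subjects and summarized by the
#' median and quartiles over voxels. Voxels with any zero baseline are
#' excluded and counted.
#'
#' @param baseline,post paired [map_stack()]s (matched by subject id).
#' @return list with `chg` (per-voxel median percent change), `median`,
#'   `q1`, `q3`, `n_voxels`, `n_excluded`.
#' @export
percent_change <- function(baseline, post) {
  stopifnot(inherits(baseline, "map_stack"), inherits(post, "map_stack"))
  common <- intersect(post$subject_ids, baseline$subject_ids)
  if (length(common) == 0) stop("no paired subjects")
  b <- baseline$values[match(common, baseline$subject_ids), , drop = FALSE]
  p <- post$values[match(common, post$subject_ids), , drop = FALSE]
  zero <- apply(b == 0, 2, any)
  chg <- rep(NA_real_, ncol(b))
  if (any(!zero))
    chg[!zero] <- apply(100 * (p[, !zero, drop = FALSE] -
                                 b[, !zero, drop = FALSE]) /
                          b[, !zero, drop = FALSE], 2, median)
  ok <- !is.na(chg)
  if (!any(ok)) stop("all voxels excluded (zero baseline)")
  q <- quantile(chg[ok], c(0.25, 0.5, 0.75))
  list(chg = chg, median = unname(q[2]), q1 = unname(q[1]), q3 = unname(q[3]),
       n_voxels = sum(ok), n_excluded = sum(!ok))
}

#' Voxel-wise normality QC of a control stack
#'
#' Shapiro-Wilk test per voxel, Benjamini-Hochberg corrected across
#' voxels at FDR `q`; reports the fraction of voxels rejecting
#' normality. Degenerate (constant) voxels are excluded, not counted.
#' A non-trivial rejected fraction motivates the non-parametric
#' normative model over a per-voxel Gaussian.
#'
#' @param stack a [map_stack()] with at least 3 subjects.
#' @param q FDR level.
#' @return list with `p` (per-voxel Shapiro-Wilk p, `NA` at excluded
#'   voxels), `rejected` (logical), `fraction`, `n_voxels`,
#'   `n_excluded`.
#' @export
normality_qc <- function(stack, q = 0.05) {
  stopifnot(inherits(stack, "map_stack"))
  if (nrow(stack$values) < 3)
    stop("Shapiro-Wilk requires at least 3 subjects")
  p <- apply(stack$values, 2, function(v) {
    if (sd(v) == 0) return(NA_real_)
    shapiro.test(v)$p.value
  })
  ok <- !is.na(p)
  rejected <- rep(FALSE, length(p))
  rejected[ok] <- p.adjust(p[ok], method = "BH") <= q
  list(p = p, rejected = rejected, fraction = mean(rejected[ok]),
       n_voxels = sum(ok), n_excluded = sum(!ok))
}
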