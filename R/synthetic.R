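# Modality calibration table. CoV quartiles, drift (median percent change
# baseline -> post-season) and change CoV are the printed control-cohort
# summaries; session_share is the fraction of total baseline CoV carried by
# session noise, derived as |drift/100| * change_CoV / sqrt(2) / CoV so that
# the generator reproduces both the baseline CoV and the much larger
# relative variability of longitudinal change.
MODALITY_DEFAULTS <- list(
  FA  = list(mu = 0.45,  cov = c(0.0586, 0.0468, 0.0766), drift = -0.12,
             chg_cov = 7.47, range = c(0, 1)),
  MD  = list(mu = 8e-4,  cov = c(0.0423, 0.0324, 0.0664), drift = 1.41,
             chg_cov = 2.26, range = c(1e-12, Inf)),
  CBF = list(mu = 50,    cov = c(0.443, 0.368, 0.562),   drift = -1.87,
             chg_cov = 2.99, range = c(0, Inf))
)

session_share <- function(modality) {
  d <- MODALITY_DEFAULTS[[modality]]
  min(1, abs(d$drift / 100) * d$chg_cov / sqrt(2) / d$cov[1])
}

#' Sample a per-voxel coefficient-of-variation field
#'
#' Draws voxel CoV values from a log-normal law matched to a target median
#' and quartiles, emulating the spread of relative variability across
#' brain voxels.
#'
#' @param n number of voxels.
#' @param med,q1,q3 target median and quartiles of the field.
#' @return numeric vector of length `n` (uses the current RNG stream).
#' @export
sample_cov_field <- function(n, med, q1, q3) {
  stopifnot(q1 > 0, q3 > q1, med > q1, med < q3)
  sigma <- (log(q3) - log(q1)) / (2 * qnorm(0.75))
  exp(rnorm(n, log(med), sigma))
}

# mean-zero unit-variance shifted log-normal transform of a standard
# normal variate; sigma controls skewness
skew_transform <- function(z, sigma) {
  e <- exp(sigma^2 / 2)
  (exp(sigma * z) - e) / (e * sqrt(exp(sigma^2) - 1))
}

# Smooth a full-grid field by circular convolution with an isotropic
# Gaussian kernel (sd in voxels), rescaled so that the marginal variance
# of a white-noise input is preserved exactly.
smooth_field <- function(z, sd) {
  if (sd <= 0) return(z)
  dm <- dim(z)
  k1 <- lapply(dm, function(n) {
    d <- 0:(n - 1)
    k <- dnorm(pmin(d, n - d), 0, sd)
    k / sum(k)
  })
  k3 <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  dim(k3) <- dm
  sm <- Re(fft(fft(z) * fft(k3), inverse = TRUE)) / prod(dm)
  sm / sqrt(sum(k3^2))
}

#' Specify a synthetic MRI cohort
#'
#' Defines the generative law for a control + concussed cohort of one
#' modality: per-voxel baseline means and CoV, a stable between-subject
#' offset component, session-level noise, a longitudinal drift, a
#' minority fraction of skewed (shifted log-normal) voxels, spatial
#' smoothing of the noise fields, and injected abnormality clusters with
#' known ground truth.
#'
#' Subject values are composed as
#' `mu(v) * (1 + offset(s, v) + drift + noise(s, session, v))`, where the
#' offset is stable across a subject's sessions (so it cancels in change
#' maps) and the session noise is drawn fresh per scan. The total baseline
#' CoV `c(v)` splits between the two components via `session_noise_frac`.
#'
#' @param modality `"FA"`, `"MD"` or `"CBF"`; sets calibrated defaults for
#'   mean level, CoV spread, drift and noise split.
#' @param dim grid shape (length 3).
#' @param mask optional 3-D logical analysis mask (default: full grid).
#' @param n_controls,n_concussed cohort sizes (at least 2 controls).
#' @param mean_field scalar or per-voxel baseline mean `mu(v)`.
#' @param cov_field scalar or per-voxel total baseline CoV `c(v)`; `NULL`
#'   samples a log-normal field matched to the modality's control summary
#'   (median and quartiles).
#' @param session_noise_frac fraction of `c(v)` carried by session noise
#'   (the rest is the stable subject offset); default calibrated from the
#'   modality's longitudinal change CoV and drift.
#' @param drift_pct median percent change from baseline applied to all
#'   post-baseline sessions.
#' @param skew_fraction fraction of voxels whose noise is skewed.
#' @param skew_sigma log-scale sigma of the skewed law.
#' @param smooth_fwhm Gaussian smoothing extent of the noise fields, as
#'   full width at half maximum in voxels (the convention used for
#'   smoothing kernels on real maps).
#' @param injections list of [injection()] specifications.
#' @param seed integer seed governing the whole cohort; per-subject
#'   sub-streams are derived from it so that enlarging the cohort never
#'   perturbs earlier subjects of the same group.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(modality = "FA", dim = c(20, 20, 20), mask = NULL,
                        n_controls = 44L, n_concussed = 12L,
                        mean_field = NULL, cov_field = NULL,
                        session_noise_frac = NULL, drift_pct = NULL,
                        skew_fraction = 0.10, skew_sigma = 0.6,
                        smooth_fwhm = 1.5, injections = list(), seed = 1L) {
  modality <- match.arg(modality, MODALITIES)
  def <- MODALITY_DEFAULTS[[modality]]
  if (is.null(mask)) mask <- array(TRUE, dim = dim)
  stopifnot(identical(dim(mask), as.integer(dim)) || identical(dim(mask), dim))
  if (n_controls < 2) stop("at least 2 controls are required")
  if (skew_fraction < 0 || skew_fraction > 1)
    stop("skew_fraction must lie in [0, 1]")
  if (is.null(mean_field)) mean_field <- def$mu
  if (is.null(session_noise_frac)) session_noise_frac <- session_share(modality)
  if (is.null(drift_pct)) drift_pct <- def$drift
  if (!is.null(cov_field) && any(cov_field < 0))
    stop("cov_field must be non-negative")
  stopifnot(session_noise_frac >= 0, session_noise_frac <= 1)
  structure(list(modality = modality, dim = as.integer(dim), mask = mask,
                 n_controls = as.integer(n_controls),
                 n_concussed = as.integer(n_concussed),
                 mean_field = mean_field, cov_field = cov_field,
                 session_noise_frac = session_noise_frac,
                 drift_pct = drift_pct, skew_fraction = skew_fraction,
                 skew_sigma = skew_sigma, smooth_fwhm = smooth_fwhm,
                 injections = injections, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Specify an injected abnormality cluster
#'
#' A spherical cluster of voxels shifted by `sign * effect` control
#' standard deviations. `mode = "value"` represents a stable anatomical
#' deviation: the shift (scaled by the control baseline SD) is applied to
#' the subject's baseline scan and every post-injury session, so it is
#' visible to cross-sectional scoring but cancels in change maps.
#' `mode = "change"` represents an injury-related change: the shift
#' (scaled by the control change SD) is applied only to the listed
#' post-injury sessions, so it is visible to longitudinal scoring.
#'
#' @param center voxel coordinates (length 3).
#' @param effect effect size in units of the relevant control SD.
#' @param sign +1 or -1.
#' @param radius cluster radius in voxels, or
#' @param n_voxels exact cluster extent (the `n_voxels` grid voxels
#'   nearest to `center`).
#' @param sessions post-injury sessions affected.
#' @param mode `"value"` or `"change"` (see above).
#' @return an object of class `injection`.
#' @export
injection <- function(center, effect, sign = 1, radius = NULL,
                      n_voxels = NULL, sessions = c("SYM", "RTP"),
                      mode = c("value", "change")) {
  mode <- match.arg(mode)
  sessions <- match.arg(sessions, c("SYM", "RTP"), several.ok = TRUE)
  if (is.null(radius) && is.null(n_voxels))
    stop("give either radius or n_voxels")
  if (!is.finite(effect)) stop("effect size must be finite")
  if (!is.null(radius) && radius < 0) stop("radius must be >= 0")
  structure(list(center = as.numeric(center), effect = effect,
                 sign = sign, radius = radius, n_voxels = n_voxels,
                 sessions = sessions, mode = mode),
            class = "injection")
}

# grid voxels forming the cluster; all must lie inside the mask
cluster_voxels <- function(inj, mask) {
  dm <- dim(mask)
  idx <- seq_len(prod(dm))
  co <- arrayInd(idx, dm)
  d2 <- (co[, 1] - inj$center[1])^2 + (co[, 2] - inj$center[2])^2 +
    (co[, 3] - inj$center[3])^2
  if (!is.null(inj$n_voxels)) {
    ord <- order(d2, idx)
    vox <- idx[ord[seq_len(inj$n_voxels)]]
  } else {
    vox <- idx[d2 <= inj$radius^2 + 1e-9]
  }
  if (length(vox) == 0)
    stop("injection cluster contains no voxels (grid too small?)")
  if (!all(mask[vox]))
    stop("injection cluster extends outside the analysis mask")
  sort(vox)
}

#' Place non-overlapping cluster centers inside a mask
#'
#' Greedy rejection sampling of masked voxels with a minimum pairwise
#' separation, for constructing disjoint injection loci.
#'
#' @param mask 3-D logical array.
#' @param n_clusters number of centers.
#' @param min_sep minimum Euclidean separation in voxels.
#' @param margin minimum distance from the grid boundary.
#' @return integer matrix `n_clusters` x 3 (uses current RNG stream).
#' @export
place_cluster_centers <- function(mask, n_clusters, min_sep = 5, margin = 2) {
  dm <- dim(mask)
  co <- arrayInd(which(mask), dm)
  ok <- co[, 1] > margin & co[, 1] <= dm[1] - margin &
    co[, 2] > margin & co[, 2] <= dm[2] - margin &
    co[, 3] > margin & co[, 3] <= dm[3] - margin
  co <- co[ok, , drop = FALSE]
  chosen <- matrix(0L, 0, 3)
  tries <- 0L
  while (nrow(chosen) < n_clusters) {
    if (tries > 10000L)
      stop("could not place the requested clusters; grid too small")
    cand <- co[sample.int(nrow(co), 1), ]
    if (nrow(chosen) == 0 ||
        all(sqrt(rowSums((t(t(chosen) - cand))^2)) >= min_sep))
      chosen <- rbind(chosen, cand)
    tries <- tries + 1L
  }
  unname(chosen)
}

#' Inject abnormality clusters into a stack
#'
#' Shifts the listed cluster voxels of every subject in `stack` by
#' `sign * effect * sd_field(v)` and records the ground-truth mask (the
#' union of the cluster voxels). All other voxels are unchanged.
#'
#' @param stack a [map_stack()].
#' @param injections list of [injection()]s.
#' @param sd_field per-voxel SD (masked vector, canonical order) setting
#'   the shift scale; must be positive on injected voxels.
#' @return list with elements `stack` (shifted) and `truth` (3-D logical).
#' @export
inject_abnormalities <- function(stack, injections, sd_field) {
  mask <- stack$mask
  midx <- which(mask)
  truth <- array(FALSE, dim = dim(mask))
  vals <- stack$values
  for (inj in injections) {
    vox <- cluster_voxels(inj, mask)
    pos <- match(vox, midx)
    if (any(sd_field[pos] <= 0))
      stop("sd_field must be positive on injected voxels")
    shift <- inj$sign * inj$effect * sd_field[pos]
    vals[, pos] <- sweep(vals[, pos, drop = FALSE], 2, shift, "+")
    truth[vox] <- TRUE
  }
  out <- stack
  out$values <- vals
  rownames(out$values) <- stack$subject_ids
  list(stack = out, truth = truth)
}

#' Generate a synthetic control + concussed cohort
#'
#' Draws control subjects (baseline and post-season sessions) and
#' concussed subjects (baseline, SYM and RTP sessions) from the law in
#' [cohort_spec()], applies the injection list to the concussed group, and
#' returns ground-truth masks per analysis type and timepoint. Identical
#' seeds give identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `controls` (stacks `baseline`,
#'   `postseason`), `concussed` (stacks `baseline`, `SYM`, `RTP`),
#'   `truth` (`$CS$SYM`, `$CS$RTP`, `$LNG$SYM`, `$LNG$RTP`, 3-D logical),
#'   `mu`, `cov`, `sd_baseline`, `sd_change` (masked vectors), `timing`
#'   (per-subject day covariates) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  dm <- spec$dim
  mask <- spec$mask
  midx <- which(mask)
  nv <- length(midx)
  rng <- MODALITY_DEFAULTS[[spec$modality]]$range

  set.seed(spec$seed)
  def <- MODALITY_DEFAULTS[[spec$modality]]
  covv <- if (is.null(spec$cov_field))
    sample_cov_field(nv, def$cov[1], def$cov[2], def$cov[3])
  else if (length(spec$cov_field) == 1) rep(spec$cov_field, nv)
  else spec$cov_field[seq_len(nv)]
  mu <- if (length(spec$mean_field) == 1) rep(spec$mean_field, nv)
  else spec$mean_field[seq_len(nv)]
  skewed <- rep(FALSE, nv)
  if (spec$skew_fraction > 0)
    skewed[sample.int(nv, round(spec$skew_fraction * nv))] <- TRUE
  n_total <- spec$n_controls + spec$n_concussed
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_total, replace = TRUE)

  lam <- spec$session_noise_frac
  off_frac <- sqrt(1 - lam^2)
  drift <- spec$drift_pct / 100

  smooth_sd <- spec$smooth_fwhm / (2 * sqrt(2 * log(2)))
  field <- function() {
    z <- smooth_field(array(rnorm(prod(dm)), dim = dm), smooth_sd)[midx]
    z[skewed] <- skew_transform(z[skewed], spec$skew_sigma)
    z
  }
  draw_subject <- function(seed, sessions) {
    set.seed(seed)
    off <- off_frac * covv * field()
    out <- lapply(sessions, function(s) {
      noise <- lam * covv * field()
      d <- if (s == "baseline") 0 else drift
      v <- mu * (1 + off + d + noise)
      pmin(pmax(v, rng[1]), rng[2])
    })
    names(out) <- sessions
    out
  }

  ctl_ids <- sprintf("C%03d", seq_len(spec$n_controls))
  con_ids <- sprintf("P%03d", seq_len(spec$n_concussed))
  ctl <- lapply(seq_len(spec$n_controls), function(i)
    draw_subject(subj_seeds[i], c("baseline", "postseason")))
  con <- if (spec$n_concussed > 0)
    lapply(seq_len(spec$n_concussed), function(i)
      draw_subject(subj_seeds[spec$n_controls + i], c("baseline", "SYM", "RTP")))
  else list()

  mk <- function(rows, ids, session)
    map_stack(do.call(rbind, rows), mask, spec$modality, session,
              subject_ids = ids)
  controls <- list(
    baseline = mk(lapply(ctl, `[[`, "baseline"), ctl_ids, "baseline"),
    postseason = mk(lapply(ctl, `[[`, "postseason"), ctl_ids, "postseason"))
  concussed <- if (spec$n_concussed > 0) list(
    baseline = mk(lapply(con, `[[`, "baseline"), con_ids, "baseline"),
    SYM = mk(lapply(con, `[[`, "SYM"), con_ids, "SYM"),
    RTP = mk(lapply(con, `[[`, "RTP"), con_ids, "RTP"))
  else NULL

  sd_base <- covv * mu
  sd_chg <- sqrt(2) * lam * covv * mu
  truth <- list(CS = list(SYM = array(FALSE, dm), RTP = array(FALSE, dm)),
                LNG = list(SYM = array(FALSE, dm), RTP = array(FALSE, dm)))
  if (length(spec$injections) && spec$n_concussed > 0) {
    val_inj <- Filter(function(i) i$mode == "value", spec$injections)
    chg_inj <- Filter(function(i) i$mode == "change", spec$injections)
    # value mode: stable shift on baseline and every post-injury session
    if (length(val_inj)) {
      for (s in c("baseline", "SYM", "RTP"))
        concussed[[s]] <- inject_abnormalities(concussed[[s]], val_inj,
                                               sd_base)$stack
      for (inj in val_inj) {
        vox <- cluster_voxels(inj, mask)
        for (s in inj$sessions) truth$CS[[s]][vox] <- TRUE
      }
    }
    # change mode: shift only the listed post-injury sessions
    for (inj in chg_inj) {
      vox <- cluster_voxels(inj, mask)
      for (s in inj$sessions) {
        res <- inject_abnormalities(concussed[[s]], list(inj), sd_chg)
        concussed[[s]] <- res$stack
        truth$LNG[[s]][vox] <- TRUE
      }
    }
  }

  set.seed(spec$seed + 1L)
  timing <- data.frame(
    subject_id = c(ctl_ids, con_ids),
    group = c(rep("control", spec$n_controls),
              rep("concussed", spec$n_concussed)),
    days_from_baseline = round(runif(n_total, 90, 200)),
    days_post_injury = c(rep(NA, spec$n_controls),
                         round(runif(spec$n_concussed, 20, 40))))

  list(controls = controls, concussed = concussed, truth = truth,
       mu = mu, cov = covv, sd_baseline = sd_base, sd_change = sd_chg,
       skewed = skewed, timing = timing, spec = spec)
}

#' Write a synthetic cohort as NIfTI volumes plus a manifest
#'
#' Serializes every subject/session volume (values inside the mask, zero
#' outside) under `dir` and writes a matching manifest TSV, so that the
#' cohort round-trips through [load_stack()].
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly written to
#'   `file.path(dir, "manifest.tsv")`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask <- cohort$spec$mask
  rows <- list()
  dump <- function(stack, group) {
    for (i in seq_along(stack$subject_ids)) {
      sid <- stack$subject_ids[i]
      path <- file.path(dir, sprintf("%s_%s_%s.nii.gz", sid, stack$session,
                                     stack$modality))
      write_volume(unmask(stack$values[i, ], mask, fill = 0), path)
      rows[[length(rows) + 1L]] <<- data.frame(
        subject_id = sid, group = group, session = stack$session,
        modality = stack$modality, path = path)
    }
  }
  for (s in names(cohort$controls)) dump(cohort$controls[[s]], "control")
  for (s in names(cohort$concussed)) dump(cohort$concussed[[s]], "concussed")
  manifest <- do.call(rbind, rows)
  manifest <- merge(manifest, cohort$timing, by = c("subject_id", "group"),
                    all.x = TRUE, sort = FALSE)
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  write_volume(array(as.numeric(mask), dim = dim(mask)),
               file.path(dir, "mask.nii.gz"))
  invisible(manifest)
}
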