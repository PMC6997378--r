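#' Least-squares cross-validation score of a KDE bandwidth
#'
#' Computes `CV(h) = int fhat^2(x) dx - (2/N) sum_n fhat_{-n}(X_n)` for a
#' Gaussian-kernel density estimate with uniform weights. The squared
#' integral is evaluated in closed form (pairwise Gaussian of center
#' differences at sd `h * sqrt(2)`); the leave-one-out density at `X_n`
#' renormalizes over the remaining `N - 1` kernels.
#'
#' @param values numeric vector of observations.
#' @param h bandwidth (> 0).
#' @return the CV score (smaller is better).
#' @export
kde_cv <- function(values, h) {
  n <- length(values)
  stopifnot(n >= 2, h > 0)
  d <- outer(values, values, "-")
  integral <- sum(dnorm(d, sd = h * sqrt(2))) / n^2
  loo <- sum(dnorm(d, sd = h)[upper.tri(d)]) * 4 / (n * (n - 1))
  integral - loo
}

#' Select a KDE bandwidth by leave-one-out cross-validation
#'
#' Evaluates [kde_cv()] over log-spaced candidates between
#' `range[1]` and `range[2]` times the sample SD and returns the
#' minimizer; exact ties go to the smallest candidate (the more
#' detail-preserving choice, fixed for determinism).
#'
#' @param values numeric vector (N >= 2) with positive sample SD.
#' @param range candidate bounds as multiples of the sample SD.
#' @param n_candidates number of log-spaced candidates.
#' @return the selected bandwidth, in the units of `values`.
#' @export
select_bandwidth <- function(values, range = c(0.01, 10),
                             n_candidates = 50L) {
  if (length(values) < 2) stop("at least 2 values are required")
  if (sd(values) == 0)
    stop("degenerate sample: zero variance, no bandwidth can be selected")
  grid <- bandwidth_grid(range, n_candidates)
  res <- cpp_select_bandwidth(matrix(values, nrow = 1), grid)
  res$h[1]
}

bandwidth_grid <- function(range = c(0.01, 10), n = 50L)
  exp(seq(log(range[1]), log(range[2]), length.out = n))

#' Hampel-loss robust KDE kernel weights
#'
#' Iteratively reweighted fit of a weighted Gaussian kernel mixture in
#' the kernel-induced geometry: each observation's distance to the
#' current mixture is computed in the reproducing-kernel norm, and
#' weights are set proportional to `psi(d) / d` for the Hampel
#' redescending `psi` with breakpoints `(a, b, c)` taken from the
#' initial (uniform-weight) distance distribution: `a` and `b` its
#' `breakpoint_quantiles` (defaults: 90th and 99th percentiles) and
#' `c = c_scale` times its maximum. Outlying control observations are
#' thereby down-weighted while typical observations keep full weight,
#' which preserves the null calibration of downstream tail
#' probabilities on uncontaminated data. Non-convergence at `max_iter`
#' returns the last iterate with a warning.
#'
#' @param values numeric vector of observations.
#' @param h bandwidth from [select_bandwidth()].
#' @param tol convergence tolerance on the maximum weight change.
#' @param max_iter maximum number of reweighting iterations.
#' @param breakpoint_quantiles quantiles of the initial distance
#'   distribution defining Hampel `a` and `b`.
#' @param c_scale multiple of the maximum initial distance defining
#'   Hampel `c`.
#' @return non-negative weights summing to 1, with attribute
#'   `"converged"`.
#' @export
fit_robust_weights <- function(values, h, tol = 1e-6, max_iter = 100L,
                               breakpoint_quantiles = c(0.90, 0.99),
                               c_scale = 1.5) {
  if (length(values) == 1) return(structure(1, converged = TRUE))
  stopifnot(h > 0)
  res <- cpp_robust_weights(matrix(values, nrow = 1), h, tol,
                            as.integer(max_iter),
                            breakpoint_quantiles[1], breakpoint_quantiles[2],
                            c_scale)
  if (!res$converged[1])
    warning("robust reweighting did not converge; returning last iterate")
  structure(as.numeric(res$weights[1, ]), converged = res$converged[1])
}

#' Weighted Gaussian-mixture cumulative probability
#'
#' `P(x) = sum_n w_n Phi((x - c_n) / h)` for one voxel's normative
#' mixture; monotone non-decreasing in `x` with limits 0 and 1.
#'
#' @param x query value(s).
#' @param centers kernel centers (the control observations).
#' @param weights kernel weights (non-negative, summing to 1).
#' @param h bandwidth.
#' @return cumulative probabilities in \[0, 1\].
#' @export
kde_cdf <- function(x, centers, weights, h) {
  stopifnot(length(centers) == length(weights), h > 0)
  p <- vapply(x, function(q) sum(weights * pnorm(q, mean = centers, sd = h)),
              numeric(1))
  pmin(pmax(p, 0), 1)  # guard summation round-off at the limits
}

#' Two-tailed extremeness probability
#'
#' `P' = 2 * min(P, 1 - P)`: the probability of a value as extreme or
#' more extreme than observed under the normative distribution.
#'
#' @param p one-tailed cumulative probabilities in \[0, 1\].
#' @return two-tailed probabilities in \[0, 1\].
#' @export
two_tailed <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  2 * pmin(p, 1 - p)
}

#' Fit per-voxel normative KDE distributions to a control stack
#'
#' The central fitting function. For each masked voxel, selects a
#' Gaussian kernel bandwidth by least-squares leave-one-out
#' cross-validation over `n_bandwidths` log-spaced candidates between
#' `bandwidth_range[1]` and `bandwidth_range[2]` times the voxel's sample
#' SD, then (optionally) fits Hampel-loss robust kernel weights. Voxels
#' with degenerate control data (zero variance) are flagged invalid and
#' never silently filled.
#'
#' For cross-sectional (CS) normative models pass the control baseline
#' stack; for longitudinal (LNG) models pass the control change stack
#' (see [change_stack()]).
#'
#' @param stack a control [map_stack()] with at least 2 subjects.
#' @param analysis `"CS"` or `"LNG"`; recorded on the model and used by
#'   [score_subject()] to decide whether a baseline is required.
#' @param config an [analysis_config()] supplying the bandwidth grid.
#' @param robust fit Hampel robust weights (`TRUE`) or keep uniform
#'   weights (`FALSE`, plain Parzen estimate).
#' @param tol,max_iter,breakpoint_quantiles,c_scale passed to the
#'   robust reweighting (see [fit_robust_weights()]).
#' @return an object of class `normative_kde` with per-voxel `centers`
#'   (voxels x N), `weights`, bandwidths `h`, validity flags and fitting
#'   provenance. Methods: `print`, `summary`, `predict`, `simulate`,
#'   `plot`.
#' @export
normative_kde <- function(stack, analysis = c("CS", "LNG"),
                          config = analysis_config(), robust = TRUE,
                          tol = 1e-6, max_iter = 100L,
                          breakpoint_quantiles = c(0.90, 0.99),
                          c_scale = 1.5) {
  analysis <- match.arg(analysis)
  stopifnot(inherits(stack, "map_stack"))
  n <- nrow(stack$values)
  if (n < 2) stop("a normative fit requires at least 2 control subjects")
  t0 <- as.numeric(proc.time()[["elapsed"]])
  X <- t(stack$values)  # voxels x subjects
  grid <- bandwidth_grid(config$bandwidth_range, config$n_bandwidths)
  bw <- cpp_select_bandwidth(X, grid)
  vn_log("bandwidth", sprintf("modality=%s voxels=%d", stack$modality,
                              nrow(X)), t0 = t0)
  if (robust) {
    rw <- cpp_robust_weights(X, bw$h, tol, as.integer(max_iter),
                             breakpoint_quantiles[1], breakpoint_quantiles[2],
                             c_scale)
    W <- rw$weights
    converged <- rw$converged
    n_nc <- sum(!converged & bw$valid)
    if (n_nc > 0)
      warning(sprintf("robust reweighting did not converge at %d voxel(s); last iterates kept", n_nc))
  } else {
    W <- matrix(1 / n, nrow(X), n)
    W[!bw$valid, ] <- NA_real_
    converged <- bw$valid
  }
  vn_log("weights", sprintf("modality=%s", stack$modality), t0 = t0)
  structure(list(centers = X, weights = W, h = bw$h, valid = bw$valid,
                 converged = converged, n_ctl = n,
                 modality = stack$modality, analysis = analysis,
                 mask = stack$mask, dim = stack$dim,
                 spacing = stack$spacing, robust = robust,
                 config = config,
                 provenance = list(
                   bandwidth_grid = grid,
                   breakpoint_quantiles = breakpoint_quantiles,
                   c_scale = c_scale,
                   tol = tol, max_iter = as.integer(max_iter))),
            class = "normative_kde")
}

#' @export
print.normative_kde <- function(x, ...) {
  cat(sprintf("normative_kde (%s, %s): %d control(s), %d voxels (%d valid)\n",
              x$modality, x$analysis, x$n_ctl, length(x$h), sum(x$valid)))
  cat(sprintf("  %s weights; median bandwidth %.4g\n",
              if (x$robust) "Hampel-robust" else "uniform",
              median(x$h[x$valid])))
  invisible(x)
}

#' @export
summary.normative_kde <- function(object, ...) {
  hv <- object$h[object$valid]
  rel <- hv / apply(object$centers[object$valid, , drop = FALSE], 1, sd)
  out <- list(modality = object$modality, analysis = object$analysis,
              n_ctl = object$n_ctl, n_voxels = length(object$h),
              n_valid = sum(object$valid),
              n_unconverged = sum(!object$converged & object$valid),
              h_quartiles = quantile(hv, c(0.25, 0.5, 0.75)),
              h_rel_quartiles = quantile(rel, c(0.25, 0.5, 0.75)),
              min_weight = min(object$weights[object$valid, ], na.rm = TRUE))
  class(out) <- "summary.normative_kde"
  out
}

#' @export
print.summary.normative_kde <- function(x, ...) {
  cat(sprintf("Normative KDE model: %s, %s analysis\n", x$modality, x$analysis))
  cat(sprintf("  controls: %d; voxels: %d (%d valid, %d unconverged)\n",
              x$n_ctl, x$n_voxels, x$n_valid, x$n_unconverged))
  cat(sprintf("  bandwidth [Q1, median, Q3]: %.4g, %.4g, %.4g\n",
              x$h_quartiles[1], x$h_quartiles[2], x$h_quartiles[3]))
  cat(sprintf("  bandwidth / sample SD:      %.3f, %.3f, %.3f\n",
              x$h_rel_quartiles[1], x$h_rel_quartiles[2], x$h_rel_quartiles[3]))
  invisible(x)
}

#' Score maps against a normative model
#'
#' `predict()` evaluates the per-voxel normative cumulative probability
#' of new values: a matrix (subjects x voxels, canonical voxel order), a
#' masked vector for one subject, or a [map_stack()]. Invalid voxels
#' yield `NA`. `type = "p2"` returns two-tailed probabilities.
#'
#' @param object a fitted `normative_kde`.
#' @param newdata new values (see above).
#' @param type `"p"` (one-tailed cumulative) or `"p2"` (two-tailed).
#' @param ... unused.
#' @return matrix of probabilities, subjects x voxels.
#' @export
predict.normative_kde <- function(object, newdata, type = c("p", "p2"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "map_stack")) newdata <- newdata$values
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != nrow(object$centers))
    stop("newdata voxel count does not match the model grid")
  P <- matrix(NA_real_, nrow(newdata), ncol(newdata))
  rownames(P) <- rownames(newdata)
  for (i in seq_len(nrow(newdata)))
    P[i, ] <- cpp_kde_cdf_batch(object$centers, object$weights, object$h,
                                as.numeric(newdata[i, ]))
  P <- pmin(pmax(P, 0), 1)  # guard summation round-off at the limits
  P[, !object$valid] <- NA_real_
  if (type == "p2") P <- two_tailed(P)
  P
}

#' Simulate draws from fitted normative mixtures
#'
#' Draws `nsim` values per requested voxel from that voxel's weighted
#' Gaussian kernel mixture (component sampled by weight, then Gaussian
#' noise at bandwidth `h`).
#'
#' @param object a fitted `normative_kde`.
#' @param nsim draws per voxel.
#' @param seed optional seed.
#' @param voxels voxel indices (default: all valid voxels).
#' @param ... unused.
#' @return matrix `nsim` x `length(voxels)`.
#' @export
simulate.normative_kde <- function(object, nsim = 1, seed = NULL,
                                   voxels = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(voxels)) voxels <- which(object$valid)
  if (any(!object$valid[voxels])) stop("cannot simulate from invalid voxels")
  out <- matrix(NA_real_, nsim, length(voxels))
  for (j in seq_along(voxels)) {
    v <- voxels[j]
    comp <- sample.int(object$n_ctl, nsim, replace = TRUE,
                       prob = object$weights[v, ])
    out[, j] <- rnorm(nsim, mean = object$centers[v, comp], sd = object$h[v])
  }
  out
}

#' Plot one voxel's normative density
#'
#' Draws the weighted kernel mixture density with a rug of control
#' observations; rug tick length is proportional to kernel weight, so
#' down-weighted outliers are visible.
#'
#' @param x a fitted `normative_kde`.
#' @param voxel voxel index (canonical masked order).
#' @param ... passed to [graphics::plot()].
#' @export
plot.normative_kde <- function(x, voxel = 1, ...) {
  if (!x$valid[voxel]) stop("voxel ", voxel, " is invalid (degenerate data)")
  ctr <- x$centers[voxel, ]
  w <- x$weights[voxel, ]
  h <- x$h[voxel]
  xs <- seq(min(ctr) - 4 * h, max(ctr) + 4 * h, length.out = 400)
  dens <- vapply(xs, function(q) sum(w * dnorm(q, ctr, h)), numeric(1))
  plot(xs, dens, type = "l",
       xlab = sprintf("%s value", x$modality), ylab = "normative density",
       main = sprintf("voxel %d (h = %.3g)", voxel, h), ...)
  for (i in seq_along(ctr))
    lines(rep(ctr[i], 2), c(0, 0.08 * max(dens) * w[i] / max(w)),
          col = "grey40")
  invisible(x)
}

#' Serialize or restore a fitted normative model
#'
#' Single-file archive (RDS) embedding the fitted arrays and the
#' configuration, so that reloaded models reproduce probabilities
#' exactly.
#'
#' @param model a `normative_kde`.
#' @param path file path.
#' @return `read_normative()` returns the model.
#' @export
write_normative <- function(model, path) {
  stopifnot(inherits(model, "normative_kde"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_normative
#' @export
read_normative <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "normative_kde"))
  model
}
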