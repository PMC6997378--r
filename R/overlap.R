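#' Jaccard overlap of two binary maps
#'
#' `|X intersect Y| / |X union Y|`. When both maps are empty the overlap
#' is undefined and `NA` is returned (and excluded from pooled
#' summaries): an empty-vs-empty pair expresses "no abnormality
#' anywhere", not disagreement.
#'
#' @param x,y logical arrays or vectors on the same grid.
#' @return value in \[0, 1\], or `NA`.
#' @export
jaccard <- function(x, y) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("maps must share the same grid")
  u <- sum(x | y)
  if (u == 0) return(NA_real_)
  sum(x & y) / u
}

# gather results into a lookup by (subject, analysis, timepoint)
result_index <- function(results) {
  data.frame(
    i = seq_along(results),
    subject = vapply(results, `[[`, "", "subject_id"),
    modality = vapply(results, `[[`, "", "modality"),
    analysis = vapply(results, `[[`, "", "analysis"),
    timepoint = vapply(results, `[[`, "", "timepoint"))
}

#' Overlap records, pooled summaries and paired contrasts
#'
#' Computes the per-subject Jaccard overlap for the four standard
#' comparisons (CS vs LNG at each timepoint; SYM vs RTP under each
#' analysis), pools medians and quartiles per comparison and family, and
#' runs paired Wilcoxon signed-rank contrasts: SYM vs RTP differences in
#' CS-vs-LNG overlap, and CS vs LNG differences in timepoint overlap.
#' Subjects with missing values are excluded pairwise; a contrast with
#' fewer than 2 complete pairs is reported as not computable (`NA`).
#'
#' @param results list of `abnormality_result` objects for one modality,
#'   covering CS/LNG analyses at SYM/RTP timepoints.
#' @return list with data frames `records` (subject-level values),
#'   `pooled` (per comparison and pooled-family medians/quartiles) and
#'   `contrasts` (Wilcoxon p-values).
#' @export
overlap_table <- function(results) {
  ix <- result_index(results)
  getmap <- function(subject, analysis, timepoint) {
    j <- which(ix$subject == subject & ix$analysis == analysis &
                 ix$timepoint == timepoint)
    if (length(j) != 1) return(NULL)
    abnormality_volume(results[[j]])
  }
  subjects <- unique(ix$subject)
  modality <- ix$modality[1]
  comparisons <- list(
    `CS-vs-LNG@SYM` = function(s) list(getmap(s, "CS", "SYM"), getmap(s, "LNG", "SYM")),
    `CS-vs-LNG@RTP` = function(s) list(getmap(s, "CS", "RTP"), getmap(s, "LNG", "RTP")),
    `SYM-vs-RTP@CS` = function(s) list(getmap(s, "CS", "SYM"), getmap(s, "CS", "RTP")),
    `SYM-vs-RTP@LNG` = function(s) list(getmap(s, "LNG", "SYM"), getmap(s, "LNG", "RTP")))
  records <- do.call(rbind, lapply(names(comparisons), function(cmp) {
    vals <- vapply(subjects, function(s) {
      m <- comparisons[[cmp]](s)
      if (is.null(m[[1]]) || is.null(m[[2]])) return(NA_real_)
      jaccard(m[[1]], m[[2]])
    }, numeric(1))
    data.frame(subject = subjects, modality = modality, comparison = cmp,
               jaccard = vals, row.names = NULL)
  }))
  fam <- ifelse(grepl("^CS-vs-LNG", records$comparison), "CS-vs-LNG",
                "SYM-vs-RTP")
  pool_stats <- function(v, label) {
    v <- v[!is.na(v)]
    q <- if (length(v)) quantile(v, c(0.25, 0.5, 0.75)) else rep(NA_real_, 3)
    data.frame(modality = modality, comparison = label, n = length(v),
               median = q[2], q1 = q[1], q3 = q[3], row.names = NULL)
  }
  pooled <- rbind(
    do.call(rbind, lapply(names(comparisons), function(cmp)
      pool_stats(records$jaccard[records$comparison == cmp], cmp))),
    pool_stats(records$jaccard[fam == "CS-vs-LNG"], "CS-vs-LNG (pooled)"),
    pool_stats(records$jaccard[fam == "SYM-vs-RTP"], "SYM-vs-RTP (pooled)"))
  paired_wilcoxon <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) return(NA_real_)
    d <- a[ok] - b[ok]
    if (all(d == 0)) return(1)
    suppressWarnings(wilcox.test(a[ok], b[ok], paired = TRUE)$p.value)
  }
  wide <- function(cmp) records$jaccard[records$comparison == cmp]
  contrasts <- data.frame(
    modality = modality,
    contrast = c("SYM-vs-RTP difference in CS-vs-LNG overlap",
                 "CS-vs-LNG difference in SYM-vs-RTP overlap"),
    p = c(paired_wilcoxon(wide("CS-vs-LNG@SYM"), wide("CS-vs-LNG@RTP")),
          paired_wilcoxon(wide("SYM-vs-RTP@CS"), wide("SYM-vs-RTP@LNG"))))
  contrasts$pooled <- is.na(contrasts$p) | contrasts$p >= 0.05
  list(records = records, pooled = pooled, contrasts = contrasts)
}

# binarize one p2 map under a thresholding scheme
apply_scheme <- function(p2, scheme, threshold) {
  ok <- !is.na(p2)
  out <- rep(FALSE, length(p2))
  switch(scheme,
         fdr = {
           out[ok] <- p.adjust(p2[ok], method = "BH") <= threshold
         },
         p = {
           out[ok] <- p2[ok] <= threshold
         },
         percentile = {
           cut <- quantile(p2[ok], (100 - threshold) / 100)
           out[ok] <- p2[ok] <= cut
         })
  out
}

#' Jaccard robustness curves under alternative thresholding schemes
#'
#' Re-thresholds the retained probability maps under a grid of FDR
#' levels, uncorrected two-tailed p cutoffs, or per-map percentile
#' cutoffs (the `pct`-th percentile keeps the `100 - pct` percent most
#' extreme voxels of each map), re-applies the minimum cluster-extent
#' filter, and summarizes the per-subject CS-vs-LNG Jaccard overlap at
#' each grid value and timepoint.
#'
#' @param results list of `abnormality_result` objects (their `p2` maps
#'   are re-thresholded; the stored binary maps are not reused).
#' @param scheme `"fdr"`, `"p"` or `"percentile"`.
#' @param grid threshold grid; defaults to the scheme's grid in `config`.
#' @param config an [analysis_config()].
#' @return data frame with columns `scheme`, `threshold`, `timepoint`,
#'   `n`, `median`, `q1`, `q3`.
#' @export
threshold_sweep <- function(results, scheme = c("fdr", "p", "percentile"),
                            grid = NULL, config = analysis_config()) {
  scheme <- match.arg(scheme)
  if (is.null(grid))
    grid <- switch(scheme, fdr = config$fdr_grid, p = config$p_grid,
                   percentile = config$percentile_grid)
  if (length(grid) == 0) stop("empty threshold grid")
  ix <- result_index(results)
  mask <- results[[1]]$mask
  midx <- which(mask)
  timepoints <- intersect(c("SYM", "RTP", "baseline"), unique(ix$timepoint))
  rows <- list()
  for (thr in grid) {
    for (tp in timepoints) {
      subjects <- unique(ix$subject[ix$timepoint == tp])
      vals <- vapply(subjects, function(s) {
        jcs <- which(ix$subject == s & ix$analysis == "CS" & ix$timepoint == tp)
        jln <- which(ix$subject == s & ix$analysis == "LNG" & ix$timepoint == tp)
        if (length(jcs) != 1 || length(jln) != 1) return(NA_real_)
        bin <- lapply(list(results[[jcs]], results[[jln]]), function(r) {
          b <- apply_scheme(r$p2, scheme, thr)
          cluster_filter(unmask(b, mask, fill = FALSE),
                         config$min_cluster_size, config$connectivity)
        })
        jaccard(bin[[1]], bin[[2]])
      }, numeric(1))
      vals <- vals[!is.na(vals)]
      q <- if (length(vals)) quantile(vals, c(0.25, 0.5, 0.75))
      else rep(NA_real_, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = scheme, threshold = thr, timepoint = tp, n = length(vals),
        median = q[2], q1 = q[1], q3 = q[3], row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Spearman correlation of a summary with a timing covariate
#'
#' Rank correlation with tie-corrected two-sided p (normal
#' approximation under ties). Pairs with missing values are dropped; a
#' constant vector makes the correlation undefined and returns `NA`.
#'
#' @param x per-subject summary values.
#' @param time timing covariate (e.g. days between scans).
#' @return list with `rho`, `p` and `n` (complete pairs).
#' @export
correlate_with_time <- function(x, time) {
  ok <- !is.na(x) & !is.na(time)
  x <- x[ok]; time <- time[ok]
  if (length(x) < 3)
    stop("at least 3 complete pairs are required")
  if (sd(x) == 0 || sd(time) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(cor.test(x, time, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
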