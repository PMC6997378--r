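#' Per-subject normative probability maps
#'
#' Cross-sectional (CS) models score the subject's values directly;
#' longitudinal (LNG) models score the subject's change map
#' (post-injury minus baseline), so a baseline stack is required and its
#' absence is an error naming the affected subjects.
#'
#' @param model a fitted [normative_kde()].
#' @param stack subject [map_stack()] at the timepoint of interest.
#' @param baseline baseline [map_stack()] (LNG models only).
#' @return list with matrices `p` and `p2` (subjects x voxels, `NA` at
#'   invalid voxels) and `timepoint`.
#' @export
score_subject <- function(model, stack, baseline = NULL) {
  stopifnot(inherits(model, "normative_kde"), inherits(stack, "map_stack"))
  if (model$analysis == "LNG" && stack$session != "change") {
    if (is.null(baseline))
      stop("LNG scoring requires baseline data; missing baseline for subject(s): ",
           paste(stack$subject_ids, collapse = ", "))
    absent <- setdiff(stack$subject_ids, baseline$subject_ids)
    if (length(absent))
      stop("LNG scoring requires baseline data; missing baseline for subject(s): ",
           paste(absent, collapse = ", "))
    values <- change_stack(baseline, stack)
  } else {
    values <- stack
  }
  p <- predict(model, values, type = "p")
  list(p = p, p2 = two_tailed(p), timepoint = stack$session,
       subject_ids = stack$subject_ids)
}

#' Benjamini-Hochberg FDR thresholding of a probability map
#'
#' Step-up BH procedure over the valid voxels of a single two-tailed
#' probability map; a voxel is abnormal iff its BH-adjusted probability
#' is at most `q`. `NA` voxels (invalid normative fits) are excluded and
#' never flagged.
#'
#' @param p2 two-tailed probabilities (masked vector).
#' @param q target false discovery rate in (0, 1).
#' @return logical vector, `FALSE` at `NA` input.
#' @export
fdr_threshold <- function(p2, q = 0.05) {
  stopifnot(q > 0, q < 1)
  ok <- !is.na(p2)
  if (!any(ok)) stop("all voxels are missing; nothing to threshold")
  stopifnot(all(p2[ok] >= 0 & p2[ok] <= 1))
  out <- rep(FALSE, length(p2))
  out[ok] <- p.adjust(p2[ok], method = "BH") <= q
  out
}

# positive-octant neighbour offsets for a connectivity scheme
conn_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g <- g[keep, ]
  # one offset per unordered neighbour pair
  g[g$dz > 0 | (g$dz == 0 & (g$dy > 0 | (g$dy == 0 & g$dx > 0))), ]
}

#' Label connected components of a binary 3-D map
#'
#' Components under the 6- (faces), 18- (faces + edges) or 26-
#' (faces + edges + corners) neighbourhood, labelled 1..k in order of
#' their smallest linear voxel index.
#'
#' @param x 3-D logical array.
#' @param connectivity 6, 18 or 26.
#' @return 3-D integer array; 0 = background.
#' @export
label_clusters <- function(x, connectivity = 26L) {
  dm <- dim(x)
  lab <- array(0L, dm)
  idx <- which(x)
  if (length(idx) == 0) return(lab)
  co <- arrayInd(idx, dm)
  off <- conn_offsets(connectivity)
  edges <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb <- cbind(co[, 1] + off$dx[k], co[, 2] + off$dy[k], co[, 3] + off$dz[k])
    inb <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    lin <- (nb[inb, 3] - 1) * dm[1] * dm[2] + (nb[inb, 2] - 1) * dm[1] +
      nb[inb, 1]
    hit <- match(lin, idx)
    from <- which(inb)[!is.na(hit)]
    to <- hit[!is.na(hit)]
    if (length(to)) edges <- c(edges, rbind(from, to))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel by smallest member index so labels are deterministic
  first <- tapply(seq_along(idx), comp, min)
  relabel <- rank(first)
  lab[idx] <- as.integer(relabel[comp])
  lab
}

#' Minimum cluster-extent filter
#'
#' Removes connected components smaller than `min_size` voxels from a
#' binary map, eliminating singleton and near-singleton detections.
#' Idempotent; an empty map passes through unchanged.
#'
#' @param x 3-D logical array.
#' @param min_size minimum surviving component extent (voxels).
#' @param connectivity 6, 18 or 26.
#' @return 3-D logical array.
#' @export
cluster_filter <- function(x, min_size = 3L, connectivity = 26L) {
  if (min_size <= 1 || !any(x)) return(x)
  lab <- label_clusters(x, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  array(lab %in% keep, dim = dim(x))
}

#' Classify abnormal voxels by direction of effect
#'
#' Abnormal voxels are "positive" (+1) when the one-tailed probability is
#' at or above `cutoff` (high relative to controls) and "negative" (-1)
#' when at or below `1 - cutoff`. An abnormal voxel strictly between the
#' tails cannot have survived FDR thresholding at q <= 2 (1 - cutoff) and
#' signals an upstream inconsistency, so it is an error.
#'
#' @param p one-tailed probabilities (masked vector).
#' @param abnormal logical masked vector of abnormal voxels.
#' @param cutoff positive-tail probability cutoff.
#' @return list with `direction` (integer masked vector in \{-1, 0, +1\})
#'   and `positive_fraction` (`NA` when no voxel is abnormal).
#' @export
classify_direction <- function(p, abnormal, cutoff = 0.975) {
  stopifnot(length(p) == length(abnormal))
  direction <- integer(length(p))
  ab <- which(abnormal)
  if (length(ab) == 0)
    return(list(direction = direction, positive_fraction = NA_real_))
  pa <- p[ab]
  if (any(is.na(pa)))
    stop("abnormal voxel with missing probability; upstream inconsistency")
  mid <- pa > (1 - cutoff) & pa < cutoff
  if (any(mid))
    stop(sprintf("%d abnormal voxel(s) with probability strictly between the tails (%g, %g); upstream inconsistency",
                 sum(mid), 1 - cutoff, cutoff))
  direction[ab] <- ifelse(pa >= cutoff, 1L, -1L)
  list(direction = direction,
       positive_fraction = mean(direction[ab] == 1L))
}

#' Detect per-subject abnormality maps
#'
#' Full per-subject pipeline: normative scoring, BH FDR thresholding of
#' each subject's two-tailed probability map, minimum cluster-extent
#' filtering, and direction classification. One BH procedure is run per
#' (subject, modality, analysis, timepoint) map.
#'
#' @param model a fitted [normative_kde()].
#' @param stack subject [map_stack()] at the timepoint of interest.
#' @param baseline baseline stack (required for LNG models).
#' @param config an [analysis_config()].
#' @return list of `abnormality_result` objects, one per subject, each
#'   with masked vectors `p`, `p2`, `abnormal`, `direction`, the scalar
#'   `abnormal_fraction` and `positive_fraction`, and identifying tags.
#' @export
detect_abnormalities <- function(model, stack, baseline = NULL,
                                 config = analysis_config()) {
  sc <- score_subject(model, stack, baseline)
  midx <- which(model$mask)
  lapply(seq_along(sc$subject_ids), function(i) {
    p <- sc$p[i, ]
    p2 <- sc$p2[i, ]
    abn <- fdr_threshold(p2, config$fdr_q)
    vol <- unmask(abn, model$mask, fill = FALSE)
    vol <- cluster_filter(vol, config$min_cluster_size, config$connectivity)
    abn <- vol[midx]
    dir <- classify_direction(p, abn, config$tail_cutoff)
    structure(list(subject_id = sc$subject_ids[i], modality = model$modality,
                   analysis = model$analysis, timepoint = sc$timepoint,
                   p = p, p2 = p2, abnormal = abn,
                   direction = dir$direction,
                   abnormal_fraction = mean(abn[!is.na(p2)]),
                   positive_fraction = dir$positive_fraction,
                   mask = model$mask, dim = model$dim),
              class = "abnormality_result")
  })
}

#' @export
print.abnormality_result <- function(x, ...) {
  cat(sprintf("abnormality_result: subject %s, %s, %s analysis, %s\n",
              x$subject_id, x$modality, x$analysis, x$timepoint))
  cat(sprintf("  %d abnormal voxel(s) (%.2f%% of valid voxels), positive fraction %s\n",
              sum(x$abnormal), 100 * x$abnormal_fraction,
              ifelse(is.na(x$positive_fraction), "NA",
                     sprintf("%.3f", x$positive_fraction))))
  invisible(x)
}

#' Reconstruct a result's binary abnormality volume
#'
#' @param result an `abnormality_result`.
#' @return 3-D logical array.
#' @export
abnormality_volume <- function(result) {
  unmask(result$abnormal, result$mask, fill = FALSE)
}

#' Spatial-extent and direction summary table
#'
#' Medians and quartiles, across subjects, of the percentage of abnormal
#' voxels and of the positive fraction, per (modality, analysis,
#' timepoint) cell. Missing positive fractions (maps with no abnormal
#' voxels) are excluded from the direction summary.
#'
#' @param results list of `abnormality_result` objects.
#' @return data frame with one row per cell.
#' @export
summarize_extent <- function(results) {
  stopifnot(length(results) >= 1)
  tags <- data.frame(
    modality = vapply(results, `[[`, "", "modality"),
    analysis = vapply(results, `[[`, "", "analysis"),
    timepoint = vapply(results, `[[`, "", "timepoint"),
    extent_pct = 100 * vapply(results, `[[`, 0, "abnormal_fraction"),
    positive_fraction = vapply(results, `[[`, 0, "positive_fraction"))
  cells <- unique(tags[c("modality", "analysis", "timepoint")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- tags$modality == cells$modality[i] &
      tags$analysis == cells$analysis[i] &
      tags$timepoint == cells$timepoint[i]
    e <- tags$extent_pct[sel]
    pf <- tags$positive_fraction[sel]
    pf <- pf[!is.na(pf)]
    qe <- quantile(e, c(0.25, 0.5, 0.75))
    qp <- if (length(pf)) quantile(pf, c(0.25, 0.5, 0.75)) else rep(NA_real_, 3)
    data.frame(cells[i, ], n = sum(sel),
               extent_median = qe[2], extent_q1 = qe[1], extent_q3 = qe[3],
               posfrac_median = qp[2], posfrac_q1 = qp[1], posfrac_q3 = qp[3],
               row.names = NULL)
  }))
  out
}

#' Representative axial slice of a subject's abnormality maps
#'
#' Ranks the axial (third-dimension) slices of each map by total abnormal
#' voxel count (ties receive average rank) and returns the slice with the
#' highest mean rank across the available maps; `NULL` or empty maps are
#' skipped. Final ties go to the lowest slice index. Returns
#' `NA_integer_` when every map is empty.
#'
#' @param maps list of binary 3-D arrays (typically the four
#'   \{CS, LNG\} x \{SYM, RTP\} maps of one subject).
#' @return integer slice index, or `NA_integer_`.
#' @export
representative_slice <- function(maps) {
  maps <- Filter(function(m) !is.null(m) && any(m), maps)
  if (length(maps) == 0) return(NA_integer_)
  ranks <- vapply(maps, function(m) {
    counts <- apply(m, 3, sum)
    rank(counts)  # average rank at ties
  }, numeric(dim(maps[[1]])[3]))
  mean_rank <- rowMeans(ranks)
  which.max(mean_rank)  # which.max returns the first (lowest) index at ties
}
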