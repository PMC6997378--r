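#' Construct an atlas parcellation
#'
#' Wraps a labelled integer volume (0 = background) with region names and
#' centers of mass (mean member-voxel coordinates). Real atlases (e.g.
#' white-matter or grey-matter parcellations) load as ordinary labelled
#' NIfTI volumes via [read_volume()]; the toy generator below provides a
#' self-contained test fixture.
#'
#' @param labels 3-D integer array of region labels.
#' @param names optional character vector named by region id.
#' @return an object of class `atlas_parcellation` with `labels`,
#'   `region_ids`, `names` and `com` (region x 3 matrix).
#' @export
atlas_parcellation <- function(labels, names = NULL) {
  labels <- array(as.integer(round(labels)), dim = dim(labels))
  if (any(labels < 0)) stop("region labels must be non-negative")
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) stop("atlas has zero regions")
  com <- t(vapply(ids, function(id)
    colMeans(arrayInd(which(labels == id), dim(labels))), numeric(3)))
  rownames(com) <- ids
  if (is.null(names)) {
    names <- sprintf("region_%d", ids)
    base::names(names) <- ids
  }
  structure(list(labels = labels, region_ids = ids,
                 names = names[as.character(ids)], com = com),
            class = "atlas_parcellation")
}

#' @export
print.atlas_parcellation <- function(x, ...) {
  cat(sprintf("atlas_parcellation: %d regions on a %s grid (%d labelled voxels)\n",
              length(x$region_ids), paste(dim(x$labels), collapse = "x"),
              sum(x$labels > 0)))
  invisible(x)
}

#' Generate a toy atlas partitioning a mask
#'
#' Voronoi partition of the masked voxels around randomly sampled seed
#' voxels: every masked voxel receives the label of its nearest seed
#' (ties to the lowest region id), so the regions partition the mask and
#' all labels are non-empty.
#'
#' @param mask 3-D logical array.
#' @param n_regions number of regions (at most the mask voxel count).
#' @param seed integer seed.
#' @return an [atlas_parcellation()].
#' @export
generate_toy_atlas <- function(mask, n_regions, seed = 1L) {
  idx <- which(mask)
  if (n_regions > length(idx))
    stop("cannot partition ", length(idx), " voxels into ", n_regions,
         " non-empty regions")
  set.seed(seed)
  seeds <- sort(sample(idx, n_regions))
  co <- arrayInd(idx, dim(mask))
  sc <- arrayInd(seeds, dim(mask))
  lab <- array(0L, dim(mask))
  d2 <- matrix(0, length(idx), n_regions)
  for (r in seq_len(n_regions))
    d2[, r] <- (co[, 1] - sc[r, 1])^2 + (co[, 2] - sc[r, 2])^2 +
      (co[, 3] - sc[r, 3])^2
  lab[idx] <- max.col(-d2, ties.method = "first")
  atlas_parcellation(lab)
}

#' Assign abnormality clusters to atlas regions
#'
#' Parcellates a binary map into connected clusters (same connectivity as
#' the cluster-extent filter) and assigns each cluster the set of atlas
#' regions it overlaps. A cluster overlapping only background is assigned
#' the single region whose center of mass is nearest (Euclidean, voxel
#' coordinates) to the cluster's center of mass, ties to the lowest
#' region id, so no cluster is ever dropped.
#'
#' @param x binary 3-D array.
#' @param atlas an [atlas_parcellation()] on the same grid.
#' @param connectivity 6, 18 or 26.
#' @return list of clusters, each with `voxels` (linear indices),
#'   `com`, `regions` (region ids) and `fallback` (logical).
#' @export
assign_clusters <- function(x, atlas, connectivity = 26L) {
  stopifnot(inherits(atlas, "atlas_parcellation"))
  if (!identical(dim(x), dim(atlas$labels)))
    stop("map and atlas must share the same grid")
  lab <- label_clusters(x, connectivity)
  k <- max(lab)
  if (k == 0) return(list())
  lapply(seq_len(k), function(i) {
    vox <- which(lab == i)
    regions <- sort(unique(atlas$labels[vox]))
    regions <- regions[regions > 0]
    com <- colMeans(arrayInd(vox, dim(x)))
    fallback <- length(regions) == 0
    if (fallback) {
      d2 <- rowSums((atlas$com - matrix(com, nrow(atlas$com), 3,
                                        byrow = TRUE))^2)
      regions <- atlas$region_ids[which.min(d2)]  # first index at ties
    }
    list(voxels = vox, com = com, regions = regions, fallback = fallback)
  })
}

#' Regional abnormality frequency table
#'
#' For each atlas region, counts the number of abnormality maps having at
#' least one assigned cluster: a map contributes at most once per region
#' regardless of how many of its clusters fall there. Maps are typically
#' pooled over subjects and timepoints within one analysis.
#'
#' @param maps list of binary 3-D arrays.
#' @param atlas an [atlas_parcellation()].
#' @param connectivity 6, 18 or 26.
#' @return data frame with columns `region`, `name`, `count`.
#' @export
frequency_map <- function(maps, atlas, connectivity = 26L) {
  stopifnot(length(maps) >= 1)
  counts <- setNames(integer(length(atlas$region_ids)),
                     atlas$region_ids)
  for (m in maps) {
    cl <- assign_clusters(m, atlas, connectivity)
    hit <- unique(unlist(lapply(cl, `[[`, "regions")))
    counts[as.character(hit)] <- counts[as.character(hit)] + 1L
  }
  data.frame(region = atlas$region_ids,
             name = unname(atlas$names),
             count = unname(counts), row.names = NULL)
}

#' Spearman concordance of regional frequencies with a bootstrap CI
#'
#' Rank correlation between two regional frequency vectors (e.g. CS vs
#' LNG counts), with a percentile confidence interval from resampling
#' regions — the correlated units — with replacement. Constant input
#' vectors make the correlation undefined (`NA`).
#'
#' @param freq_a,freq_b frequency vectors over the same regions (length
#'   >= 3), or `frequency_map()` outputs sharing a region column.
#' @param n_boot number of bootstrap resamples.
#' @param seed optional integer seed.
#' @param conf confidence level.
#' @return list with `rho`, `ci` (length 2), `n_regions`, `n_boot`.
#' @export
regional_concordance <- function(freq_a, freq_b, n_boot = 10000L,
                                 seed = NULL, conf = 0.95) {
  if (is.data.frame(freq_a)) freq_a <- freq_a$count
  if (is.data.frame(freq_b)) freq_b <- freq_b$count
  stopifnot(length(freq_a) == length(freq_b))
  if (length(freq_a) < 3) stop("at least 3 regions are required")
  if (sd(freq_a) == 0 || sd(freq_b) == 0)
    return(list(rho = NA_real_, ci = c(NA_real_, NA_real_),
                n_regions = length(freq_a), n_boot = 0L))
  if (!is.null(seed)) set.seed(seed)
  rho <- cor(freq_a, freq_b, method = "spearman")
  n <- length(freq_a)
  boots <- vapply(seq_len(n_boot), function(i) {
    j <- sample.int(n, n, replace = TRUE)
    if (sd(freq_a[j]) == 0 || sd(freq_b[j]) == 0) return(NA_real_)
    cor(freq_a[j], freq_b[j], method = "spearman")
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE)
  list(rho = rho, ci = unname(ci), n_regions = n, n_boot = n_boot)
}
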