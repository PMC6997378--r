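#' Construct a parameter-map stack
#'
#' A `map_stack` holds co-registered scalar maps (one row per
#' subject/session) restricted to an analysis mask. Masked voxels are
#' stored in a fixed linear order: ascending raster order of the 3-D
#' index, i.e. the column-major order returned by `which(mask)`, with the
#' first grid index varying fastest. All per-voxel arrays in the package
#' align to this order.
#'
#' @param values numeric matrix, subjects x masked voxels, or a vector for
#'   a single subject. FA values must lie in \[0, 1\], MD values must be
#'   positive (mm^2/s), and all values must be finite.
#' @param mask 3-D logical array; `sum(mask)` must equal `ncol(values)`.
#' @param modality one of `"FA"`, `"MD"`, `"CBF"`.
#' @param session session label: `"baseline"`, `"postseason"`, `"SYM"`,
#'   `"RTP"` or `"change"`.
#' @param subject_ids character vector of row identifiers.
#' @param spacing voxel spacing in mm (length 3).
#' @return an object of class `map_stack`.
#' @export
map_stack <- function(values, mask, modality, session,
                      subject_ids = NULL, spacing = c(1, 1, 1)) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  modality <- match.arg(modality, MODALITIES)
  session <- match.arg(session, SESSIONS)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3-D logical array")
  mask <- array(as.logical(mask), dim = dim(mask))
  nv <- sum(mask)
  if (ncol(values) != nv)
    stop(sprintf("values has %d columns but mask has %d voxels",
                 ncol(values), nv))
  if (!all(is.finite(values)))
    stop("non-finite values inside the mask; inputs must be cleaned upstream")
  if (session != "change") {  # change maps are differences; range rules lapse
    if (modality == "FA" && (any(values < 0) || any(values > 1)))
      stop("FA values must lie in [0, 1]")
    if (modality == "MD" && any(values <= 0))
      stop("MD values must be positive")
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(nrow(values)))
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length must match the number of rows")
  rownames(values) <- subject_ids
  structure(list(values = values, mask = mask, modality = modality,
                 session = session, subject_ids = as.character(subject_ids),
                 dim = dim(mask), spacing = as.numeric(spacing)),
            class = "map_stack")
}

#' @export
print.map_stack <- function(x, ...) {
  cat(sprintf("map_stack: %d subject(s) x %d masked voxels\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  modality %s, session %s, grid %s, spacing %s mm\n",
              x$modality, x$session, paste(x$dim, collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Masked-voxel indices and volume reconstruction
#'
#' `mask_indices()` returns the linear indices of the masked voxels in the
#' package's canonical order (`which(mask)`); `unmask()` scatters a masked
#' vector back into a 3-D volume, with `fill` outside the mask.
#'
#' @param mask 3-D logical array.
#' @param x numeric/logical vector of length `sum(mask)`.
#' @param fill value placed outside the mask.
#' @return integer vector, or a 3-D array shaped like `mask`.
#' @export
mask_indices <- function(mask) which(mask)

#' @rdname mask_indices
#' @export
unmask <- function(x, mask, fill = NA) {
  if (length(x) != sum(mask))
    stop("length(x) must equal the number of masked voxels")
  out <- array(fill, dim = dim(mask))
  out[which(mask)] <- x
  out
}

#' Read and write scalar NIfTI volumes
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()]
#' storing voxels as double precision so that write-then-read round-trips
#' are bit-exact for finite values.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol numeric 3-D array.
#' @param spacing voxel spacing in mm.
#' @return `read_volume()` returns a plain numeric array with attribute
#'   `"spacing"`; `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "spacing") <- RNifti::pixdim(img)
  out
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  arr <- array(as.numeric(vol), dim = dim(vol))
  attr(arr, "pixdim") <- spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' Read or write a cohort manifest
#'
#' The manifest is a tab-separated table with one row per volume and
#' columns `subject_id`, `group` (`control`/`concussed`), `session`,
#' `modality`, `path`, plus optional timing covariates
#' (`days_from_baseline`, `days_post_injury`). `(subject_id, session,
#' modality)` must be unique.
#'
#' @param path TSV file path.
#' @param manifest a data frame with the columns above.
#' @return a data frame.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  need <- c("subject_id", "group", "session", "modality", "path")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(m$subject_id, m$session, m$modality)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, session, modality) rows in manifest")
  invisible(m)
}

#' Load a parameter-map stack from a manifest
#'
#' Reads the NIfTI volumes selected by group/session/modality, checks that
#' every volume shares the mask's grid, and extracts masked voxels in the
#' canonical raster order. Rows are ordered as in the manifest.
#'
#' @param manifest data frame as in [read_manifest()].
#' @param group,session,modality row selectors.
#' @param mask 3-D logical analysis mask.
#' @return a [map_stack()].
#' @export
load_stack <- function(manifest, group, session, modality, mask) {
  validate_manifest(manifest)
  sel <- manifest[manifest$group == group & manifest$session == session &
                    manifest$modality == modality, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop(sprintf("no manifest rows for group=%s session=%s modality=%s",
                 group, session, modality))
  missing_paths <- sel$path[!file.exists(sel$path)]
  if (length(missing_paths))
    stop("missing volume file(s): ", paste(missing_paths, collapse = ", "))
  idx <- which(mask)
  vals <- matrix(NA_real_, nrow(sel), length(idx))
  spacing <- c(1, 1, 1)
  for (i in seq_len(nrow(sel))) {
    vol <- read_volume(sel$path[i])
    if (!identical(dim(vol), dim(mask)))
      stop(sprintf("grid mismatch for %s: volume %s vs mask %s",
                   sel$path[i], paste(dim(vol), collapse = "x"),
                   paste(dim(mask), collapse = "x")))
    v <- vol[idx]
    if (!all(is.finite(v)))
      stop(sprintf("non-finite voxels inside the mask in %s", sel$path[i]))
    vals[i, ] <- v
    spacing <- attr(vol, "spacing")[seq_len(3)]
  }
  map_stack(vals, mask, modality, session, subject_ids = sel$subject_id,
            spacing = spacing)
}

#' Difference two paired stacks into a change stack
#'
#' Computes post minus baseline per subject, matching rows by subject id.
#' Used to build longitudinal (LNG) inputs.
#'
#' @param baseline,post `map_stack`s sharing mask, modality and subjects.
#' @return a `map_stack` with session `"change"`.
#' @export
change_stack <- function(baseline, post) {
  if (!identical(baseline$dim, post$dim) ||
      !identical(which(baseline$mask), which(post$mask)))
    stop("baseline and post stacks must share the same mask and grid")
  if (baseline$modality != post$modality)
    stop("modalities differ between baseline and post stacks")
  absent <- setdiff(post$subject_ids, baseline$subject_ids)
  if (length(absent))
    stop("missing baseline data for subject(s): ",
         paste(absent, collapse = ", "))
  b <- baseline$values[match(post$subject_ids, baseline$subject_ids), ,
                       drop = FALSE]
  out <- map_stack(post$values - b, post$mask, post$modality, "change",
                   subject_ids = post$subject_ids, spacing = post$spacing)
  out
}

#' Build a tissue analysis mask from a control mean map
#'
#' White matter (FA) voxels are included iff mean FA > 0.25; grey matter
#' (CBF) voxels iff mean CBF > 20 mL/100 g/min. Both thresholds are
#' strict. MD analyses reuse the FA-derived white-matter mask, which the
#' caller must supply; requesting an MD mask here is an error.
#'
#' @param mean_map 3-D array of voxel-wise control means.
#' @param modality `"FA"` or `"CBF"`.
#' @param fa_threshold,cbf_threshold inclusion thresholds.
#' @return 3-D logical array.
#' @export
build_tissue_mask <- function(mean_map, modality,
                              fa_threshold = 0.25, cbf_threshold = 20) {
  modality <- match.arg(modality, MODALITIES)
  if (!all(is.finite(mean_map))) stop("mean_map must be finite")
  if (modality == "MD")
    stop("MD analyses use the FA-derived white-matter mask; supply it directly")
  thr <- if (modality == "FA") fa_threshold else cbf_threshold
  m <- array(mean_map > thr, dim = dim(mean_map))
  if (!any(m))
    stop(sprintf("empty %s mask at threshold %g: nothing to analyze",
                 modality, thr))
  m
}
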