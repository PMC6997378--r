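#' Analysis configuration
#'
#' Bundles the thresholding and bandwidth-selection settings shared by the
#' pipeline stages. Defaults follow the reference analysis: FDR q = 0.05,
#' minimum cluster extent 3 voxels under full 26-connectivity, bandwidth
#' candidates spanning 0.01-10 times the per-voxel sample SD, and a
#' positive-tail cutoff of 0.975.
#'
#' @param fdr_q false discovery rate for map thresholding, in (0, 1).
#' @param min_cluster_size minimum connected-component extent (voxels).
#' @param connectivity 6 (faces), 18 (faces+edges) or 26
#'   (faces+edges+corners) neighbourhood.
#' @param bandwidth_range bandwidth grid bounds as multiples of the sample
#'   SD; must be positive and increasing.
#' @param n_bandwidths number of log-spaced bandwidth candidates.
#' @param tail_cutoff one-tailed probability defining a "positive"
#'   abnormality (the negative tail is `1 - tail_cutoff`).
#' @param fdr_grid,p_grid,percentile_grid threshold grids for
#'   [threshold_sweep()].
#' @param seed optional integer seed recorded for provenance.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(fdr_q = 0.05, min_cluster_size = 3L,
                            connectivity = 26L,
                            bandwidth_range = c(0.01, 10),
                            n_bandwidths = 50L,
                            tail_cutoff = 0.975,
                            fdr_grid = seq(0.005, 0.10, length.out = 7),
                            p_grid = seq(0.005, 0.05, length.out = 7),
                            percentile_grid = seq(99.9, 95, length.out = 7),
                            seed = NULL) {
  stopifnot(fdr_q > 0, fdr_q < 1, min_cluster_size >= 1,
            connectivity %in% c(6L, 18L, 26L),
            length(bandwidth_range) == 2, all(bandwidth_range > 0),
            bandwidth_range[2] > bandwidth_range[1],
            n_bandwidths >= 2, tail_cutoff > 0.5, tail_cutoff < 1)
  structure(list(fdr_q = fdr_q, min_cluster_size = as.integer(min_cluster_size),
                 connectivity = as.integer(connectivity),
                 bandwidth_range = as.numeric(bandwidth_range),
                 n_bandwidths = as.integer(n_bandwidths),
                 tail_cutoff = tail_cutoff,
                 fdr_grid = as.numeric(fdr_grid),
                 p_grid = as.numeric(p_grid),
                 percentile_grid = as.numeric(percentile_grid),
                 seed = seed),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  cat(sprintf("  FDR q = %g, min cluster = %d, connectivity = %d\n",
              x$fdr_q, x$min_cluster_size, x$connectivity))
  cat(sprintf("  bandwidth grid: %d candidates in [%g, %g] x sample SD\n",
              x$n_bandwidths, x$bandwidth_range[1], x$bandwidth_range[2]))
  cat(sprintf("  tail cutoff = %g\n", x$tail_cutoff))
  invisible(x)
}

#' Read or write an analysis configuration file
#'
#' Plain-text YAML mirroring the fields of [analysis_config()].
#'
#' @param path file path.
#' @param config an `analysis_config`.
#' @return `read_config()` returns an `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}
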