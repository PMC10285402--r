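#' @title Instance decoding from predicted maps
#' @description Watershed-based conversion of dense predictions into instance
#'   segmentations: a zwatershed-style affinity decoder and a marker-based
#'   watershed for BCD predictions. Both are fully deterministic — every
#'   priority tie breaks by raster order — and canonicalize label ids by
#'   first-voxel raster order.
#' @name postprocess
NULL

#' zwatershed-style affinity decoding
#'
#' Seeds are connected components over edges with affinity >= `t_high`;
#' seeds grow along edges in decreasing affinity down to `t_low`; fragments
#' smaller than `min_size` merge into their strongest-affinity neighbour (or
#' background if isolated); finally fragment pairs whose boundary mean
#' affinity is >= `merge_threshold` are merged greedily in decreasing order
#' of that mean. Defaults are community-typical values; with ground-truth
#' affinities the result is threshold-insensitive.
#'
#' @param aff 4D array `(z, y, x, 3)` of affinities in `[0, 1]`
#' @param t_high,t_low seed and growth thresholds, `0 <= t_low <= t_high <= 1`
#' @param min_size minimum fragment size in voxels
#' @param merge_threshold boundary mean affinity above which fragments merge
#' @return integer label array
#' @export
zwatershed <- function(aff, t_high = 0.9, t_low = 0.1, min_size = 128,
                       merge_threshold = 0.3) {
  if (t_low < 0 || t_high > 1 || t_low > t_high)
    stop("thresholds must satisfy 0 <= t_low <= t_high <= 1")
  d <- dim(aff)[1:3]
  lab <- .zwatershed_cpp(as.numeric(aff[, , , 1]), as.numeric(aff[, , , 2]),
                         as.numeric(aff[, , , 3]), as.integer(d),
                         t_high, t_low, as.integer(min_size), merge_threshold)
  array(lab, dim = d)
}

#' Marker-based watershed decoding of BCD predictions
#'
#' Markers are connected components of
#' \code{binary > theta_binary & contour < theta_contour}; a seeded watershed
#' on \code{1 - distance} (or on the contour probability when no distance
#' channel is available) grows them within the \code{binary > theta_binary}
#' mask; instances smaller than `min_size` are removed last.
#'
#' @param pred list with `binary`, `contour` and optionally `distance`
#'   probability volumes in `[0, 1]`
#' @param theta_binary,theta_contour thresholds in (0, 1)
#' @param min_size minimum instance size in voxels
#' @return integer label array
#' @export
decode_bcd <- function(pred, theta_binary = 0.5, theta_contour = 0.5,
                       min_size = 128) {
  if (theta_binary <= 0 || theta_binary >= 1 || theta_contour <= 0 || theta_contour >= 1)
    stop("thresholds must lie strictly inside (0, 1)")
  d <- dim(pred$binary)
  mask <- pred$binary > theta_binary
  seed_mask <- mask & pred$contour < theta_contour
  markers <- .cc_label_3d(as.vector(seed_mask), as.integer(d))
  height <- if (!is.null(pred$distance)) 1 - pred$distance else pred$contour
  lab <- .seeded_watershed_cpp(as.numeric(height), markers,
                               as.vector(mask), as.integer(d))
  lab <- array(lab, dim = d)
  if (min_size > 0) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_size)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  .canonicalize_labels(lab)
}

# consecutive ids 1..k ordered by each instance's first voxel in raster order
.canonicalize_labels <- function(lab) {
  ids <- lab[lab > 0L]
  if (!length(ids)) return(array(0L, dim = dim(lab)))
  first <- !duplicated(ids)
  remap <- integer(max(ids))
  remap[ids[first]] <- seq_len(sum(first))
  out <- lab
  out[lab > 0L] <- remap[ids]
  out
}
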