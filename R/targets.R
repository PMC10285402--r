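#' @title Training targets from instance labels
#' @description Two target families for fine-tuning: nearest-neighbour
#'   affinity maps (3 channels for the -z, -y, -x offsets) and BCD maps
#'   (foreground binary, instance contour, per-instance normalized distance).
#'   Both depend only on label geometry, never on label ids.
#' @name targets
NULL

.shift_eq <- function(labels, axis) {
  # out[v] <- labels[v] == labels[v - e_axis] & labels[v] != 0; border = FALSE
  d <- dim(labels)
  out <- array(FALSE, dim = d)
  if (axis == 1L && d[1] > 1L)
    out[2:d[1], , ] <- labels[2:d[1], , , drop = FALSE] ==
      labels[1:(d[1] - 1L), , , drop = FALSE] & labels[2:d[1], , , drop = FALSE] != 0L
  if (axis == 2L && d[2] > 1L)
    out[, 2:d[2], ] <- labels[, 2:d[2], , drop = FALSE] ==
      labels[, 1:(d[2] - 1L), , drop = FALSE] & labels[, 2:d[2], , drop = FALSE] != 0L
  if (axis == 3L && d[3] > 1L)
    out[, , 2:d[3]] <- labels[, , 2:d[3], drop = FALSE] ==
      labels[, , 1:(d[3] - 1L), drop = FALSE] & labels[, , 2:d[3], drop = FALSE] != 0L
  out
}

#' Nearest-neighbour affinity map from labels
#'
#' Channel c at voxel v is 1 iff v and its neighbour at offset \code{-e_c}
#' carry the same non-background label. Volume-border entries are 0.
#'
#' @param labels integer label array
#' @return 4D array `(z, y, x, 3)`; channels ordered z, y, x
#' @export
affinity_from_labels <- function(labels) {
  labels <- validate_labels(labels)
  d <- dim(labels)
  aff <- array(0, dim = c(d, 3L))
  for (c in 1:3) aff[, , , c] <- .shift_eq(labels, c) * 1
  dimnames(aff) <- list(NULL, NULL, NULL, c("z", "y", "x"))
  aff
}

#' Recover the foreground partition from a binary affinity map
#'
#' Connected components over edges with affinity >= `thresh`; with
#' ground-truth affinities this reproduces the original foreground partition
#' exactly (up to relabeling).
#'
#' @param aff 4D affinity array as from [affinity_from_labels()]
#' @param thresh edge threshold
#' @return integer label array
#' @export
labels_from_affinity <- function(aff, thresh = 0.5) {
  d <- dim(aff)[1:3]
  lab <- .cc_from_affinity(as.numeric(aff[, , , 1]), as.numeric(aff[, , , 2]),
                           as.numeric(aff[, , , 3]), as.integer(d), thresh)
  array(lab, dim = d)
}

#' Binary / contour / distance (BCD) targets from labels
#'
#' \itemize{
#'   \item binary: foreground indicator.
#'   \item contour: foreground voxels within `contour_width` (xy Chebyshev
#'     neighbourhood) of a voxel with a different label, background included;
#'     `include_z` adds the two z-neighbours at width 1. The default is
#'     xy-only: with z sampled much coarser than xy, z-face voxels of thin
#'     instances would otherwise all become contour and sever their
#'     interiors. Out-of-volume is never a boundary.
#'   \item distance: per-instance Euclidean distance to the nearest
#'     differently-labeled voxel, normalized to `[0, 1]` by the instance
#'     maximum (so large and small instances contribute comparably).
#' }
#'
#' @param labels integer label array
#' @param contour_width xy half-width in voxels (>= 1)
#' @param include_z include z-neighbours (width 1) in the contour test
#' @param spacing voxel spacing `(z, y, x)` for the distance transform
#' @return list(binary, contour, distance), each a 3D array
#' @export
bcd_from_labels <- function(labels, contour_width = 1L, include_z = FALSE,
                            spacing = c(1, 1, 1)) {
  stopifnot(contour_width >= 1)
  labels <- validate_labels(labels)
  d <- dim(labels)
  binary <- (labels > 0L) * 1

  # contour: differing-neighbour test over the stated neighbourhood
  w <- as.integer(contour_width)
  shell <- array(FALSE, dim = d)
  offs <- expand.grid(dy = -w:w, dx = -w:w)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  offs <- rbind(cbind(dz = 0L, offs),
                if (include_z) data.frame(dz = c(-1L, 1L), dy = 0L, dx = 0L))
  for (i in seq_len(nrow(offs))) {
    dz <- offs$dz[i]; dy <- offs$dy[i]; dx <- offs$dx[i]
    sz <- seq_len(d[1]); sy <- seq_len(d[2]); sx <- seq_len(d[3])
    kz <- sz + dz >= 1L & sz + dz <= d[1]
    ky <- sy + dy >= 1L & sy + dy <= d[2]
    kx <- sx + dx >= 1L & sx + dx <= d[3]
    a <- labels[sz[kz], sy[ky], sx[kx], drop = FALSE]
    b <- labels[sz[kz] + dz, sy[ky] + dy, sx[kx] + dx, drop = FALSE]
    tmp <- array(FALSE, dim = d)
    tmp[sz[kz], sy[ky], sx[kx]] <- a != b
    shell <- shell | tmp
  }
  contour <- (shell & labels > 0L) * 1

  # per-instance normalized distance
  distance <- array(0, dim = d)
  for (lab in sort(unique(labels[labels > 0L]))) {
    w_ <- which(labels == lab)
    zc <- ((w_ - 1L) %% d[1]) + 1L
    yc <- ((w_ - 1L) %/% d[1]) %% d[2] + 1L
    xc <- (w_ - 1L) %/% (d[1] * d[2]) + 1L
    zr <- max(1L, min(zc) - 1L):min(d[1], max(zc) + 1L)
    yr <- max(1L, min(yc) - 1L):min(d[2], max(yc) + 1L)
    xr <- max(1L, min(xc) - 1L):min(d[3], max(xc) + 1L)
    crop <- labels[zr, yr, xr, drop = FALSE]
    mask <- crop == lab
    dsq <- .edt_sq_3d(as.vector(mask), as.integer(dim(crop)), as.numeric(spacing))
    dist <- array(sqrt(dsq), dim = dim(crop))
    mx <- max(dist[mask])
    val <- if (mx > 0 && mx < 1e5) dist / mx else array(1, dim = dim(crop))
    full <- distance[zr, yr, xr, drop = FALSE]
    full[mask] <- val[mask]
    distance[zr, yr, xr] <- full
  }
  list(binary = binary, contour = contour, distance = distance)
}
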