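#' @title Synthetic serial-section EM volumes
#' @description Paired (image, labels) generation emulating anisotropic
#'   serial-section EM: bright textured cell interiors separated by dark
#'   membranes, instances spanning several sections, additive Gaussian noise.
#'   Two structure classes are drawn — random-walk tubes (neurite-like) and
#'   ellipsoids (mitochondria-like) — so both the affinity-based neuron task
#'   and the BCD-based organelle task can be exercised. Anisotropy is
#'   geometric: objects extend less in z than in xy.
#' @name synthetic
NULL

# stamp an ellipsoid of semi-axes (rz, ry, rx) centred at (cz, cy, cx) into
# `free` positions of canvas; returns linear indices stamped (possibly empty)
.stamp_ellipsoid <- function(d, cz, cy, cx, rz, ry, rx) {
  zr <- max(1L, floor(cz - rz)):min(d[1], ceiling(cz + rz))
  yr <- max(1L, floor(cy - ry)):min(d[2], ceiling(cy + ry))
  xr <- max(1L, floor(cx - rx)):min(d[3], ceiling(cx + rx))
  g <- expand.grid(z = zr, y = yr, x = xr)
  e <- ((g$z - cz) / rz)^2 + ((g$y - cy) / ry)^2 + ((g$x - cx) / rx)^2
  keep <- e <= 1
  if (!any(keep)) return(integer(0))
  g <- g[keep, , drop = FALSE]
  g$z + d[1] * (g$y - 1L) + d[1] * d[2] * (g$x - 1L)
}

# drop candidate voxels 6-adjacent to existing foreground so that a 1-voxel
# background membrane always separates instances (SNEMI-style labels, where
# the dark boundary voxels carry no instance id)
.clear_neighbors <- function(vox, canvas, d) {
  if (!length(vox)) return(vox)
  z <- ((vox - 1L) %% d[1]) + 1L
  y <- ((vox - 1L) %/% d[1]) %% d[2] + 1L
  x <- (vox - 1L) %/% (d[1] * d[2]) + 1L
  bad <- logical(length(vox))
  for (o in list(c(-1L,0L,0L), c(1L,0L,0L), c(0L,-1L,0L), c(0L,1L,0L),
                 c(0L,0L,-1L), c(0L,0L,1L))) {
    zz <- z + o[1]; yy <- y + o[2]; xx <- x + o[3]
    ok <- zz >= 1L & zz <= d[1] & yy >= 1L & yy <= d[2] & xx >= 1L & xx <= d[3]
    ni <- zz[ok] + d[1] * (yy[ok] - 1L) + d[1] * d[2] * (xx[ok] - 1L)
    b <- logical(length(vox)); b[ok] <- canvas[ni] > 0L
    bad <- bad | b
  }
  vox[!bad]
}

.object_voxels_ok <- function(vox, d, min_vox = 150L) {
  if (length(vox) < min_vox) return(FALSE)
  z <- ((vox - 1L) %% d[1]) + 1L
  if (length(unique(z)) < 2L) return(FALSE)           # must span >= 2 sections
  mask <- logical(prod(d)); mask[vox] <- TRUE
  cc <- .cc_label_3d(mask, as.integer(d))
  max(cc) == 1L                                        # 6-connected
}

#' Generate non-overlapping 3D instances
#'
#' Places `n_objects` instances (random-walk tubes and ellipsoids, roughly
#' half each) into an empty canvas. Instances never overlap and are separated
#' by a 1-voxel background membrane line (as in SNEMI-style ground truth,
#' where the dark boundary voxels carry no instance id); each instance is
#' 6-connected and spans at least two z-sections. Objects that cannot be
#' placed after bounded retries are skipped, so the returned label count k
#' may be below `n_objects`; placing zero objects is an error.
#'
#' @param shape volume shape `(z, y, x)`
#' @param n_objects number of instances to attempt
#' @param min_radius,max_radius xy radius range in voxels
#' @param retries placement attempts per object
#' @param min_voxels smallest acceptable instance volume; serial-section EM
#'   instances at this resolution are far larger than watershed size filters,
#'   so the default keeps every instance above typical `min_size` settings
#' @return integer label array, labels `1..k`, 0 background
#' @export
make_instances <- function(shape, n_objects = 70, min_radius = 5, max_radius = 12,
                           retries = 20, min_voxels = 150L) {
  stopifnot(length(shape) == 3, n_objects >= 1, min_radius >= 1,
            max_radius >= min_radius)
  d <- as.integer(shape)
  canvas <- array(0L, dim = d)
  placed <- 0L
  for (obj in seq_len(n_objects)) {
    type <- if (runif(1) < 0.5) "tube" else "ellipsoid"
    for (try in seq_len(retries)) {
      rxy <- runif(1, min_radius, max_radius)
      rz <- max(1.2, rxy * 0.35)                       # geometric anisotropy
      # an object of this size cannot fit; counts as a failed attempt
      if (1 + rz >= d[1] - rz || 1 + rxy >= d[2] - rxy || 1 + rxy >= d[3] - rxy)
        next
      vox <- integer(0)
      if (type == "ellipsoid") {
        cz <- runif(1, 1 + rz, d[1] - rz)
        cy <- runif(1, 1 + rxy, d[2] - rxy)
        cx <- runif(1, 1 + rxy, d[3] - rxy)
        vox <- .stamp_ellipsoid(d, cz, cy, cx, rz, runif(1, 0.7, 1.3) * rxy, rxy)
      } else {
        # random walk in xy with slow z drift, stamping small balls
        r <- max(min_radius, rxy * 0.6)
        rzt <- max(1.1, r * 0.35)
        cz <- runif(1, 1 + rzt, d[1] - rzt)
        cy <- runif(1, 1 + r, d[2] - r)
        cx <- runif(1, 1 + r, d[3] - r)
        ang <- runif(1, 0, 2 * pi)
        steps <- sample(8:20, 1)
        for (s in seq_len(steps)) {
          vox <- c(vox, .stamp_ellipsoid(d, cz, cy, cx, rzt, r, r))
          ang <- ang + rnorm(1, 0, 0.5)
          cy <- min(max(cy + 1.5 * sin(ang), 1 + r), d[2] - r)
          cx <- min(max(cx + 1.5 * cos(ang), 1 + r), d[3] - r)
          cz <- min(max(cz + rnorm(1, 0, 0.3), 1 + rzt), d[1] - rzt)
        }
        vox <- unique(vox)
      }
      vox <- .clear_neighbors(vox[canvas[vox] == 0L], canvas, d)
      if (.object_voxels_ok(vox, d, min_voxels)) {
        placed <- placed + 1L
        canvas[vox] <- placed
        break
      }
    }
  }
  if (placed == 0L)
    stop("could not place any instance (placed 0 of ", n_objects,
         "); enlarge the volume or reduce radii")
  canvas
}

# geometry-only boundary shell: voxels within `width` (xy chebyshev, plus z
# at width 1) of a voxel carrying a different label (background included)
.boundary_shell <- function(labels, width = 1L) {
  d <- dim(labels)
  shell <- array(FALSE, dim = d)
  offs <- expand.grid(dy = -width:width, dx = -width:width)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  cmp <- function(dz, dy, dx) {
    sz <- seq_len(d[1]); sy <- seq_len(d[2]); sx <- seq_len(d[3])
    vz <- sz + dz; vy <- sy + dy; vx <- sx + dx
    kz <- vz >= 1 & vz <= d[1]; ky <- vy >= 1 & vy <= d[2]; kx <- vx >= 1 & vx <= d[3]
    a <- labels[sz[kz], sy[ky], sx[kx], drop = FALSE]
    b <- labels[vz[kz], vy[ky], vx[kx], drop = FALSE]
    out <- array(FALSE, dim = d)
    out[sz[kz], sy[ky], sx[kx]] <- a != b
    out
  }
  for (i in seq_len(nrow(offs))) shell <- shell | cmp(0L, offs$dy[i], offs$dx[i])
  shell <- shell | cmp(-1L, 0L, 0L) | cmp(1L, 0L, 0L)
  shell
}

#' Render a synthetic EM image from instance labels
#'
#' Voxels within `membrane_width` of an inter-instance or instance/background
#' boundary are drawn around `membrane_mean`; instance interiors around
#' `interior_mean`; far background slightly above `membrane_mean`. Gaussian
#' noise is added and values clipped to \code{[0, 1]}. The rendering depends
#' only on label geometry, never on label ids.
#'
#' @param labels integer label array
#' @param membrane_width boundary shell half-width in voxels
#' @param interior_mean,membrane_mean intensities in \code{[0,1]},
#'   `membrane_mean < interior_mean`
#' @param noise_sigma Gaussian noise standard deviation
#' @return image array in \code{[0,1]}, same shape
#' @export
render_em <- function(labels, membrane_width = 1, interior_mean = 0.75,
                      membrane_mean = 0.15, noise_sigma = 0.06) {
  stopifnot(membrane_mean < interior_mean,
            interior_mean <= 1, membrane_mean >= 0)
  labels <- validate_labels(labels)
  shell <- .boundary_shell(labels, as.integer(membrane_width))
  img <- array(membrane_mean + 0.15, dim = dim(labels))   # far background
  img[labels > 0L] <- interior_mean
  img[shell] <- membrane_mean
  if (noise_sigma > 0)
    img <- img + array(rnorm(length(img), 0, noise_sigma), dim = dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' Write a synthetic paired dataset to disk
#'
#' Generates `n_volumes` paired image/label volumes under one seed and writes
#' them with [write_volume()]; file names are `vol_<i>.<ext>` and
#' `vol_<i>_labels.<ext>`. Regeneration with the same config is byte-identical.
#'
#' @param config list with fields `outdir`, `seed`, and optionally
#'   `n_volumes` (2), `shape` (c(16, 128, 128)), `n_objects` (14),
#'   `min_radius` (3), `max_radius` (8), `format` ("h5" or "tiff"),
#'   `membrane_width`, `interior_mean`, `membrane_mean`, `noise_sigma`
#' @return data.frame of image/label paths, invisibly
#' @export
make_dataset <- function(config) {
  cfg <- modifyList(list(n_volumes = 2L, shape = c(16, 128, 128), n_objects = 70L,
                         min_radius = 5, max_radius = 12, format = "h5",
                         membrane_width = 1, interior_mean = 0.75,
                         membrane_mean = 0.15, noise_sigma = 0.06, seed = 1L),
                    config)
  if (is.null(cfg$outdir)) stop("config$outdir is required")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$outdir)) stop("cannot create output directory ", cfg$outdir)
  ext <- switch(cfg$format, h5 = "h5", tiff = "tiff",
                stop("format must be 'h5' or 'tiff'"))
  set.seed(cfg$seed)
  out <- data.frame(image = character(cfg$n_volumes), labels = character(cfg$n_volumes))
  for (i in seq_len(cfg$n_volumes)) {
    lab <- make_instances(cfg$shape, cfg$n_objects, cfg$min_radius, cfg$max_radius)
    img <- render_em(lab, cfg$membrane_width, cfg$interior_mean,
                     cfg$membrane_mean, cfg$noise_sigma)
    pi_ <- file.path(cfg$outdir, sprintf("vol_%d.%s", i, ext))
    pl <- file.path(cfg$outdir, sprintf("vol_%d_labels.%s", i, ext))
    write_volume(img, pi_, kind = "image")
    write_volume(lab, pl, kind = "labels")
    out$image[i] <- pi_; out$labels[i] <- pl
  }
  invisible(out)
}
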