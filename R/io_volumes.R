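#' @title Volume and label I/O
#' @description Read and write 3D grayscale EM volumes and integer instance
#'   label volumes from/to the two community-standard containers: HDF5 (one
#'   named 3D dataset, default name \code{"main"}) and multipage TIFF stacks
#'   (one page per z-section). On-disk layout is the connectomics convention
#'   \code{(z, y, x)} row-major; in R the same volume is an array with
#'   \code{dim = c(z, y, x)}.
#' @name io_volumes
NULL

.is_h5 <- function(path) grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)
.is_tiff <- function(path) grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)

#' Validate a grayscale volume
#'
#' A valid volume is a 3D numeric array (z, y, x) with all values finite and
#' in \code{[0, 1]}.
#'
#' @param vol candidate array
#' @return `vol`, invisibly, after validation
#' @export
validate_volume <- function(vol) {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop("expected 3 dimensions, got ", if (is.array(vol)) length(dim(vol)) else "a non-array")
  if (!all(is.finite(vol))) stop("volume contains non-finite values")
  r <- range(vol)
  if (r[1] < 0 || r[2] > 1)
    stop("volume values must lie in [0,1]; observed range [",
         signif(r[1], 4), ", ", signif(r[2], 4), "]")
  invisible(vol)
}

#' Validate an instance label volume
#'
#' @param labels candidate array; 3D, non-negative integers, 0 = background
#' @param vol optional paired volume whose shape must match
#' @return `labels` as an integer-mode array, invisibly
#' @export
validate_labels <- function(labels, vol = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("expected 3 dimensions, got ", if (is.array(labels)) length(dim(labels)) else "a non-array")
  if (any(labels < 0)) stop("labels must be non-negative")
  if (any(labels != round(labels))) stop("labels must be integers")
  if (!is.null(vol) && !identical(dim(labels), dim(vol)))
    stop("label shape (", paste(dim(labels), collapse = "x"),
         ") does not match volume shape (", paste(dim(vol), collapse = "x"), ")")
  storage.mode(labels) <- "integer"
  invisible(labels)
}

#' Read a 3D volume or label volume
#'
#' HDF5 input is read from the dataset named `dataset_key`; TIFF input is read
#' as a page-per-section stack. For `kind = "image"`, integer-typed data is
#' rescaled to \code{[0, 1]} by its dtype maximum (e.g. uint8 by 255);
#' floating-point data is taken as already normalized. For `kind = "labels"`
#' values are kept as integers.
#'
#' @param path file path (`.h5`/`.hdf5` or `.tif`/`.tiff`)
#' @param dataset_key HDF5 dataset name (default `"main"`, ignored for TIFF)
#' @param kind `"image"` or `"labels"`
#' @return a 3D array, dim `(z, y, x)`
#' @export
read_volume <- function(path, dataset_key = "main", kind = c("image", "labels")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (.is_h5(path)) {
    raw <- .h5_read3d(path, dataset_key)
    d <- raw$dims                                 # (z, y, x), row-major on disk
    arr <- aperm(array(raw$data, dim = rev(d)), c(3L, 2L, 1L))
    if (kind == "labels") {
      storage.mode(arr) <- "integer"
      return(validate_labels(arr))
    }
    if (isTRUE(raw$is_integer)) arr <- arr / raw$type_max
    validate_volume(arr)
    return(arr)
  }
  if (.is_tiff(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = (kind == "labels"))
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 1L || length(dim(pages[[1]])) != 2L)
      stop("expected 3 dimensions (a multipage 2D stack); got a non-2D page")
    Z <- length(pages); Y <- nrow(pages[[1]]); X <- ncol(pages[[1]])
    arr <- array(0, dim = c(Z, Y, X))
    for (z in seq_len(Z)) arr[z, , ] <- pages[[z]]
    if (kind == "labels") {
      storage.mode(arr) <- "integer"
      return(validate_labels(arr))
    }
    validate_volume(arr)
    return(arr)
  }
  stop("unrecognized container for '", path, "': expected .h5/.hdf5 or .tif/.tiff")
}

#' Write a 3D volume or label volume
#'
#' @param arr 3D array (z, y, x); values in \code{[0,1]} for images, integers
#'   for labels
#' @param path output path; extension selects the container
#' @param dataset_key HDF5 dataset name
#' @param kind `"image"` or `"labels"`. Images are written float64 (HDF5) or
#'   16-bit (TIFF); labels as uint32 (HDF5) or 16-bit pages (TIFF).
#' @param append add the dataset to an existing HDF5 file instead of
#'   truncating it (HDF5 only)
#' @return `path`, invisibly
#' @export
write_volume <- function(arr, path, dataset_key = "main", kind = c("image", "labels"),
                         append = FALSE) {
  kind <- match.arg(kind)
  if (kind == "image") validate_volume(arr) else arr <- validate_labels(arr)
  d <- dim(arr)
  if (.is_h5(path)) {
    flat <- as.numeric(aperm(arr, c(3L, 2L, 1L)))   # to row-major (z,y,x)
    .h5_write3d(path, dataset_key, flat, as.integer(d),
                if (kind == "image") "double" else "uint32",
                !append || !file.exists(path))
    return(invisible(path))
  }
  if (.is_tiff(path)) {
    if (kind == "labels" && max(arr) > 65535L)
      stop("TIFF label container supports ids up to 65535; got ", max(arr))
    pages <- lapply(seq_len(d[1]), function(z) {
      m <- matrix(as.numeric(arr[z, , ]), d[2], d[3])
      if (kind == "labels") m / 65535 else m
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    return(invisible(path))
  }
  stop("unrecognized container for '", path, "': expected .h5/.hdf5 or .tif/.tiff")
}

#' Randomly sample a paired training sub-volume
#'
#' Draws one crop of shape `size` uniformly over all valid (z, y, x) corners;
#' the image and label crops share the same corner. Randomness comes from R's
#' global RNG, so `set.seed()` makes crops reproducible.
#'
#' @param vol 3D image array
#' @param labels optional paired label array
#' @param size crop shape `(z, y, x)`; default `c(6, 96, 96)`
#' @return list with `volume`, `labels` (or NULL) and the 1-based `corner`
#' @export
sample_subvolume <- function(vol, labels = NULL, size = c(6, 96, 96)) {
  d <- dim(vol)
  if (any(size > d)) {
    bad <- c("z", "y", "x")[size > d]
    stop("crop size exceeds volume extent on axis ", paste(bad, collapse = ", "),
         " (size ", paste(size, collapse = "x"), " vs volume ",
         paste(d, collapse = "x"), ")")
  }
  if (!is.null(labels) && !identical(dim(labels), d))
    stop("labels shape does not match volume shape")
  corner <- vapply(1:3, function(a) sample.int(d[a] - size[a] + 1L, 1L), integer(1))
  zi <- corner[1]:(corner[1] + size[1] - 1L)
  yi <- corner[2]:(corner[2] + size[2] - 1L)
  xi <- corner[3]:(corner[3] + size[3] - 1L)
  list(volume = vol[zi, yi, xi, drop = FALSE],
       labels = if (!is.null(labels)) labels[zi, yi, xi, drop = FALSE],
       corner = corner)
}
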