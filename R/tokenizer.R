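#' @title Anisotropic patch tokenization
#' @description A volume is divided into a regular grid of non-overlapping
#'   blocks. The serial-section axis keeps full resolution — the default patch
#'   is \code{1 x 16 x 16} voxels, so a \code{6 x 96 x 96} input yields a
#'   \code{6 x 6 x 6} token grid (216 tokens). Token order is fixed: z-major,
#'   then y, then x (x fastest); every mask plan refers to this order.
#' @name tokenizer
NULL

#' Build a patch grid for a volume shape
#'
#' @param vol_shape volume shape `(z, y, x)`; every axis must be divisible by
#'   the corresponding patch dimension (no padding is ever applied)
#' @param patch_size patch shape `(pz, py, px)`, default `c(1, 16, 16)`
#' @return a `semmae_grid`: patch_size, grid_shape `(Gz, Gy, Gx)`, n_tokens,
#'   patch_dim, vol_shape, and a cached gather-index matrix
#' @export
patch_grid <- function(vol_shape, patch_size = c(1, 16, 16)) {
  vol_shape <- as.integer(vol_shape); patch_size <- as.integer(patch_size)
  stopifnot(length(vol_shape) == 3, length(patch_size) == 3, all(patch_size >= 1))
  rem <- vol_shape %% patch_size
  if (any(rem != 0)) {
    bad <- c("z", "y", "x")[rem != 0]
    stop("volume axis ", paste(bad, collapse = ", "),
         " not divisible by patch size (volume ",
         paste(vol_shape, collapse = "x"), ", patch ",
         paste(patch_size, collapse = "x"), ")")
  }
  g <- vol_shape %/% patch_size
  n_tokens <- as.integer(prod(g))
  patch_dim <- as.integer(prod(patch_size))
  # token t (1-based) has grid coords with x fastest, then y, then z
  tok <- expand.grid(ix = 0:(g[3] - 1L), iy = 0:(g[2] - 1L), iz = 0:(g[1] - 1L))
  off <- expand.grid(dx = 0:(patch_size[3] - 1L), dy = 0:(patch_size[2] - 1L),
                     dz = 0:(patch_size[1] - 1L))
  Z <- vol_shape[1]; Y <- vol_shape[2]
  z0 <- outer(off$dz, tok$iz * patch_size[1], "+")   # patch_dim x n_tokens
  y0 <- outer(off$dy, tok$iy * patch_size[2], "+")
  x0 <- outer(off$dx, tok$ix * patch_size[3], "+")
  idx <- (z0 + 1L) + Z * y0 + Z * Y * x0
  structure(list(patch_size = patch_size, grid_shape = g, n_tokens = n_tokens,
                 patch_dim = patch_dim, vol_shape = vol_shape,
                 idx = matrix(as.integer(idx), patch_dim, n_tokens),
                 coords = as.matrix(tok[, c("iz", "iy", "ix")])),
            class = "semmae_grid")
}

#' Patchify a volume into a token-by-voxel matrix
#'
#' @param vol 3D array
#' @param patch_size patch shape, or a prebuilt [patch_grid()]
#' @return list(`patches` = n_tokens x patch_dim matrix, `grid`)
#' @export
patchify <- function(vol, patch_size = c(1, 16, 16)) {
  grid <- if (inherits(patch_size, "semmae_grid")) patch_size else
    patch_grid(dim(vol), patch_size)
  if (!identical(as.integer(dim(vol)), grid$vol_shape))
    stop("volume shape does not match grid")
  patches <- t(matrix(vol[c(grid$idx)], grid$patch_dim, grid$n_tokens))
  list(patches = patches, grid = grid)
}

#' Reassemble a volume from its patches (exact inverse of [patchify()])
#'
#' @param patches n_tokens x patch_dim matrix
#' @param grid the [patch_grid()] the patches came from
#' @return 3D array with `grid$vol_shape`
#' @export
unpatchify <- function(patches, grid) {
  if (nrow(patches) != grid$n_tokens || ncol(patches) != grid$patch_dim)
    stop("patch matrix is ", nrow(patches), "x", ncol(patches),
         "; grid expects ", grid$n_tokens, "x", grid$patch_dim)
  vol <- array(0, dim = grid$vol_shape)
  vol[c(grid$idx)] <- as.vector(t(patches))
  vol
}

#' Fixed 3D sin-cos positional embeddings
#'
#' One 1D sin-cos embedding per axis over absolute grid indices, concatenated
#' (z, y, x). Each axis receives \code{2 * floor(embed_dim / 6)} dimensions
#' (sin and cos halves); any remaining columns are zero so that embed
#' dimensions not divisible by 6 (e.g. 64 or 1024) are usable. The table is
#' deterministic and non-learned; distinct grid coordinates map to distinct
#' rows.
#'
#' @param grid a [patch_grid()]
#' @param embed_dim embedding width (>= 6)
#' @return n_tokens x embed_dim matrix, rows in token order
#' @export
posembed_3d <- function(grid, embed_dim) {
  embed_dim <- as.integer(embed_dim)
  if (embed_dim < 6L) stop("embed_dim must be at least 6, got ", embed_dim)
  d_axis <- 2L * (embed_dim %/% 6L)          # per-axis width (even)
  half <- d_axis %/% 2L
  omega <- 1 / 10000^((seq_len(half) - 1L) / half)
  emb1d <- function(pos) {
    a <- outer(pos, omega)                   # n x half
    cbind(sin(a), cos(a))
  }
  pe <- cbind(emb1d(grid$coords[, "iz"]), emb1d(grid$coords[, "iy"]),
              emb1d(grid$coords[, "ix"]))
  if (ncol(pe) < embed_dim)
    pe <- cbind(pe, matrix(0, nrow(pe), embed_dim - ncol(pe)))
  pe
}

#' Per-patch target normalization
#'
#' Each patch row is standardized as \code{(p - mean(p)) / (sd_b(p) + eps)}
#' with the biased (population) standard deviation. This is the target
#' representation of the reconstruction loss.
#'
#' @param patches n_tokens x patch_dim matrix
#' @param eps numerical floor, default `1e-6`
#' @return matrix of the same shape
#' @export
normalize_patches <- function(patches, eps = 1e-6) {
  m <- rowMeans(patches)
  v <- rowMeans(patches^2) - m^2
  v[v < 0] <- 0
  (patches - m) / (sqrt(v) + eps)
}
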