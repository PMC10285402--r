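# Vanilla ViT encoder over patch tokens: linear patch embedding + fixed 3D
# sin-cos positions + pre-LN transformer blocks + final layer norm. The
# forward optionally restricts the sequence to a visible subset (MAE
# pre-training) and can record per-block outputs as UNETR skip taps.

#' Encoder/decoder size presets
#'
#' `vit-base` (12 blocks, 768 dims, 12 heads) and `vit-large` (24, 1024, 16)
#' follow the standard ViT sizing; `vit-micro` (2, 64, 4) is a desk-scale
#' preset for tests and CPU experiments.
#'
#' @param name preset name
#' @return list(depth, embed_dim, heads)
#' @export
vit_preset <- function(name) {
  switch(name,
    "vit-base" = list(depth = 12L, embed_dim = 768L, heads = 12L),
    "vit-large" = list(depth = 24L, embed_dim = 1024L, heads = 16L),
    "vit-micro" = list(depth = 2L, embed_dim = 64L, heads = 4L),
    stop("unknown ViT preset '", name, "'"))
}

vit_init <- function(cfg, patch_dim) {
  D <- cfg$embed_dim
  stopifnot(D %% cfg$heads == 0)
  list(pe = list(W = matrix(.tnorm(patch_dim * D), patch_dim, D), b = rep(0, D)),
       blocks = lapply(seq_len(cfg$depth), function(i)
         .block_init(D, cfg$heads, cfg$mlp_ratio %||% 4)),
       lnf = list(g = rep(1, D), b = rep(0, D)))
}

# patches: n_tokens x patch_dim (full set); pos added before any subsetting
vit_fwd <- function(params, patches, pos, cfg, visible = NULL, train = FALSE,
                    dropout = 0, droppath = 0) {
  x <- .addb(patches %*% params$pe$W, params$pe$b) + pos
  if (!is.null(visible)) x <- x[visible, , drop = FALSE]
  x0 <- x
  caches <- vector("list", cfg$depth)
  taps <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    r <- .block_fwd(x, params$blocks[[i]], cfg$heads, dropout, droppath, train)
    x <- r$out
    caches[[i]] <- r$cache
    taps[[i]] <- x
  }
  lnf <- .ln_fwd(x, params$lnf$g, params$lnf$b)
  list(out = lnf$out, taps = taps,
       cache = list(blocks = caches, lnf = lnf, x0 = x0,
                    patches = patches, visible = visible))
}

# dout: gradient on final output; d_taps: optional list of gradients flowing
# into each block's output (UNETR skips)
vit_bwd <- function(params, dout, cache, cfg, d_taps = NULL) {
  lb <- .ln_bwd(dout, cache$lnf)
  grads <- list(lnf = list(g = lb$dg, b = lb$db))
  dx <- lb$dx
  gb <- vector("list", cfg$depth)
  for (i in rev(seq_len(cfg$depth))) {
    if (!is.null(d_taps) && !is.null(d_taps[[i]])) dx <- dx + d_taps[[i]]
    r <- .block_bwd(dx, params$blocks[[i]], cache$blocks[[i]])
    dx <- r$dx
    gb[[i]] <- r$grads
  }
  grads$blocks <- gb
  pr <- cache$patches
  if (!is.null(cache$visible)) pr <- pr[cache$visible, , drop = FALSE]
  grads$pe <- list(W = t(pr) %*% dx, b = colSums(dx))
  grads[c("pe", "blocks", "lnf")]
}
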