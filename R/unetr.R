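#' @title UNETR-style segmentation with a (pre-trainable) ViT backbone
#' @description The MAE encoder, stripped of its decoder, becomes the
#'   backbone of a U-shaped segmentation network: skip taps from intermediate
#'   transformer blocks (blocks 3/6/9 plus the final output for depth 12,
#'   proportionally scaled otherwise) feed a convolutional decoder that
#'   upsamples 2x per stage in y and x only — the anisotropic 1x16x16 patch
#'   embedding keeps z at full resolution throughout, so all decoder
#'   convolutions are 1x3x3. Heads: 3 affinity channels, or 3 BCD channels
#'   (binary, contour, distance), all squashed to `[0, 1]` by a logistic at
#'   prediction time.
#' @name unetr_seg
NULL

# ---- conv primitives on (z, h, w, C) arrays --------------------------------

.shift_yx4 <- function(X, dy, dx) {
  d <- dim(X)
  out <- array(0, dim = d)
  ys <- max(1L, 1L + dy):min(d[2], d[2] + dy)    # dest rows with valid src
  xs <- max(1L, 1L + dx):min(d[3], d[3] + dx)
  if (!length(ys) || !length(xs)) return(out)
  out[, ys - dy, xs - dx, ] <- X[, ys, xs, , drop = FALSE]
  out
}

.conv3x3_fwd <- function(X, W, b) {
  d <- dim(X); Cout <- dim(W)[4]
  Y <- .conv3x3_fwd_cpp(as.numeric(X), as.integer(d), as.numeric(W),
                        as.numeric(b), Cout)
  array(Y, dim = c(d[1:3], Cout))
}

.conv3x3_bwd <- function(dY, X, W) {
  d <- dim(X); Cout <- dim(W)[4]
  r <- .conv3x3_bwd_cpp(as.numeric(dY), as.numeric(X), as.integer(d),
                        as.numeric(W), Cout)
  list(dX = array(r$dX, dim = d), dW = array(r$dW, dim = dim(W)), db = r$db)
}

.up2_fwd <- function(X) {
  d <- dim(X)
  X[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), , drop = FALSE]
}

.up2_bwd <- function(dY) {
  d <- dim(dY)
  h <- d[2] %/% 2L; w <- d[3] %/% 2L
  o <- dY[, seq(1L, d[2], 2L), seq(1L, d[3], 2L), , drop = FALSE] +
    dY[, seq(2L, d[2], 2L), seq(1L, d[3], 2L), , drop = FALSE] +
    dY[, seq(1L, d[2], 2L), seq(2L, d[3], 2L), , drop = FALSE] +
    dY[, seq(2L, d[2], 2L), seq(2L, d[3], 2L), , drop = FALSE]
  o
}

.upn <- function(X, f) {                        # nearest upsample by factor f
  d <- dim(X)
  X[, rep(seq_len(d[2]), each = f), rep(seq_len(d[3]), each = f), , drop = FALSE]
}
.upn_bwd <- function(dY, f) {
  d <- dim(dY)
  h <- d[2] %/% f; w <- d[3] %/% f
  out <- array(0, dim = c(d[1], h, w, d[4]))
  for (a in seq_len(f)) for (b in seq_len(f))
    out <- out + dY[, seq(a, d[2], f), seq(b, d[3], f), , drop = FALSE]
  out
}

.relu_fwd <- function(x) { x[x < 0] <- 0; x }

# token matrix (n_tokens x D) <-> grid feature array (Gz, Gy, Gx, D)
.tok_to_grid <- function(mat, g) {
  a <- array(mat, dim = c(g[3], g[2], g[1], ncol(mat)))
  aperm(a, c(3L, 2L, 1L, 4L))
}
.grid_to_tok <- function(A) {
  d <- dim(A)
  a <- aperm(A, c(3L, 2L, 1L, 4L))
  dim(a) <- c(d[1] * d[2] * d[3], d[4])
  a
}

# ---- model -----------------------------------------------------------------

#' Build a UNETR-style segmentation model
#'
#' With `init = "scratch"` all weights are fresh; with a pre-training
#' checkpoint, every backbone parameter is copied from the MAE encoder while
#' the convolutional decoder and head are freshly initialized.
#'
#' @param cfg list: `encoder` (preset name or list(depth, embed_dim, heads)),
#'   `patch_size` (pz must be 1), `input_size`, optional `dec_channels`
#'   (4 stage widths, coarse to fine, default `c(32, 16, 16, 8)`)
#' @param target_kind `"affinity"` or `"bcd"` (both use 3 output channels)
#' @param init `"scratch"` or a `semmae_checkpoint` from [mae_pretrain()]
#' @return a `semmae_seg_model`
#' @export
build_seg_model <- function(cfg, target_kind = c("affinity", "bcd"),
                            init = "scratch") {
  target_kind <- match.arg(target_kind)
  if (is.character(cfg$encoder)) cfg$encoder <- vit_preset(cfg$encoder)
  cfg$patch_size <- cfg$patch_size %||% c(1, 16, 16)
  cfg$input_size <- cfg$input_size %||% c(6, 96, 96)
  if (cfg$patch_size[1] != 1)
    stop("the segmentation decoder requires pz = 1 (z stays at full resolution)")
  if (cfg$patch_size[2] != cfg$patch_size[3] ||
      log2(cfg$patch_size[2]) %% 1 != 0)
    stop("xy patch size must be square and a power of two")
  n_steps <- as.integer(log2(cfg$patch_size[2]))
  ch <- cfg$dec_channels %||% c(32, 16, 16, 8)
  if (length(ch) < n_steps) ch <- rep_len(ch, n_steps)
  ch <- ch[seq_len(n_steps)]
  skip_ch <- pmax(4L, ch %/% 2L)
  D <- cfg$encoder$embed_dim
  grid <- patch_grid(cfg$input_size, cfg$patch_size)

  if (inherits(init, "semmae_checkpoint")) {
    e1 <- init$cfg$encoder; e2 <- cfg$encoder
    bad <- names(which(!mapply(identical, lapply(e1[c("depth","embed_dim","heads")], as.integer),
                               lapply(e2[c("depth","embed_dim","heads")], as.integer))))
    if (length(bad))
      stop("checkpoint incompatible with requested backbone: ",
           paste(bad, collapse = ", "), " differ")
    backbone <- init$params$enc
  } else if (identical(init, "scratch")) {
    backbone <- vit_init(cfg$encoder, grid$patch_dim)
  } else stop("init must be \"scratch\" or a semmae_checkpoint")

  c0 <- ch[1]
  conv_in <- c(c0, ch[-n_steps]) + skip_ch
  params <- list(
    backbone = backbone,
    bottleneck = list(W = matrix(.tnorm(D * c0, 0.05), D, c0), b = rep(0, c0)),
    skips = lapply(seq_len(n_steps - 1L), function(k)
      list(W = matrix(.tnorm(D * skip_ch[k], 0.05), D, skip_ch[k]),
           b = rep(0, skip_ch[k]))),
    stem = list(W = array(.tnorm(9 * skip_ch[n_steps], 0.1),
                          dim = c(3, 3, 1, skip_ch[n_steps])),
                b = rep(0, skip_ch[n_steps])),
    convs = lapply(seq_len(n_steps), function(k)
      list(W = array(.tnorm(9 * conv_in[k] * ch[k],
                            sqrt(2 / (9 * conv_in[k]))),
                     dim = c(3, 3, conv_in[k], ch[k])),
           b = rep(0, ch[k]))),
    head = list(W = matrix(.tnorm(ch[n_steps] * 3, 0.05), ch[n_steps], 3),
                b = rep(0, 3)))

  structure(list(params = params, cfg = cfg, grid = grid,
                 pos = posembed_3d(grid, D), n_steps = n_steps,
                 taps_at = pmax(1L, as.integer(round(
                   cfg$encoder$depth * seq_len(3) / 4))),
                 target_kind = target_kind,
                 pretrained = inherits(init, "semmae_checkpoint")),
            class = "semmae_seg_model")
}

# forward; returns logits (z, y, x, 3) and, if `train`, all caches
.seg_fwd <- function(model, vol, train = FALSE, dropout = 0, droppath = 0) {
  cfg <- model$cfg; g <- model$grid
  pr <- patchify(vol, g)
  enc <- vit_fwd(model$params$backbone, pr$patches, model$pos, cfg$encoder,
                 train = train, dropout = dropout, droppath = droppath)
  P <- model$params
  gs <- g$grid_shape
  x <- .tok_to_grid(.addb(enc$out %*% P$bottleneck$W, P$bottleneck$b), gs)
  n_steps <- model$n_steps
  caches <- list(enc = enc, patches = pr$patches, stages = vector("list", n_steps),
                 bottleneck_in = enc$out)
  vol4 <- array(vol, dim = c(dim(vol), 1L))
  for (k in seq_len(n_steps)) {
    xu <- .up2_fwd(x)
    if (k < n_steps) {
      tapmat <- enc$taps[[model$taps_at[n_steps - k]]]
      skip_small <- .tok_to_grid(.addb(tapmat %*% P$skips[[k]]$W, P$skips[[k]]$b), gs)
      skip <- .upn(skip_small, 2L^k)
    } else {
      stem_pre <- .conv3x3_fwd(vol4, P$stem$W, P$stem$b)
      skip <- .relu_fwd(stem_pre)
      caches$stem_pre <- stem_pre
    }
    cin <- array(c(xu, skip), dim = c(dim(xu)[1:3], dim(xu)[4] + dim(skip)[4]))
    pre <- .conv3x3_fwd(cin, P$convs[[k]]$W, P$convs[[k]]$b)
    x <- .relu_fwd(pre)
    caches$stages[[k]] <- list(cin = cin, pre = pre, xu_ch = dim(xu)[4])
  }
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  logits <- array(.addb(xm %*% P$head$W, P$head$b), dim = c(d[1:3], 3L))
  caches$final <- x
  list(logits = logits, cache = caches)
}

.seg_bwd <- function(model, dlogits, cache) {
  P <- model$params
  n_steps <- model$n_steps
  g <- model$grid; gs <- g$grid_shape
  d <- dim(cache$final)
  n <- d[1] * d[2] * d[3]
  dlm <- dlogits; dim(dlm) <- c(n, 3L)
  fm <- cache$final; dim(fm) <- c(n, d[4])
  ghead <- list(W = t(fm) %*% dlm, b = colSums(dlm))
  dx <- array(dlm %*% t(P$head$W), dim = d)

  gconvs <- vector("list", n_steps)
  gskips <- vector("list", n_steps - 1L)
  gstem <- NULL
  d_taps <- vector("list", model$cfg$encoder$depth)
  denc_out <- NULL
  for (k in rev(seq_len(n_steps))) {
    st <- cache$stages[[k]]
    dpre <- dx * (st$pre > 0)
    cb <- .conv3x3_bwd(dpre, st$cin, P$convs[[k]]$W)
    gconvs[[k]] <- list(W = cb$dW, b = cb$db)
    nc <- st$xu_ch
    dxu <- cb$dX[, , , seq_len(nc), drop = FALSE]
    dskip <- cb$dX[, , , -seq_len(nc), drop = FALSE]
    if (k < n_steps) {
      dsmall <- .upn_bwd(dskip, 2L^k)
      dtapmat <- .grid_to_tok(dsmall)
      tapmat <- cache$enc$taps[[model$taps_at[n_steps - k]]]
      gskips[[k]] <- list(W = t(tapmat) %*% dtapmat, b = colSums(dtapmat))
      ti <- model$taps_at[n_steps - k]
      add <- dtapmat %*% t(P$skips[[k]]$W)
      d_taps[[ti]] <- if (is.null(d_taps[[ti]])) add else d_taps[[ti]] + add
    } else {
      dstem_out <- dskip * (cache$stem_pre > 0)
      vol4 <- array(unpatchify(cache$patches, g), dim = c(g$vol_shape, 1L))
      sb <- .conv3x3_bwd(dstem_out, vol4, P$stem$W)
      gstem <- list(W = sb$dW, b = sb$db)
    }
    dx <- .up2_bwd(dxu)
  }
  dbott <- .grid_to_tok(dx)
  gbott <- list(W = t(cache$bottleneck_in) %*% dbott, b = colSums(dbott))
  denc_out <- dbott %*% t(P$bottleneck$W)
  gback <- vit_bwd(P$backbone, denc_out, cache$enc$cache, model$cfg$encoder,
                   d_taps = d_taps)
  list(backbone = gback, bottleneck = gbott,
       skips = gskips[seq_len(n_steps - 1L)], stem = gstem,
       convs = gconvs, head = ghead)
}

# ---- losses ----------------------------------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))

# mean BCE with logits; returns loss and d/dlogit. `balanced` reweights the
# two classes to equal total mass (the convention of the affinity-map
# segmentation literature, which weights rare boundary/background edges up)
.bce_logits <- function(logit, target, balanced = FALSE) {
  s <- .sigmoid(logit)
  eps <- 1e-12
  if (balanced) {
    p1 <- mean(target)
    if (p1 <= 0 || p1 >= 1) return(.bce_logits(logit, target, FALSE))
    w <- ifelse(target > 0.5, 0.5 / p1, 0.5 / (1 - p1))
    loss <- -mean(w * (target * log(s + eps) + (1 - target) * log(1 - s + eps)))
    return(list(loss = loss, dlogit = w * (s - target) / length(logit)))
  }
  loss <- -mean(target * log(s + eps) + (1 - target) * log(1 - s + eps))
  list(loss = loss, dlogit = (s - target) / length(logit))
}

# segmentation loss on 3-channel logits: affinity = class-balanced BCE on all
# channels; BCD = BCE(binary) + BCE(contour) + MSE(sigmoid(distance)), equal
# weights
seg_loss <- function(logits, target, target_kind) {
  if (target_kind == "affinity") {
    r <- .bce_logits(logits, target, balanced = TRUE)
    return(list(loss = r$loss, dlogits = r$dlogit))
  }
  dl <- array(0, dim = dim(logits))
  b <- .bce_logits(logits[, , , 1], target$binary)
  cn <- .bce_logits(logits[, , , 2], target$contour)
  s <- .sigmoid(logits[, , , 3])
  mse <- mean((s - target$distance)^2)
  dl[, , , 1] <- b$dlogit
  dl[, , , 2] <- cn$dlogit
  dl[, , , 3] <- 2 * (s - target$distance) * s * (1 - s) / length(s)
  list(loss = b$loss + cn$loss + mse, dlogits = dl)
}

# ---- training --------------------------------------------------------------

.downsample_yx <- function(vol, labels = NULL) {
  d <- dim(vol)
  h <- d[2] %/% 2L; w <- d[3] %/% 2L
  v <- (vol[, seq(1L, 2L * h, 2L), seq(1L, 2L * w, 2L), drop = FALSE] +
        vol[, seq(2L, 2L * h, 2L), seq(1L, 2L * w, 2L), drop = FALSE] +
        vol[, seq(1L, 2L * h, 2L), seq(2L, 2L * w, 2L), drop = FALSE] +
        vol[, seq(2L, 2L * h, 2L), seq(2L, 2L * w, 2L), drop = FALSE]) / 4
  l <- if (!is.null(labels))
    labels[, seq(1L, 2L * h, 2L), seq(1L, 2L * w, 2L), drop = FALSE]
  list(volume = v, labels = l)
}

# default augmentations: xy flips, xy transpose, z flip, brightness/contrast
# jitter, per-section intensity perturbation; all toggleable
.augment_pair <- function(vol, lab, aug) {
  if (isTRUE(aug$flip_y) && runif(1) < 0.5) {
    vol <- vol[, dim(vol)[2]:1, , drop = FALSE]
    lab <- lab[, dim(lab)[2]:1, , drop = FALSE]
  }
  if (isTRUE(aug$flip_x) && runif(1) < 0.5) {
    vol <- vol[, , dim(vol)[3]:1, drop = FALSE]
    lab <- lab[, , dim(lab)[3]:1, drop = FALSE]
  }
  if (isTRUE(aug$transpose_xy) && dim(vol)[2] == dim(vol)[3] && runif(1) < 0.5) {
    vol <- aperm(vol, c(1, 3, 2)); lab <- aperm(lab, c(1, 3, 2))
  }
  if (isTRUE(aug$flip_z) && runif(1) < 0.5) {
    vol <- vol[dim(vol)[1]:1, , , drop = FALSE]
    lab <- lab[dim(lab)[1]:1, , , drop = FALSE]
  }
  if (isTRUE(aug$intensity)) {
    a <- runif(1, 0.9, 1.1); b <- runif(1, -0.05, 0.05)
    vol <- vol * a + b
    if (isTRUE(aug$per_section)) vol <- vol + runif(dim(vol)[1], -0.03, 0.03)
    vol[vol < 0] <- 0; vol[vol > 1] <- 1
  }
  list(volume = vol, labels = lab)
}

#' Fine-tune a segmentation model
#'
#' Training targets (affinity or BCD) are generated on the fly from the label
#' crop. Reference-scale defaults follow the standard fine-tuning recipe
#' (AdamW, base lr 1e-4, weight decay 0.05, 5k/200k warmup/total, dropout
#' 0.3, drop-path 0.1, batch 8); the MitoEM-style variant uses SGD (lr 4e-3,
#' weight decay 1e-4, 10k/300k, scales `[1, 0.5, 0.5]`). Desk-scale runs
#' shrink `total` and `batch_size`.
#'
#' @param model a [build_seg_model()]
#' @param dataset list of `list(volume =, labels =)` pairs
#' @param seed integer seed
#' @param total,warmup,batch_size iteration settings
#' @param optimizer `"adamw"` or `"sgd"`
#' @param base_lr,weight_decay,beta1,beta2,momentum optimizer settings
#' @param dropout,droppath regularization rates
#' @param scales per-axis scale factors applied to volumes before cropping;
#'   `c(1, 0.5, 0.5)` halves y and x only
#' @param augment list of toggles (flip_y, flip_x, transpose_xy, flip_z,
#'   intensity, per_section), all on by default
#' @param log_every loss recording stride
#' @return a `semmae_checkpoint` of kind `"seg"`
#' @export
finetune <- function(model, dataset, seed = 1L, total = 200000L,
                     warmup = 5000L, batch_size = 8L, optimizer = "adamw",
                     base_lr = 1e-4, weight_decay = 0.05, beta1 = 0.9,
                     beta2 = 0.95, momentum = 0.9, dropout = 0.3,
                     droppath = 0.1, scales = c(1, 1, 1),
                     augment = list(flip_y = TRUE, flip_x = TRUE,
                                    transpose_xy = TRUE, flip_z = TRUE,
                                    intensity = TRUE, per_section = TRUE),
                     log_every = 10L) {
  stopifnot(length(dataset) >= 1)
  for (p in dataset) if (is.null(p$labels)) stop("fine-tuning requires labels")
  set.seed(seed)
  if (!all(scales %in% c(1, 0.5)) || scales[1] != 1)
    stop("supported scales are 1 (keep) or 0.5 (halve) for y/x; z must be 1")
  if (any(scales[2:3] == 0.5))
    dataset <- lapply(dataset, function(p) .downsample_yx(p$volume, p$labels))
  state <- if (optimizer == "adamw") adamw_init(model$params) else sgd_init(model$params)
  loss_history <- numeric(0)
  input_size <- model$cfg$input_size
  for (it in seq_len(total)) {
    lr <- lr_schedule(it, base_lr, warmup, total)
    gacc <- NULL; lacc <- 0
    for (b in seq_len(batch_size)) {
      p <- dataset[[sample.int(length(dataset), 1L)]]
      crop <- sample_subvolume(p$volume, p$labels, input_size)
      ag <- .augment_pair(crop$volume, crop$labels, augment)
      target <- if (model$target_kind == "affinity")
        affinity_from_labels(ag$labels) else bcd_from_labels(ag$labels)
      fw <- .seg_fwd(model, ag$volume, train = TRUE,
                     dropout = dropout, droppath = droppath)
      ls <- seg_loss(fw$logits, target, model$target_kind)
      gr <- .seg_bwd(model, ls$dlogits, fw$cache)
      gacc <- if (is.null(gacc)) gr else .nn_add(gacc, gr)
      lacc <- lacc + ls$loss
    }
    loss <- lacc / batch_size
    if (!is.finite(loss)) stop("NaN loss at iteration ", it)
    g <- .nn_scale(gacc, 1 / batch_size)
    upd <- if (optimizer == "adamw")
      adamw_step(model$params, g, state, lr, beta1, beta2, weight_decay = weight_decay)
    else sgd_step(model$params, g, state, lr, momentum, weight_decay)
    model$params <- upd$params
    state <- upd$state
    if (it %% log_every == 0L || it == 1L) loss_history <- c(loss_history, loss)
  }
  structure(list(kind = "seg", params = model$params, cfg = model$cfg,
                 target_kind = model$target_kind, seed = seed,
                 iteration = total, loss_history = loss_history),
            class = "semmae_checkpoint")
}

#' Restore a runnable segmentation model from a checkpoint
#' @param ckpt a `semmae_checkpoint` of kind `"seg"`
#' @return a `semmae_seg_model`
#' @export
seg_from_checkpoint <- function(ckpt) {
  stopifnot(inherits(ckpt, "semmae_checkpoint"), ckpt$kind == "seg")
  m <- build_seg_model(ckpt$cfg, ckpt$target_kind, init = "scratch")
  m$params <- ckpt$params
  m
}

# ---- inference -------------------------------------------------------------

.reflect_pad <- function(vol, size) {
  d <- dim(vol)
  for (a in 1:3) {
    need <- size[a] - d[a]
    if (need > 0) {
      ref <- min(need, d[a] - 1L)
      if (ref < need) stop("volume too small to reflect-pad on axis ", a)
      pick <- c(seq_len(d[a]), d[a] - seq_len(need))
      vol <- switch(a, vol[pick, , , drop = FALSE], vol[, pick, , drop = FALSE],
                    vol[, , pick, drop = FALSE])
      d <- dim(vol)
    }
  }
  vol
}

#' Sliding-window prediction
#'
#' Tiles of the model's input size are run across the volume with the given
#' overlap and blended by averaging; outputs are squashed to `[0, 1]` with a
#' logistic. Volumes smaller than one tile are reflect-padded and cropped
#' back.
#'
#' @param model a `semmae_seg_model`
#' @param vol 3D image array
#' @param overlap fractional tile overlap in `[0, 1)`
#' @return 4D probability array `(z, y, x, 3)`; for BCD models the channels
#'   are binary, contour, distance
#' @export
seg_predict <- function(model, vol, overlap = 0.25) {
  tile <- model$cfg$input_size
  d0 <- dim(vol)
  vol <- .reflect_pad(vol, tile)
  d <- dim(vol)
  starts <- function(n, t) {
    if (n == t) return(1L)
    step <- max(1L, as.integer(round(t * (1 - overlap))))
    unique(c(seq(1L, n - t + 1L, step), n - t + 1L))
  }
  acc <- array(0, dim = c(d, 3L))
  wt <- array(0, dim = d)
  for (z0 in starts(d[1], tile[1]))
    for (y0 in starts(d[2], tile[2]))
      for (x0 in starts(d[3], tile[3])) {
        zi <- z0:(z0 + tile[1] - 1L); yi <- y0:(y0 + tile[2] - 1L)
        xi <- x0:(x0 + tile[3] - 1L)
        lg <- .seg_fwd(model, vol[zi, yi, xi, drop = FALSE])$logits
        acc[zi, yi, xi, ] <- acc[zi, yi, xi, , drop = FALSE] + .sigmoid(lg)
        wt[zi, yi, xi] <- wt[zi, yi, xi] + 1
      }
  for (c in 1:3) acc[, , , c] <- acc[, , , c] / wt
  acc[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), , drop = FALSE]
}

#' Split a 4D BCD prediction into its named channels
#' @param pred 4D array from [seg_predict()] on a BCD model
#' @return list(binary, contour, distance)
#' @export
pred_to_bcd <- function(pred) {
  list(binary = pred[, , , 1], contour = pred[, , , 2], distance = pred[, , , 3])
}
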