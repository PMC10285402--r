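#' @title 3D masked autoencoder
#' @description The encoder (a vanilla ViT) processes only the visible tokens
#'   of a mask plan — at 90% masking of 216 tokens that is 21 rows, the
#'   mechanism that cuts encoder cost to roughly a tenth. The decoder is a
#'   second, smaller ViT that receives the encoded set plus one learned mask
#'   token broadcast into every masked slot, restored to canonical grid order,
#'   with its own fixed 3D sin-cos positional table, and predicts full patch
#'   voxels through a linear head. The loss is mean-squared error against
#'   per-patch-normalized targets, averaged over masked patches only.
#' @name mae
NULL

#' Assemble an MAE configuration
#'
#' @param encoder list(depth, embed_dim, heads) or a [vit_preset()] name
#' @param decoder list(depth, embed_dim, heads); default depth 4, dim 512,
#'   8 heads (the decoder is deliberately smaller than the encoder)
#' @param patch_size patch shape, default `c(1, 16, 16)`
#' @param input_size training crop shape, default `c(6, 96, 96)`
#' @param mask list(strategy, ratio, keep_columns, keep_sections)
#' @return config list used by [mae_init()] and [mae_pretrain()]
#' @export
mae_config <- function(encoder = "vit-base",
                       decoder = list(depth = 4L, embed_dim = 512L, heads = 8L),
                       patch_size = c(1, 16, 16),
                       input_size = c(6, 96, 96),
                       mask = list(strategy = "random", ratio = 0.9)) {
  if (is.character(encoder)) encoder <- vit_preset(encoder)
  stopifnot(decoder$embed_dim <= encoder$embed_dim,
            encoder$embed_dim %% encoder$heads == 0,
            decoder$embed_dim %% decoder$heads == 0)
  list(encoder = encoder, decoder = decoder, patch_size = patch_size,
       input_size = input_size, mask = mask)
}

#' Initialize MAE parameters for a given grid
#'
#' @param cfg a [mae_config()]
#' @param grid a [patch_grid()] matching `cfg$input_size` / `cfg$patch_size`
#' @param mask_token_noise sd of the optional small-noise initialization of
#'   the learned mask token (0 = zero-init)
#' @return model list: `params` (encoder+decoder), fixed positional tables,
#'   `grid`, `cfg`
#' @export
mae_init <- function(cfg, grid = NULL, mask_token_noise = 0) {
  if (is.null(grid)) grid <- patch_grid(cfg$input_size, cfg$patch_size)
  De <- cfg$encoder$embed_dim; Dd <- cfg$decoder$embed_dim
  params <- list(
    enc = vit_init(cfg$encoder, grid$patch_dim),
    dec = list(proj = list(W = matrix(.tnorm(De * Dd), De, Dd), b = rep(0, Dd)),
               mask_token = if (mask_token_noise > 0)
                 rnorm(Dd, 0, mask_token_noise) else rep(0, Dd),
               blocks = lapply(seq_len(cfg$decoder$depth), function(i)
                 .block_init(Dd, cfg$decoder$heads)),
               lnf = list(g = rep(1, Dd), b = rep(0, Dd)),
               head = list(W = matrix(.tnorm(Dd * grid$patch_dim), Dd, grid$patch_dim),
                           b = rep(0, grid$patch_dim))))
  list(params = params, cfg = cfg, grid = grid,
       enc_pos = posembed_3d(grid, De), dec_pos = posembed_3d(grid, Dd))
}

#' Encode the visible tokens of a masked volume
#'
#' @param model a [mae_init()] model
#' @param patches full n_tokens x patch_dim matrix
#' @param plan a mask plan over the same token count
#' @return latent matrix with one row per visible token
#' @export
mae_encode <- function(model, patches, plan) {
  if (plan$n_tokens != model$grid$n_tokens)
    stop("mask plan covers ", plan$n_tokens, " tokens; grid has ",
         model$grid$n_tokens)
  vit_fwd(model$params$enc, patches, model$enc_pos, model$cfg$encoder,
          visible = plan$visible_idx)$out
}

#' Decode latents back to full patch predictions
#'
#' Visible slots receive the projected latents, masked slots the learned mask
#' token; decoder positions are added and the full canonical-order sequence
#' runs through the decoder and linear head.
#'
#' @param model a [mae_init()] model
#' @param latents output of [mae_encode()] under the same plan
#' @param plan the mask plan used for encoding
#' @return n_tokens x patch_dim prediction matrix
#' @export
mae_decode <- function(model, latents, plan) {
  if (nrow(latents) != length(plan$visible_idx))
    stop("latents have ", nrow(latents), " rows; plan has ",
         length(plan$visible_idx), " visible tokens")
  p <- model$params$dec
  n <- plan$n_tokens
  z <- matrix(p$mask_token, n, length(p$mask_token), byrow = TRUE)
  z[plan$visible_idx, ] <- .addb(latents %*% p$proj$W, p$proj$b)
  z <- z + model$dec_pos
  for (i in seq_along(p$blocks))
    z <- .block_fwd(z, p$blocks[[i]], model$cfg$decoder$heads)$out
  z <- .ln_fwd(z, p$lnf$g, p$lnf$b)$out
  .addb(z %*% p$head$W, p$head$b)
}

#' Masked reconstruction loss
#'
#' Mean over masked patches (and their voxels) of the squared error between
#' predictions and per-patch-normalized targets; visible rows contribute
#' exactly zero.
#'
#' @param pred n_tokens x patch_dim predictions
#' @param target_norm per-patch-normalized targets (see [normalize_patches()])
#' @param plan the mask plan
#' @return scalar loss
#' @export
recon_loss <- function(pred, target_norm, plan) {
  if (length(plan$masked_idx) == 0L) stop("mask plan has no masked tokens")
  d <- pred[plan$masked_idx, , drop = FALSE] -
    target_norm[plan$masked_idx, , drop = FALSE]
  mean(d^2)
}

# full differentiable pass: forward, loss, gradients for all parameters
.mae_step <- function(model, patches, plan, train = TRUE) {
  cfg <- model$cfg
  enc <- vit_fwd(model$params$enc, patches, model$enc_pos, cfg$encoder,
                 visible = plan$visible_idx, train = train)
  p <- model$params$dec
  n <- plan$n_tokens
  lat_proj <- .addb(enc$out %*% p$proj$W, p$proj$b)
  z <- matrix(p$mask_token, n, length(p$mask_token), byrow = TRUE)
  z[plan$visible_idx, ] <- lat_proj
  z <- z + model$dec_pos
  dcaches <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    r <- .block_fwd(z, p$blocks[[i]], cfg$decoder$heads, train = train)
    z <- r$out; dcaches[[i]] <- r$cache
  }
  lnf <- .ln_fwd(z, p$lnf$g, p$lnf$b)
  pred <- .addb(lnf$out %*% p$head$W, p$head$b)

  target <- normalize_patches(patches)
  m <- plan$masked_idx
  loss <- mean((pred[m, , drop = FALSE] - target[m, , drop = FALSE])^2)

  # backward
  dpred <- matrix(0, n, ncol(pred))
  dpred[m, ] <- 2 * (pred[m, , drop = FALSE] - target[m, , drop = FALSE]) /
    (length(m) * ncol(pred))
  ghead <- list(W = t(lnf$out) %*% dpred, b = colSums(dpred))
  dz <- dpred %*% t(p$head$W)
  lb <- .ln_bwd(dz, lnf)
  glnf <- list(g = lb$dg, b = lb$db)
  dz <- lb$dx
  gblocks <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    r <- .block_bwd(dz, p$blocks[[i]], dcaches[[i]])
    dz <- r$dx; gblocks[[i]] <- r$grads
  }
  dmask <- colSums(dz[plan$masked_idx, , drop = FALSE])
  dlat_proj <- dz[plan$visible_idx, , drop = FALSE]
  gproj <- list(W = t(enc$out) %*% dlat_proj, b = colSums(dlat_proj))
  dlat <- dlat_proj %*% t(p$proj$W)
  genc <- vit_bwd(model$params$enc, dlat, enc$cache, cfg$encoder)
  list(loss = loss, pred = pred,
       grads = list(enc = genc,
                    dec = list(proj = gproj, mask_token = dmask,
                               blocks = gblocks, lnf = glnf, head = ghead)))
}

#' Pre-train a masked autoencoder
#'
#' AdamW with linear warmup + cosine decay. Reference-scale defaults follow
#' the standard recipe (base lr 1e-4, betas 0.9/0.95, weight decay 0.005,
#' warmup 50k of 400k iterations, batch 128, 6x96x96 inputs); desk-scale runs
#' override `total`, `batch_size` and the encoder preset. No dropout is used
#' during pre-training.
#'
#' @param volumes list of 3D image arrays to crop training samples from
#' @param cfg a [mae_config()]
#' @param seed integer seed driving cropping, masking and initialization
#' @param total,warmup iteration counts
#' @param batch_size crops per iteration
#' @param base_lr,weight_decay,beta1,beta2 AdamW settings
#' @param log_every record smoothed loss every this many iterations
#' @param resume a previous `semmae_checkpoint` to continue from; parameters,
#'   optimizer state and the RNG stream are restored, so an interrupted
#'   (`stop_at`) and an uninterrupted run produce identical results (single
#'   worker). `total` must match the original run — the schedule depends on it.
#' @param stop_at checkpoint and return after this iteration (interrupting a
#'   `total`-iteration schedule); NULL runs to `total`
#' @return a `semmae_checkpoint`: parameters, config, seed, iteration count,
#'   loss history, optimizer and RNG state
#' @export
mae_pretrain <- function(volumes, cfg, seed = 1L, total = 400000L,
                         warmup = 50000L, batch_size = 128L, base_lr = 1e-4,
                         weight_decay = 0.005, beta1 = 0.9, beta2 = 0.95,
                         log_every = 10L, resume = NULL, stop_at = NULL) {
  stopifnot(length(volumes) >= 1)
  if (is.null(resume)) {
    set.seed(seed)
    grid <- patch_grid(cfg$input_size, cfg$patch_size)
    model <- mae_init(cfg, grid)
    state <- adamw_init(model$params)
    loss_history <- numeric(0)
    it0 <- 0L
  } else {
    stopifnot(inherits(resume, "semmae_checkpoint"), resume$kind == "mae")
    cfg <- resume$cfg
    seed <- resume$seed
    model <- mae_from_checkpoint(resume)
    state <- resume$opt_state
    loss_history <- resume$loss_history
    it0 <- resume$iteration
    if (it0 >= total) stop("checkpoint already at iteration ", it0)
    assign(".Random.seed", resume$rng_state, envir = globalenv())
  }
  grid <- model$grid
  last <- min(total, stop_at %||% total)
  for (it in (it0 + 1L):last) {
    lr <- lr_schedule(it, base_lr, warmup, total)
    gacc <- NULL; lacc <- 0
    for (b in seq_len(batch_size)) {
      v <- volumes[[sample.int(length(volumes), 1L)]]
      crop <- sample_subvolume(v, size = cfg$input_size)$volume
      patches <- patchify(crop, grid)$patches
      plan <- plan_mask(grid, cfg$mask$strategy, cfg$mask$ratio %||% 0.9,
                        cfg$mask$keep_columns, cfg$mask$keep_sections)
      st <- .mae_step(model, patches, plan)
      gacc <- if (is.null(gacc)) st$grads else .nn_add(gacc, st$grads)
      lacc <- lacc + st$loss
    }
    loss <- lacc / batch_size
    if (!is.finite(loss)) stop("NaN loss at iteration ", it)
    upd <- adamw_step(model$params, .nn_scale(gacc, 1 / batch_size), state,
                      lr, beta1, beta2, weight_decay = weight_decay)
    model$params <- upd$params
    state <- upd$state
    if (it %% log_every == 0L || it == 1L) loss_history <- c(loss_history, loss)
  }
  structure(list(kind = "mae", params = model$params, cfg = cfg, seed = seed,
                 iteration = last, loss_history = loss_history,
                 opt_state = state, rng_state = get(".Random.seed", globalenv())),
            class = "semmae_checkpoint")
}

#' Rebuild a runnable MAE model from a checkpoint
#' @param ckpt a `semmae_checkpoint` of kind `"mae"`
#' @return model list as from [mae_init()]
#' @export
mae_from_checkpoint <- function(ckpt) {
  stopifnot(inherits(ckpt, "semmae_checkpoint"), ckpt$kind == "mae")
  model <- mae_init(ckpt$cfg)
  model$params <- ckpt$params
  model
}

#' Save / load checkpoints
#'
#' Checkpoints are single-file archives holding the weights, the full config
#' and the seed.
#'
#' @param ckpt a `semmae_checkpoint`
#' @param path file path
#' @return `path` / the checkpoint
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "semmae_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "semmae_checkpoint"))
  ckpt
}

#' Zero out the masked voxels of a volume (visualization)
#'
#' For figure-style inspection of what the encoder sees: masked patches get
#' voxel value 0.
#'
#' @param vol 3D array
#' @param grid a [patch_grid()]
#' @param plan a mask plan
#' @return the volume with masked patches zeroed
#' @export
mask_volume_zeroed <- function(vol, grid, plan) {
  p <- patchify(vol, grid)$patches
  p[plan$masked_idx, ] <- 0
  unpatchify(p, grid)
}
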