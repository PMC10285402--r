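# a small model/config used throughout: 2x8x8 volume, 1x4x4 patches -> 8 tokens
tiny_mae <- function(seed = 1) {
  set.seed(seed)
  cfg <- mae_config(encoder = list(depth = 2L, embed_dim = 24L, heads = 4L),
                    decoder = list(depth = 1L, embed_dim = 12L, heads = 2L),
                    patch_size = c(1, 4, 4), input_size = c(2, 8, 8),
                    mask = list(strategy = "random", ratio = 0.5))
  mae_init(cfg)
}

test_that("the encoder sees exactly the visible tokens", {
  set.seed(81)
  cfg <- mae_config(encoder = list(depth = 1L, embed_dim = 24L, heads = 4L),
                    decoder = list(depth = 1L, embed_dim = 12L, heads = 2L))
  model <- mae_init(cfg)                       # 6x96x96, 216 tokens
  vol <- array(runif(6 * 96 * 96), c(6, 96, 96))
  patches <- patchify(vol, model$grid)$patches
  plan <- plan_random(216, 0.90)
  lat <- mae_encode(model, patches, plan)
  expect_identical(nrow(lat), 21L)             # 90% of 216 masked

  plan0 <- plan_random(216, 0)
  expect_identical(nrow(mae_encode(model, patches, plan0)), 216L)

  # scrambling masked tokens' contents leaves the latents unchanged
  scrambled <- patches
  scrambled[plan$masked_idx, ] <- matrix(runif(length(plan$masked_idx) * 256),
                                         length(plan$masked_idx))
  expect_identical(lat, mae_encode(model, scrambled, plan))

  bad <- plan_random(10, 0.5)
  expect_error(mae_encode(model, patches, bad), "plan covers")
})

test_that("the decoder returns the full token set deterministically", {
  model <- tiny_mae()
  vol <- array(runif(2 * 8 * 8), c(2, 8, 8))
  patches <- patchify(vol, model$grid)$patches
  for (r in c(0.25, 0.5, 0.875)) {
    set.seed(82); plan <- plan_random(8, r)
    lat <- mae_encode(model, patches, plan)
    pred <- mae_decode(model, lat, plan)
    expect_identical(dim(pred), c(8L, 16L))    # n_tokens x patch_dim always
    expect_identical(pred, mae_decode(model, lat, plan))
  }
})

test_that("reconstruction loss is masked-mean squared error with closed forms", {
  model <- tiny_mae()
  set.seed(83)
  plan <- plan_random(8, 0.5)
  target <- matrix(rnorm(8 * 16), 8, 16)
  # pred equals target on masked rows -> 0, whatever the visible rows hold
  pred <- matrix(rnorm(8 * 16), 8, 16)
  pred[plan$masked_idx, ] <- target[plan$masked_idx, ]
  expect_identical(recon_loss(pred, target, plan), 0)
  # constant unit error on masked rows -> 1
  pred[plan$masked_idx, ] <- target[plan$masked_idx, ] + 1
  expect_equal(recon_loss(pred, target, plan), 1)
  # an all-visible plan has no masked rows to average over
  expect_error(recon_loss(pred, target, plan_random(8, 0)), "no masked")
})

test_that("the loss is local to masked rows (finite-difference oracle)", {
  model <- tiny_mae()
  vol <- array(runif(2 * 8 * 8), c(2, 8, 8))
  patches <- patchify(vol, model$grid)$patches
  set.seed(84); plan <- plan_random(8, 0.5)
  target <- normalize_patches(patches)
  pred <- matrix(rnorm(8 * 16), 8, 16)
  base <- recon_loss(pred, target, plan)
  # perturbing any visible-row prediction (or target) leaves the loss fixed
  for (v in plan$visible_idx) {
    p2 <- pred; p2[v, ] <- p2[v, ] + rnorm(16)
    expect_identical(recon_loss(p2, target, plan), base)
    t2 <- target; t2[v, ] <- t2[v, ] + rnorm(16)
    expect_identical(recon_loss(pred, t2, plan), base)
  }
  # analytic gradient of the full model step is zero on visible rows and
  # matches central differences on masked rows
  st <- semmae:::.mae_step(model, patches, plan)
  n_vis <- length(plan$visible_idx)
  eps <- 1e-6
  dpred_fd <- function(r, c) {
    f <- function(delta) {
      m2 <- model
      # perturb through the head bias so only row structure matters? no —
      # perturb pred directly via recon_loss
      pr <- st$pred; pr[r, c] <- pr[r, c] + delta
      recon_loss(pr, normalize_patches(patches), plan)
    }
    (f(eps) - f(-eps)) / (2 * eps)
  }
  for (r in plan$visible_idx) expect_identical(dpred_fd(r, 3), 0)
  for (r in plan$masked_idx[1:2]) {
    expect_gt(abs(dpred_fd(r, 3)), 0)
  }
})

test_that("parameter gradients agree with central differences", {
  model <- tiny_mae(seed = 42)
  vol <- array(runif(2 * 8 * 8), c(2, 8, 8))
  patches <- patchify(vol, model$grid)$patches
  set.seed(85); plan <- plan_random(8, 0.5)
  st <- semmae:::.mae_step(model, patches, plan)
  fd <- function(get, set, eps = 1e-6) {
    p0 <- get()
    set(p0 + eps); lp <- semmae:::.mae_step(model, patches, plan)$loss
    set(p0 - eps); lm <- semmae:::.mae_step(model, patches, plan)$loss
    set(p0)
    (lp - lm) / (2 * eps)
  }
  cases <- list(
    list(function() model$params$enc$pe$W[3, 5],
         function(v) model$params$enc$pe$W[3, 5] <<- v,
         function(g) g$enc$pe$W[3, 5]),
    list(function() model$params$enc$blocks[[2]]$mlp$W1[1, 3],
         function(v) model$params$enc$blocks[[2]]$mlp$W1[1, 3] <<- v,
         function(g) g$enc$blocks[[2]]$mlp$W1[1, 3]),
    list(function() model$params$dec$mask_token[5],
         function(v) model$params$dec$mask_token[5] <<- v,
         function(g) g$dec$mask_token[5]),
    list(function() model$params$dec$head$W[3, 7],
         function(v) model$params$dec$head$W[3, 7] <<- v,
         function(g) g$dec$head$W[3, 7]))
  for (cs in cases) {
    num <- fd(cs[[1]], cs[[2]])
    ana <- cs[[3]](st$grads)
    expect_lt(abs(num - ana), 1e-6 + 1e-3 * abs(num))
  }
})

test_that("short pre-training reduces the reconstruction loss", {
  set.seed(86)
  lab <- make_instances(c(12, 48, 48), n_objects = 10, min_radius = 5,
                        max_radius = 8)
  vol <- render_em(lab)
  cfg <- mae_config(encoder = "vit-micro",
                    decoder = list(depth = 2L, embed_dim = 32L, heads = 4L),
                    input_size = c(6, 32, 32),
                    mask = list(strategy = "random", ratio = 0.75))
  ck <- mae_pretrain(list(vol), cfg, seed = 2, total = 120L, warmup = 20L,
                     batch_size = 2L, base_lr = 3e-3)
  lh <- ck$loss_history
  expect_lt(mean(tail(lh, 4)), mean(head(lh, 4)))
  expect_false(any(!is.finite(lh)))
})

test_that("pre-training runs at extreme masking and resumes exactly", {
  set.seed(87)
  vol <- array(runif(8 * 32 * 32), c(8, 32, 32))
  cfg <- mae_config(encoder = "vit-micro",
                    decoder = list(depth = 1L, embed_dim = 32L, heads = 4L),
                    input_size = c(6, 32, 32),
                    mask = list(strategy = "random", ratio = 0.95))
  # 95% masking leaves fewer visible tokens than heads; still legal.
  # interrupt a 10-iteration schedule after 5 iterations...
  ck5 <- mae_pretrain(list(vol), cfg, seed = 3, total = 10L, warmup = 2L,
                      batch_size = 1L, base_lr = 1e-3, log_every = 1L,
                      stop_at = 5L)
  expect_identical(ck5$iteration, 5L)

  # ...then resuming reproduces the uninterrupted run exactly
  ck10a <- mae_pretrain(list(vol), cfg, seed = 3, total = 10L, warmup = 2L,
                        batch_size = 1L, base_lr = 1e-3, log_every = 1L,
                        resume = ck5)
  ck10b <- mae_pretrain(list(vol), cfg, seed = 3, total = 10L, warmup = 2L,
                        batch_size = 1L, base_lr = 1e-3, log_every = 1L)
  expect_equal(ck10a$loss_history, ck10b$loss_history, tolerance = 1e-12)
  expect_equal(ck10a$params, ck10b$params, tolerance = 1e-12)
})

test_that("checkpoints round-trip through disk", {
  model <- tiny_mae()
  ck <- structure(list(kind = "mae", params = model$params, cfg = model$cfg,
                       seed = 1L, iteration = 0L, loss_history = numeric(0)),
                  class = "semmae_checkpoint")
  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(ck, f)
  back <- load_checkpoint(f)
  expect_equal(back$params, ck$params, tolerance = 0)
  expect_identical(back$cfg, ck$cfg)
})

test_that("masked-slot visualization zeroes masked voxels only", {
  set.seed(88)
  vol <- array(runif(2 * 8 * 8), c(2, 8, 8))
  g <- patch_grid(dim(vol), c(1, 4, 4))
  plan <- plan_random(g$n_tokens, 0.5)
  z <- mask_volume_zeroed(vol, g, plan)
  p <- patchify(z, g)$patches
  expect_true(all(p[plan$masked_idx, ] == 0))
  expect_identical(p[plan$visible_idx, ],
                   patchify(vol, g)$patches[plan$visible_idx, ])
})
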