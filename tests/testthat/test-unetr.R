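micro_cfg <- function(input = c(6, 32, 32)) {
  list(encoder = vit_preset("vit-micro"), patch_size = c(1, 16, 16),
       input_size = input, dec_channels = c(16, 16, 8, 8))
}

test_that("checkpoint initialization transfers the backbone exactly", {
  set.seed(121)
  mcfg <- mae_config(encoder = "vit-micro",
                     decoder = list(depth = 1L, embed_dim = 32L, heads = 4L),
                     input_size = c(6, 32, 32))
  vol <- array(runif(8 * 32 * 32), c(8, 32, 32))
  ck <- mae_pretrain(list(vol), mcfg, seed = 4, total = 3L, warmup = 1L,
                     batch_size = 1L, base_lr = 1e-3)
  m <- build_seg_model(micro_cfg(), "affinity", init = ck)
  expect_identical(semmae:::.nn_max_abs(
    semmae:::.nn_add(m$params$backbone, semmae:::.nn_scale(ck$params$enc, -1))), 0)
  expect_true(m$pretrained)

  # incompatible checkpoints are rejected with the differing fields listed
  bad <- micro_cfg(); bad$encoder$embed_dim <- 128L; bad$encoder$heads <- 8L
  expect_error(build_seg_model(bad, "affinity", init = ck),
               "embed_dim, heads")
})

test_that("heads expose three channels for both target kinds", {
  set.seed(122)
  for (kind in c("affinity", "bcd")) {
    m <- build_seg_model(micro_cfg(), kind)
    expect_identical(ncol(m$params$head$W), 3L)
    expect_identical(m$target_kind, kind)
  }
})

test_that("scratch builds are seed-deterministic", {
  set.seed(7); a <- build_seg_model(micro_cfg(), "affinity")
  set.seed(7); b <- build_seg_model(micro_cfg(), "affinity")
  set.seed(8); c_ <- build_seg_model(micro_cfg(), "affinity")
  expect_identical(a$params, b$params)
  expect_gt(semmae:::.nn_max_abs(
    semmae:::.nn_add(a$params, semmae:::.nn_scale(c_$params, -1))), 0)
})

test_that("segmentation losses hit their floor on perfect predictions", {
  seg_loss <- semmae:::seg_loss
  # 2-voxel toy: logits at +-30 saturate the logistic
  target <- array(c(1, 0, 1, 0, 1, 0), dim = c(1, 1, 2, 3))
  logits <- (2 * target - 1) * 30
  r <- seg_loss(logits, target, "affinity")
  expect_lt(r$loss, 1e-8)
  expect_true(all(abs(r$dlogits) < 1e-8))

  bt <- list(binary = target[, , , 1], contour = target[, , , 2],
             distance = target[, , , 3])
  # distance channel trains on the squashed output, so a saturated logit
  # reproduces a {0,1}-valued distance exactly
  rb <- seg_loss(logits, bt, "bcd")
  expect_lt(rb$loss, 1e-8)
})

test_that("short fine-tuning reduces the loss on synthetic data", {
  set.seed(123)
  lab <- make_instances(c(12, 48, 48), n_objects = 14, min_radius = 5,
                        max_radius = 8)
  vol <- render_em(lab)
  ds <- list(list(volume = vol, labels = lab))
  for (kind in c("affinity", "bcd")) {
    set.seed(124)
    m <- build_seg_model(micro_cfg(), kind)
    ck <- finetune(m, ds, seed = 5, total = 60L, warmup = 10L,
                   batch_size = 1L, base_lr = 3e-3, dropout = 0, droppath = 0,
                   log_every = 5L)
    lh <- ck$loss_history
    expect_lt(mean(tail(lh, 3)), mean(head(lh, 3)))
    expect_identical(ck$target_kind, kind)
  }
})

test_that("y/x-only downscaling halves those axes and keeps z", {
  set.seed(125)
  vol <- array(runif(4 * 8 * 8), c(4, 8, 8))
  lab <- array(sample(0:2, 4 * 8 * 8, TRUE), c(4, 8, 8))
  ds <- semmae:::.downsample_yx(vol, lab)
  expect_identical(dim(ds$volume), c(4L, 4L, 4L))
  expect_identical(dim(ds$labels), c(4L, 4L, 4L))
  expect_equal(ds$volume[1, 1, 1], mean(vol[1, 1:2, 1:2]))
  expect_identical(ds$labels[2, 2, 2], lab[2, 3, 3])

  # scales c(1, .5, .5) routes training volumes through that downscaling
  lab2 <- make_instances(c(8, 64, 64), n_objects = 8, min_radius = 5,
                         max_radius = 8)
  vol2 <- render_em(lab2)
  m <- build_seg_model(micro_cfg(), "affinity")
  ck <- finetune(m, list(list(volume = vol2, labels = lab2)), seed = 6,
                 total = 2L, warmup = 1L, batch_size = 1L, base_lr = 1e-3,
                 scales = c(1, 0.5, 0.5), dropout = 0, droppath = 0)
  expect_identical(ck$iteration, 2L)
  expect_error(finetune(m, list(list(volume = vol2, labels = lab2)),
                        scales = c(0.5, 1, 1), total = 1L), "z must be 1")
  expect_error(finetune(m, list(list(volume = vol2, labels = NULL)),
                        total = 1L), "requires labels")
})

test_that("sliding-window prediction preserves shape and probability ranges", {
  set.seed(126)
  m <- build_seg_model(micro_cfg(), "affinity")
  # volume equal to one tile: single forward pass
  v1 <- array(runif(6 * 32 * 32), c(6, 32, 32))
  p1 <- seg_predict(m, v1)
  expect_identical(dim(p1), c(6L, 32L, 32L, 3L))
  expect_true(all(p1 >= 0 & p1 <= 1))

  # larger volume, different overlaps: same shape, finite values
  v2 <- array(runif(10 * 48 * 48), c(10, 48, 48))
  p2a <- seg_predict(m, v2, overlap = 0)
  p2b <- seg_predict(m, v2, overlap = 0.5)
  expect_identical(dim(p2a), dim(p2b))
  expect_true(all(is.finite(p2a)) && all(is.finite(p2b)))

  # constant input: near-constant output away from tile seams (positional
  # embeddings keep it from being exactly constant)
  vc <- array(0.5, c(6, 64, 64))
  pc <- seg_predict(m, vc, overlap = 0)
  inner <- pc[, 9:24, 9:24, 1]
  expect_lt(stats::var(as.vector(inner)), 1e-3)

  # smaller than one tile: reflect-pad then crop back
  vs <- array(runif(4 * 20 * 20), c(4, 20, 20))
  ps <- seg_predict(m, vs)
  expect_identical(dim(ps), c(4L, 20L, 20L, 3L))

  bc <- pred_to_bcd(ps)
  expect_identical(dim(bc$binary), dim(vs))
})
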