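#' @title Desk-scale pretrain-vs-scratch experiment
#' @description A CPU-sized analogue of the reference pretrain-versus-scratch
#'   comparison: on synthetic serial-section volumes with the `vit-micro`
#'   preset, a short MAE pre-train followed by a short affinity fine-tune is
#'   compared against fine-tuning from scratch at the same iteration budget,
#'   over several seed pairs. Both arms share the same fine-tuning seed and
#'   the same freshly initialized decoder; only the backbone initialization
#'   differs.
#' @name experiments
NULL

#' Run the pretrain-vs-scratch transfer experiment
#'
#' For each seed pair: generate a training and a test volume (16 x 64 x 64,
#' 10 instances), pre-train a `vit-micro` MAE (random masking at ratio 0.9)
#' on the unlabeled training volume, then fine-tune two identical affinity
#' segmentation models — one from the pre-trained backbone, one from scratch
#' — with the same seed and budget. Predictions on the held-out volume are
#' decoded with [zwatershed()] and scored by adapted Rand error.
#'
#' Desk-scale settings (documented in the methods vignette): volumes
#' 16 x 64 x 64 with 35 instances, input crops 6 x 32 x 32 (a 6 x 2 x 2 token
#' grid), base learning rate 3e-3, batch 4 (pre-train) / 1 (fine-tune),
#' dropout and drop-path off; decoding at seed/growth thresholds 0.8 / 0.2
#' with agglomeration at 0.9, suited to the soft calibration of briefly
#' trained models.
#'
#' @param base_seed integer; all per-pair seeds derive from it
#' @param n_pairs number of seed pairs
#' @param pretrain_iters,finetune_iters iteration budgets
#' @param verbose print per-pair results
#' @return data.frame with one row per pair: `seed`, `arand_pretrained`,
#'   `arand_scratch`
#' @export
transfer_experiment <- function(base_seed = 1L, n_pairs = 4L,
                                pretrain_iters = 300L, finetune_iters = 300L,
                                verbose = FALSE) {
  input_size <- c(6, 32, 32)
  mcfg <- mae_config(encoder = "vit-micro",
                     decoder = list(depth = 2L, embed_dim = 32L, heads = 4L),
                     input_size = input_size,
                     mask = list(strategy = "random", ratio = 0.9))
  scfg <- list(encoder = vit_preset("vit-micro"), patch_size = c(1, 16, 16),
               input_size = input_size, dec_channels = c(16, 16, 8, 8))
  out <- data.frame(seed = integer(0), arand_pretrained = numeric(0),
                    arand_scratch = numeric(0))
  for (i in seq_len(n_pairs)) {
    s <- as.integer(base_seed + i)
    set.seed(s)
    lab_tr <- make_instances(c(16, 64, 64), n_objects = 35, min_radius = 6,
                             max_radius = 10)
    vol_tr <- render_em(lab_tr)
    lab_te <- make_instances(c(16, 64, 64), n_objects = 35, min_radius = 6,
                             max_radius = 10)
    vol_te <- render_em(lab_te)
    ds <- list(list(volume = vol_tr, labels = lab_tr))

    ck <- mae_pretrain(list(vol_tr), mcfg, seed = s + 1000L,
                       total = pretrain_iters, warmup = 30L, batch_size = 4L,
                       base_lr = 3e-3)
    arand <- numeric(2)
    for (arm in 1:2) {
      set.seed(s + 2000L)              # identical decoder/head init in both arms
      model <- build_seg_model(scfg, "affinity",
                               init = if (arm == 1) ck else "scratch")
      ft <- finetune(model, ds, seed = s + 3000L, total = finetune_iters,
                     warmup = 30L, batch_size = 1L, base_lr = 3e-3,
                     dropout = 0, droppath = 0)
      m <- seg_from_checkpoint(ft)
      pred <- seg_predict(m, vol_te)
      seg <- zwatershed(pred, t_high = 0.8, t_low = 0.2,
                        merge_threshold = 0.9)
      arand[arm] <- adapted_rand_error(seg, lab_te)
    }
    if (verbose)
      message(sprintf("pair %d: pretrained %.4f  scratch %.4f", i,
                      arand[1], arand[2]))
    out <- rbind(out, data.frame(seed = s, arand_pretrained = arand[1],
                                 arand_scratch = arand[2]))
  }
  out
}
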