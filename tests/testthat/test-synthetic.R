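test_that("generated instances are connected, consecutive, z-spanning, separated", {
  set.seed(21)
  lab <- make_instances(c(12, 48, 48), n_objects = 8, min_radius = 4,
                        max_radius = 7)
  k <- max(lab)
  expect_gte(k, 1)
  expect_identical(sort(unique(as.vector(lab[lab > 0]))), 1:k)
  for (i in seq_len(k)) {
    m <- lab == i
    expect_identical(n_components_igraph(m), 1L)          # igraph oracle
    expect_gte(length(unique(which(m, arr.ind = TRUE)[, 1])), 2)
  }
  # 1-voxel background separation: no 6-neighbouring voxels carry
  # different positive labels
  d <- dim(lab)
  expect_false(any(lab[2:d[1], , ] > 0 & lab[1:(d[1]-1), , ] > 0 &
                   lab[2:d[1], , ] != lab[1:(d[1]-1), , ]))
  expect_false(any(lab[, 2:d[2], ] > 0 & lab[, 1:(d[2]-1), ] > 0 &
                   lab[, 2:d[2], ] != lab[, 1:(d[2]-1), ]))
  expect_false(any(lab[, , 2:d[3]] > 0 & lab[, , 1:(d[3]-1)] > 0 &
                   lab[, , 2:d[3]] != lab[, , 1:(d[3]-1)]))
})

test_that("a single requested object yields exactly one label", {
  set.seed(22)
  lab <- make_instances(c(10, 40, 40), n_objects = 1, min_radius = 5,
                        max_radius = 8)
  expect_identical(max(lab), 1L)
})

test_that("impossible packing reports the placed count", {
  set.seed(23)
  expect_error(make_instances(c(6, 10, 10), n_objects = 1, min_radius = 9,
                              max_radius = 9), "placed 0")
})

test_that("default parameters give a non-degenerate foreground fraction", {
  set.seed(24)
  lab <- make_instances(c(16, 128, 128))
  fg <- mean(lab > 0)
  expect_gte(fg, 0.2)
  expect_lte(fg, 0.9)
})

test_that("rendering is darker on membranes, noise-free case is flat", {
  set.seed(25)
  lab <- make_instances(c(12, 48, 48), n_objects = 6, min_radius = 5,
                        max_radius = 8)
  img <- render_em(lab, noise_sigma = 0)
  shell <- semmae:::.boundary_shell(lab, 1L)
  expect_lt(mean(img[shell]), mean(img[lab > 0 & !shell]))   # masked means
  # single instance, no noise: constant interior away from its boundary
  one <- array(1L, c(4, 8, 8))
  flat <- render_em(one, noise_sigma = 0)
  expect_true(all(flat == flat[1]))
  expect_error(render_em(one, interior_mean = 0.2, membrane_mean = 0.5))
})

test_that("rendering depends on geometry only, not label ids", {
  set.seed(26)
  lab <- make_instances(c(8, 32, 32), n_objects = 4, min_radius = 4,
                        max_radius = 6)
  perm <- sample(max(lab))
  relab <- lab
  relab[lab > 0] <- perm[lab[lab > 0]]
  set.seed(99); a <- render_em(lab)
  set.seed(99); b <- render_em(relab)
  expect_identical(a, b)
})

test_that("rendering with a fixed seed is bit-identical", {
  lab <- array(0L, c(4, 16, 16)); lab[2:3, 4:10, 4:10] <- 1L
  set.seed(5); a <- render_em(lab)
  set.seed(5); b <- render_em(lab)
  expect_identical(a, b)
})

test_that("datasets on disk regenerate byte-identically and read back", {
  for (fmt in c("h5", "tiff")) {
    d1 <- file.path(tempdir(), paste0("ds1_", fmt))
    d2 <- file.path(tempdir(), paste0("ds2_", fmt))
    cfg <- list(outdir = d1, n_volumes = 2L, shape = c(8, 32, 32),
                n_objects = 4L, min_radius = 4, max_radius = 6, seed = 31L,
                format = fmt)
    files <- make_dataset(cfg)
    expect_identical(nrow(files), 2L)
    expect_true(all(file.exists(files$image), file.exists(files$labels)))
    cfg$outdir <- d2
    files2 <- make_dataset(cfg)
    for (i in 1:2) {
      expect_identical(readBin(files$image[i], "raw", 1e6),
                       readBin(files2$image[i], "raw", 1e6), label = fmt)
      expect_identical(readBin(files$labels[i], "raw", 1e6),
                       readBin(files2$labels[i], "raw", 1e6), label = fmt)
    }
    vol <- read_volume(files$image[1], kind = "image")
    lab <- read_volume(files$labels[1], kind = "labels")
    expect_identical(dim(vol), c(8L, 32L, 32L))
    expect_identical(dim(lab), dim(vol))
  }
})
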