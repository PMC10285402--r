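test_that("affinity maps match the brute-force neighbour comparison", {
  set.seed(91)
  for (i in 1:5) {
    lab <- random_labels(c(4, 4, 4), k = 3)
    expect_equal(affinity_from_labels(lab), affinity_bruteforce(lab),
                 ignore_attr = TRUE)
  }
})

test_that("affinity boundary conventions hold", {
  # single instance filling the volume: every interior affinity is 1,
  # volume-border entries are 0
  lab <- array(1L, c(3, 4, 4))
  aff <- affinity_from_labels(lab)
  expect_true(all(aff[2:3, , , 1] == 1)); expect_true(all(aff[1, , , 1] == 0))
  expect_true(all(aff[, 2:4, , 2] == 1)); expect_true(all(aff[, 1, , 2] == 0))

  # two instances touching across a y-interface: y-channel is 0 there
  lab2 <- array(0L, c(2, 4, 4))
  lab2[, 1:2, ] <- 1L; lab2[, 3:4, ] <- 2L
  aff2 <- affinity_from_labels(lab2)
  expect_true(all(aff2[, 3, , 2] == 0))
  expect_true(all(aff2[, 2, , 2] == 1))
})

test_that("affinity graph components recover the foreground partition", {
  set.seed(92)
  lab <- make_instances(c(10, 40, 40), n_objects = 6, min_radius = 4,
                        max_radius = 7)
  rec <- labels_from_affinity(affinity_from_labels(lab))
  expect_identical(adapted_rand_error(rec, lab), 0)
  vi <- variation_of_information(rec, lab)
  expect_identical(vi$voi_split + vi$voi_merge, 0)
})

test_that("BCD targets honour their contracts on degenerate inputs", {
  empty <- array(0L, c(2, 4, 4))
  b <- bcd_from_labels(empty)
  expect_true(all(b$binary == 0) && all(b$contour == 0) && all(b$distance == 0))

  # single 1-voxel instance: binary, contour and distance all 1 there
  one <- array(0L, c(3, 5, 5)); one[2, 3, 3] <- 1L
  b1 <- bcd_from_labels(one)
  expect_identical(b1$binary[2, 3, 3], 1)
  expect_identical(b1$contour[2, 3, 3], 1)
  expect_identical(b1$distance[2, 3, 3], 1)
  expect_true(all(b1$distance[one == 0L] == 0))
})

test_that("BCD geometry matches a hand-computed fixture", {
  # a 5x5 square column spanning every section: out-of-volume is never a
  # boundary, so the distance field is driven by the xy geometry alone
  lab <- array(0L, c(3, 9, 9))
  lab[1:3, 3:7, 3:7] <- 1L
  b <- bcd_from_labels(lab, contour_width = 1)
  sq <- lab[2, , ] == 1L
  # contour: the outer ring of the square (xy-neighbour of background)
  ring <- sq & !(row(sq) %in% 4:6 & col(sq) %in% 4:6)
  expect_identical(b$contour[2, , ] == 1, ring)
  # hand EDT: ring voxels are 1 voxel from background, the centre 3; the
  # per-instance normalization puts the centre at 1 and the ring at 1/3
  expect_equal(max(b$distance), 1)
  expect_identical(which.max(b$distance[2, , ]), which(row(sq) == 5 & col(sq) == 5))
  expect_equal(b$distance[2, 3, 3], 1 / 3, tolerance = 1e-9)
  expect_equal(b$distance[1, 5, 5], 1, tolerance = 1e-9)

  # distance is strictly positive exactly on the foreground
  expect_true(all((b$distance > 0) == (b$binary == 1)))
})

test_that("targets are invariant to bijective relabeling", {
  set.seed(93)
  lab <- make_instances(c(8, 32, 32), n_objects = 5, min_radius = 4,
                        max_radius = 6)
  perm <- sample(max(lab))
  relab <- lab; relab[lab > 0] <- perm[lab[lab > 0]]
  expect_identical(affinity_from_labels(lab), affinity_from_labels(relab))
  expect_identical(bcd_from_labels(lab), bcd_from_labels(relab))
})
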