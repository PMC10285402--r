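test_that("identical partitions score perfectly", {
  set.seed(101)
  lab <- random_labels(c(3, 4, 4), k = 4)
  lab[1, 1, 1] <- 1L                             # ensure some foreground
  vi <- variation_of_information(lab, lab)
  expect_identical(vi$voi_split, 0)
  expect_identical(vi$voi_merge, 0)
  expect_identical(adapted_rand_error(lab, lab), 0)
  ap <- average_precision(lab, lab)
  expect_identical(unname(ap), c(1, 1))
})

test_that("a 2/2 split of one segment gives voi_split = ln 2", {
  T_ <- array(1L, c(1, 1, 4))
  S <- array(c(1L, 1L, 2L, 2L), c(1, 1, 4))
  vi <- variation_of_information(S, T_)
  expect_equal(vi$voi_split, log(2), tolerance = 1e-12)
  expect_identical(vi$voi_merge, 0)
})

test_that("swapping arguments swaps the split and merge components", {
  set.seed(102)
  for (i in 1:5) {
    S <- random_labels(c(2, 3, 3), 3) + 1L       # all-foreground so masks agree
    T_ <- random_labels(c(2, 3, 3), 3) + 1L
    a <- variation_of_information(S, T_)
    b <- variation_of_information(T_, S)
    expect_equal(a$voi_split, b$voi_merge, tolerance = 1e-12)
    expect_equal(a$voi_merge, b$voi_split, tolerance = 1e-12)
  }
})

test_that("VI and adapted Rand agree with brute force on small volumes", {
  set.seed(103)
  for (i in 1:20) {
    d <- c(sample(2:3, 1), sample(2:4, 1), sample(2:4, 1))   # <= 36 voxels
    S <- random_labels(d, sample(2:4, 1))
    T_ <- random_labels(d, sample(2:4, 1))
    if (!any(T_ != 0)) T_[1] <- 1L
    expect_equal(adapted_rand_error(S, T_), arand_bruteforce(S, T_),
                 tolerance = 1e-12)
    vi <- variation_of_information(S, T_)
    oracle <- voi_bruteforce(S, T_)
    expect_equal(vi$voi_split, oracle["split"], tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(vi$voi_merge, oracle["merge"], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("a single segment covering two equal truth segments matches brute force", {
  T_ <- array(rep(1:2, each = 25), c(1, 5, 10))
  S <- array(1L, c(1, 5, 10))
  expect_equal(adapted_rand_error(S, T_), arand_bruteforce(S, T_),
               tolerance = 1e-12)
})

test_that("adapted Rand error stays within [0, 1] across random pairs", {
  set.seed(104)
  for (i in 1:1000) {
    S <- random_labels(c(2, 3, 3), 4)
    T_ <- random_labels(c(2, 3, 3), 4)
    if (!any(T_ != 0)) T_[1] <- 1L
    v <- adapted_rand_error(S, T_)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("metrics are invariant to bijective relabeling of either input", {
  set.seed(105)
  S <- random_labels(c(3, 4, 4), 4)
  T_ <- random_labels(c(3, 4, 4), 4)
  T_[1, 1, 1] <- 1L
  permS <- sample(10); permT <- sample(10)
  S2 <- S; S2[S > 0] <- permS[S[S > 0]] + 10L
  T2 <- T_; T2[T_ > 0] <- permT[T_[T_ > 0]] + 10L
  expect_equal(variation_of_information(S, T_), variation_of_information(S2, T2),
               tolerance = 1e-12)
  expect_equal(adapted_rand_error(S, T_), adapted_rand_error(S2, T2),
               tolerance = 1e-12)
  expect_equal(average_precision(S, T_), average_precision(S2, T2))
})

test_that("average precision follows the matched-instance PR curve", {
  # two equal truth instances, one missed entirely -> AP 0.5
  T_ <- array(0L, c(1, 4, 8))
  T_[1, , 1:3] <- 1L; T_[1, , 6:8] <- 2L
  S <- array(0L, c(1, 4, 8)); S[1, , 1:3] <- 7L
  ap <- average_precision(S, T_)
  expect_equal(unname(ap["ap50"]), 0.5)

  # a prediction shrunk to IoU 0.6 counts at 0.5 but not at 0.75
  T2 <- array(0L, c(1, 1, 10)); T2[1, 1, ] <- 1L
  S2 <- array(0L, c(1, 1, 10)); S2[1, 1, 1:6] <- 1L   # IoU 6/10
  ap2 <- average_precision(S2, T2)
  expect_equal(unname(ap2["ap50"]), 1)
  expect_equal(unname(ap2["ap75"]), 0)

  # no truth instances is undefined and reported as such
  expect_error(average_precision(S2, array(0L, c(1, 1, 10))), "undefined")
})

test_that("shape mismatches and empty masks are rejected", {
  expect_error(variation_of_information(array(1L, c(2, 2, 2)),
                                        array(1L, c(2, 2, 3))), "mismatch")
  expect_error(variation_of_information(array(1L, c(2, 2, 2)),
                                        array(0L, c(2, 2, 2))), "empty")
})

test_that("the full report carries all five quantities", {
  set.seed(106)
  lab <- make_instances(c(8, 32, 32), n_objects = 4, min_radius = 4,
                        max_radius = 6)
  rep <- metrics_report(lab, lab)
  expect_s3_class(rep, "semmae_metrics")
  expect_identical(rep$a_rand, 0)
  expect_identical(rep$ap50, 1)
  expect_identical(rep$ap75, 1)
  expect_output(print(rep), "A-Rand")
})
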