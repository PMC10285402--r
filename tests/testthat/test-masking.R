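test_that("random masking reproduces the reference visible counts", {
  set.seed(51)
  pl <- plan_random(216, 0.90)
  expect_identical(length(pl$visible_idx), 21L)       # floor(0.1 * 216)
  expect_equal(pl$ratio_effective, 195 / 216)

  pl0 <- plan_random(216, 0)
  expect_identical(pl0$visible_idx, 1:216)
  expect_identical(length(pl0$masked_idx), 0L)

  expect_error(plan_random(216, 1), "\\[0, 1\\)")
  expect_error(plan_random(216, -0.1), "\\[0, 1\\)")
})

test_that("each token is visible at the expected frequency", {
  set.seed(52)
  n <- 20; draws <- 10000
  counts <- integer(n)
  for (i in seq_len(draws)) {
    pl <- plan_random(n, 0.5)
    counts[pl$visible_idx] <- counts[pl$visible_idx] + 1
  }
  # each token visible in ~50% of plans; binomial 5-sigma band
  p_hat <- counts / draws
  tol <- 5 * sqrt(0.25 / draws)
  expect_true(all(abs(p_hat - 0.5) < tol))
})

test_that("space-only masking keeps whole xy-columns across all sections", {
  g <- patch_grid(c(6, 96, 96))
  set.seed(53)
  pl <- plan_space_only(g, 4)
  expect_identical(length(pl$visible_idx), 24L)        # 4 x 6 tokens
  expect_equal(pl$ratio_effective, 192 / 216)
  # group by xy-position: every visible column contributes exactly Gz tokens
  col_of <- ((pl$visible_idx - 1L) %% 36L)
  expect_true(all(table(col_of) == 6L))
  expect_identical(length(unique(col_of)), 4L)

  expect_equal(plan_space_only(g, 36)$ratio_effective, 0)
  expect_error(plan_space_only(g, 0), "keep_columns")
  expect_error(plan_space_only(g, 37), "keep_columns")
})

test_that("section-only masking keeps whole z-sections", {
  g <- patch_grid(c(6, 96, 96))
  set.seed(54)
  pl <- plan_section_only(g, 1)
  expect_equal(pl$ratio_effective, 5 / 6)              # 83.3%
  # masked indices form a union of complete section blocks
  sec_of <- (pl$masked_idx - 1L) %/% 36L
  expect_identical(sort(unique(sec_of)), setdiff(0:5, (pl$visible_idx[1] - 1L) %/% 36L))
  expect_true(all(table(sec_of) == 36L))

  expect_equal(plan_section_only(g, 6)$ratio_effective, 0)
  expect_error(plan_section_only(g, 7), "keep_sections")
})

test_that("every plan partitions the token set and reproduces under a seed", {
  for (i in 1:10) {
    set.seed(60 + i)
    gz <- sample(2:4, 1); gy <- sample(2:5, 1); gx <- sample(2:5, 1)
    g <- patch_grid(c(gz, gy * 4, gx * 4), c(1, 4, 4))
    plans <- list(plan_random(g$n_tokens, runif(1, 0, 0.95)),
                  plan_space_only(g, sample(gy * gx, 1)),
                  plan_section_only(g, sample(gz, 1)))
    for (pl in plans) {
      expect_identical(sort(c(pl$visible_idx, pl$masked_idx)), 1:g$n_tokens)
      expect_length(intersect(pl$visible_idx, pl$masked_idx), 0)
      expect_gte(length(pl$visible_idx), 1)
      expect_lte(abs(pl$ratio_effective - pl$ratio_requested), 1 / g$n_tokens + 1e-9)
    }
  }
  set.seed(77); a <- plan_random(50, 0.7)
  set.seed(77); b <- plan_random(50, 0.7)
  expect_identical(a, b)
})

test_that("a higher requested ratio never yields more visible tokens", {
  set.seed(70)
  ratios <- sort(runif(20, 0, 0.99))
  vis <- vapply(ratios, function(r) length(plan_random(100, r)$visible_idx),
                integer(1))
  expect_true(all(diff(vis) <= 0))
})

test_that("ratio-to-count conversion breaks ties toward more masking", {
  expect_identical(ratio_to_keep(0.5, 4), 2L)
  # with 4 units, feasible ratios are 0, .25, .5, .75; request .625 ties
  # between keep 1 (ratio .75) and keep 2 (ratio .5): more masking wins
  expect_identical(ratio_to_keep(0.625, 4), 1L)
  expect_identical(ratio_to_keep(0, 6), 6L)
  g <- patch_grid(c(6, 96, 96))
  set.seed(1)
  pl <- plan_mask(g, "space_only", ratio = 0.89)
  expect_identical(length(pl$visible_idx), 24L)       # 4 columns survive
})
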