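#' @title Mask-sampling strategies
#' @description Three ways to choose which tokens the encoder sees during
#'   pre-training. Random sampling ignores spatial structure; space-only
#'   sampling keeps whole xy-columns of tokens across all sections;
#'   section-only sampling keeps whole z-sections. Structure-aware sampling
#'   quantizes the feasible ratios, so those strategies take counts.
#'   The visible count under random sampling is
#'   \code{floor((1 - ratio) * n_tokens)} — with 216 tokens at ratio 0.90
#'   exactly 21 tokens remain visible.
#' @name masking
NULL

.new_plan <- function(visible, n_tokens, ratio_requested, strategy) {
  visible <- sort(as.integer(visible))
  if (length(visible) < 1L) stop("a mask plan must keep at least one visible token")
  masked <- setdiff(seq_len(n_tokens), visible)
  structure(list(visible_idx = visible, masked_idx = masked,
                 n_tokens = as.integer(n_tokens),
                 ratio_requested = ratio_requested,
                 ratio_effective = length(masked) / n_tokens,
                 strategy = strategy),
            class = "semmae_mask_plan")
}

#' Structure-agnostic random masking
#'
#' Keeps \code{floor((1 - ratio) * n_tokens)} tokens (at least 1), drawn
#' uniformly without replacement.
#'
#' @param n_tokens token count
#' @param ratio requested masking ratio in `[0, 1)`
#' @return a `semmae_mask_plan` (1-based token indices)
#' @export
plan_random <- function(n_tokens, ratio) {
  if (ratio < 0 || ratio >= 1) stop("masking ratio must be in [0, 1), got ", ratio)
  n_vis <- max(1L, as.integer(floor((1 - ratio) * n_tokens)))
  .new_plan(sample.int(n_tokens, n_vis), n_tokens, ratio, "random")
}

#' Space-only masking: keep whole xy-columns
#'
#' Draws `keep_columns` xy-positions uniformly; tokens at those positions are
#' visible in every z-section, all others masked. With a 6x6x6 grid and 4
#' kept columns, 24 tokens stay visible (masking ratio 192/216 ~ 89%).
#'
#' @param grid a [patch_grid()]
#' @param keep_columns number of xy-columns kept visible
#' @return a `semmae_mask_plan`
#' @export
plan_space_only <- function(grid, keep_columns) {
  g <- grid$grid_shape
  n_cols <- g[2] * g[3]
  if (keep_columns < 1 || keep_columns > n_cols)
    stop("keep_columns must be in [1, ", n_cols, "], got ", keep_columns)
  cols <- sample.int(n_cols, keep_columns)            # 1-based xy index, x fastest
  per_section <- rep(cols, each = g[1])
  section_base <- rep((0:(g[1] - 1L)) * n_cols, times = keep_columns)
  visible <- section_base + per_section
  .new_plan(visible, grid$n_tokens, 1 - keep_columns / n_cols, "space_only")
}

#' Section-only masking: keep whole z-sections
#'
#' Keeps `keep_sections` entire z-sections of tokens; all other sections are
#' fully masked. On a 6x6x6 grid with one kept section the effective masking
#' ratio is 5/6 (83.3%).
#'
#' @param grid a [patch_grid()]
#' @param keep_sections number of z-sections kept visible
#' @return a `semmae_mask_plan`
#' @export
plan_section_only <- function(grid, keep_sections) {
  g <- grid$grid_shape
  if (keep_sections < 1 || keep_sections > g[1])
    stop("keep_sections must be in [1, ", g[1], "], got ", keep_sections)
  secs <- sample.int(g[1], keep_sections)
  n_cols <- g[2] * g[3]
  visible <- as.vector(outer(seq_len(n_cols), (secs - 1L) * n_cols, "+"))
  .new_plan(visible, grid$n_tokens, 1 - keep_sections / g[1], "section_only")
}

#' Convert a requested ratio to the nearest feasible keep-count
#'
#' Structure-aware strategies only realize quantized ratios `1 - k/n`. The
#' nearest feasible count is returned; ties break toward more masking
#' (smaller k). Used by the config layer.
#'
#' @param ratio requested masking ratio in `[0, 1)`
#' @param n_units number of maskable units (columns or sections)
#' @return integer keep-count in `[1, n_units]`
#' @export
ratio_to_keep <- function(ratio, n_units) {
  if (ratio < 0 || ratio >= 1) stop("masking ratio must be in [0, 1), got ", ratio)
  k <- seq_len(n_units)
  err <- abs((1 - k / n_units) - ratio)
  best <- which(err == min(err))
  min(best)                                            # smaller k = more masking
}

#' Dispatch a mask plan from config fields
#'
#' @param grid a [patch_grid()]
#' @param strategy one of `"random"`, `"space_only"`, `"section_only"`
#' @param ratio masking ratio (used directly by `"random"`; converted to the
#'   nearest feasible keep-count otherwise)
#' @param keep_columns,keep_sections explicit counts overriding `ratio`
#' @return a `semmae_mask_plan`
#' @export
plan_mask <- function(grid, strategy = "random", ratio = 0.9,
                      keep_columns = NULL, keep_sections = NULL) {
  switch(strategy,
    random = plan_random(grid$n_tokens, ratio),
    space_only = plan_space_only(grid, keep_columns %||%
                                   ratio_to_keep(ratio, grid$grid_shape[2] * grid$grid_shape[3])),
    section_only = plan_section_only(grid, keep_sections %||%
                                       ratio_to_keep(ratio, grid$grid_shape[1])),
    stop("unknown masking strategy '", strategy, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
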