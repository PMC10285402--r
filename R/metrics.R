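#' @title Segmentation evaluation metrics
#' @description Variation of information split into its over-segmentation
#'   (Voi-S = H(S|T)) and under-segmentation (Voi-M = H(T|S)) components,
#'   adapted Rand error (1 minus the pair-counting F-score; lower is better),
#'   and instance average precision at IoU 0.5 / 0.75. Following the SNEMI3D
#'   convention, voxel-wise metrics are evaluated on truth-foreground voxels
#'   (T != 0) by default. Entropies are in nats.
#' @name metrics
NULL

#' Joint contingency table of two labelings
#'
#' @param S,T equal-shape label arrays (prediction, truth)
#' @param restrict_foreground evaluate only where `T != 0`
#' @return list: `n_ij` (count matrix, rows = S segments, cols = T segments),
#'   marginals `a_i`, `b_j`, total `n`
#' @export
contingency_table <- function(S, T, restrict_foreground = TRUE) {
  if (!identical(dim(S), dim(T)))
    stop("shape mismatch: ", paste(dim(S), collapse = "x"), " vs ",
         paste(dim(T), collapse = "x"))
  keep <- if (restrict_foreground) T != 0 else rep(TRUE, length(T))
  if (!any(keep)) stop("empty evaluation mask (no truth-foreground voxels)")
  s <- as.vector(S)[keep]; t <- as.vector(T)[keep]
  n_ij <- unclass(table(s, t))
  list(n_ij = n_ij, a_i = rowSums(n_ij), b_j = colSums(n_ij), n = sum(n_ij))
}

#' Variation of information (split / merge components)
#'
#' \code{VI(S,T) = H(S|T) + H(T|S)}; the first conditional entropy measures
#' over-segmentation (split error), the second under-segmentation (merge
#' error). Computed in nats from the contingency table.
#'
#' @inheritParams contingency_table
#' @return list(voi_split, voi_merge)
#' @export
variation_of_information <- function(S, T, restrict_foreground = TRUE) {
  ct <- contingency_table(S, T, restrict_foreground)
  p <- ct$n_ij / ct$n
  pa <- ct$a_i / ct$n
  pb <- ct$b_j / ct$n
  ent <- function(x) -sum(x[x > 0] * log(x[x > 0]))
  h_joint <- ent(p)
  list(voi_split = h_joint - ent(pb),   # H(S|T)
       voi_merge = h_joint - ent(pa))   # H(T|S)
}

#' Adapted Rand error
#'
#' One minus the F-score of same-segment pair classification, computed from
#' squared contingency sums (ordered pairs including self-pairs, the
#' SNEMI3D/skimage convention). 0 for identical partitions; lower is better.
#'
#' @inheritParams contingency_table
#' @return scalar in `[0, 1]`
#' @export
adapted_rand_error <- function(S, T, restrict_foreground = TRUE) {
  ct <- contingency_table(S, T, restrict_foreground)
  sum_p2 <- sum(ct$n_ij^2)
  sum_a2 <- sum(ct$a_i^2)
  sum_b2 <- sum(ct$b_j^2)
  precision <- sum_p2 / sum_a2
  recall <- sum_p2 / sum_b2
  1 - 2 * precision * recall / (precision + recall)
}

#' Instance average precision at IoU thresholds
#'
#' Predicted instances are ranked by voxel count (no probability survives
#' watershed decoding) and matched greedily, one-to-one, to truth instances
#' at IoU >= threshold; AP is the area under the precision-recall curve over
#' the ranked list. Background is not an instance.
#'
#' @param S,T equal-shape label arrays (prediction, truth)
#' @param iou_thresholds numeric vector of IoU thresholds
#' @return named numeric vector, one AP per threshold (e.g. `ap50`, `ap75`);
#'   error if T contains no instances
#' @export
average_precision <- function(S, T, iou_thresholds = c(0.5, 0.75)) {
  if (!identical(dim(S), dim(T))) stop("shape mismatch")
  t_ids <- setdiff(sort(unique(as.vector(T))), 0L)
  if (!length(t_ids)) stop("no truth instances: average precision undefined")
  s_ids <- setdiff(sort(unique(as.vector(S))), 0L)
  out <- numeric(length(iou_thresholds))
  names(out) <- paste0("ap", round(100 * iou_thresholds))
  if (!length(s_ids)) return(out)

  # voxel overlap table between S and T instances
  keep <- S != 0 & T != 0
  ov <- if (any(keep))
    unclass(table(factor(S[keep], levels = s_ids), factor(T[keep], levels = t_ids)))
  else matrix(0L, length(s_ids), length(t_ids))
  s_sz <- vapply(s_ids, function(i) sum(S == i), numeric(1))
  t_sz <- vapply(t_ids, function(i) sum(T == i), numeric(1))
  iou <- ov / (outer(s_sz, t_sz, "+") - ov)

  ord <- order(-s_sz, s_ids)                 # score = size, ties by label id
  for (k in seq_along(iou_thresholds)) {
    thr <- iou_thresholds[k]
    matched_t <- logical(length(t_ids))
    tp <- logical(length(s_ids))
    for (r in ord) {
      cand <- which(iou[r, ] >= thr & !matched_t)
      if (length(cand)) {
        best <- cand[which.max(iou[r, cand])]
        matched_t[best] <- TRUE
        tp[r] <- TRUE
      }
    }
    tp_ranked <- tp[ord]
    cum_tp <- cumsum(tp_ranked)
    precision <- cum_tp / seq_along(tp_ranked)
    recall <- cum_tp / length(t_ids)
    out[k] <- sum(diff(c(0, recall)) * precision)
  }
  out
}

#' Full metrics report for a (prediction, truth) pair
#'
#' @inheritParams average_precision
#' @param restrict_foreground evaluate VI and adapted Rand on `T != 0` voxels
#' @return a `semmae_metrics` list: voi_split, voi_merge, a_rand, ap50, ap75
#' @export
metrics_report <- function(S, T, restrict_foreground = TRUE) {
  vi <- variation_of_information(S, T, restrict_foreground)
  ap <- average_precision(S, T)
  structure(list(voi_split = vi$voi_split, voi_merge = vi$voi_merge,
                 a_rand = adapted_rand_error(S, T, restrict_foreground),
                 ap50 = unname(ap["ap50"]), ap75 = unname(ap["ap75"])),
            class = "semmae_metrics")
}

#' @export
print.semmae_metrics <- function(x, ...) {
  cat(sprintf("Voi-S %.4f  Voi-M %.4f  A-Rand %.4f  AP-50 %.3f  AP-75 %.3f\n",
              x$voi_split, x$voi_merge, x$a_rand, x$ap50, x$ap75))
  invisible(x)
}
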