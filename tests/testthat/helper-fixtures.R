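# Shared fixtures and independent oracles for the test suite. Oracles here
# are deliberately naive (brute force, graph libraries) and never call the
# package's own fast paths.

# two background-separated rectangular blobs in a small canvas
two_blob_labels <- function() {
  lab <- array(0L, dim = c(4, 12, 12))
  lab[1:4, 2:5, 2:5] <- 1L
  lab[1:4, 8:11, 7:11] <- 2L
  lab
}

# brute-force nearest-neighbour affinity: per-voxel double loop
affinity_bruteforce <- function(labels) {
  d <- dim(labels)
  aff <- array(0, dim = c(d, 3))
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    l <- labels[z, y, x]
    if (z > 1 && l != 0 && labels[z - 1, y, x] == l) aff[z, y, x, 1] <- 1
    if (y > 1 && l != 0 && labels[z, y - 1, x] == l) aff[z, y, x, 2] <- 1
    if (x > 1 && l != 0 && labels[z, y, x - 1] == l) aff[z, y, x, 3] <- 1
  }
  aff
}

# brute-force adapted Rand error: ordered voxel pairs (self-pairs included)
arand_bruteforce <- function(S, T) {
  keep <- T != 0
  s <- as.vector(S)[keep]; t <- as.vector(T)[keep]
  n <- length(s)
  tp <- 0; pred_pos <- 0; truth_pos <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ss <- s[i] == s[j]; tt <- t[i] == t[j]
    if (ss && tt) tp <- tp + 1
    if (ss) pred_pos <- pred_pos + 1
    if (tt) truth_pos <- truth_pos + 1
  }
  prec <- tp / pred_pos; rec <- tp / truth_pos
  1 - 2 * prec * rec / (prec + rec)
}

# conditional entropies from first principles (nats)
voi_bruteforce <- function(S, T) {
  keep <- T != 0
  s <- as.vector(S)[keep]; t <- as.vector(T)[keep]
  n <- length(s)
  joint <- table(s, t) / n
  hs_t <- 0; ht_s <- 0
  pt <- colSums(joint); ps <- rowSums(joint)
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    p <- joint[i, j]
    if (p > 0) {
      hs_t <- hs_t - p * log(p / pt[j])
      ht_s <- ht_s - p * log(p / ps[i])
    }
  }
  c(split = unname(hs_t), merge = unname(ht_s))
}

# 6-connectivity components through igraph (independent of the C++ path)
n_components_igraph <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  coord <- arrayInd(idx, d)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  pos <- setNames(seq_along(idx), key(coord))
  edges <- integer(0)
  for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    nb <- sweep(coord, 2, off, "+")
    ok <- nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    hit <- pos[key(nb[ok, , drop = FALSE])]
    src <- which(ok)[!is.na(hit)]
    edges <- c(edges, rbind(src, hit[!is.na(hit)]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  as.integer(igraph::components(g)$no)
}

# tiny random label volume for metric property sweeps
random_labels <- function(d = c(3, 3, 3), k = 3) {
  array(sample(0:k, prod(d), replace = TRUE), dim = d)
}
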