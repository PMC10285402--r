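# Minimal neural-network core: dense/layer-norm/multi-head-attention layers
# with explicit forward caches and hand-derived backward passes, plus AdamW,
# SGD-momentum and the warmup+cosine learning-rate schedule. Everything
# operates on plain matrices (tokens x features); parameters are nested named
# lists of arrays. Gradient correctness is pinned by finite-difference tests.

.tnorm <- function(n, sd = 0.02) {
  x <- rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

.addb <- function(m, b) sweep(m, 2L, b, "+")

# exact GELU: x * Phi(x)
.gelu_fwd <- function(x) x * pnorm(x)
.gelu_bwd <- function(x) pnorm(x) + x * dnorm(x)

.ln_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = .addb(sweep(xhat, 2L, g, "*"), b), xhat = xhat, inv = inv, g = g)
}

.ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, cache$g, "*")
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

.dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, mask = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(out = x * mask, mask = mask)
}
.dropout_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

.mha_fwd <- function(x, p, heads, dropout = 0, train = FALSE) {
  D <- ncol(x); dh <- D %/% heads
  Q <- .addb(x %*% p$Wq, p$bq)
  K <- .addb(x %*% p$Wk, p$bk)
  V <- .addb(x %*% p$Wv, p$bv)
  scl <- 1 / sqrt(dh)
  O <- matrix(0, nrow(x), D)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    id <- ((h - 1L) * dh + 1L):(h * dh)
    S <- (Q[, id, drop = FALSE] %*% t(K[, id, drop = FALSE])) * scl
    S <- S - apply(S, 1L, max)
    E <- exp(S)
    A[[h]] <- E / rowSums(E)
    O[, id] <- A[[h]] %*% V[, id, drop = FALSE]
  }
  out <- .addb(O %*% p$Wo, p$bo)
  dr <- .dropout_fwd(out, dropout, train)
  list(out = dr$out, cache = list(x = x, Q = Q, K = K, V = V, A = A, O = O,
                                  heads = heads, dh = dh, scl = scl,
                                  drop_mask = dr$mask))
}

.mha_bwd <- function(dout, p, cache) {
  dout <- .dropout_bwd(dout, cache$drop_mask)
  heads <- cache$heads; dh <- cache$dh; scl <- cache$scl
  dWo <- t(cache$O) %*% dout
  dbo <- colSums(dout)
  dO <- dout %*% t(p$Wo)
  D <- ncol(dO)
  dQ <- matrix(0, nrow(dO), D); dK <- dQ; dV <- dQ
  for (h in seq_len(heads)) {
    id <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, id, drop = FALSE]
    Vh <- cache$V[, id, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, id] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))
    dQ[, id] <- (dS %*% cache$K[, id, drop = FALSE]) * scl
    dK[, id] <- (t(dS) %*% cache$Q[, id, drop = FALSE]) * scl
  }
  x <- cache$x
  grads <- list(Wq = t(x) %*% dQ, bq = colSums(dQ),
                Wk = t(x) %*% dK, bk = colSums(dK),
                Wv = t(x) %*% dV, bv = colSums(dV),
                Wo = dWo, bo = dbo)
  dx <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dx = dx, grads = grads)
}

.mlp_fwd <- function(x, p, dropout = 0, train = FALSE) {
  h <- .addb(x %*% p$W1, p$b1)
  a <- .gelu_fwd(h)
  out <- .addb(a %*% p$W2, p$b2)
  dr <- .dropout_fwd(out, dropout, train)
  list(out = dr$out, cache = list(x = x, h = h, a = a, drop_mask = dr$mask))
}

.mlp_bwd <- function(dout, p, cache) {
  dout <- .dropout_bwd(dout, cache$drop_mask)
  dW2 <- t(cache$a) %*% dout
  db2 <- colSums(dout)
  da <- dout %*% t(p$W2)
  dh <- da * .gelu_bwd(cache$h)
  list(dx = dh %*% t(p$W1),
       grads = list(W1 = t(cache$x) %*% dh, b1 = colSums(dh), W2 = dW2, b2 = db2))
}

.block_init <- function(D, heads, mlp_ratio = 4) {
  H <- as.integer(D * mlp_ratio)
  list(ln1g = rep(1, D), ln1b = rep(0, D),
       attn = list(Wq = matrix(.tnorm(D * D), D, D), bq = rep(0, D),
                   Wk = matrix(.tnorm(D * D), D, D), bk = rep(0, D),
                   Wv = matrix(.tnorm(D * D), D, D), bv = rep(0, D),
                   Wo = matrix(.tnorm(D * D), D, D), bo = rep(0, D)),
       ln2g = rep(1, D), ln2b = rep(0, D),
       mlp = list(W1 = matrix(.tnorm(D * H), D, H), b1 = rep(0, H),
                  W2 = matrix(.tnorm(H * D), H, D), b2 = rep(0, D)))
}

# pre-LN transformer block with optional dropout / stochastic depth
.block_fwd <- function(x, p, heads, dropout = 0, droppath = 0, train = FALSE) {
  keep1 <- !train || droppath <= 0 || runif(1) >= droppath
  s1 <- if (train && droppath > 0 && keep1) 1 / (1 - droppath) else 1
  l1 <- .ln_fwd(x, p$ln1g, p$ln1b)
  at <- if (keep1) .mha_fwd(l1$out, p$attn, heads, dropout, train) else NULL
  x2 <- if (keep1) x + s1 * at$out else x
  keep2 <- !train || droppath <= 0 || runif(1) >= droppath
  s2 <- if (train && droppath > 0 && keep2) 1 / (1 - droppath) else 1
  l2 <- .ln_fwd(x2, p$ln2g, p$ln2b)
  ml <- if (keep2) .mlp_fwd(l2$out, p$mlp, dropout, train) else NULL
  out <- if (keep2) x2 + s2 * ml$out else x2
  list(out = out, cache = list(l1 = l1, at = at, l2 = l2, ml = ml,
                               keep1 = keep1, keep2 = keep2, s1 = s1, s2 = s2,
                               heads = heads))
}

.block_bwd <- function(dout, p, cache) {
  g <- list()
  dx2 <- dout
  if (cache$keep2) {
    mb <- .mlp_bwd(cache$s2 * dout, p$mlp, cache$ml$cache)
    lb <- .ln_bwd(mb$dx, cache$l2)
    dx2 <- dout + lb$dx
    g$mlp <- mb$grads; g$ln2g <- lb$dg; g$ln2b <- lb$db
  } else {
    g$mlp <- .nn_zeros(p$mlp); g$ln2g <- rep(0, length(p$ln2g)); g$ln2b <- g$ln2g
  }
  dx <- dx2
  if (cache$keep1) {
    ab <- .mha_bwd(cache$s1 * dx2, p$attn, cache$at$cache)
    lb1 <- .ln_bwd(ab$dx, cache$l1)
    dx <- dx2 + lb1$dx
    g$attn <- ab$grads; g$ln1g <- lb1$dg; g$ln1b <- lb1$db
  } else {
    g$attn <- .nn_zeros(p$attn); g$ln1g <- rep(0, length(p$ln1g)); g$ln1b <- g$ln1g
  }
  list(dx = dx, grads = g)
}

# ---- nested-parameter utilities -------------------------------------------

.nn_zeros <- function(p) {
  if (is.list(p)) lapply(p, .nn_zeros)
  else { z <- p; z[] <- 0; z }
}

# pick entry i of a parallel structure, by name when names exist (gradient
# lists may order named fields differently than the parameter lists)
.nn_pick <- function(x, nm, i) {
  if (!is.null(nm) && nzchar(nm[i])) x[[nm[i]]] else x[[i]]
}

.nn_add <- function(a, b) {
  if (is.list(a)) {
    nm <- names(a)
    for (i in seq_along(a)) a[[i]] <- .nn_add(a[[i]], .nn_pick(b, nm, i))
    a
  } else a + b
}

.nn_scale <- function(a, s) {
  if (is.list(a)) lapply(a, .nn_scale, s = s) else a * s
}

.nn_max_abs <- function(a) {
  if (is.list(a)) max(vapply(a, .nn_max_abs, numeric(1)), 0) else
    if (length(a)) max(abs(a)) else 0
}

.nn_any_nan <- function(a) {
  if (is.list(a)) any(vapply(a, .nn_any_nan, logical(1))) else any(!is.finite(a))
}

# ---- optimizers ------------------------------------------------------------

#' @keywords internal
adamw_init <- function(params) list(m = .nn_zeros(params), v = .nn_zeros(params), t = 0L)

# decoupled weight decay applied to weight matrices only (not biases/norms)
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.95,
                       eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      nm <- names(p)
      for (i in seq_along(p)) {
        r <- rec(p[[i]], .nn_pick(g, nm, i), m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    wd <- if (is.matrix(p)) weight_decay else 0
    p <- p - lr * (mh / (sqrt(vh) + eps) + wd * p)
    list(p = p, m = m, v = v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

sgd_init <- function(params) list(u = .nn_zeros(params))

sgd_step <- function(params, grads, state, lr, momentum = 0.9, weight_decay = 0) {
  rec <- function(p, g, u) {
    if (is.list(p)) {
      nm <- names(p)
      for (i in seq_along(p)) {
        r <- rec(p[[i]], .nn_pick(g, nm, i), u[[i]])
        p[[i]] <- r$p; u[[i]] <- r$u
      }
      return(list(p = p, u = u))
    }
    if (is.matrix(p)) g <- g + weight_decay * p
    u <- momentum * u + g
    p <- p - lr * u
    list(p = p, u = u)
  }
  r <- rec(params, grads, state$u)
  list(params = r$p, state = list(u = r$u))
}

#' Warmup + cosine learning-rate schedule
#'
#' Linear warmup from 0 to `base_lr` over `warmup` iterations, then cosine
#' decay to 0 at `total` iterations.
#'
#' @param iter 1-based iteration
#' @param base_lr peak learning rate
#' @param warmup,total iteration counts
#' @return learning rate for `iter`
#' @export
lr_schedule <- function(iter, base_lr, warmup, total) {
  if (warmup > 0 && iter <= warmup) return(base_lr * iter / warmup)
  if (total <= warmup) return(base_lr)
  frac <- (iter - warmup) / (total - warmup)
  0.5 * base_lr * (1 + cos(pi * min(max(frac, 0), 1)))
}
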