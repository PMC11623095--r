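# Independent brute-force oracles, deliberately written with explicit loops
# and none of the package's internal helpers.

# dense softmax attention over all tokens: every token attends to every token
oracle_dense_attention <- function(tok, WQ, WK, WV, h) {
  n <- nrow(tok)
  Q <- tok %*% WQ; K <- tok %*% WK; V <- tok %*% WV
  out <- matrix(0, n, ncol(tok))
  for (i in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(h)
    e <- exp(s - max(s))
    a <- e / sum(e)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + a[j] * V[j, ]
  }
  out
}

# dice loss by direct summation of the defining formula
oracle_dice <- function(p, g_onehot, w, eps = 1e-5) {
  K <- ncol(p)
  total <- 0
  for (k in seq_len(K)) {
    num <- 0; dp <- 0; dg <- 0
    for (i in seq_len(nrow(p))) {
      num <- num + p[i, k] * g_onehot[i, k]
      dp <- dp + p[i, k]^2
      dg <- dg + g_onehot[i, k]^2
    }
    total <- total + 2 * w[k] * num / (dp + dg + eps)
  }
  1 - total
}

# binary cross-entropy averaged over classes and pixels, by direct summation
oracle_ce <- function(p, g_onehot, clamp = 1e-7) {
  K <- ncol(p); N <- nrow(p)
  acc <- 0
  for (k in seq_len(K)) {
    for (i in seq_len(N)) {
      pk <- min(max(p[i, k], clamp), 1 - clamp)
      acc <- acc - (g_onehot[i, k] * log(pk) + (1 - g_onehot[i, k]) * log(1 - pk))
    }
  }
  acc / (N * K)
}

# boundary pixels by explicit neighbourhood inspection
oracle_boundary <- function(b) {
  n <- nrow(b); m <- ncol(b)
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!b[i, j]) next
    if (i == 1 || j == 1 || i == n || j == m ||
        !b[i - 1, j] || !b[i + 1, j] || !b[i, j - 1] || !b[i, j + 1]) {
      out[i, j] <- TRUE
    }
  }
  out
}

# classic Hausdorff distance via all boundary pairs
oracle_hd <- function(a, b) {
  pa <- which(oracle_boundary(a), arr.ind = TRUE)
  pb <- which(oracle_boundary(b), arr.ind = TRUE)
  dir_max <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        d <- sqrt((p[i, 1] - q[j, 1])^2 + (p[i, 2] - q[j, 2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(dir_max(pa, pb), dir_max(pb, pa))
}

# a small random blob mask containing a filled disc
random_blob <- function(side, seed) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, side, side)
    r <- sample(2:5, 1)
    cx <- runif(1, r + 1, side - r)
    cy <- runif(1, r + 1, side - r)
    for (i in seq_len(side)) for (j in seq_len(side)) {
      if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- TRUE
    }
    m
  })
}

# small smoke-scale model shared across tests
smoke_model <- function(preset = "default", seed = 1L, side = 64L, K = 4L,
                        fusion = "max") {
  msr_unet(side = side, K = K, widths = c(16L, 32L, 64L, 128L),
           depths = rep(1L, 4L), groups = c(2L, 4L, 8L, 8L),
           preset = preset, fusion = fusion, bridge_d = 2L, seed = seed)
}
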