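## Multi-scale reconfiguration self-attention (MSR-SA).
##
## The operator splits channels into G groups; group i tiles the feature grid
## into non-overlapping S_i x S_i windows, samples an M x M point grid in each
## window at dilation D_i = (S_i - 1)/(M - 1), projects the sampled features to
## keys/values, fuses same-position samples across windows with a symmetric
## reduction, and runs scaled-dot-product attention of all tokens against the
## M^2 fused keys.  Every group therefore attends to exactly M^2 keys no
## matter how large its window is.

#' Per-group attention configuration
#'
#' @param channels group channel width C' (C / G)
#' @param S window side in grid cells; must satisfy `S = D * (M - 1) + 1`
#' @param M sample-grid side (number of sampled points per axis), default 7
#' @param D dilation rate; derived from `S` and `M` when `NULL`
#' @param h attention scaling; defaults to `channels` (per-head width)
#' @return an object of class `msr_group_spec`
#' @export
group_spec <- function(channels, S, M = 7L, D = NULL, h = channels) {
  stopifnot(channels >= 1, M >= 2, S >= 1)
  if (is.null(D)) D <- dilation_rate(S, M)
  if (D * (M - 1L) + 1L != S) {
    stop(sprintf("inconsistent window/grid/dilation: S=%d, M=%d, D=%d (need S = D*(M-1)+1)",
                 S, M, D))
  }
  structure(list(channels = as.integer(channels), S = as.integer(S),
                 M = as.integer(M), D = as.integer(D), h = h),
            class = "msr_group_spec")
}

#' Dilation rate for a window/grid pairing
#'
#' `D = (S - 1) / (M - 1)`, defined only when integral: `M` sampled points at
#' spacing `D` must span the window side exactly.
#'
#' @param S window side
#' @param M sample-grid side
#' @return integer dilation rate
#' @export
dilation_rate <- function(S, M) {
  stopifnot(S >= M, M >= 2)
  if ((S - 1L) %% (M - 1L) != 0L) {
    stop(sprintf("invalid window/grid pairing: (S-1)=%d is not divisible by (M-1)=%d",
                 S - 1L, M - 1L))
  }
  as.integer((S - 1L) %/% (M - 1L))
}

#' Build the per-group window schedule for a feature grid
#'
#' The default schedule assigns ascending dilation rates `D_i = 2^(i-1)`
#' (window sides 7, 13, 25, ... for `M = 7`), clamped to the largest window
#' that fits the grid.  Preset `"low"` sets every `D_i = 1` (single-scale
#' baseline); preset `"high"` gives every group one window covering the whole
#' grid (smallest valid `S >= max(H, W)`).
#'
#' @param H,W feature-grid extent
#' @param C total channels; must be divisible by `G`
#' @param G number of attention groups
#' @param M sample-grid side
#' @param preset one of `"default"`, `"low"`, `"high"`
#' @param dilations optional explicit integer dilation per group (overrides
#'   the preset)
#' @return list of `G` [group_spec()] objects
#' @export
msr_groups <- function(H, W, C, G, M = 7L, preset = c("default", "low", "high"),
                       dilations = NULL) {
  preset <- match.arg(preset)
  if (C %% G != 0L) {
    stop(sprintf("channel count C=%d is not divisible by group count G=%d", C, G))
  }
  Cg <- C %/% G
  side <- min(H, W)
  max_d <- max(1L, (side - 1L) %/% (M - 1L))       # largest D with S <= min(H, W)
  pick <- function(i) {
    if (!is.null(dilations)) return(as.integer(dilations[i]))
    switch(preset,
      default = min(2L^(i - 1L), max_d),
      low     = 1L,
      high    = as.integer(ceiling((max(H, W) - 1L) / (M - 1L))))
  }
  lapply(seq_len(G), function(i) {
    D <- max(1L, pick(i))
    group_spec(Cg, D * (M - 1L) + 1L, M = M, D = D)
  })
}

#' Split a feature map evenly along channels
#'
#' @param x numeric array `H x W x C`
#' @param G number of groups; `C` must be divisible by `G`
#' @return list of `G` arrays `H x W x C/G`; concatenating them along the
#'   third axis recovers `x`
#' @export
split_groups <- function(x, G) {
  stopifnot(length(dim(x)) == 3L)
  C <- dim(x)[3L]
  if (C %% G != 0L) {
    stop(sprintf("channel count C=%d is not divisible by group count G=%d", C, G))
  }
  Cg <- C %/% G
  lapply(seq_len(G), function(i) x[, , ((i - 1L) * Cg + 1L):(i * Cg), drop = FALSE])
}

#' Partition a feature map into non-overlapping square windows
#'
#' The grid is zero-padded on the bottom/right to the next multiple of `S`;
#' the padding record allows exact restoration with [unpartition_windows()].
#' Windows are ordered row-fastest over the window grid.
#'
#' @param xg numeric array `H x W x C`
#' @param S window side
#' @return object of class `msr_windows`: list with `windows` (array
#'   `S x S x C x Mi`), `pad` (bottom, right), `grid` (windows per axis),
#'   `H`, `W`, `S`
#' @export
partition_windows <- function(xg, S) {
  stopifnot(length(dim(xg)) == 3L, S >= 1)
  H <- dim(xg)[1L]; W <- dim(xg)[2L]; C <- dim(xg)[3L]
  nwh <- as.integer(ceiling(H / S)); nww <- as.integer(ceiling(W / S))
  Hp <- nwh * S; Wp <- nww * S
  xp <- array(0, c(Hp, Wp, C))
  xp[seq_len(H), seq_len(W), ] <- xg
  Mi <- nwh * nww
  win <- array(0, c(S, S, C, Mi))
  for (wx in seq_len(nww)) {
    for (wy in seq_len(nwh)) {
      j <- wy + (wx - 1L) * nwh
      win[, , , j] <- xp[((wy - 1L) * S + 1L):(wy * S),
                         ((wx - 1L) * S + 1L):(wx * S), , drop = FALSE]
    }
  }
  structure(list(windows = win, pad = c(Hp - H, Wp - W),
                 grid = c(nwh, nww), H = H, W = W, S = S),
            class = "msr_windows")
}

#' Restore the original feature map from a window partition
#'
#' @param pw an `msr_windows` object from [partition_windows()]
#' @return numeric array `H x W x C` (padding removed)
#' @export
unpartition_windows <- function(pw) {
  stopifnot(inherits(pw, "msr_windows"))
  S <- pw$S; nwh <- pw$grid[1L]; nww <- pw$grid[2L]
  C <- dim(pw$windows)[3L]
  xp <- array(0, c(nwh * S, nww * S, C))
  for (wx in seq_len(nww)) {
    for (wy in seq_len(nwh)) {
      j <- wy + (wx - 1L) * nwh
      xp[((wy - 1L) * S + 1L):(wy * S),
         ((wx - 1L) * S + 1L):(wx * S), ] <- pw$windows[, , , j]
    }
  }
  xp[seq_len(pw$H), seq_len(pw$W), , drop = FALSE]
}

#' Dilated sampling of an M x M point grid inside a window
#'
#' Sampled row/column offsets are `{0, D, 2D, ..., (M-1) D}` from the window
#' origin; `D * (M - 1) + 1` must equal the window side.
#'
#' @param window numeric array `S x S x C`
#' @param M sample-grid side
#' @param D dilation rate
#' @return numeric array `M x M x C`
#' @export
dilated_sample <- function(window, M, D) {
  stopifnot(length(dim(window)) == 3L)
  S <- dim(window)[1L]
  if (D * (M - 1L) + 1L != S) {
    stop(sprintf("inconsistent (S, M, D) = (%d, %d, %d): need S = D*(M-1)+1", S, M, D))
  }
  ix <- seq(1L, by = D, length.out = M)
  window[ix, ix, , drop = FALSE]
}

#' Fuse sampled features across windows
#'
#' Reduces the window axis with a symmetric aggregation: `"max"`/`"mean"` are
#' invariant to window order; `"linear"` is a learnable weighted sum over
#' windows (weights `theta`, one per window).  Positions flagged invalid
#' (padding) are excluded from the reduction; positions invalid in every
#' window yield 0.
#'
#' @param pf numeric array `Mi x M^2 x C` (windows x sample positions x
#'   channels)
#' @param mode one of `"max"`, `"mean"`, `"linear"`
#' @param valid optional logical `Mi x M^2` validity mask (default all valid)
#' @param theta numeric weights of length `Mi` for `mode = "linear"`
#' @return numeric matrix `M^2 x C` of fused features
#' @export
fuse_cross_window <- function(pf, mode = c("max", "mean", "linear"),
                              valid = NULL, theta = NULL) {
  if (is.character(mode)) mode <- mode[1L]
  if (!mode %in% c("max", "mean", "linear")) {
    stop(sprintf("unknown fusion mode '%s'; valid modes: max, mean, linear", mode))
  }
  stopifnot(length(dim(pf)) == 3L)
  Mi <- dim(pf)[1L]; M2 <- dim(pf)[2L]; C <- dim(pf)[3L]
  if (is.null(valid)) valid <- matrix(TRUE, Mi, M2)
  out <- matrix(0, M2, C)
  for (m in seq_len(M2)) {
    vj <- which(valid[, m])
    if (!length(vj)) next
    blk <- matrix(pf[vj, m, ], nrow = length(vj), ncol = C)
    out[m, ] <- switch(mode,
      max    = apply(blk, 2L, max),
      mean   = colMeans(blk),
      linear = {
        if (is.null(theta) || length(theta) != Mi) {
          stop("linear fusion requires 'theta' of length Mi (one weight per window)")
        }
        as.numeric(theta[vj] %*% blk)
      })
  }
  out
}

#' Scaled dot-product attention of queries against a fused key set
#'
#' @param Q numeric matrix `N x C'` of queries
#' @param K,V numeric matrices `M^2 x C'` of fused keys and values
#' @param h scaling factor (> 0); scores are divided by `sqrt(h)`
#' @param mask optional logical vector over keys; `FALSE` keys are excluded
#' @return numeric matrix `N x C'`; each softmax row sums to 1
#' @export
group_attention <- function(Q, K, V, h, mask = NULL) {
  stopifnot(h > 0, ncol(Q) == ncol(K), nrow(K) == nrow(V), ncol(K) == ncol(V))
  sc <- tcrossprod(Q, K) / sqrt(h)
  if (!is.null(mask)) sc[, !mask] <- -Inf
  sc <- sc - apply(sc, 1L, max)
  e <- exp(sc)
  A <- e / rowSums(e)
  A %*% V
}

#' Initialize projection weights for MSR-SA
#'
#' One independent `W^Q`, `W^K`, `W^V` (each `C' x C'`, truncated-normal,
#' sd 0.02) plus zero biases per group, matching 1x1-convolution embeddings.
#'
#' @param groups list of [group_spec()] objects
#' @param seed integer RNG seed
#' @param identity if `TRUE`, use identity matrices and zero biases instead
#' @return list (per group) of lists with `WQ`, `WK`, `WV`, `bQ`, `bK`, `bV`
#' @export
msr_sa_weights <- function(groups, seed = 1L, identity = FALSE) {
  withr::with_seed(seed, {
    lapply(groups, function(gs) {
      Cg <- gs$channels
      mk <- function() if (identity) diag(Cg) else matrix(trunc_normal(Cg * Cg), Cg, Cg)
      list(WQ = mk(), WK = mk(), WV = mk(),
           bQ = numeric(Cg), bK = numeric(Cg), bV = numeric(Cg))
    })
  })
}

## truncated normal at +-2 sd, the conventional transformer weight init
trunc_normal <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

#' Multi-scale reconfiguration self-attention forward pass
#'
#' Reference implementation composed from the individual operator stages:
#' channel split, query projection, window partition, dilated sampling,
#' key/value projection, cross-window fusion, grouped attention, channel
#' concatenation.  Output shape equals input shape.
#'
#' @param x numeric array `H x W x C`
#' @param groups list of [group_spec()] whose channel widths sum to `C`
#' @param weights per-group projection weights from [msr_sa_weights()];
#'   identity projections when `NULL`
#' @param mode cross-window fusion mode (`"max"`, `"mean"`, `"linear"`)
#' @param theta list of per-group linear-fusion weights (only `mode="linear"`)
#' @return numeric array `H x W x C`
#' @export
msr_sa_forward <- function(x, groups, weights = NULL, mode = "max", theta = NULL) {
  stopifnot(length(dim(x)) == 3L)
  H <- dim(x)[1L]; W <- dim(x)[2L]; C <- dim(x)[3L]
  widths <- vapply(groups, function(g) g$channels, integer(1))
  if (sum(widths) != C) {
    stop(sprintf("group channel widths sum to %d but the map has C=%d channels",
                 sum(widths), C))
  }
  G <- length(groups)
  if (is.null(weights)) weights <- msr_sa_weights(groups, identity = TRUE)
  xg_list <- split_groups(x, G)
  out <- vector("list", G)
  for (i in seq_len(G)) {
    gs <- groups[[i]]
    wt <- weights[[i]]
    xg <- xg_list[[i]]
    Cg <- gs$channels
    tok <- xg; dim(tok) <- c(H * W, Cg)
    Q <- sweep(tok %*% wt$WQ, 2L, wt$bQ, "+")

    pw <- partition_windows(xg, gs$S)
    Mi <- prod(pw$grid)
    M2 <- gs$M^2
    Kp <- array(0, c(Mi, M2, Cg))
    Vp <- array(0, c(Mi, M2, Cg))
    for (j in seq_len(Mi)) {
      wj <- pw$windows[, , , j, drop = FALSE]
      dim(wj) <- dim(wj)[1:3]
      pj <- dilated_sample(wj, gs$M, gs$D)
      pj_tok <- pj; dim(pj_tok) <- c(M2, Cg)
      Kp[j, , ] <- sweep(pj_tok %*% wt$WK, 2L, wt$bK, "+")
      Vp[j, , ] <- sweep(pj_tok %*% wt$WV, 2L, wt$bV, "+")
    }
    valid <- t(.sample_valid(H, W, gs$S, gs$M, gs$D, pw$grid))   # Mi x M2
    th <- if (!is.null(theta)) theta[[i]] else NULL
    Kf <- fuse_cross_window(Kp, mode, valid = valid, theta = th)
    Vf <- fuse_cross_window(Vp, mode, valid = valid, theta = th)
    kmask <- colSums(valid) > 0L
    og <- group_attention(Q, Kf, Vf, gs$h, mask = kmask)
    dim(og) <- c(H, W, Cg)
    out[[i]] <- og
  }
  res <- array(0, c(H, W, C))
  off <- 0L
  for (i in seq_len(G)) {
    res[, , (off + 1L):(off + widths[i])] <- out[[i]]
    off <- off + widths[i]
  }
  res
}

## ---- shared index builders (also used by the tape-level network path) ------

## Validity of sample position m (of M^2, position-fastest order) in window j:
## TRUE when the sampled pixel lies inside the unpadded H x W extent.
.sample_valid <- function(H, W, S, M, D, grid) {
  nwh <- grid[1L]; nww <- grid[2L]
  Mi <- nwh * nww
  valid <- matrix(FALSE, M * M, Mi)
  offs <- (seq_len(M) - 1L) * D
  for (wx in seq_len(nww)) {
    for (wy in seq_len(nwh)) {
      j <- wy + (wx - 1L) * nwh
      rows_ok <- (wy - 1L) * S + offs + 1L <= H
      cols_ok <- (wx - 1L) * S + offs + 1L <= W
      valid[, j] <- as.vector(outer(rows_ok, cols_ok, "&"))
    }
  }
  valid
}

## Sampling geometry for a (H, W) grid under (S, M, D): token indices into the
## zero-padded Hp x Wp grid for every (sample position, window) pair, plus the
## validity mask.  Cached per geometry.
.sample_index <- function(H, W, S, M, D) {
  key <- paste0("samp_", H, "_", W, "_", S, "_", M, "_", D)
  if (!is.null(.tape_env[[key]])) return(.tape_env[[key]])
  nwh <- as.integer(ceiling(H / S)); nww <- as.integer(ceiling(W / S))
  Hp <- nwh * S; Wp <- nww * S
  Mi <- nwh * nww
  M2 <- M * M
  idx <- matrix(0L, M2, Mi)
  offs <- (seq_len(M) - 1L) * D
  for (wx in seq_len(nww)) {
    for (wy in seq_len(nwh)) {
      j <- wy + (wx - 1L) * nwh
      rr <- (wy - 1L) * S + offs + 1L
      cc <- (wx - 1L) * S + offs + 1L
      idx[, j] <- as.vector(outer(rr, (cc - 1L) * Hp, "+"))
    }
  }
  res <- list(idx = idx, valid = .sample_valid(H, W, S, M, D, c(nwh, nww)),
              Mi = Mi, M2 = M2, Hp = Hp, Wp = Wp, grid = c(nwh, nww))
  .tape_env[[key]] <- res
  res
}

## Map from original token index to padded-grid token index (cached).
.pad_map <- function(H, W, Hp, Wp) {
  key <- paste0("padmap_", H, "_", W, "_", Hp, "_", Wp)
  if (!is.null(.tape_env[[key]])) return(.tape_env[[key]])
  m <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"))
  .tape_env[[key]] <- m
  m
}

## Tape-level MSR-SA on a token-matrix node (N x C); returns a token node.
## par: list per group with nodes WQ,bQ,WK,bK,WV,bV (+ theta for linear).
.attn_apply <- function(x, H, W, specs, par, mode) {
  G <- length(specs)
  widths <- vapply(specs, function(g) g$channels, integer(1))
  off <- c(0L, cumsum(widths))
  outs <- vector("list", G)
  for (i in seq_len(G)) {
    gs <- specs[[i]]
    p <- par[[i]]
    xg <- if (G == 1L) x else t_slice_cols(x, off[i] + 1L, off[i + 1L])
    si <- .sample_index(H, W, gs$S, gs$M, gs$D)
    Q <- t_linear(xg, p$WQ, p$bQ)
    xp <- t_scatter_rows(xg, .pad_map(H, W, si$Hp, si$Wp), si$Hp * si$Wp)
    samp <- t_gather_rows(xp, as.vector(si$idx))
    Kp <- t_linear(samp, p$WK, p$bK)
    Vp <- t_linear(samp, p$WV, p$bV)
    fuse <- function(z) switch(mode,
      max = t_fuse_max(z, si$Mi, si$M2, si$valid),
      mean = {
        cnt <- pmax(rowSums(si$valid), 1L)
        t_fuse_wsum(z, si$Mi, si$M2, si$valid / cnt)
      },
      linear = t_fuse_linear(z, p$theta, si$Mi, si$M2, si$valid),
      stop(sprintf("unknown fusion mode '%s'; valid modes: max, mean, linear", mode)))
    Kf <- fuse(Kp)
    Vf <- fuse(Vp)
    sc <- t_scale(t_matmul(Q, Kf, transB = TRUE), 1 / sqrt(gs$h))
    dead <- rowSums(si$valid) == 0L
    if (any(dead)) {
      sc <- t_addbias(sc, t_const(ifelse(dead, -1e30, 0)))
    }
    A <- t_softmax_rows(sc)
    outs[[i]] <- t_matmul(A, Vf)
  }
  if (G == 1L) outs[[1L]] else t_concat_cols(outs)
}
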