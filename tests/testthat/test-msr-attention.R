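# MSR-SA operator: grouping, windows, dilated sampling, fusion, attention.

test_that("split_groups slices channels evenly and round-trips", {
  x <- array(seq_len(4 * 4 * 8), c(4, 4, 8))
  gs <- split_groups(x, 2)
  expect_length(gs, 2)
  expect_equal(dim(gs[[1]]), c(4, 4, 4))
  expect_equal(gs[[1]], x[, , 1:4, drop = FALSE])
  expect_equal(gs[[2]], x[, , 5:8, drop = FALSE])
  # concatenation recovers the input exactly, for several G
  for (G in c(1, 2, 4, 8)) {
    parts <- split_groups(x, G)
    back <- array(unlist(parts), dim(x))
    expect_identical(back, x)
  }
  expect_identical(split_groups(x, 1)[[1]], x)
  expect_error(split_groups(x, 3), "not divisible")
})

test_that("dilation_rate implements D = (S-1)/(M-1) and rejects bad pairings", {
  expect_identical(dilation_rate(7, 7), 1L)
  expect_identical(dilation_rate(13, 7), 2L)
  expect_identical(dilation_rate(25, 7), 4L)
  expect_error(dilation_rate(12, 7), "not divisible")
})

test_that("partition_windows tiles, pads, and restores exactly", {
  x <- array(rnorm(14 * 14 * 3), c(14, 14, 3))
  pw <- partition_windows(x, 7)
  expect_equal(dim(pw$windows)[4], 4)
  expect_equal(pw$pad, c(0, 0))
  expect_identical(unpartition_windows(pw), x)

  x7 <- array(rnorm(7 * 7 * 2), c(7, 7, 2))
  pw7 <- partition_windows(x7, 7)
  expect_equal(dim(pw7$windows)[4], 1)

  x10 <- array(rnorm(10 * 10 * 2), c(10, 10, 2))
  pw10 <- partition_windows(x10, 7)
  expect_equal(pw10$pad, c(4, 4))
  expect_equal(dim(pw10$windows)[4], 4)
  expect_identical(unpartition_windows(pw10), x10)
  # window count is ceil(H/S) * ceil(W/S) for non-square maps too
  xr <- array(rnorm(9 * 15 * 2), c(9, 15, 2))
  pwr <- partition_windows(xr, 7)
  expect_equal(dim(pwr$windows)[4], ceiling(9 / 7) * ceiling(15 / 7))
  expect_identical(unpartition_windows(pwr), xr)
})

test_that("dilated_sample picks the arithmetic grid {0, D, ..., (M-1)D}", {
  w7 <- array(rnorm(7 * 7 * 2), c(7, 7, 2))
  expect_identical(dilated_sample(w7, 7, 1), w7)
  w13 <- array(seq_len(13 * 13), c(13, 13, 1))
  s <- dilated_sample(w13, 7, 2)
  expect_equal(dim(s), c(7, 7, 1))
  expect_equal(s[, , 1], w13[seq(1, 13, by = 2), seq(1, 13, by = 2), 1])
  expect_equal(length(s[, , 1]), 49)
  expect_error(dilated_sample(w13, 7, 1), "inconsistent")
})

test_that("cross-window fusion reduces the window axis and is symmetric", {
  # single window: max/mean return the input unchanged
  one <- array(rnorm(1 * 4 * 3), c(1, 4, 3))
  expect_equal(fuse_cross_window(one, "max"), matrix(one[1, , ], 4, 3))
  expect_equal(fuse_cross_window(one, "mean"), matrix(one[1, , ], 4, 3))
  # two windows with values 1 and 3
  two <- array(0, c(2, 2, 1)); two[1, , ] <- 1; two[2, , ] <- 3
  expect_equal(as.vector(fuse_cross_window(two, "max")), c(3, 3))
  expect_equal(as.vector(fuse_cross_window(two, "mean")), c(2, 2))
  # linear fusion is a theta-weighted sum
  expect_equal(as.vector(fuse_cross_window(two, "linear", theta = c(0.25, 0.75))),
               c(0.25 + 2.25, 0.25 + 2.25))
  expect_error(fuse_cross_window(two, "median"), "valid modes")
  # permutation invariance of max/mean, bitwise, including validity masks
  withr::with_seed(7, {
    for (r in 1:20) {
      Mi <- sample(2:6, 1)
      pf <- array(rnorm(Mi * 9 * 2), c(Mi, 9, 2))
      valid <- matrix(runif(Mi * 9) > 0.2, Mi, 9)
      valid[1, ] <- TRUE
      perm <- sample(Mi)
      for (mode in c("max", "mean")) {
        a <- fuse_cross_window(pf, mode, valid)
        b <- fuse_cross_window(pf[perm, , , drop = FALSE], mode,
                               valid[perm, , drop = FALSE])
        expect_identical(a, b)
      }
    }
  })
})

test_that("group_attention matches closed forms and a dense oracle", {
  withr::with_seed(11, {
    Q <- matrix(rnorm(10 * 4), 10, 4)
    # single key: output equals V for every query
    K1 <- matrix(rnorm(4), 1, 4); V1 <- matrix(rnorm(4), 1, 4)
    out <- group_attention(Q, K1, V1, 4)
    expect_equal(out, matrix(rep(V1, each = 10), 10, 4), tolerance = 1e-12)
    # identical keys: uniform softmax, output is the column mean of V
    K5 <- matrix(rep(rnorm(4), each = 5), 5, 4)
    V5 <- matrix(rnorm(20), 5, 4)
    out5 <- group_attention(Q, K5, V5, 4)
    expect_equal(out5, matrix(rep(colMeans(V5), each = 10), 10, 4), tolerance = 1e-10)
    # rows of the attention matrix sum to 1: implied by 2x2 oracle check
    tok <- matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2)
    W <- diag(2)
    expect_equal(group_attention(tok %*% W, tok %*% W, tok %*% W, 2),
                 oracle_dense_attention(tok, W, W, W, 2), tolerance = 1e-6)
  })
})

test_that("msr_sa_forward equals dense attention in the degenerate config", {
  withr::with_seed(13, {
    x <- array(rnorm(7 * 7 * 6), c(7, 7, 6))
    specs <- list(group_spec(6, 7, M = 7, D = 1))
    # identity projections
    tok <- x; dim(tok) <- c(49, 6)
    ref_id <- oracle_dense_attention(tok, diag(6), diag(6), diag(6), 6)
    out_id <- msr_sa_forward(x, specs)
    expect_lt(max(abs(matrix(out_id, 49, 6) - ref_id)), 1e-5)
    # random projections
    wts <- msr_sa_weights(specs, seed = 5)
    ref <- oracle_dense_attention(tok, wts[[1]]$WQ, wts[[1]]$WK, wts[[1]]$WV, 6)
    out <- msr_sa_forward(x, specs, wts)
    expect_lt(max(abs(matrix(out, 49, 6) - ref)), 1e-5)
  })
})

test_that("msr_sa_forward preserves shape and the tape path agrees with it", {
  ns <- asNamespace("msrunet")
  withr::with_seed(17, {
    cases <- list(list(H = 16, W = 16, C = 8, G = 2),
                  list(H = 10, W = 12, C = 6, G = 3),
                  list(H = 7, W = 7, C = 4, G = 1),
                  list(H = 4, W = 4, C = 8, G = 4))
    for (cs in cases) {
      x <- array(rnorm(cs$H * cs$W * cs$C), c(cs$H, cs$W, cs$C))
      specs <- msr_groups(cs$H, cs$W, cs$C, cs$G)
      wts <- msr_sa_weights(specs, seed = 2)
      for (mode in c("max", "mean")) {
        out <- msr_sa_forward(x, specs, wts, mode)
        expect_equal(dim(out), dim(x))
        par <- lapply(wts, function(w) lapply(w, ns$t_const))
        tok <- x; dim(tok) <- c(cs$H * cs$W, cs$C)
        tp <- ns$.attn_apply(ns$t_const(tok), cs$H, cs$W, specs, par, mode)
        expect_lt(max(abs(tp$value - matrix(out, cs$H * cs$W, cs$C))), 1e-10)
      }
    }
  })
})

test_that("every group samples exactly M^2 keys whatever its window size", {
  ns <- asNamespace("msrunet")
  M <- 7L
  for (D in c(1L, 2L, 3L, 4L)) {
    S <- D * (M - 1L) + 1L
    for (side in c(7L, 16L, 28L, 56L)) {
      si <- ns$.sample_index(side, side, S, M, D)
      expect_identical(si$M2, 49L)
      expect_equal(nrow(si$idx), 49L)
      # fused output has exactly M^2 rows
      pf <- array(rnorm(si$Mi * 49 * 2), c(si$Mi, 49, 2))
      expect_equal(nrow(fuse_cross_window(pf, "max", t(si$valid))), 49L)
    }
  }
})

test_that("msr_groups builds ascending clamped schedules and presets", {
  specs <- msr_groups(56, 56, 64, 4)
  expect_equal(vapply(specs, function(s) s$D, integer(1)), c(1L, 2L, 4L, 8L))
  expect_true(all(vapply(specs, function(s) s$S, integer(1)) ==
                  vapply(specs, function(s) s$D, integer(1)) * 6L + 1L))
  # clamped on a small grid
  specs16 <- msr_groups(16, 16, 64, 4)
  expect_true(all(vapply(specs16, function(s) s$S, integer(1)) <= 16))
  expect_equal(vapply(specs16, function(s) s$D, integer(1)), c(1L, 2L, 2L, 2L))
  # low: single-scale
  low <- msr_groups(56, 56, 64, 4, preset = "low")
  expect_true(all(vapply(low, function(s) s$D, integer(1)) == 1L))
  # high: one window covering the grid
  high <- msr_groups(16, 16, 64, 2, preset = "high")
  expect_true(all(vapply(high, function(s) s$S, integer(1)) >= 16))
  expect_error(msr_groups(16, 16, 62, 4), "not divisible")
  # explicit schedule overrides
  cust <- msr_groups(56, 56, 64, 2, dilations = c(3, 5))
  expect_equal(vapply(cust, function(s) s$D, integer(1)), c(3L, 5L))
})

test_that("low and default presets differ on inputs with multi-scale content", {
  withr::with_seed(19, {
    x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
    wts <- msr_sa_weights(msr_groups(16, 16, 8, 2), seed = 3)
    out_def <- msr_sa_forward(x, msr_groups(16, 16, 8, 2), wts)
    out_low <- msr_sa_forward(x, msr_groups(16, 16, 8, 2, preset = "low"), wts)
    expect_gt(max(abs(out_def - out_low)), 1e-6)
  })
})
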