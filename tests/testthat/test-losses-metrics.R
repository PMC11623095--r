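# Dice / cross-entropy / hybrid losses and DSC / HD metrics.

test_that("dice loss hits its limits and matches direct summation", {
  # perfect one-hot prediction
  g <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  p_perfect <- msrunet:::.to_onehot(as.vector(g), 2)
  expect_lt(dice_loss(p_perfect, g), 1e-4)
  # fully disjoint prediction
  p_wrong <- msrunet:::.to_onehot(1L - as.vector(g), 2)
  expect_gt(dice_loss(p_wrong, g), 1 - 1e-4)
  # hand case: K=2, 4 pixels, p = 0.5 everywhere, labels half/half
  p_half <- matrix(0.5, 4, 2)
  g_half <- c(0L, 0L, 1L, 1L)
  expect_equal(dice_loss(p_half, g_half),
               oracle_dice(p_half, msrunet:::.to_onehot(g_half, 2), c(0.5, 0.5)),
               tolerance = 1e-12)
  # random cases against the oracle, and the [0, 1] range invariant
  withr::with_seed(1, {
    for (r in 1:10) {
      N <- sample(5:40, 1); K <- sample(2:5, 1)
      z <- matrix(rexp(N * K), N, K); p <- z / rowSums(z)
      g <- sample(0:(K - 1), N, TRUE)
      cfg <- loss_config(K)
      d <- dice_loss(p, g, cfg)
      expect_equal(d, oracle_dice(p, msrunet:::.to_onehot(g, K), cfg$w),
                   tolerance = 1e-10)
      expect_gte(d, 0); expect_lte(d, 1)
    }
  })
})

test_that("cross-entropy matches closed forms and direct summation", {
  # single pixel, single-class view, g = 1, p = 0.5 -> ln 2
  expect_equal(ce_loss(matrix(0.5), matrix(1)), log(2), tolerance = 1e-9)
  # perfect prediction is ~0 after clamping
  g <- c(0L, 1L, 2L)
  expect_lt(ce_loss(msrunet:::.to_onehot(g, 3), g), 1e-5)
  withr::with_seed(2, {
    for (r in 1:10) {
      N <- sample(5:30, 1); K <- sample(2:4, 1)
      z <- matrix(rexp(N * K), N, K); p <- z / rowSums(z)
      gg <- sample(0:(K - 1), N, TRUE)
      expect_equal(ce_loss(p, gg), oracle_ce(p, msrunet:::.to_onehot(gg, K)),
                   tolerance = 1e-8)
    }
  })
})

test_that("the hybrid loss is the lambda-convex combination of its parts", {
  withr::with_seed(3, {
    N <- 20; K <- 3
    z <- matrix(rexp(N * K), N, K); p <- z / rowSums(z)
    g <- sample(0:(K - 1), N, TRUE)
    d <- dice_loss(p, g, loss_config(K)); ce <- ce_loss(p, g)
    expect_equal(hybrid_loss(p, g), 0.6 * d + 0.4 * ce, tolerance = 1e-12)
    expect_equal(hybrid_loss(p, g, loss_config(K, lambda = 1)), d, tolerance = 1e-12)
    expect_equal(hybrid_loss(p, g, loss_config(K, lambda = 0)), ce, tolerance = 1e-12)
    # monotone in lambda between its endpoints
    ls <- vapply(seq(0, 1, by = 0.1), function(l)
      hybrid_loss(p, g, loss_config(K, lambda = l)), numeric(1))
    expect_true(all(diff(ls) > 0) || all(diff(ls) < 0) || d == ce)
    expect_error(loss_config(K, lambda = 1.2), "lambda")
    expect_error(loss_config(K, w = c(1, 1, 1)), "sum to 1")
  })
})

test_that("DSC matches closed forms, is symmetric, and handles absent classes", {
  a <- matrix(0L, 8, 8); a[2:3, 2:3] <- 1L
  expect_equal(dsc_metric(a, a, 2)$per_class[["1"]], 100)
  b <- matrix(0L, 8, 8); b[6:7, 6:7] <- 1L
  expect_equal(dsc_metric(a, b, 2)$per_class[["1"]], 0)
  # two 4-pixel squares overlapping in 2 pixels: 2*2/(4+4) = 50%
  c1 <- matrix(0L, 8, 8); c1[2:3, 2:3] <- 1L
  c2 <- matrix(0L, 8, 8); c2[2:3, 3:4] <- 1L
  expect_equal(dsc_metric(c1, c2, 2)$per_class[["1"]], 50)
  expect_equal(dsc_metric(c1, c2, 2)$per_class, dsc_metric(c2, c1, 2)$per_class)
  # class absent from both masks scores 100; from exactly one, 0
  z <- matrix(0L, 8, 8)
  r <- dsc_metric(z, z, 3)
  expect_equal(unname(r$per_class), c(100, 100, 100))
  r2 <- dsc_metric(a, z, 2)
  expect_equal(r2$per_class[["1"]], 0)
  expect_error(dsc_metric(a, matrix(0L, 4, 4), 2), "shape mismatch")
})

test_that("one-hot dice loss and DSC agree", {
  withr::with_seed(4, {
    for (r in 1:5) {
      K <- 3
      pred <- matrix(sample(0:(K - 1), 100, TRUE), 10, 10)
      gt <- matrix(sample(0:(K - 1), 100, TRUE), 10, 10)
      d <- dice_loss(msrunet:::.to_onehot(as.vector(pred), K), as.vector(gt),
                     loss_config(K), eps = 0)
      ds <- dsc_metric(pred, gt, K)
      expect_equal(1 - d, mean(ds$per_class) / 100, tolerance = 1e-9)
    }
  })
})

test_that("Hausdorff distance matches closed forms and the all-pairs oracle", {
  a <- matrix(0L, 10, 10); a[3:5, 3:5] <- 1L
  expect_equal(hd_metric(a, a)$per_class[["1"]], 0)
  # two single-pixel masks 5 pixels apart on one axis
  p1 <- matrix(0L, 12, 12); p1[4, 4] <- 1L
  p2 <- matrix(0L, 12, 12); p2[9, 4] <- 1L
  expect_equal(hd_metric(p1, p2)$per_class[["1"]], 5)
  # random blob pairs: exact agreement with the brute-force oracle
  withr::with_seed(5, {
    for (r in 1:10) {
      ba <- random_blob(20, 100 + r)
      bb <- random_blob(20, 200 + r)
      m1 <- matrix(as.integer(ba), 20, 20)
      m2 <- matrix(as.integer(bb), 20, 20)
      h <- hd_metric(m1, m2)$per_class[["1"]]
      expect_equal(h, oracle_hd(ba, bb), tolerance = 1e-9)
      # symmetry
      expect_equal(h, hd_metric(m2, m1)$per_class[["1"]], tolerance = 1e-12)
      # HD95 never exceeds the classic maximum
      expect_lte(hd_metric(m1, m2, hd95 = TRUE)$per_class[["1"]], h)
    }
  })
  # physical spacing scales distances
  expect_equal(hd_metric(p1, p2, spacing = c(2, 2))$per_class[["1"]], 10)
  # empty mask: NaN sentinel with a warning, excluded from the mean
  z <- matrix(0L, 12, 12)
  expect_warning(hz <- hd_metric(p1, z), "empty")
  expect_true(is.nan(hz$per_class[["1"]]))
})

test_that("metric_report produces per-case, per-class and mean rows", {
  withr::with_seed(6, {
    gt <- matrix(0L, 16, 16); gt[4:9, 4:9] <- 1L
    pred <- matrix(0L, 16, 16); pred[5:10, 4:9] <- 1L
    f <- tempfile(fileext = ".csv")
    rep_ <- metric_report(list(pred, gt), list(gt, gt), K = 2, file = f)
    expect_true(file.exists(f))
    mean_row <- rep_[is.na(rep_$case), ]
    expect_equal(nrow(mean_row), 1)
    # case 2 is a perfect prediction
    case2 <- rep_[!is.na(rep_$case) & rep_$case == 2 & is.na(rep_$class), ]
    expect_equal(case2$dsc, 100)
    expect_equal(case2$hd, 0)
  })
})
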