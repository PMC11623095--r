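# Assembled MSR-UNet: forward geometry, schedule, training mechanics.

test_that("forward maps an image to aligned per-pixel class scores", {
  m <- smoke_model()
  withr::with_seed(1, img <- matrix(rnorm(64 * 64), 64, 64))
  lg <- msr_forward(m, img)
  expect_equal(dim(lg), c(64, 64, 4))
  expect_true(all(is.finite(lg)))
  # deterministic: identical on repeat
  expect_identical(lg, msr_forward(m, img))
  pr <- msr_predict(m, img)
  expect_equal(dim(pr), c(64, 64))
  expect_true(all(pr %in% 0:3))
  expect_error(msr_forward(m, matrix(0, 60, 60)), "divisible by 32")
  expect_error(msr_unet(side = 100), "divisible by 32")
  expect_error(msr_unet(side = 64, widths = c(15, 32, 64, 128)), "divisible")
})

test_that("the poly learning-rate schedule decays from base to zero", {
  expect_equal(poly_lr(0, 1000), 0.05)
  expect_equal(poly_lr(1000, 1000), 0)
  expect_equal(poly_lr(500, 1000, power = 1), 0.025)
  lrs <- poly_lr(0:1000, 1000)
  expect_true(all(diff(lrs) <= 0))
  expect_warning(lr <- poly_lr(1500, 1000), "clamped")
  expect_equal(lr, 0)
})

test_that("parameter count is invariant to the dilation schedule", {
  n_def <- n_params(smoke_model("default"))
  n_low <- n_params(smoke_model("low"))
  n_high <- n_params(smoke_model("high"))
  expect_equal(n_def, n_low)
  expect_equal(n_def, n_high)
})

test_that("flips and 90-degree rotations preserve per-class pixel counts", {
  ph <- generate_phantom(phantom_spec(seed = 3))
  withr::with_seed(4, {
    for (r in 1:10) {
      au <- augment_pair(ph$image, ph$mask, small_rot = FALSE)
      expect_equal(dim(au$image), dim(ph$image))
      expect_equal(table(au$mask), table(ph$mask))
    }
    # small rotations keep shapes and the label alphabet
    au2 <- augment_pair(ph$image, ph$mask, small_rot = TRUE)
    expect_equal(dim(au2$mask), dim(ph$mask))
    expect_true(all(au2$mask %in% 0:3))
  })
})

test_that("a short SGD run reduces the training loss deterministically", {
  m <- smoke_model(seed = 2)
  ds <- make_dataset(4, phantom_spec(seed = 21))
  cfg <- train_config(max_iters = 12, batch_size = 1, val_every = 12,
                      seed = 3, small_rot = FALSE)
  fit <- msr_train(m, ds, cfg)
  expect_equal(nrow(fit$log), 12)
  expect_lt(mean(tail(fit$log$loss, 3)), mean(head(fit$log$loss, 3)))
  # reproducible given the seed
  fit2 <- msr_train(m, ds, cfg)
  expect_identical(fit$log$loss, fit2$log$loss)
  expect_identical(fit$model$params$head$proj$W, fit2$model$params$head$proj$W)
  expect_error(msr_train(m, list(train = list()), cfg), "empty")
})

test_that("dice-only training ignores lambda", {
  m <- smoke_model(seed = 5)
  ds <- make_dataset(3, phantom_spec(seed = 31))
  f1 <- msr_train(m, ds, train_config(max_iters = 3, batch_size = 1,
                                      loss = "dice", lambda = 0.1, seed = 7,
                                      val_every = 10, small_rot = FALSE))
  f2 <- msr_train(m, ds, train_config(max_iters = 3, batch_size = 1,
                                      loss = "dice", lambda = 0.9, seed = 7,
                                      val_every = 10, small_rot = FALSE))
  expect_identical(f1$log$loss, f2$log$loss)
  # and dice-mode loss equals its dice component
  expect_equal(f1$log$loss, f1$log$dice, tolerance = 1e-12)
})

test_that("one optimization step sends a gradient to every parameter", {
  ns <- asNamespace("msrunet")
  m <- smoke_model(seed = 8)
  ph <- generate_phantom(phantom_spec(seed = 41))
  pn <- ns$.wrap_params(m$params)
  ti <- ns$.as_tokens(ph$image)
  out <- ns$.msr_forward_node(m, pn, ns$t_const(ti$tok), 64, 64)
  p <- ns$t_softmax_rows(out$logits)
  loss <- ns$t_seg_loss(p, msrunet:::.to_onehot(as.vector(ph$mask), 4),
                        rep(0.25, 4), 0.6)
  ns$t_backward(loss)
  for (nd in ns$.param_nodes(pn)) {
    expect_false(is.null(nd$grad))
    expect_gt(max(abs(nd$grad)), 0)
  }
})
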