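## SGD training loop with the poly learning-rate schedule.

#' Training configuration
#'
#' Defaults follow the benchmark recipe: SGD with momentum 0.9 and weight
#' decay 1e-4, initial learning rate 0.05 decayed per iteration by the poly
#' schedule, hybrid dice + cross-entropy loss with `lambda = 0.6`.
#'
#' @param max_iters total optimization iterations
#' @param batch_size cases per iteration (default 24)
#' @param base_lr initial learning rate (default 0.05)
#' @param power poly-schedule decay power (default 0.9)
#' @param momentum SGD momentum (default 0.9)
#' @param weight_decay L2 weight decay (default 1e-4)
#' @param loss `"hybrid"` (dice + cross-entropy) or `"dice"` (dice only;
#'   `lambda` is ignored)
#' @param lambda dice weight of the hybrid loss (default 0.6)
#' @param class_weights dice class weights summing to 1 (default `1/K`)
#' @param augment apply random flips and 90-degree rotations
#' @param small_rot additionally apply a random rotation within +-20 degrees
#' @param val_every evaluate held-out Dice every this many iterations
#' @param seed RNG seed controlling batching and augmentation
#' @param verbose print a progress line at every validation point
#' @return list of class `msr_train_config`
#' @export
train_config <- function(max_iters = 1000L, batch_size = 24L, base_lr = 0.05,
                         power = 0.9, momentum = 0.9, weight_decay = 1e-4,
                         loss = c("hybrid", "dice"), lambda = 0.6,
                         class_weights = NULL, augment = TRUE, small_rot = TRUE,
                         val_every = 100L, seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(max_iters >= 1, batch_size >= 1, base_lr > 0, momentum >= 0,
            weight_decay >= 0)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  structure(list(max_iters = as.integer(max_iters),
                 batch_size = as.integer(batch_size), base_lr = base_lr,
                 power = power, momentum = momentum, weight_decay = weight_decay,
                 loss = loss, lambda = lambda, class_weights = class_weights,
                 augment = augment, small_rot = small_rot,
                 val_every = as.integer(val_every), seed = as.integer(seed),
                 verbose = verbose),
            class = "msr_train_config")
}

#' Joint augmentation of an image/mask pair
#'
#' Random horizontal/vertical flips and 90-degree rotations (label-count
#' preserving), optionally followed by a small rotation within +-20 degrees
#' (bilinear for the image, nearest for the mask).  Uses the current RNG
#' stream.
#'
#' @param image numeric matrix
#' @param mask integer matrix, same shape
#' @param small_rot enable the +-20 degree rotation
#' @return list with `image` and `mask`
#' @export
augment_pair <- function(image, mask, small_rot = TRUE) {
  if (stats::runif(1) < 0.5) { image <- image[nrow(image):1, ]; mask <- mask[nrow(mask):1, ] }
  if (stats::runif(1) < 0.5) { image <- image[, ncol(image):1]; mask <- mask[, ncol(mask):1] }
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  k <- sample(0:3, 1L)
  if (k > 0) for (r in seq_len(k)) {
    image <- rot90(image)
    mask <- rot90(mask)
  }
  if (small_rot) {
    ang <- stats::runif(1, -20, 20)
    dm <- dim(image)
    img <- EBImage::rotate(EBImage::Image(image), ang, output.dim = dm,
                           bg.col = stats::median(image))
    msk <- EBImage::rotate(EBImage::Image(mask), ang, output.dim = dm,
                           filter = "none", bg.col = 0)
    image <- matrix(EBImage::imageData(img), dm[1L], dm[2L])
    mask <- matrix(as.integer(round(EBImage::imageData(msk))), dm[1L], dm[2L])
  }
  list(image = image, mask = mask)
}

#' Train an MSR-UNet with SGD
#'
#' @param model an [msr_unet()] model
#' @param data list with `train` and `val`, each a list of cases
#'   `list(image =, mask =)` (as produced by [make_dataset()])
#' @param cfg a [train_config()]
#' @return list with `model` (final weights), `best` (weights at the best
#'   validation Dice), `best_dsc`, and `log` (per-iteration data frame)
#' @export
msr_train <- function(model, data, cfg = train_config()) {
  if (!length(data$train)) stop("empty training set")
  K <- model$cfg$K
  w <- cfg$class_weights
  if (is.null(w)) w <- rep(1 / K, K)
  if (abs(sum(w) - 1) > 1e-8) stop("class weights must sum to 1")
  lambda <- if (cfg$loss == "dice") 1 else cfg$lambda

  pn <- .wrap_params(model$params)
  nodes <- .param_nodes(pn)
  vel <- lapply(nodes, function(nd) array(0, dim = if (is.null(dim(nd$value))) length(nd$value) else dim(nd$value)))

  log <- vector("list", cfg$max_iters)
  best <- NULL
  best_dsc <- -Inf
  withr::with_seed(cfg$seed, {
    for (it in seq_len(cfg$max_iters)) {
      lr <- poly_lr(it - 1L, cfg$max_iters, cfg$base_lr, cfg$power)
      ids <- sample(length(data$train), cfg$batch_size, replace = TRUE)
      loss_nodes <- vector("list", length(ids))
      dice_v <- ce_v <- numeric(length(ids))
      for (b in seq_along(ids)) {
        cs <- data$train[[ids[b]]]
        img <- cs$image; msk <- cs$mask
        if (cfg$augment) {
          au <- augment_pair(img, msk, small_rot = cfg$small_rot)
          img <- au$image; msk <- au$mask
        }
        ti <- .as_tokens(img)
        out <- .msr_forward_node(model, pn, t_const(ti$tok), ti$H, ti$W)
        p <- t_softmax_rows(out$logits)
        gmat <- .to_onehot(as.vector(msk), K)
        ln <- t_seg_loss(p, gmat, w, lambda)
        dice_v[b] <- attr(ln, "dice"); ce_v[b] <- attr(ln, "ce")
        loss_nodes[[b]] <- ln
      }
      total <- if (length(loss_nodes) == 1L) loss_nodes[[1L]] else
        t_scale(Reduce(t_add, loss_nodes), 1 / length(loss_nodes))
      if (!is.finite(total$value)) {
        stop(sprintf("non-finite loss at iteration %d (lr=%.4g); aborting", it, lr))
      }
      t_backward(total)
      for (j in seq_along(nodes)) {
        nd <- nodes[[j]]
        g <- nd$grad
        if (is.null(g)) g <- 0
        g <- g + cfg$weight_decay * nd$value
        vel[[j]] <- cfg$momentum * vel[[j]] - lr * g
        nd$value <- nd$value + vel[[j]]
        nd$grad <- NULL
      }
      row <- data.frame(iter = it, lr = lr, loss = total$value,
                        dice = mean(dice_v), ce = mean(ce_v), val_dsc = NA_real_)
      if (length(data$val) && (it %% cfg$val_every == 0L || it == cfg$max_iters)) {
        cur <- model; cur$params <- .unwrap_params(pn)
        vd <- vapply(data$val, function(cs) {
          pr <- msr_predict(cur, cs$image)
          dsc_metric(pr, cs$mask, K)$mean_fg
        }, numeric(1))
        row$val_dsc <- mean(vd)
        if (row$val_dsc >= best_dsc) {
          best_dsc <- row$val_dsc
          best <- cur$params
        }
        if (cfg$verbose) {
          message(sprintf("iter %d/%d lr %.4f loss %.4f val DSC %.2f%%",
                          it, cfg$max_iters, lr, total$value, row$val_dsc))
        }
      }
      log[[it]] <- row
    }
  })
  final <- model
  final$params <- .unwrap_params(pn)
  best_model <- model
  best_model$params <- if (is.null(best)) final$params else best
  list(model = final, best = best_model,
       best_dsc = if (is.finite(best_dsc)) best_dsc else NA_real_,
       log = do.call(rbind, log))
}
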