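## Dice, cross-entropy and hybrid segmentation losses.

#' Loss configuration
#'
#' @param K number of classes
#' @param w per-class dice weights; must sum to 1 (default `1/K`)
#' @param lambda dice weight of the hybrid loss, in `[0, 1]` (default 0.6)
#' @export
loss_config <- function(K, w = rep(1 / K, K), lambda = 0.6) {
  stopifnot(K >= 1, length(w) == K)
  if (abs(sum(w) - 1) > 1e-8) stop("class weights w must sum to 1")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  structure(list(K = as.integer(K), w = w, lambda = lambda), class = "msr_loss_config")
}

## one-hot encode an integer label vector/matrix to (N x K)
.to_onehot <- function(g, K) {
  g <- as.vector(g)
  if (any(g < 0L | g > K - 1L)) stop(sprintf("labels outside 0..%d", K - 1L))
  m <- matrix(0, length(g), K)
  m[cbind(seq_along(g), g + 1L)] <- 1
  m
}

## normalize (p, g) inputs to an (N x K) probability matrix and one-hot matrix
.pg_mats <- function(p, g, K = NULL) {
  dp <- dim(p)
  if (length(dp) == 3L) { K <- dp[3L]; dim(p) <- c(dp[1L] * dp[2L], K) }
  else if (is.null(K)) K <- ncol(p)
  gm <- if (!is.null(dim(g)) && length(dim(g)) == 2L && ncol(g) == K && all(g %in% c(0, 1)) &&
            nrow(g) == nrow(p)) g else .to_onehot(g, K)
  if (nrow(gm) != nrow(p)) {
    stop(sprintf("shape mismatch: %d predicted pixels vs %d labelled pixels",
                 nrow(p), nrow(gm)))
  }
  list(p = p, g = gm, K = K)
}

#' Dice loss
#'
#' `L = 1 - sum_k 2 w_k (sum_i p g) / (sum_i p^2 + sum_i g^2)`, with a small
#' additive smoothing `eps` in the denominator so empty classes are safe.
#' Lies in `[0, 1]` for probability inputs.
#'
#' @param p probabilities, array `H x W x K` or matrix `N x K`
#' @param g integer labels (`H x W` or length-`N`) or one-hot matrix
#' @param cfg a [loss_config()]; defaults to uniform weights
#' @param eps denominator smoothing (default 1e-5)
#' @return scalar loss
#' @export
dice_loss <- function(p, g, cfg = NULL, eps = 1e-5) {
  pg <- .pg_mats(p, g)
  if (is.null(cfg)) cfg <- loss_config(pg$K)
  stopifnot(cfg$K == pg$K)
  a <- colSums(pg$p * pg$g)
  b <- colSums(pg$p * pg$p) + colSums(pg$g * pg$g) + eps
  1 - sum(2 * cfg$w * a / b)
}

#' Binary cross-entropy loss averaged over classes and pixels
#'
#' `-(1/(N K)) sum_k sum_i [g log p + (1-g) log(1-p)]`, with probabilities
#' clamped away from 0 and 1.
#'
#' @inheritParams dice_loss
#' @param clamp probability clamp (default 1e-7)
#' @return scalar loss
#' @export
ce_loss <- function(p, g, clamp = 1e-7) {
  pg <- .pg_mats(p, g)
  pc <- pmin(pmax(pg$p, clamp), 1 - clamp)
  -sum(pg$g * log(pc) + (1 - pg$g) * log(1 - pc)) / (nrow(pc) * pg$K)
}

#' Hybrid dice + cross-entropy loss
#'
#' `lambda * L_dice + (1 - lambda) * L_ce` with default `lambda = 0.6`.
#'
#' @inheritParams dice_loss
#' @return scalar loss
#' @export
hybrid_loss <- function(p, g, cfg = NULL) {
  pg <- .pg_mats(p, g)
  if (is.null(cfg)) cfg <- loss_config(pg$K)
  cfg$lambda * dice_loss(p, g, cfg) + (1 - cfg$lambda) * ce_loss(p, g)
}
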