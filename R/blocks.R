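## Reconfiguration transformer blocks and resolution-changing layers.
##
## Tokens are stored as (N x C) matrices in column-major grid order
## (token n = h + (w-1) * H); every layer keeps the (H, W) metadata alongside.
## The `.p_*` builders create nested lists of plain numeric arrays (so models
## serialize with saveRDS); `.wrap_params()` lifts them onto the autodiff tape.

## ---- parameter builders ----------------------------------------------------

## Main-path linear layers use Glorot-style fan scaling so activation
## magnitude is preserved through unnormalized layers; residual-branch
## projections (attention Q/K/V) use the conventional 0.02 truncated normal.
.p_lin <- function(cin, cout, zero = FALSE) {
  W <- if (zero) matrix(0, cin, cout)
       else matrix(trunc_normal(cin * cout, sd = sqrt(2 / (cin + cout))), cin, cout)
  list(W = W, b = numeric(cout))
}

.p_ln <- function(c) list(g = rep(1, c), b = numeric(c))

.p_attn <- function(specs, mode, mis = NULL) {
  lapply(seq_along(specs), function(i) {
    Cg <- specs[[i]]$channels
    p <- list(WQ = matrix(trunc_normal(Cg * Cg), Cg, Cg), bQ = numeric(Cg),
              WK = matrix(trunc_normal(Cg * Cg), Cg, Cg), bK = numeric(Cg),
              WV = matrix(trunc_normal(Cg * Cg), Cg, Cg), bV = numeric(Cg))
    if (mode == "linear") {
      mi <- if (is.null(mis)) stop("linear fusion requires window counts at build time")
            else mis[i]
      p$theta <- rep(1 / mi, mi)
    }
    p
  })
}

.p_ffn <- function(c, expand = 4L) {
  ce <- c * expand
  list(fc1 = .p_lin(c, ce),
       dw = matrix(trunc_normal(9L * ce, sd = 1 / 3), 9L, ce),
       fc2 = .p_lin(ce, c))
}

.p_block <- function(c, specs, mode, mis = NULL) {
  list(ln1 = .p_ln(c), attn = .p_attn(specs, mode, mis),
       ln2 = .p_ln(c), ffn = .p_ffn(c))
}

## Lift plain-array parameter trees onto the tape.
.wrap_params <- function(p, ctor = t_param) {
  if (is.list(p)) lapply(p, .wrap_params, ctor = ctor) else ctor(p)
}

## Flatten a wrapped tree into a list of nodes (stable order).
.param_nodes <- function(pn) {
  if (inherits(pn, "msr_tensor")) return(list(pn))
  unlist(lapply(pn, .param_nodes), recursive = FALSE)
}

## Write node values back into a plain tree (same shape).
.unwrap_params <- function(pn) {
  if (inherits(pn, "msr_tensor")) return(pn$value)
  lapply(pn, .unwrap_params)
}

## ---- convolution geometry (cached) -----------------------------------------

.conv_idx <- function(H, W, k, stride, pad) {
  key <- paste0("conv_", H, "_", W, "_", k, "_", stride, "_", pad)
  if (!is.null(.tape_env[[key]])) return(.tape_env[[key]])
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  ho <- rep.int(seq_len(Ho), Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  idx <- matrix(0L, Ho * Wo, k * k)
  for (kw in seq_len(k)) {
    for (kh in seq_len(k)) {
      kp <- kh + (kw - 1L) * k
      r <- (ho - 1L) * stride + kh
      cc <- (wo - 1L) * stride + kw
      idx[, kp] <- r + (cc - 1L) * Hp
    }
  }
  res <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
              inmap = as.vector(outer(seq_len(H) + pad, (seq_len(W) + pad - 1L) * Hp, "+")))
  .tape_env[[key]] <- res
  res
}

.dw_idx <- function(H, W) {
  key <- paste0("dw_", H, "_", W)
  if (!is.null(.tape_env[[key]])) return(.tape_env[[key]])
  ci <- .conv_idx(H, W, 3L, 1L, 1L)
  res <- list(idx = ci$idx, inmap = ci$inmap, Np = ci$Hp * ci$Wp)
  .tape_env[[key]] <- res
  res
}

## ---- tape-level appliers ---------------------------------------------------

## Strided convolution as im2col + linear.  x: (H*W x Cin) token node.
.conv_apply <- function(x, H, W, k, stride, pad, par) {
  ci <- .conv_idx(H, W, k, stride, pad)
  xp <- t_scatter_rows(x, ci$inmap, ci$Hp * ci$Wp)
  a <- t_im2col(xp, ci$idx)
  list(x = t_linear(a, par$W, par$b), H = ci$Ho, W = ci$Wo)
}

.ffn_apply <- function(x, H, W, par) {
  h1 <- t_linear(x, par$fc1$W, par$fc1$b)
  di <- .dw_idx(H, W)
  hp <- t_scatter_rows(h1, di$inmap, di$Np)
  h2 <- t_gelu(t_dwconv3(hp, par$dw, di$idx))
  t_linear(h2, par$fc2$W, par$fc2$b)
}

## Pre-norm reconfiguration transformer block on a token node.
.block_apply <- function(x, H, W, specs, par, mode) {
  a <- .attn_apply(t_layernorm(x, par$ln1$g, par$ln1$b), H, W, specs, par$attn, mode)
  x <- t_add(x, a)
  f <- .ffn_apply(t_layernorm(x, par$ln2$g, par$ln2$b), H, W, par$ffn)
  t_add(x, f)
}

## ---- plain-array surfaces --------------------------------------------------

.as_tokens <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    d <- c(dim(x), 1L)
    dim(x) <- d
  }
  tok <- x
  dim(tok) <- c(d[1L] * d[2L], d[3L])
  list(tok = tok, H = d[1L], W = d[2L], C = d[3L])
}

.as_map <- function(tok, H, W) {
  out <- as.matrix(tok)
  dim(out) <- c(H, W, ncol(tok))
  out
}

#' Parameters for the overlapping patch embedding
#' @param out_channels embedding width
#' @param in_channels input image channels (default 1, grayscale)
#' @return list of plain arrays (`conv`, `ln`)
#' @export
embed_params <- function(out_channels, in_channels = 1L) {
  list(conv = .p_lin(49L * in_channels, out_channels), ln = .p_ln(out_channels))
}

#' Overlapping patch embedding
#'
#' Embeds a grayscale image into a token grid at 1/4 resolution using a
#' strided convolution with overlapping receptive fields (kernel 7, stride 4,
#' padding 3), followed by layer normalization.
#'
#' @param image numeric matrix `H x W` (or array `H x W x 1`); `H` and `W`
#'   must be divisible by 4
#' @param params from [embed_params()]; initialized with `seed` when `NULL`
#' @param out_channels embedding width used when `params` is `NULL`
#' @param seed RNG seed for default initialization
#' @return numeric array `H/4 x W/4 x out_channels`
#' @export
overlap_patch_embed <- function(image, params = NULL, out_channels = 64L, seed = 1L) {
  ti <- .as_tokens(image)
  if (ti$H %% 4L != 0L || ti$W %% 4L != 0L) {
    stop(sprintf("image extent %dx%d is not divisible by 4; pad or resize the input",
                 ti$H, ti$W))
  }
  if (is.null(params)) params <- withr::with_seed(seed, embed_params(out_channels, ti$C))
  pn <- .wrap_params(params, t_const)
  cv <- .conv_apply(t_const(ti$tok), ti$H, ti$W, 7L, 4L, 3L, pn$conv)
  out <- t_layernorm(cv$x, pn$ln$g, pn$ln$b)
  .as_map(out$value, cv$H, cv$W)
}

#' Parameters for a reconfiguration transformer block
#' @param channels token width
#' @param specs list of [group_spec()] for the MSR-SA stage
#' @param mode fusion mode
#' @param mis per-group window counts (required for `mode = "linear"`)
#' @return nested list of plain arrays
#' @export
block_params <- function(channels, specs, mode = "max", mis = NULL) {
  .p_block(channels, specs, mode, mis)
}

#' Reconfiguration transformer block
#'
#' Pre-norm residual block: `x + MSR-SA(LN(x))` then `x + FFN(LN(x))`, where
#' the feed-forward expands 4x, applies a 3x3 depthwise convolution on the
#' spatial grid, GELU, and contracts back.
#'
#' @param x numeric array `H x W x C`
#' @param specs list of [group_spec()] valid for `(H, W, C)`
#' @param params from [block_params()]; initialized with `seed` when `NULL`
#' @param mode cross-window fusion mode
#' @param seed RNG seed for default initialization
#' @return numeric array with the shape of `x`
#' @export
reconfig_block <- function(x, specs, params = NULL, mode = "max", seed = 1L) {
  ti <- .as_tokens(x)
  widths <- vapply(specs, function(g) g$channels, integer(1))
  if (sum(widths) != ti$C) {
    stop(sprintf("group channel widths sum to %d but the map has C=%d channels",
                 sum(widths), ti$C))
  }
  if (is.null(params)) params <- withr::with_seed(seed, block_params(ti$C, specs, mode))
  pn <- .wrap_params(params, t_const)
  out <- .block_apply(t_const(ti$tok), ti$H, ti$W, specs, pn, mode)
  .as_map(out$value, ti$H, ti$W)
}

#' Parameters for a patch-merging layer
#' @param in_channels,out_channels widths before/after merging
#' @export
merge_params <- function(in_channels, out_channels) {
  list(conv = .p_lin(9L * in_channels, out_channels), ln = .p_ln(out_channels))
}

#' Overlapping patch merging (2x downsampling)
#'
#' Strided convolution (kernel 3, stride 2, padding 1) followed by layer
#' normalization; halves the spatial extent and widens channels.
#'
#' @param x numeric array `H x W x C` with even `H`, `W`
#' @param params from [merge_params()]; initialized with `seed` when `NULL`
#' @param out_channels target width when `params` is `NULL` (default `2 C`)
#' @param seed RNG seed for default initialization
#' @return numeric array `H/2 x W/2 x out_channels`
#' @export
patch_merge <- function(x, params = NULL, out_channels = NULL, seed = 1L) {
  ti <- .as_tokens(x)
  if (ti$H %% 2L != 0L || ti$W %% 2L != 0L) {
    stop(sprintf("cannot merge odd extent %dx%d", ti$H, ti$W))
  }
  if (is.null(out_channels)) out_channels <- 2L * ti$C
  if (is.null(params)) params <- withr::with_seed(seed, merge_params(ti$C, out_channels))
  pn <- .wrap_params(params, t_const)
  cv <- .conv_apply(t_const(ti$tok), ti$H, ti$W, 3L, 2L, 1L, pn$conv)
  out <- t_layernorm(cv$x, pn$ln$g, pn$ln$b)
  .as_map(out$value, cv$H, cv$W)
}

#' Parameters for a patch-expanding layer
#' @param in_channels,out_channels widths before/after expansion
#' @export
expand_params <- function(in_channels, out_channels) {
  list(lin = .p_lin(in_channels, 4L * out_channels))
}

#' Patch expanding (2x upsampling)
#'
#' Linear width adjustment to `4 * out_channels` followed by channel-to-space
#' rearrangement: doubles the spatial extent, halves the channel width (by
#' default).
#'
#' @param x numeric array `H x W x C`
#' @param params from [expand_params()]; initialized with `seed` when `NULL`
#' @param out_channels target width when `params` is `NULL` (default `C / 2`)
#' @param seed RNG seed for default initialization
#' @return numeric array `2H x 2W x out_channels`
#' @export
patch_expand <- function(x, params = NULL, out_channels = NULL, seed = 1L) {
  ti <- .as_tokens(x)
  if (is.null(out_channels)) out_channels <- max(1L, ti$C %/% 2L)
  if (is.null(params)) params <- withr::with_seed(seed, expand_params(ti$C, out_channels))
  pn <- .wrap_params(params, t_const)
  h <- t_linear(t_const(ti$tok), pn$lin$W, pn$lin$b)
  out <- t_depth_to_space(h, ti$H, ti$W, 2L)
  .as_map(out$value, 2L * ti$H, 2L * ti$W)
}

#' Parameters for the segmentation head
#' @param channels decoder output width
#' @param K number of classes
#' @export
head_params <- function(channels, K) {
  list(up = .p_lin(channels, 16L * channels), proj = .p_lin(channels, K))
}

#' Final 4x expansion and pixel-level projection
#'
#' Expands stage-1 tokens back to full image resolution (channel-to-space,
#' factor 4) and projects each pixel to `K` unnormalized class scores.
#'
#' @param x numeric array `H x W x C` (tokens at 1/4 image resolution)
#' @param K number of classes
#' @param params from [head_params()]; initialized with `seed` when `NULL`
#' @param seed RNG seed for default initialization
#' @return numeric array `4H x 4W x K` of logits
#' @export
final_expand_project <- function(x, K, params = NULL, seed = 1L) {
  ti <- .as_tokens(x)
  if (is.null(params)) params <- withr::with_seed(seed, head_params(ti$C, K))
  pn <- .wrap_params(params, t_const)
  h <- t_linear(t_const(ti$tok), pn$up$W, pn$up$b)
  h <- t_depth_to_space(h, ti$H, ti$W, 4L)
  out <- t_linear(h, pn$proj$W, pn$proj$b)
  .as_map(out$value, 4L * ti$H, 4L * ti$W)
}

## Tape-level head applier (shared with the assembled model).
.head_apply <- function(x, H, W, K, par) {
  h <- t_linear(x, par$up$W, par$up$b)
  h <- t_depth_to_space(h, H, W, 4L)
  t_linear(h, par$proj$W, par$proj$b)
}
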