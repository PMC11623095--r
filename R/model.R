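## MSR-UNet: hierarchical encoder (overlapping embed -> [blocks -> merge] x4),
## context bridge, decoder (expand -> skip concat -> blocks) and segmentation
## head.  Models are plain nested lists of numeric arrays (saveRDS-able).

#' Build an MSR-UNet model
#'
#' @param side input image side in pixels; must be divisible by 32 (one 4x
#'   embedding plus three 2x merges)
#' @param K number of segmentation classes (background included)
#' @param widths per-stage channel widths (4 encoder stages)
#' @param depths per-stage block depths
#' @param groups per-stage MSR-SA group counts; each width must be divisible
#'   by its group count
#' @param M sample-grid side of MSR-SA (default 7)
#' @param preset dilation preset: `"default"` (ascending `D_i = 2^(i-1)`,
#'   clamped to the grid), `"low"` (all `D_i = 1`), `"high"` (one window
#'   covering the grid)
#' @param fusion cross-window fusion mode (`"max"`, `"mean"`, `"linear"`)
#' @param bridge_d context-bridge loop count (default 4)
#' @param bridge_groups group count at the bridge width (default: last stage's)
#' @param seed RNG seed for weight initialization
#' @return object of class `msr_unet`
#' @export
msr_unet <- function(side = 224L, K = 9L,
                     widths = c(64L, 128L, 320L, 512L),
                     depths = c(2L, 2L, 2L, 2L),
                     groups = c(1L, 2L, 5L, 8L),
                     M = 7L, preset = "default", fusion = "max",
                     bridge_d = 4L, bridge_groups = groups[4L], seed = 1L) {
  if (side %% 32L != 0L) {
    stop(sprintf("input side %d is not divisible by 32", side))
  }
  stopifnot(length(widths) == 4L, length(depths) == 4L, length(groups) == 4L,
            all(depths >= 1L))
  if (any(widths %% groups != 0L)) {
    stop("every stage width must be divisible by its group count")
  }
  grid <- side %/% (4L * 2L^(0:3))
  dims <- lapply(grid, function(g) c(g, g))
  specs <- lapply(1:4, function(s) {
    msr_groups(grid[s], grid[s], widths[s], groups[s], M = M, preset = preset)
  })
  mis <- function(s) vapply(specs[[s]], function(gs) {
    .sample_index(grid[s], grid[s], gs$S, gs$M, gs$D)$Mi
  }, integer(1))
  params <- withr::with_seed(seed, {
    list(
      embed = embed_params(widths[1L]),
      enc = lapply(1:4, function(s) {
        list(blocks = lapply(seq_len(depths[s]), function(b) {
          .p_block(widths[s], specs[[s]], fusion,
                   mis = if (fusion == "linear") mis(s) else NULL)
        }))
      }),
      merge = lapply(1:3, function(s) merge_params(widths[s], widths[s + 1L])),
      bridge = .p_bridge(widths, bridge_d, bridge_groups, M, fusion,
                         dims = dims, preset = preset),
      dec = lapply(3:1, function(s) {
        list(expand = expand_params(widths[s + 1L], widths[s]),
             fuse = .p_lin(2L * widths[s], widths[s]),
             blocks = lapply(seq_len(depths[s]), function(b) {
               .p_block(widths[s], specs[[s]], fusion,
                        mis = if (fusion == "linear") mis(s) else NULL)
             }))
      }),
      head = head_params(widths[1L], K)
    )
  })
  structure(list(
    cfg = list(side = as.integer(side), K = as.integer(K),
               widths = as.integer(widths), depths = as.integer(depths),
               groups = as.integer(groups), M = as.integer(M),
               preset = preset, fusion = fusion,
               bridge_d = as.integer(bridge_d),
               bridge_groups = as.integer(bridge_groups), seed = as.integer(seed)),
    params = params), class = "msr_unet")
}

## Tape-level full forward.  pn: wrapped parameter tree; tok: (H*W x 1) image
## token node.  Returns the logits node plus geometry.
.msr_forward_node <- function(model, pn, tok, H, W) {
  cfg <- model$cfg
  if (H %% 32L != 0L || W %% 32L != 0L) {
    stop(sprintf("input extent %dx%d is not divisible by 32; pad to %dx%d",
                 H, W, 32L * ceiling(H / 32L), 32L * ceiling(W / 32L)))
  }
  if (cfg$fusion == "linear" && (H != cfg$side || W != cfg$side)) {
    stop("a linear-fusion model is bound to its build-time input side")
  }
  cv <- .conv_apply(tok, H, W, 7L, 4L, 3L, pn$embed$conv)
  x <- t_layernorm(cv$x, pn$embed$ln$g, pn$embed$ln$b)
  hs <- cv$H; ws <- cv$W
  skips <- vector("list", 4L)
  dims <- vector("list", 4L)
  specs_s <- vector("list", 4L)
  for (s in 1:4) {
    specs_s[[s]] <- msr_groups(hs, ws, cfg$widths[s], cfg$groups[s],
                               M = cfg$M, preset = cfg$preset)
    for (bp in pn$enc[[s]]$blocks) {
      x <- .block_apply(x, hs, ws, specs_s[[s]], bp, cfg$fusion)
    }
    skips[[s]] <- x
    dims[[s]] <- c(hs, ws)
    if (s < 4L) {
      mg <- .conv_apply(x, hs, ws, 3L, 2L, 1L, pn$merge[[s]]$conv)
      x <- t_layernorm(mg$x, pn$merge[[s]]$ln$g, pn$merge[[s]]$ln$b)
      hs <- mg$H; ws <- mg$W
    }
  }
  ref <- .bridge_apply(skips, dims, cfg$widths, pn$bridge, cfg$bridge_groups,
                       cfg$M, cfg$preset, cfg$fusion)
  x <- ref[[4L]]
  for (k in seq_along(pn$dec)) {           # decoder stages 3, 2, 1
    s <- 4L - k
    dp <- pn$dec[[k]]
    x <- t_linear(x, dp$expand$lin$W, dp$expand$lin$b)
    x <- t_depth_to_space(x, dims[[s + 1L]][1L], dims[[s + 1L]][2L], 2L)
    x <- t_concat_cols(list(x, ref[[s]]))
    x <- t_linear(x, dp$fuse$W, dp$fuse$b)
    for (bp in dp$blocks) {
      x <- .block_apply(x, dims[[s]][1L], dims[[s]][2L], specs_s[[s]], bp, cfg$fusion)
    }
  }
  logits <- .head_apply(x, dims[[1L]][1L], dims[[1L]][2L], cfg$K, pn$head)
  list(logits = logits, H = 4L * dims[[1L]][1L], W = 4L * dims[[1L]][2L])
}

#' MSR-UNet forward pass
#'
#' @param model an [msr_unet()] model
#' @param image numeric matrix `H x W` (grayscale), `H`, `W` divisible by 32
#' @return numeric array `H x W x K` of unnormalized class scores
#' @export
msr_forward <- function(model, image) {
  ti <- .as_tokens(image)
  pn <- .wrap_params(model$params, t_const)
  out <- .msr_forward_node(model, pn, t_const(ti$tok), ti$H, ti$W)
  .as_map(out$logits$value, out$H, out$W)
}

#' Predict a label mask
#'
#' @param model an [msr_unet()] model
#' @param image numeric matrix `H x W`
#' @return integer matrix `H x W` of labels in `0..K-1`
#' @export
msr_predict <- function(model, image) {
  lg <- msr_forward(model, image)
  d <- dim(lg)
  lm <- lg; dim(lm) <- c(d[1L] * d[2L], d[3L])
  lab <- max.col(lm, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1L], d[2L])
}

#' Count trainable parameters
#' @param model an [msr_unet()] model
#' @return integer total number of scalar parameters
#' @export
n_params <- function(model) {
  leaves <- .param_leaves(model$params)
  sum(vapply(leaves, length, numeric(1)))
}

.param_leaves <- function(p) {
  if (is.numeric(p)) return(list(p))
  unlist(lapply(p, .param_leaves), recursive = FALSE)
}

#' Zero all residual-branch outputs (test harness)
#'
#' Sets every attention value projection and every feed-forward output layer
#' to zero, and replaces the bridge adapters by exact identity embed/project
#' pairs, so each reconfiguration block and the bridge become identities.
#'
#' @param model an [msr_unet()] model
#' @return the modified model
#' @export
zero_branches <- function(model) {
  zero_block <- function(bp) {
    bp$attn <- lapply(bp$attn, function(a) {
      a$WV[] <- 0; a$bV[] <- 0; a
    })
    bp$ffn$fc2$W[] <- 0; bp$ffn$fc2$b[] <- 0
    bp
  }
  p <- model$params
  for (s in 1:4) p$enc[[s]]$blocks <- lapply(p$enc[[s]]$blocks, zero_block)
  for (k in seq_along(p$dec)) p$dec[[k]]$blocks <- lapply(p$dec[[k]]$blocks, zero_block)
  p$bridge$blocks <- lapply(p$bridge$blocks, zero_block)
  Cc <- max(model$cfg$widths)
  for (s in seq_along(p$bridge$ain)) {
    w <- nrow(p$bridge$ain[[s]]$W)
    Win <- matrix(0, w, Cc); diag(Win[seq_len(w), seq_len(w)]) <- 1
    Wout <- matrix(0, Cc, w); diag(Wout[seq_len(w), seq_len(w)]) <- 1
    p$bridge$ain[[s]]$W <- Win;  p$bridge$ain[[s]]$b[] <- 0
    p$bridge$aout[[s]]$W <- Wout; p$bridge$aout[[s]]$b[] <- 0
  }
  model$params <- p
  model
}

#' Poly learning-rate schedule
#'
#' `eta = base * (1 - t/total)^power`; monotone non-increasing in `t`.
#'
#' @param t current step (0-based), `0 <= t <= total`
#' @param total total number of steps
#' @param base initial learning rate (default 0.05)
#' @param power polynomial decay power (default 0.9)
#' @return learning rate(s); steps beyond `total` clamp to 0 with a warning
#' @export
poly_lr <- function(t, total, base = 0.05, power = 0.9) {
  stopifnot(total > 0, base > 0, all(t >= 0))
  if (any(t > total)) {
    warning(sprintf("step beyond schedule end (t > %d); learning rate clamped to 0", total))
    t <- pmin(t, total)
  }
  base * (1 - t / total)^power
}
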