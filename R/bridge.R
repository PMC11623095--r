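## Reconfiguration transformer context bridge.
##
## Encoder stage maps are projected to a common channel width, flattened and
## concatenated along tokens, refined by d reconfiguration transformer blocks
## (attention windows are defined on each stage's own 2D grid; the pointwise
## layers and shared weights couple the stages), then split and restored to
## the original per-stage shapes.

#' Bridge configuration
#' @param d number of reconfiguration blocks applied to the packed sequence
#'   (default 4); the blocks are distinct (no weight sharing across loops)
#' @export
bridge_config <- function(d = 4L) {
  stopifnot(d >= 1)
  structure(list(d = as.integer(d)), class = "msr_bridge_config")
}

#' Pack a list of stage maps into one token sequence
#'
#' @param stage_maps list of numeric arrays `H_s x W_s x C` (equal `C`)
#' @return list with `tokens` (`sum(H_s W_s) x C` matrix) and `plan` (per-stage
#'   `H`, `W`, `C`), sufficient to invert the packing
#' @export
bridge_pack <- function(stage_maps) {
  if (!length(stage_maps)) stop("bridge_pack needs at least one stage map")
  tis <- lapply(stage_maps, .as_tokens)
  cs <- vapply(tis, function(t) t$C, integer(1))
  if (length(unique(cs)) != 1L) {
    stop(sprintf("stage maps must share a channel width; got %s",
                 paste(cs, collapse = ", ")))
  }
  list(tokens = do.call(rbind, lapply(tis, function(t) t$tok)),
       plan = lapply(tis, function(t) list(H = t$H, W = t$W, C = t$C)))
}

#' Invert [bridge_pack()]
#' @param tokens packed token matrix
#' @param plan split plan from [bridge_pack()]
#' @return list of stage maps with their original shapes
#' @export
bridge_unpack <- function(tokens, plan) {
  ns <- vapply(plan, function(p) p$H * p$W, integer(1))
  if (nrow(tokens) != sum(ns)) {
    stop(sprintf("packed length %d does not match plan total %d",
                 nrow(tokens), sum(ns)))
  }
  ends <- cumsum(ns); starts <- ends - ns + 1L
  lapply(seq_along(plan), function(s) {
    .as_map(tokens[starts[s]:ends[s], , drop = FALSE], plan[[s]]$H, plan[[s]]$W)
  })
}

## Bridge parameters: per-stage in/out adapters to the common width plus d
## blocks whose attention/FFN weights are shared across stages (the block acts
## on the packed sequence; only the window geometry is per-stage).
.p_bridge <- function(widths, d, G, M, mode, dims = NULL, preset = "default") {
  Cc <- max(widths)
  if (Cc %% G != 0L) {
    stop(sprintf("bridge width %d is not divisible by bridge group count %d", Cc, G))
  }
  blocks <- lapply(seq_len(d), function(b) {
    bp <- .p_block(Cc, msr_groups(64L, 64L, Cc, G, M = M), mode = if (mode == "linear") "max" else mode)
    if (mode == "linear") {
      if (is.null(dims)) stop("linear fusion requires stage dims at build time")
      bp$theta <- lapply(dims, function(dm) {
        specs <- msr_groups(dm[1L], dm[2L], Cc, G, M = M, preset = preset)
        lapply(specs, function(gs) {
          si <- .sample_index(dm[1L], dm[2L], gs$S, gs$M, gs$D)
          rep(1 / si$Mi, si$Mi)
        })
      })
    }
    bp
  })
  list(ain = lapply(widths, function(w) .p_lin(w, Cc)),
       blocks = blocks,
       aout = lapply(widths, function(w) .p_lin(Cc, w)))
}

#' Parameters for a standalone context bridge
#' @param widths per-stage channel widths
#' @param d loop count
#' @param G attention group count at the common width
#' @param M sample-grid side
#' @param mode fusion mode
#' @param dims list of per-stage `c(H, W)` (needed for `mode = "linear"`)
#' @param preset dilation preset
#' @export
bridge_params <- function(widths, d = 4L, G = 1L, M = 7L, mode = "max",
                          dims = NULL, preset = "default") {
  .p_bridge(widths, d, G, M, mode, dims, preset)
}

## Tape-level bridge.  xs: list of stage token nodes; dims: list of c(H, W);
## widths: per-stage channel widths.
.bridge_apply <- function(xs, dims, widths, par, G, M, preset, mode, dilations = NULL) {
  S <- length(xs)
  Cc <- max(widths)
  specs_s <- lapply(seq_len(S), function(s) {
    msr_groups(dims[[s]][1L], dims[[s]][2L], Cc, G, M = M, preset = preset,
               dilations = dilations)
  })
  ys <- lapply(seq_len(S), function(s) {
    t_linear(xs[[s]], par$ain[[s]]$W, par$ain[[s]]$b)
  })
  for (b in seq_along(par$blocks)) {
    bp <- par$blocks[[b]]
    for (s in seq_len(S)) {
      attn_par <- bp$attn
      if (mode == "linear") {
        for (g in seq_along(attn_par)) attn_par[[g]]$theta <- bp$theta[[s]][[g]]
      }
      a <- .attn_apply(t_layernorm(ys[[s]], bp$ln1$g, bp$ln1$b),
                       dims[[s]][1L], dims[[s]][2L], specs_s[[s]], attn_par, mode)
      ys[[s]] <- t_add(ys[[s]], a)
    }
    for (s in seq_len(S)) {
      f <- .ffn_apply(t_layernorm(ys[[s]], bp$ln2$g, bp$ln2$b),
                      dims[[s]][1L], dims[[s]][2L], bp$ffn)
      ys[[s]] <- t_add(ys[[s]], f)
    }
  }
  lapply(seq_len(S), function(s) {
    t_linear(ys[[s]], par$aout[[s]]$W, par$aout[[s]]$b)
  })
}

#' Context-bridge forward pass
#'
#' Projects every stage map to the common width (the widest stage), refines
#' the packed token sequence with `d` reconfiguration transformer blocks, and
#' restores the original per-stage shapes.
#'
#' @param stage_maps list of numeric arrays `H_s x W_s x C_s`
#' @param params from [bridge_params()]; initialized with `seed` when `NULL`
#' @param d loop count used when `params` is `NULL`
#' @param G attention group count at the common width
#' @param M sample-grid side
#' @param preset dilation preset
#' @param mode fusion mode
#' @param seed RNG seed for default initialization
#' @return list of refined stage maps, shapes identical to the input
#' @export
bridge_forward <- function(stage_maps, params = NULL, d = 4L, G = 1L, M = 7L,
                           preset = "default", mode = "max", seed = 1L) {
  if (!length(stage_maps)) stop("bridge_forward needs at least one stage map")
  tis <- lapply(stage_maps, .as_tokens)
  widths <- vapply(tis, function(t) t$C, integer(1))
  dims <- lapply(tis, function(t) c(t$H, t$W))
  if (is.null(params)) {
    params <- withr::with_seed(seed, bridge_params(widths, d, G, M, mode, dims, preset))
  }
  if (length(params$ain) != length(stage_maps)) {
    stop(sprintf("bridge was built for %d stages but received %d",
                 length(params$ain), length(stage_maps)))
  }
  pn <- .wrap_params(params, t_const)
  xs <- lapply(tis, function(t) t_const(t$tok))
  ys <- .bridge_apply(xs, dims, widths, pn, G, M, preset, mode)
  lapply(seq_along(ys), function(s) .as_map(ys[[s]]$value, dims[[s]][1L], dims[[s]][2L]))
}
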