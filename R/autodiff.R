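## Reverse-mode automatic differentiation over plain R arrays.
##
## A tensor node is an environment holding a value, an optional gradient, the
## parent nodes it was computed from, and a closure that maps the incoming
## gradient to per-parent gradients.  Graphs are built eagerly by the t_*
## operations below and differentiated by `t_backward()`.  Values are base-R
## matrices/arrays so all heavy lifting lands in BLAS.

.tape_env <- new.env(parent = emptyenv())
.tape_env$next_id <- 1L

## fast row-broadcast helpers (column-major layout: element (i, j) pairs with v[j])
.addrow <- function(x, v) x + rep(v, each = nrow(x))
.mulrow <- function(x, v) x * rep(v, each = nrow(x))
.rowmax <- function(x) x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

new_tensor <- function(value, parents = list(), bwd = NULL, requires = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$visit <- NULL
  nd$parents <- parents
  nd$bwd <- bwd
  nd$requires <- requires || any(vapply(parents, function(p) p$requires, logical(1)))
  nd$id <- .tape_env$next_id
  .tape_env$next_id <- .tape_env$next_id + 1L
  class(nd) <- "msr_tensor"
  nd
}

#' Create a constant (non-differentiated) tensor node
#' @param value numeric array/matrix/vector
#' @keywords internal
t_const <- function(value) new_tensor(value)

#' Create a trainable parameter node
#' @param value numeric array/matrix/vector
#' @keywords internal
t_param <- function(value) new_tensor(value, requires = TRUE)

t_value <- function(x) if (inherits(x, "msr_tensor")) x$value else x

## Accumulate gradient g into node nd.
.acc_grad <- function(nd, g) {
  if (!nd$requires) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar root node
#'
#' Fills `$grad` on every upstream node with `requires = TRUE`.
#' @param root tensor node holding a scalar value
#' @keywords internal
t_backward <- function(root) {
  stopifnot(inherits(root, "msr_tensor"), length(root$value) == 1L)
  ## iterative topological order (DFS post-order); nodes are marked visited
  ## with a per-run tag so repeated backward passes stay cheap
  run <- .tape_env$next_id
  .tape_env$next_id <- run + 1L
  order <- vector("list", 256L)
  n_ord <- 0L
  stack <- list(list(nd = root, i = 0L))
  root$visit <- run
  while (length(stack)) {
    top <- stack[[length(stack)]]
    nd <- top$nd
    if (top$i < length(nd$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      p <- nd$parents[[top$i + 1L]]
      if (p$requires && !identical(p$visit, run)) {
        p$visit <- run
        stack[[length(stack) + 1L]] <- list(nd = p, i = 0L)
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- nd
      stack[[length(stack)]] <- NULL
    }
  }
  root$grad <- array(1, dim = if (is.null(dim(root$value))) 1L else dim(root$value))
  for (k in seq(n_ord, 1L)) {
    nd <- order[[k]]
    if (is.null(nd$bwd) || is.null(nd$grad)) next
    gs <- nd$bwd(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) .acc_grad(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(root)
}

## ---- elementwise and linear-algebra primitives -----------------------------

t_add <- function(a, b) {
  new_tensor(a$value + b$value, list(a, b), function(g) list(g, g))
}

t_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  new_tensor(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

t_scale <- function(a, s) {
  new_tensor(a$value * s, list(a), function(g) list(g * s))
}

## X + row-broadcast bias (b has length ncol(X))
t_addbias <- function(x, b) {
  xv <- x$value
  new_tensor(.addrow(xv, b$value), list(x, b),
             function(g) list(g, colSums(g)))
}

## matrix product with optional transposes
t_matmul <- function(a, b, transA = FALSE, transB = FALSE) {
  av <- a$value; bv <- b$value
  v <- if (!transA && !transB) av %*% bv
       else if (!transA && transB) tcrossprod(av, bv)
       else if (transA && !transB) crossprod(av, bv)
       else t(bv %*% av)
  new_tensor(v, list(a, b), function(g) {
    if (!transA && !transB) list(tcrossprod(g, bv), crossprod(av, g))
    else if (!transA && transB) list(g %*% bv, crossprod(g, av))
    else if (transA && !transB) list(tcrossprod(bv, g), av %*% g)
    else list(t(bv) %*% t(g), t(g) %*% t(av))
  })
}

## X W + b with W (Cin x Cout), b length Cout (bias optional)
t_linear <- function(x, w, b = NULL) {
  out <- t_matmul(x, w)
  if (is.null(b)) out else t_addbias(out, b)
}

t_gelu <- function(x) {
  xv <- x$value
  ph <- stats::pnorm(xv)
  new_tensor(xv * ph, list(x), function(g) list(g * (ph + xv * stats::dnorm(xv))))
}

t_softmax_rows <- function(x) {
  xv <- x$value
  n <- nrow(xv); k <- ncol(xv)
  e <- exp(xv - .rowmax(xv))
  p <- e / .rowSums(e, n, k)
  new_tensor(p, list(x), function(g) list(p * (g - .rowSums(g * p, n, k))))
}

t_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  n <- nrow(xv); k <- ncol(xv)
  mu <- .rowMeans(xv, n, k)
  xc <- xv - mu
  inv <- 1 / sqrt(.rowMeans(xc * xc, n, k) + eps)
  xhat <- xc * inv
  gv <- gamma$value
  y <- .addrow(.mulrow(xhat, gv), beta$value)
  new_tensor(y, list(x, gamma, beta), function(g) {
    dxhat <- .mulrow(g, gv)
    dx <- inv * (dxhat - .rowMeans(dxhat, n, k) - xhat * .rowMeans(dxhat * xhat, n, k))
    list(dx, colSums(g * xhat), colSums(g))
  })
}

## ---- indexing / reshaping primitives ---------------------------------------

## Select rows (duplicates allowed); gradient scatter-adds.
t_gather_rows <- function(x, idx) {
  xv <- x$value
  n <- nrow(xv)
  new_tensor(cpp_gather_rows(xv, idx), list(x), function(g) {
    list(cpp_scatter_add_rows(g, idx, n))
  })
}

## Scatter rows of x into a zero matrix of nrow_out rows (idx must be unique).
t_scatter_rows <- function(x, idx, nrow_out) {
  xv <- x$value
  v <- matrix(0, nrow_out, ncol(xv))
  v[idx, ] <- xv
  new_tensor(v, list(x), function(g) list(g[idx, , drop = FALSE]))
}

t_concat_cols <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  ncs <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncs)
  starts <- ends - ncs + 1L
  new_tensor(do.call(cbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

t_concat_rows <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  nrs <- vapply(vals, nrow, integer(1))
  ends <- cumsum(nrs)
  starts <- ends - nrs + 1L
  new_tensor(do.call(rbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(j) g[starts[j]:ends[j], , drop = FALSE])
  })
}

t_slice_rows <- function(x, from, to) {
  xv <- x$value
  n <- nrow(xv)
  new_tensor(xv[from:to, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, n, ncol(xv))
    gx[from:to, ] <- g
    list(gx)
  })
}

t_slice_cols <- function(x, from, to) {
  xv <- x$value
  new_tensor(xv[, from:to, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[, from:to] <- g
    list(gx)
  })
}

## im2col as one op: xp is (Np x Cin) padded token matrix, idx (Nout x k2)
## token indices.  Output (Nout x k2*Cin), columns ordered kernel-position
## fastest within each input channel.
t_im2col <- function(xp, idx) {
  xv <- xp$value
  np <- nrow(xv); cin <- ncol(xv)
  nout <- nrow(idx); k2 <- ncol(idx)
  iv <- as.vector(idx)                       # (n,k) pairs, n fastest
  a <- cpp_gather_rows(xv, iv)               # (Nout*k2) x Cin
  dim(a) <- c(nout, k2 * cin)
  new_tensor(a, list(xp), function(g) {
    dim(g) <- c(nout * k2, cin)
    list(cpp_scatter_add_rows(g, iv, np))
  })
}

## Depth-to-space: tokens (H*W x r^2*Cout) -> tokens (H*r * W*r x Cout).
## Input channel layout: c_in = dh + (dw-1)*r + (c-1)*r^2 (dh, dw in 1..r).
t_depth_to_space <- function(x, H, W, r) {
  xv <- x$value
  cout <- ncol(xv) / (r * r)
  stopifnot(cout == round(cout))
  perm <- .d2s_perm(H, W, r, as.integer(cout))
  v <- as.vector(xv)[perm]
  dim(v) <- c(H * r * W * r, cout)
  new_tensor(v, list(x), function(g) {
    gx <- numeric(length(g))
    gx[perm] <- as.vector(g)
    dim(gx) <- dim(xv)
    list(gx)
  })
}

## Linear index permutation for depth-to-space (cached per geometry).
.d2s_perm <- function(H, W, r, cout) {
  key <- paste0("d2s_", H, "_", W, "_", r, "_", cout)
  if (!is.null(.tape_env[[key]])) return(.tape_env[[key]])
  H2 <- H * r; W2 <- W * r
  ## output element (h2, w2, c): source token n1 = h + (w-1)H,
  ## source column c_in = dh + (dw-1)r + (c-1)r^2
  h2 <- rep.int(seq_len(H2), times = W2 * cout)
  w2 <- rep.int(rep(seq_len(W2), each = H2), times = cout)
  cc <- rep(seq_len(cout), each = H2 * W2)
  h <- (h2 - 1L) %/% r + 1L; dh <- (h2 - 1L) %% r + 1L
  w <- (w2 - 1L) %/% r + 1L; dw <- (w2 - 1L) %% r + 1L
  n1 <- h + (w - 1L) * H
  cin <- dh + (dw - 1L) * r + (cc - 1L) * r * r
  perm <- n1 + (cin - 1L) * (H * W)
  .tape_env[[key]] <- perm
  perm
}

## ---- cross-window fusion primitives ----------------------------------------
## x: (Mi*M2 x C) rows ordered sample-position fastest (row = m + (j-1)*M2).
## valid: logical (M2 x Mi); padded sample positions are excluded.

t_fuse_max <- function(x, Mi, M2, valid) {
  ## sample positions that are padding in every window emit 0 and route no
  ## gradient back (argw = 0 there)
  fm <- cpp_fuse_max_fwd(x$value, valid, Mi, M2)
  new_tensor(fm$out, list(x), function(g) {
    list(cpp_fuse_max_bwd(g, fm$argw, Mi, M2))
  })
}

## Weighted sum over the window axis with a fixed weight matrix wmat (M2 x Mi)
## (mean fusion: wmat = valid / rowSums(valid)).
t_fuse_wsum <- function(x, Mi, M2, wmat) {
  xv <- x$value
  C <- ncol(xv)
  out <- matrix(0, M2, C)
  for (j in seq_len(Mi)) {
    out <- out + wmat[, j] * xv[((j - 1L) * M2 + 1L):(j * M2), , drop = FALSE]
  }
  new_tensor(out, list(x), function(g) {
    gx <- matrix(0, Mi * M2, C)
    for (j in seq_len(Mi)) {
      gx[((j - 1L) * M2 + 1L):(j * M2), ] <- wmat[, j] * g
    }
    list(gx)
  })
}

## Learnable linear fusion: theta is a parameter node of length Mi; padded
## positions contribute weight zero.
t_fuse_linear <- function(x, theta, Mi, M2, valid) {
  xv <- x$value
  th <- theta$value
  C <- ncol(xv)
  out <- matrix(0, M2, C)
  for (j in seq_len(Mi)) {
    wj <- th[j] * valid[, j]
    out <- out + wj * xv[((j - 1L) * M2 + 1L):(j * M2), , drop = FALSE]
  }
  new_tensor(out, list(x, theta), function(g) {
    gx <- matrix(0, Mi * M2, C)
    gth <- numeric(Mi)
    for (j in seq_len(Mi)) {
      rows <- ((j - 1L) * M2 + 1L):(j * M2)
      wj <- th[j] * valid[, j]
      gx[rows, ] <- wj * g
      gth[j] <- sum(g * (valid[, j] * xv[rows, , drop = FALSE]))
    }
    list(gx, gth)
  })
}

## Depthwise 3x3 convolution on a token grid: xp is the zero-padded token
## matrix ((H+2)*(W+2) x C), idx an (N x 9) matrix of padded-token indices,
## wd a (9 x C) parameter.
t_dwconv3 <- function(xp, wd, idx) {
  xv <- xp$value
  wv <- wd$value
  new_tensor(cpp_dw_fwd(xv, wv, idx), list(xp, wd), function(g) {
    r <- cpp_dw_bwd(g, xv, wv, idx)
    list(r$gx, r$gw)
  })
}

## ---- segmentation loss node ------------------------------------------------

## Hybrid dice + binary-cross-entropy loss over softmax probabilities.
## p: (N x K) probability node; gmat: (N x K) one-hot matrix (constant);
## w: class weights summing to 1; lambda in [0,1].  Analytic gradient.
t_seg_loss <- function(p, gmat, w, lambda, eps = 1e-5, clamp = 1e-7) {
  pv <- p$value
  N <- nrow(pv); K <- ncol(pv)
  a <- colSums(pv * gmat)
  b <- colSums(pv * pv) + colSums(gmat) + eps     # g is 0/1 so g^2 = g
  dice <- 1 - sum(2 * w * a / b)
  pc <- pmin(pmax(pv, clamp), 1 - clamp)
  ce <- -sum(gmat * log(pc) + (1 - gmat) * log(1 - pc)) / (N * K)
  loss <- lambda * dice + (1 - lambda) * ce
  nd <- new_tensor(loss, list(p), function(g) {
    ## d dice / d p = -2 w_k (g B_k - 2 p A_k) / B_k^2
    gd <- sweep(gmat, 2L, b, "*") - 2 * sweep(pv, 2L, a, "*")
    gd <- -2 * sweep(gd, 2L, w / (b * b), "*")
    gce <- (-gmat / pc + (1 - gmat) / (1 - pc)) / (N * K)
    list(as.numeric(g) * (lambda * gd + (1 - lambda) * gce))
  })
  attr(nd, "dice") <- dice
  attr(nd, "ce") <- ce
  nd
}
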