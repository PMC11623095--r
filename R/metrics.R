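## Evaluation metrics: Dice similarity coefficient and Hausdorff distance.

#' Dice similarity coefficient
#'
#' Per class, `DSC = 2 |A n B| / (|A| + |B|)` in percent.  A class empty in
#' both masks scores 100; empty in exactly one scores 0.  The summary is the
#' mean over foreground classes (labels `1..K-1`).
#'
#' @param pred,gt integer label matrices of identical shape
#' @param K number of classes
#' @return list with `per_class` (named numeric, length `K`) and `mean_fg`
#' @export
dsc_metric <- function(pred, gt, K) {
  if (!identical(dim(pred), dim(gt))) {
    stop(sprintf("shape mismatch: pred %s vs gt %s",
                 paste(dim(pred), collapse = "x"), paste(dim(gt), collapse = "x")))
  }
  per <- vapply(seq_len(K) - 1L, function(k) {
    a <- pred == k; b <- gt == k
    na <- sum(a); nb <- sum(b)
    if (na == 0L && nb == 0L) return(100)
    if (na == 0L || nb == 0L) return(0)
    200 * sum(a & b) / (na + nb)
  }, numeric(1))
  names(per) <- as.character(seq_len(K) - 1L)
  list(per_class = per,
       mean_fg = if (K > 1L) mean(per[-1L]) else per[[1L]])
}

## boundary pixels of a binary mask: TRUE pixels with a 4-neighbor outside
## the region (the image border counts as outside)
.boundary <- function(b) {
  n <- nrow(b); m <- ncol(b)
  up <- rbind(FALSE, b[-n, , drop = FALSE])
  dn <- rbind(b[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, b[, -m, drop = FALSE])
  rt <- cbind(b[, -1, drop = FALSE], FALSE)
  b & !(up & dn & lf & rt)
}

## directed boundary distances from every boundary pixel of `ba` to the
## nearest boundary pixel of `bb` (Euclidean, isotropic) via a distance map
.boundary_dists <- function(ba, bb) {
  d <- EBImage::distmap(EBImage::Image(1 - bb), metric = "euclidean")
  as.numeric(EBImage::imageData(d))[as.vector(ba)]
}

## anisotropic fallback: explicit minimum distances between scaled point sets
.boundary_dists_aniso <- function(ba, bb, spacing) {
  pa <- which(ba, arr.ind = TRUE) * rep(spacing, each = sum(ba))
  pb <- which(bb, arr.ind = TRUE) * rep(spacing, each = sum(bb))
  vapply(seq_len(nrow(pa)), function(i) {
    sqrt(min((pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2))
  }, numeric(1))
}

#' Hausdorff distance between two masks
#'
#' For each class, the classic (maximum) symmetric Hausdorff distance between
#' the boundary point sets of prediction and ground truth; `hd95 = TRUE`
#' reports the 95th percentile of the pooled directed boundary distances
#' instead.  Distances are in pixels, or physical units when `spacing` is
#' given.  A class empty in either mask yields `NaN` with a warning and is
#' excluded from the mean.
#'
#' @param pred,gt integer label matrices of identical shape
#' @param K number of classes; classes `1..K-1` are evaluated (with `K = 2`
#'   a binary mask evaluates its foreground)
#' @param spacing pixel spacing `c(row, col)` (default `c(1, 1)`)
#' @param hd95 report the 95th-percentile variant
#' @return list with `per_class` (named, foreground classes) and `mean_fg`
#' @export
hd_metric <- function(pred, gt, K = 2L, spacing = c(1, 1), hd95 = FALSE) {
  if (!identical(dim(pred), dim(gt))) {
    stop(sprintf("shape mismatch: pred %s vs gt %s",
                 paste(dim(pred), collapse = "x"), paste(dim(gt), collapse = "x")))
  }
  iso <- isTRUE(all.equal(spacing[1], spacing[2]))
  ks <- if (K > 1L) seq_len(K - 1L) else 0L
  per <- vapply(ks, function(k) {
    a <- pred == k; b <- gt == k
    if (!sum(a) || !sum(b)) {
      warning(sprintf("class %d empty in %s; HD undefined (NaN)", k,
                      if (!sum(a) && !sum(b)) "both masks" else if (!sum(a)) "the prediction" else "the ground truth"))
      return(NaN)
    }
    ba <- .boundary(a); bb <- .boundary(b)
    if (iso) {
      dab <- .boundary_dists(ba, bb) * spacing[1]
      dba <- .boundary_dists(bb, ba) * spacing[1]
    } else {
      dab <- .boundary_dists_aniso(ba, bb, spacing)
      dba <- .boundary_dists_aniso(bb, ba, spacing)
    }
    if (hd95) stats::quantile(c(dab, dba), 0.95, names = FALSE)
    else max(max(dab), max(dba))
  }, numeric(1))
  names(per) <- as.character(ks)
  ok <- is.finite(per)
  list(per_class = per, mean_fg = if (any(ok)) mean(per[ok]) else NaN)
}

#' Per-case, per-class metric report
#'
#' @param preds,gts lists of predicted and ground-truth label matrices
#' @param K number of classes
#' @param spacing pixel spacing passed to [hd_metric()]
#' @param file optional CSV path; the table is written when given
#' @return data frame with one row per (case, class), per-case mean rows, and
#'   a final overall mean row
#' @export
metric_report <- function(preds, gts, K, spacing = c(1, 1), file = NULL) {
  stopifnot(length(preds) == length(gts))
  rows <- list()
  case_means <- numeric(0)
  case_hds <- numeric(0)
  for (i in seq_along(preds)) {
    ds <- dsc_metric(preds[[i]], gts[[i]], K)
    hd <- suppressWarnings(hd_metric(preds[[i]], gts[[i]], K, spacing))
    for (k in seq_len(K) - 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        case = i, class = k, dsc = ds$per_class[[as.character(k)]],
        hd = if (k == 0L) NA_real_ else hd$per_class[[as.character(k)]])
    }
    rows[[length(rows) + 1L]] <- data.frame(case = i, class = NA_integer_,
                                            dsc = ds$mean_fg, hd = hd$mean_fg)
    case_means <- c(case_means, ds$mean_fg)
    case_hds <- c(case_hds, hd$mean_fg)
  }
  rows[[length(rows) + 1L]] <- data.frame(case = NA_integer_, class = NA_integer_,
                                          dsc = mean(case_means),
                                          hd = mean(case_hds[is.finite(case_hds)]))
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
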