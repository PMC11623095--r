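## Deterministic multi-class 2D segmentation phantoms.
##
## Each phantom carries structures at several spatial scales: a large rotated
## ellipse whose diameter exceeds the widest default attention window, a thin
## annulus (sub-pixel-critical boundary), and a small circle narrower than the
## sample grid.  Class mean intensities are closer than the noise level is
## wide, so single pixels are ambiguous and spatial context is required to
## segment — which is what the multi-scale attention is meant to provide.

#' Phantom specification
#'
#' @param side image side in pixels (>= 32)
#' @param K class count including background (2..4); foreground classes are,
#'   in order: large ellipse, thin annulus, small circle
#' @param intensities per-class mean intensities, background first (length
#'   `K`); defaults to background 0.2 and foreground evenly spaced in
#'   `[0.45, 0.85]`
#' @param noise_sd standard deviation of the additive Gaussian noise
#' @param seed RNG seed; the same spec always yields the same phantom
#' @export
phantom_spec <- function(side = 64L, K = 4L, intensities = NULL,
                         noise_sd = 0.1, seed = 1L) {
  stopifnot(side >= 32L, K >= 2L, K <= 4L, noise_sd >= 0)
  if (is.null(intensities)) {
    intensities <- c(0.2, seq(0.45, 0.85, length.out = K - 1L))
  }
  stopifnot(length(intensities) == K)
  structure(list(side = as.integer(side), K = as.integer(K),
                 intensities = intensities, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "msr_phantom_spec")
}

## rasterizers: xs/ys are column/row coordinate grids
.disc_mask <- function(xs, ys, cx, cy, r) (xs - cx)^2 + (ys - cy)^2 <= r^2
.annulus_mask <- function(xs, ys, cx, cy, r, thick) {
  d2 <- (xs - cx)^2 + (ys - cy)^2
  d2 <= r^2 & d2 >= (r - thick)^2
}
.ellipse_mask <- function(xs, ys, cx, cy, a, b, th) {
  u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
  v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one phantom
#'
#' @param spec a [phantom_spec()]
#' @return list with `image` (numeric matrix), `mask` (integer matrix with
#'   labels `0..K-1`) and `spec`
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "msr_phantom_spec"))
  n <- spec$side
  withr::with_seed(spec$seed, {
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column coordinate
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row coordinate
    mask <- matrix(0L, n, n)

    ## class 1: large rotated ellipse, major diameter > the widest default
    ## window (window side 13 on the 1/4-resolution grid = 52 input pixels
    ## for a 64-pixel phantom)
    a <- stats::runif(1, 0.42, 0.47) * n
    bax <- stats::runif(1, 0.14, 0.20) * n
    th <- stats::runif(1, 0, pi)
    cx <- n / 2 + stats::runif(1, -n / 16, n / 16)
    cy <- n / 2 + stats::runif(1, -n / 16, n / 16)
    mask[.ellipse_mask(xs, ys, cx, cy, a, bax, th)] <- 1L

    place <- function(make_shape, label) {
      for (try in seq_len(500L)) {
        sh <- make_shape()
        if (!any(sh) || any(sh & mask > 0L)) next
        mask[sh] <<- label
        return(invisible(TRUE))
      }
      stop("could not place a non-overlapping phantom structure after 500 tries")
    }

    if (spec$K >= 3L) {
      ## class 2: thin annulus (boundary-like structure, ~3 px thick)
      place(function() {
        r <- stats::runif(1, 0.08, 0.10) * n
        ax <- stats::runif(1, r + 2, n - r - 2)
        ay <- stats::runif(1, r + 2, n - r - 2)
        .annulus_mask(xs, ys, ax, ay, r, 3)
      }, 2L)
    }
    if (spec$K >= 4L) {
      ## class 3: small circle, diameter below the sample-grid side M = 7
      place(function() {
        r <- sample(2:3, 1L)
        ax <- stats::runif(1, r + 2, n - r - 2)
        ay <- stats::runif(1, r + 2, n - r - 2)
        .disc_mask(xs, ys, ax, ay, r)
      }, 3L)
    }

    image <- matrix(spec$intensities[mask + 1L], n, n)
    if (spec$noise_sd > 0) {
      image <- image + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
    }
    list(image = image, mask = mask, spec = spec)
  })
}

#' Generate a phantom dataset with a train/validation split
#'
#' Case seeds are derived deterministically from the spec seed, so the same
#' spec always yields the same cases and the same split.
#'
#' @param n number of cases (>= 2)
#' @param spec a [phantom_spec()]; per-case seeds are derived from its seed
#' @param split training fraction (default 0.8); both splits are non-empty
#' @return list with `train`, `val` (lists of `list(image, mask)`), and the
#'   index vectors `train_idx`, `val_idx`
#' @export
make_dataset <- function(n, spec = phantom_spec(), split = 0.8) {
  if (n < 2L) stop("a dataset needs at least 2 cases (one per split)")
  cases <- lapply(seq_len(n), function(i) {
    si <- spec
    si$seed <- as.integer((spec$seed + 7919 * i) %% 2147483647)
    ph <- generate_phantom(si)
    list(image = ph$image, mask = ph$mask)
  })
  n_train <- max(1L, min(n - 1L, round(split * n)))
  train_idx <- withr::with_seed(spec$seed, sort(sample(n, n_train)))
  val_idx <- setdiff(seq_len(n), train_idx)
  list(train = cases[train_idx], val = cases[val_idx],
       train_idx = train_idx, val_idx = val_idx)
}

#' Write a phantom dataset to disk
#'
#' Each case is written both as a PNG pair (`case###.png`,
#' `case###_mask.png`, identity-grayscale labels) and as an RDS file
#' (`case###.rds`, `list(image, label, spacing)`) matching the
#' [read_case()] schema.
#'
#' @param dir output directory (created if needed)
#' @param n number of cases
#' @param spec a [phantom_spec()]
#' @return invisibly, the vector of RDS paths
#' @export
write_phantoms <- function(dir, n, spec = phantom_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n)
  for (i in seq_len(n)) {
    si <- spec
    si$seed <- as.integer((spec$seed + 7919 * i) %% 2147483647)
    ph <- generate_phantom(si)
    base <- file.path(dir, sprintf("case%03d", i))
    img01 <- pmin(pmax(ph$image, 0), 1)
    png::writePNG(img01, paste0(base, ".png"))
    png::writePNG(ph$mask / 255, paste0(base, "_mask.png"))
    saveRDS(list(image = ph$image, label = ph$mask, spacing = c(1, 1)),
            paste0(base, ".rds"))
    paths[i] <- paste0(base, ".rds")
  }
  invisible(paths)
}
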