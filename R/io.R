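## Readers and writers for images, masks and serialized cases.

.case_ext <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p)) ".nii.gz"
  else paste0(".", tools::file_ext(p))
}

#' Read a segmentation case
#'
#' Supported formats, dispatched on the file extension:
#' * PNG (`.png`) — grayscale image (multi-channel images are averaged);
#'   an optional mask PNG holds identity-grayscale labels.
#' * NIfTI (`.nii`, `.nii.gz`) — 2D, or 3D treated as a stack of 2D slices
#'   along the last axis; pixel spacing is taken from the header.
#' * RDS (`.rds`) — a list with `image`, optional `label`, optional `spacing`.
#'
#' Images are min-max normalized to `[0, 1]`; masks are integer labels.
#'
#' @param path image (or RDS case) path
#' @param mask_path optional mask path for PNG/NIfTI inputs
#' @return list with `image`, `mask` (`NULL` when absent), `spacing`
#' @export
read_case <- function(path, mask_path = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  ext <- .case_ext(path)
  out <- switch(ext,
    ".png" = {
      img <- png::readPNG(path)
      if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
      msk <- if (!is.null(mask_path)) .read_mask_png(mask_path)
      list(image = img, mask = msk, spacing = c(1, 1))
    },
    ".rds" = {
      cs <- readRDS(path)
      if (!is.list(cs) || is.null(cs$image)) {
        stop(sprintf("%s is not a case RDS (expected list(image, label, spacing))", path))
      }
      list(image = cs$image, mask = cs$label,
           spacing = if (is.null(cs$spacing)) c(1, 1) else cs$spacing)
    },
    ".nii" = ,
    ".nii.gz" = {
      img <- RNifti::readNifti(path)
      sp <- RNifti::pixdim(img)[1:2]
      arr <- as.array(img)
      msk <- if (!is.null(mask_path)) as.array(RNifti::readNifti(mask_path))
      list(image = arr, mask = if (is.null(msk)) NULL else .as_int_mask(msk),
           spacing = sp)
    },
    stop(sprintf("unknown case format '%s' (supported: .png, .nii, .nii.gz, .rds)", ext))
  )
  out$image <- .norm01(out$image)
  if (!is.null(out$mask)) {
    out$mask <- .as_int_mask(out$mask)
    if (!identical(dim(out$image), dim(out$mask))) {
      stop(sprintf("image/mask shape mismatch: %s vs %s",
                   paste(dim(out$image), collapse = "x"),
                   paste(dim(out$mask), collapse = "x")))
    }
  }
  out
}

.read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

.as_int_mask <- function(m) {
  d <- dim(m)
  m <- as.integer(round(m))
  dim(m) <- d
  m
}

.norm01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

#' Write a label mask
#'
#' PNG masks use the identity grayscale palette (pixel value = label value);
#' NIfTI and RDS store the integer labels directly.
#'
#' @param mask integer label matrix
#' @param path output path ending in `.png`, `.nii`, `.nii.gz`, or `.rds`
#' @return invisibly, `path`
#' @export
write_mask <- function(mask, path) {
  ext <- .case_ext(path)
  switch(ext,
    ".png" = png::writePNG(mask / 255, path),
    ".nii" = ,
    ".nii.gz" = RNifti::writeNifti(RNifti::asNifti(mask + 0L), path),
    ".rds" = saveRDS(list(label = mask), path),
    stop(sprintf("unknown mask format '%s'", ext)))
  invisible(path)
}
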