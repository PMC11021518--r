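## Synthetic fluorescence images and label masks: a fixture generator for the
## quantification stage.  Cells are drawn as spherocylinders (rods with
## hemispherical caps) whose mask-summed intensity equals the generating
## signal up to rounding.

## pixels of a horizontal spherocylinder: centreline from (x0, y) to (x1, y),
## radius r; a pixel belongs when its centre is within r of the segment
.rodPixels <- function(nrow_, ncol_, x0, x1, y, r) {
  cols <- seq_len(ncol_); rows <- seq_len(nrow_)
  cx <- pmin(pmax(matrix(cols, nrow_, ncol_, byrow = TRUE), x0), x1)
  dx <- matrix(cols, nrow_, ncol_, byrow = TRUE) - cx
  dy <- matrix(rows, nrow_, ncol_) - y
  dx^2 + dy^2 <= r^2
}

## spread an integer total uniformly over npx pixels, exactly
.spreadCounts <- function(total, npx) {
  base <- total %/% npx
  rem <- total %% npx
  counts <- rep(base, npx)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  counts
}

#' Render cells into a fluorescence image and label masks
#'
#' Draws each cell as a horizontal rod with hemispherical caps, of pixel
#' length `length_um * px_per_um`, stacked vertically with a margin.  The
#' summed pixel intensity inside each cell's mask equals its channel signal
#' up to rounding; each cell carries `n_nuclei` DNA blobs, every blob a
#' uniquely labelled component of the DNA mask.  Additive Gaussian camera
#' noise (default 0, for exactness) is applied after drawing.
#'
#' @param cells Cell table subset (must fit the canvas).
#' @param meas A [MeasurementParams-class] (pixel scale).
#' @param channel Channel whose signal is drawn (default `"HPG"`).
#' @param radius_um Rod radius (default 1.75, a typical half-width).
#' @param margin_px Margin between cells and canvas border (default 6).
#' @param canvas Optional `c(nrow, ncol)`; cells that do not fit raise an
#'   error listing the offenders.
#' @param camera_sd SD of additive Gaussian camera noise in counts.
#' @param seed Seed for the camera noise.
#' @return List with `image` (integer counts), `cell_mask` and `dna_mask`
#'   (integer label matrices); cell mask label i corresponds to row i of
#'   `cells`.
#' @export
renderImages <- function(cells, meas, channel = "HPG", radius_um = 1.75,
                         margin_px = 6, canvas = NULL, camera_sd = 0,
                         seed = 1L) {
  stopifnot(is(meas, "MeasurementParams"), nrow(cells) >= 1L)
  col <- .signalCol(channel)
  .checkChannel(cells, col)
  scale <- meas@px_per_um
  r <- radius_um * scale
  len_px <- cells$length_um * scale
  row_h <- ceiling(2 * r) + margin_px
  need_nrow <- nrow(cells) * row_h + margin_px
  need_ncol <- ceiling(max(len_px)) + 2 * margin_px
  if (is.null(canvas)) canvas <- c(need_nrow, need_ncol)
  too_long <- which(len_px + 2 * margin_px > canvas[2])
  if (need_nrow > canvas[1] && !length(too_long))
    too_long <- seq_len(nrow(cells))
  if (length(too_long))
    stop("canvas overflow for cell(s): ",
         paste(cells$cell_id[too_long], collapse = ", "))
  img <- matrix(0, canvas[1], canvas[2])
  cell_mask <- matrix(0L, canvas[1], canvas[2])
  dna_mask <- matrix(0L, canvas[1], canvas[2])
  dna_label <- 0L
  dna_r <- max(2, 0.5 * scale)
  for (i in seq_len(nrow(cells))) {
    y <- margin_px + (i - 1) * row_h + r
    x0 <- margin_px + r
    x1 <- margin_px + len_px[i] - r
    if (x1 < x0) { x0 <- x1 <- margin_px + len_px[i] / 2 }
    ## half-pixel dilation centres the pixel-centre Feret diameter on the
    ## nominal length (raw pixelation shortens it by ~1 px)
    rod <- .rodPixels(canvas[1], canvas[2], x0, x1, y, r + 0.5)
    idx <- which(rod)
    cell_mask[idx] <- i
    total <- round(cells[[col]][i])
    if (is.finite(total) && total > 0)
      img[idx] <- img[idx] + .spreadCounts(total, length(idx))
    nn <- cells$n_nuclei[i]
    if (is.finite(nn) && nn > 0) {
      fr <- if (nn == 1L) 0.5 else c(0.3, 0.7)
      for (f in fr[seq_len(nn)]) {
        dna_label <- dna_label + 1L
        cx <- x0 + f * (x1 - x0)
        blob <- .rodPixels(canvas[1], canvas[2], cx, cx, y, dna_r)
        dna_mask[which(blob)] <- dna_label
      }
    }
  }
  if (camera_sd > 0) {
    set.seed(as.integer(seed))
    img <- pmax(round(img + rnorm(length(img), 0, camera_sd)), 0)
  }
  if (max(img) > 65535)
    warning("pixel values exceed the 16-bit range; TIFF export will clip")
  list(image = img, cell_mask = cell_mask, dna_mask = dna_mask)
}

#' Write / read a 16-bit single-channel TIFF
#'
#' Integer counts (0..65535) round-trip exactly; label masks are stored the
#' same way (supports up to 65535 labels).
#'
#' @param x Numeric/integer matrix.
#' @param path Output path.
#' @return `readImageTIFF` returns the integer matrix.
#' @export
writeImageTIFF <- function(x, path) {
  tiff::writeTIFF(pmin(pmax(x, 0), 65535) / 65535, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeImageTIFF
#' @export
readImageTIFF <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  round(m * 65535)
}
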