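## Mask-based single-cell quantification and gating.  Images and masks are
## numeric matrices (row-major rasters); mask labels are positive integers,
## 0 is background.

#' Feret diameter of a pixel mask
#'
#' The longest distance between any two pixel centres of the mask, used as
#' the cell length of rod-shaped cells.  Computed on the convex hull of the
#' pixel coordinates, which equals the brute-force all-pairs maximum; the
#' pixel-centre convention is used (no endpoint correction), so a single
#' pixel has Feret diameter 0.
#'
#' @param mask A logical/numeric matrix (non-zero pixels belong to the mask)
#'   or a two-column matrix of pixel coordinates.
#' @return The Feret diameter in pixels.
#' @examples
#' feretDiameter(matrix(1, 3, 3))        # 2 * sqrt(2)
#' feretDiameter(matrix(1, 1, 20))       # 19
#' @export
feretDiameter <- function(mask) {
  pts <- if (is.matrix(mask) && ncol(mask) == 2L && !all(mask %in% c(0, 1)))
    mask else which(mask != 0, arr.ind = TRUE)
  if (!nrow(pts)) stop("empty mask")
  if (nrow(pts) == 1L) return(0)
  hull <- pts[chull(pts[, 1], pts[, 2]), , drop = FALSE]
  d2 <- outer(hull[, 1], hull[, 1], "-")^2 + outer(hull[, 2], hull[, 2], "-")^2
  sqrt(max(d2))
}

#' Convert pixel lengths to micrometres
#'
#' @param length_px Length(s) in pixels.
#' @param px_per_um Pixels per micrometre (default 15.3609, the imaging scale
#'   emulated throughout the package).
#' @return Length(s) in micrometres.
#' @examples
#' pxToUm(15.3609)   # 1
#' @export
pxToUm <- function(length_px, px_per_um = 15.3609) {
  if (!is.finite(px_per_um) || px_per_um <= 0)
    stop("'px_per_um' must be positive")
  length_px / px_per_um
}

#' Per-cell intensity statistics under label masks
#'
#' For every label of the cell mask: total, mean, median and maximum pixel
#' intensity on the fluorescence image, the mask area in pixels and the
#' Feret diameter.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param cell_mask Integer label matrix of the same shape (0 = background).
#' @param labels Labels to quantify (default: all labels present); requested
#'   labels absent from the mask are omitted with a warning.
#' @param px_per_um Optional pixel scale; when given, a `length_um` column
#'   (Feret / scale) is added.
#' @return A data.frame with one row per label: `label`, `area_px`, `total`,
#'   `mean`, `median`, `max`, `feret_px` (and `length_um`).
#' @export
quantifyCells <- function(image, cell_mask, labels = NULL,
                          px_per_um = NULL) {
  if (!all(dim(image) == dim(cell_mask)))
    stop("image and mask shapes differ")
  present <- sort(unique(cell_mask[cell_mask > 0]))
  if (is.null(labels)) labels <- present
  missing <- setdiff(labels, present)
  if (length(missing)) {
    warning("label(s) absent from mask, omitted: ",
            paste(missing, collapse = ", "))
    labels <- intersect(labels, present)
  }
  rows <- lapply(labels, function(lab) {
    sel <- cell_mask == lab
    v <- image[sel]
    data.frame(label = lab, area_px = sum(sel), total = sum(v),
               mean = mean(v), median = median(v), max = max(v),
               feret_px = feretDiameter(sel))
  })
  out <- do.call(rbind, rows)
  if (!is.null(px_per_um)) out$length_um <- pxToUm(out$feret_px, px_per_um)
  rownames(out) <- NULL
  out
}

#' Count nuclei per cell mask
#'
#' Each DNA mask component is assigned to the cell mask containing the
#' majority (> 50\%) of its pixels; ties or components with no majority cell
#' are left unassigned and reported in attribute `"unassigned"`.
#'
#' @param cell_mask,dna_mask Integer label matrices of the same shape.
#' @return A data.frame with columns `label` (cell label) and `n_nuclei`,
#'   covering every cell label (0 where no DNA component was assigned).
#' @export
countNuclei <- function(cell_mask, dna_mask) {
  if (!all(dim(cell_mask) == dim(dna_mask)))
    stop("mask shapes differ")
  cells <- sort(unique(cell_mask[cell_mask > 0]))
  counts <- setNames(integer(length(cells)), cells)
  unassigned <- integer(0)
  for (lab in sort(unique(dna_mask[dna_mask > 0]))) {
    under <- cell_mask[dna_mask == lab]
    tab <- table(under)
    top <- tab[which.max(tab)]
    host <- as.integer(names(top))
    majority <- top > length(under) / 2 && sum(tab == top[[1]]) == 1L
    if (host > 0 && majority) {
      counts[as.character(host)] <- counts[as.character(host)] + 1L
    } else {
      unassigned <- c(unassigned, lab)
    }
  }
  if (length(unassigned))
    message(length(unassigned), " DNA component(s) unassigned")
  out <- data.frame(label = cells, n_nuclei = as.integer(counts))
  attr(out, "unassigned") <- unassigned
  out
}

#' Apply post-acquisition gates to a cell table
#'
#' Removes rows failing any enabled gate of a [GateConfig-class]: thickness
#' range, width maximum, mononucleate requirement, and any extra numeric
#' gates on named columns.  The number of removals per gate is reported in
#' attribute `"removed"`; the input table is not modified.  Gating is
#' idempotent.
#'
#' @param tab Cell table.
#' @param gates A [GateConfig-class] object.
#' @return The filtered table.
#' @export
gateCells <- function(tab, gates = GateConfig()) {
  stopifnot(is(gates, "GateConfig"))
  keep <- rep(TRUE, nrow(tab))
  removed <- integer(0)
  applyGate <- function(colname, pass, gate_name) {
    if (!colname %in% names(tab))
      stop("missing feature column '", colname, "' for enabled gate ",
           gate_name)
    drop <- keep & !pass
    removed[gate_name] <<- sum(drop)
    keep <<- keep & pass
  }
  if (gates@thickness_min_px > 0 || is.finite(gates@thickness_max_px))
    applyGate("thickness_px",
              tab[["thickness_px"]] >= gates@thickness_min_px &
                tab[["thickness_px"]] <= gates@thickness_max_px,
              "thickness")
  if (is.finite(gates@width_max_px))
    applyGate("width_px", tab[["width_px"]] <= gates@width_max_px, "width")
  if (gates@require_mononucleate)
    applyGate("n_nuclei", tab[["n_nuclei"]] == 1L, "mononucleate")
  for (colname in names(gates@numeric_gates)) {
    rng <- gates@numeric_gates[[colname]]
    applyGate(colname, tab[[colname]] >= rng[1] & tab[[colname]] <= rng[2],
              colname)
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}
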