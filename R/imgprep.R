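# Frame preparation and segmentation. EBImage supplies the morphological
# primitives; frames are plain numeric matrices (rows = image rows, 1-based).

#' Background-correct a frame to [0, 1] attenuation units
#'
#' Estimates the background level as the mode of a 256-bin intensity histogram
#' (background dominates a sparse field), subtracts it, clips at zero and
#' rescales so the maximum attenuation maps to 1. The transform is monotone
#' and invariant to an image-wide additive offset.
#'
#' @param frame Nonnegative numeric matrix.
#' @return Matrix in \[0, 1\] with attribute `degenerate = TRUE` (and a
#'   warning) when the frame is constant, in which case all zeros are returned.
#' @export
background_correct <- function(frame) {
  if (any(frame < 0)) stop("frame must be nonnegative")
  rng <- range(frame)
  if (diff(rng) == 0) {
    warning("constant frame: background correction is degenerate")
    out <- matrix(0, nrow(frame), ncol(frame))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  br <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(frame, br, rightmost.closed = TRUE), 256)
  bg <- (br[which.max(h)] + br[which.max(h) + 1]) / 2
  out <- pmax(frame - bg, 0)
  out / max(out)
}

#' Segment cells in a background-corrected frame
#'
#' Gaussian smoothing (to suppress intracellular texture), global Otsu
#' threshold, morphological opening (disc radius 2), hole filling, removal of
#' objects below `min_area`, then a distance-transform watershed to split
#' touching cells. Labels are renumbered in raster order of centroids
#' (top-to-bottom, then left-to-right), so labeling is reproducible.
#'
#' @param frame Background-corrected matrix in \[0, 1\].
#' @param min_area Minimum object area in pixels.
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels (0 disables).
#' @param split_touching Run the watershed split (default `TRUE`).
#' @param tolerance Watershed tolerance (in distance-map units); higher merges
#'   shallow maxima, preventing oversplitting of irregular single cells.
#' @return Integer label matrix (0 = background, k > 0 = cell k); an empty
#'   frame yields an all-zero mask.
#' @export
segment_cells <- function(frame, min_area = 30, smooth_sigma = 2,
                          split_touching = TRUE, tolerance = 3) {
  if (diff(range(frame)) == 0) return(matrix(0L, nrow(frame), ncol(frame)))
  img <- EBImage::Image(frame)
  smoothed <- if (smooth_sigma > 0) EBImage::gblur(img, sigma = smooth_sigma)
              else img
  # threshold level from the smoothed image (texture-robust), applied to the
  # raw frame so sharp cell boundaries are not eroded by the blur
  thr <- EBImage::otsu(smoothed, range = c(0, 1))
  bw <- img > thr
  kern <- EBImage::makeBrush(5, shape = "disc")
  bw <- EBImage::closing(bw, kern)   # seal texture holes before opening
  bw <- EBImage::opening(bw, kern)
  bw <- EBImage::fillHull(bw)
  lab <- if (split_touching)
    EBImage::watershed(EBImage::distmap(bw), tolerance = tolerance) else
    EBImage::bwlabel(bw)
  lab <- as.matrix(EBImage::imageData(lab))
  # drop small objects, then renumber in raster order of centroids
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (!length(keep)) return(matrix(0L, nrow(frame), ncol(frame)))
  out <- matrix(0L, nrow(frame), ncol(frame))
  cent <- t(vapply(keep, function(k) colMeans(which(lab == k, arr.ind = TRUE)),
                   numeric(2)))
  ord <- keep[order(round(cent[, 1]), round(cent[, 2]))]
  for (i in seq_along(ord)) out[lab == ord[i]] <- i
  out
}

#' Bounding boxes of a label mask
#'
#' @param mask Integer label matrix.
#' @return Data frame with one row per label: `cell`, `row_min`, `row_max`,
#'   `col_min`, `col_max`, `area`.
#' @export
mask_bboxes <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  do.call(rbind, lapply(labs, function(k) {
    ij <- which(mask == k, arr.ind = TRUE)
    data.frame(cell = k, row_min = min(ij[, 1]), row_max = max(ij[, 1]),
               col_min = min(ij[, 2]), col_max = max(ij[, 2]),
               area = nrow(ij))
  }))
}

#' Crop one cell into a zero-padded square
#'
#' Extracts the cell's pixels (all other pixels set to exactly zero) and
#' centers them in a `side x side` image.
#'
#' @param frame Numeric matrix (e.g. a background-corrected frame, or one
#'   dynamic map).
#' @param mask Integer label matrix.
#' @param cell_id Label of the cell to crop.
#' @param side Crop side length in pixels (default 128).
#' @return A `side x side` matrix, zero outside the cell, with attributes
#'   `cell_id` and `offset` (row/col of crop pixel (1,1) in the frame).
#' @export
crop_and_pad <- function(frame, mask, cell_id, side = 128) {
  ij <- which(mask == cell_id, arr.ind = TRUE)
  if (!nrow(ij)) stop("cell_id ", cell_id, " not present in mask")
  h <- diff(range(ij[, 1])) + 1
  w <- diff(range(ij[, 2])) + 1
  if (h > side || w > side)
    stop("cell ", cell_id, " (", h, "x", w,
         " px) does not fit in side = ", side, "; increase side")
  out <- matrix(0, side, side)
  r0 <- floor((side - h) / 2) + 1 - min(ij[, 1])
  c0 <- floor((side - w) / 2) + 1 - min(ij[, 2])
  out[cbind(ij[, 1] + r0, ij[, 2] + c0)] <- frame[ij]
  attr(out, "cell_id") <- cell_id
  attr(out, "offset") <- c(row = 1 - r0, col = 1 - c0)
  out
}

# Otsu threshold over an arbitrary set of values (EBImage's otsu thresholds
# whole rectangular images only). Maximizes between-class variance on a
# 256-bin histogram; returns a threshold in the value range.
.otsu_values <- function(v, n_bins = 256) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-(n_bins + 1)]) / 2
  w0 <- cumsum(w); w1 <- 1 - w0
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * w1)
  bcv[!is.finite(bcv)] <- -Inf
  br[which.max(bcv) + 1]
}

#' Partition a cell crop into nucleus and cytoplasm
#'
#' Otsu's threshold on the within-mask intensities; the higher-attenuation
#' class is the nucleus (at 255 nm nucleic acids dominate absorption, and the
#' nucleus is nucleic-acid dense). Morphological opening and closing remove
#' thresholding artifacts and smooth the border; the largest connected
#' component is kept. The nucleus and cytoplasm masks partition the cell mask
#' exactly.
#'
#' @param crop A [crop_and_pad()] image (zero outside the cell).
#' @param cell_mask Optional logical matrix of the cell support; by default
#'   nonzero crop pixels.
#' @param brush Diameter of the opening/closing disc brush (odd, default 5,
#'   i.e. radius 2).
#' @return List with logical `nucleus` and `cytoplasm` masks and `flag`
#'   (`"ok"`, or `"degenerate"` with an empty nucleus when the cell has a
#'   single intensity level).
#' @export
segment_nucleus <- function(crop, cell_mask = NULL, brush = 5) {
  if (is.null(cell_mask)) cell_mask <- crop != 0
  cell_mask <- cell_mask != 0
  vals <- crop[cell_mask]
  if (length(vals) < 2 || diff(range(vals)) < 1e-9)
    return(list(nucleus = matrix(FALSE, nrow(crop), ncol(crop)),
                cytoplasm = cell_mask, flag = "degenerate"))
  thr <- .otsu_values(vals)
  nuc <- cell_mask & crop >= thr
  kern <- EBImage::makeBrush(brush, shape = "disc")
  nuc_img <- EBImage::closing(EBImage::opening(EBImage::Image(nuc * 1), kern), kern)
  nuc <- as.matrix(EBImage::imageData(nuc_img)) > 0 & cell_mask
  if (any(nuc)) {
    lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(nuc * 1))))
    sizes <- tabulate(lab[lab > 0])
    nuc <- lab == which.max(sizes)
  }
  if (!any(nuc))
    return(list(nucleus = matrix(FALSE, nrow(crop), ncol(crop)),
                cytoplasm = cell_mask, flag = "degenerate"))
  list(nucleus = nuc, cytoplasm = cell_mask & !nuc, flag = "ok")
}

#' Match segmented labels to ground-truth labels by majority overlap
#'
#' @param seg_mask,truth_mask Integer label matrices of the same shape.
#' @return Data frame with `seg`, `truth` (0 when nothing overlaps) and `iou`
#'   (intersection-over-union with the matched truth object).
#' @export
match_labels <- function(seg_mask, truth_mask) {
  segs <- sort(unique(seg_mask[seg_mask > 0]))
  do.call(rbind, lapply(segs, function(k) {
    tv <- truth_mask[seg_mask == k]
    tv <- tv[tv > 0]
    if (!length(tv))
      return(data.frame(seg = k, truth = 0L, iou = 0))
    best <- as.integer(names(which.max(table(tv))))
    inter <- sum(seg_mask == k & truth_mask == best)
    union <- sum(seg_mask == k | truth_mask == best)
    data.frame(seg = k, truth = best, iou = inter / union)
  }))
}
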