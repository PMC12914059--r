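# Per-cell static features: morphology, intensity texture, box-counting
# fractal dimensions per intensity bin; chi-square feature ranking and a
# 2-D UMAP embedding for visualization.

#' The eight fractal intensity bins
#'
#' Equal-width intervals of the background-corrected intensity axis:
#' bin k = \[(k-1)/8, k/8), with bin 8 closed at 1. Bin 6 is
#' \[0.625, 0.750), bin 3 is \[0.25, 0.375).
#'
#' @return Data frame with `bin`, `lower`, `upper`.
#' @export
fractal_bins <- function() {
  data.frame(bin = 1:8, lower = (0:7) / 8, upper = (1:8) / 8)
}

#' Box-counting fractal dimension of a binary mask
#'
#' Counts occupied boxes at grid sizes \{2, 4, 8, 16, 32\} px and returns the
#' least-squares slope of log(count) versus log(1/size). An empty mask has
#' dimension 0 by convention.
#'
#' @param mask Logical matrix.
#' @param sizes Box sizes in pixels.
#' @return Scalar dimension estimate.
#' @export
box_count_dim <- function(mask, sizes = c(2, 4, 8, 16, 32)) {
  mask <- mask != 0
  if (!any(mask)) return(0)
  idx <- which(mask, arr.ind = TRUE)
  nc <- ncol(mask)
  counts <- vapply(sizes, function(s) {
    boxes <- (ceiling(idx[, 1] / s) - 1) * ceiling(nc / s) + ceiling(idx[, 2] / s)
    length(unique(boxes))
  }, numeric(1))
  # slope of log(count) vs log(1/size) == -slope of log(count) vs log(size)
  fit <- stats::lm.fit(cbind(1, log(sizes)), log(counts))
  -unname(fit$coefficients[2])
}

#' Fractal dimensions per intensity bin
#'
#' For each of the eight intensity bins, binarizes the mask pixels whose
#' intensity falls in the bin and returns the box-counting dimension of that
#' binary mask (0 for an empty bin).
#'
#' @param crop Background-corrected cell crop in \[0, 1\].
#' @param mask Optional logical support (default: nonzero crop pixels).
#' @return Named numeric vector `fractal_1` ... `fractal_8`.
#' @export
fractal_features <- function(crop, mask = NULL) {
  if (is.null(mask)) mask <- crop != 0
  mask <- mask != 0
  bins <- fractal_bins()
  out <- vapply(seq_len(nrow(bins)), function(k) {
    hi_ok <- if (k == 8) crop <= bins$upper[k] else crop < bins$upper[k]
    box_count_dim(mask & crop >= bins$lower[k] & hi_ok)
  }, numeric(1))
  setNames(out, paste0("fractal_", 1:8))
}

# Perimeter via Kulpa-corrected chain length over the ordered object contour
# (raw boundary-pixel counts bias circularity of a disc far from 1).
.perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) return(0)
  sum(vapply(oc, function(pts) {
    if (nrow(pts) < 2) return(1)
    d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
    steps <- abs(d[, 1]) + abs(d[, 2])
    0.948 * sum(steps == 1) + 1.340 * sum(steps == 2)
  }, numeric(1)))
}

#' Static feature row for one cell crop
#'
#' Morphology: area (px^2 and um^2), circularity `4*pi*area/perimeter^2`
#' (Kulpa-corrected contour perimeter), equivalent diameter `2*sqrt(area/pi)`,
#' eccentricity from the mask's second central moments. Texture over mask
#' pixels only: mean and standard deviation of attenuation, Shannon entropy of
#' a 64-bin histogram over \[0, 1\] (bits), skewness, kurtosis, and the eight
#' per-bin fractal dimensions.
#'
#' @param crop Background-corrected crop in \[0, 1\].
#' @param mask Optional logical support (default: nonzero crop pixels).
#' @param pixel_size Micrometers per pixel (for `area_um2`).
#' @return One-row data frame; a mask under 5 px gives `valid = FALSE` and
#'   `NA` features.
#' @export
static_features <- function(crop, mask = NULL, pixel_size = 1) {
  if (is.null(mask)) mask <- crop != 0
  mask <- mask != 0
  area <- sum(mask)
  feat_names <- c("area_px", "area_um2", "circularity", "equivalent_diameter",
                  "eccentricity", "mean_attenuation", "sd_attenuation",
                  "entropy", "skewness", "kurtosis", paste0("fractal_", 1:8))
  if (area < 5) {
    row <- as.data.frame(as.list(setNames(rep(NA_real_, length(feat_names)),
                                          feat_names)))
    row$valid <- FALSE
    return(row)
  }
  vals <- crop[mask]
  per <- .perimeter(mask)
  ij <- which(mask, arr.ind = TRUE)
  cen <- colMeans(ij)
  cc <- stats::cov(sweep(ij, 2, cen))
  ev <- sort(eigen(cc, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
  row <- data.frame(
    area_px = area,
    area_um2 = area * pixel_size^2,
    circularity = 4 * pi * area / per^2,
    equivalent_diameter = 2 * sqrt(area / pi),
    eccentricity = ecc,
    mean_attenuation = mean(vals),
    sd_attenuation = sd(vals),
    entropy = .shannon_entropy(vals, n_bins = 64, range = c(0, 1)),
    skewness = if (sd(vals) == 0) 0 else e1071::skewness(vals),
    kurtosis = if (sd(vals) == 0) 0 else e1071::kurtosis(vals))
  row <- cbind(row, as.data.frame(as.list(fractal_features(crop, mask))))
  row$valid <- TRUE
  row
}

#' Static feature table for every cell in a frame
#'
#' Crops each labeled cell, computes [static_features()] and binds the rows.
#'
#' @param frame Background-corrected frame.
#' @param mask Integer label mask.
#' @param pixel_size Micrometers per pixel.
#' @param side Crop side passed to [crop_and_pad()].
#' @return Data frame with a leading `cell` column.
#' @export
feature_table <- function(frame, mask, pixel_size = 1, side = 128) {
  labs <- sort(unique(mask[mask > 0]))
  rows <- lapply(labs, function(k) {
    crop <- crop_and_pad(frame, mask, k, side = side)
    cbind(cell = k, static_features(crop, pixel_size = pixel_size))
  })
  do.call(rbind, rows)
}

#' Rank features by chi-square association with class labels
#'
#' Each feature is discretized into up to `n_bins` quantile bins and tested
#' against the class labels with Pearson's chi-square statistic on the
#' contingency table; features are ranked by descending statistic. A feature
#' that is constant across classes collapses to one bin and scores 0.
#'
#' @param table Data frame of numeric features (non-numeric and `cell`/`valid`
#'   columns are dropped).
#' @param labels Class labels, one per row; at least two classes.
#' @param n_bins Number of quantile bins (default 10).
#' @param top Optionally return only the `top` best features (the display
#'   convention is 12 for the 3-class task, 8 for subtyping).
#' @return Data frame `feature`, `score`, `rank`, ordered by rank.
#' @export
rank_features_chi2 <- function(table, labels, n_bins = 10, top = NULL) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 classes")
  num <- vapply(table, is.numeric, logical(1))
  drop <- names(table) %in% c("cell", "valid")
  feats <- table[, num & !drop, drop = FALSE]
  scores <- vapply(names(feats), function(nm) {
    v <- feats[[nm]]
    ok <- is.finite(v)
    if (sum(ok) < 2) return(0)
    br <- unique(quantile(v[ok], probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 3) return(0)
    b <- cut(v[ok], breaks = br, include.lowest = TRUE)
    tab <- table(b, droplevels(labels[ok]))
    suppressWarnings(unname(stats::chisq.test(tab)$statistic))
  }, numeric(1))
  out <- data.frame(feature = names(scores), score = unname(scores))
  out <- out[order(-out$score), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top)) out <- head(out, top)
  out
}

#' Per-class mean z-scores (clustergram values)
#'
#' Z-scores each feature across cells, then averages per class — the values a
#' feature clustergram displays.
#'
#' @inheritParams rank_features_chi2
#' @param features Optional character vector restricting/ordering the columns.
#' @return Matrix: rows = features, columns = classes.
#' @export
class_zscore_matrix <- function(table, labels, features = NULL) {
  labels <- as.factor(labels)
  num <- vapply(table, is.numeric, logical(1))
  feats <- table[, num & !(names(table) %in% c("cell", "valid")), drop = FALSE]
  if (!is.null(features)) feats <- feats[, features, drop = FALSE]
  z <- scale(as.matrix(feats))
  z[!is.finite(z)] <- 0
  t(vapply(levels(labels), function(cl) colMeans(z[labels == cl, , drop = FALSE]),
           numeric(ncol(z))))
}

#' 2-D UMAP embedding of a feature table
#'
#' Standardizes the features (z-score) and embeds with UMAP using 15 nearest
#' neighbors and minimum distance 0.1; deterministic for a fixed seed.
#'
#' @inheritParams rank_features_chi2
#' @param seed Integer seed.
#' @param n_neighbors,min_dist UMAP parameters.
#' @return Matrix of `n x 2` finite coordinates.
#' @export
embed_2d <- function(table, seed = 1L, n_neighbors = 15, min_dist = 0.1) {
  num <- vapply(table, is.numeric, logical(1))
  feats <- as.matrix(table[, num & !(names(table) %in% c("cell", "valid")),
                           drop = FALSE])
  if (nrow(feats) < 16) stop("need at least 16 cells to embed")
  z <- scale(feats)
  z[!is.finite(z)] <- 0
  set.seed(seed)
  emb <- uwot::umap(z, n_neighbors = n_neighbors, min_dist = min_dist,
                    n_threads = 1, n_sgd_threads = 1)
  stopifnot(all(is.finite(emb)))
  emb
}

#' Mean silhouette width of an embedding against labels
#'
#' Small helper used to judge class separation of a 2-D embedding.
#'
#' @param coords `n x 2` coordinates.
#' @param labels Class labels.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouette_score <- function(coords, labels) {
  labels <- as.factor(labels)
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  sil <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(levels(labels), as.character(labels[i])),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
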