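# Pixelwise temporal-frequency analysis: magnitude spectra, first-harmonic
# phasor (g, s) of the spectral decay, and power-law exponent fitting.

#' Magnitude spectrum of a pixel's temporal trace
#'
#' Discrete Fourier transform of the mean-subtracted trace; magnitudes are
#' returned at the positive frequencies up to Nyquist (DC excluded).
#'
#' @param trace Numeric vector, length >= 8.
#' @param frame_rate Sampling rate in Hz.
#' @return A `pixel_spectrum`: list with `f` (Hz, strictly increasing) and
#'   `I` (DFT magnitudes, attenuation units).
#' @export
pixel_spectrum <- function(trace, frame_rate) {
  if (length(trace) < 8) stop("trace must have at least 8 samples")
  n <- length(trace)
  nhalf <- n %/% 2
  F <- fft(trace - mean(trace))
  structure(list(f = (1:nhalf) * frame_rate / n, I = Mod(F[2:(nhalf + 1)])),
            class = "pixel_spectrum")
}

#' Fit a power-law decay to a magnitude spectrum
#'
#' Ordinary least squares of `log10 I` on `log10 f` over frequencies in
#' `[f_min, Nyquist]`; the exponent is reported as the positive decay slope
#' beta, so `I(f) = f^-1` gives beta = 1 (diffuse, Brownian-like motion) and
#' `I(f) = f^-2` gives beta = 2 (advective motion). Frequencies below `f_min`
#' (default 0.1 Hz) are excluded; zero-magnitude bins are dropped before
#' fitting.
#'
#' @param spectrum A [pixel_spectrum()].
#' @param f_min Low-frequency cutoff in Hz.
#' @return List with `beta`, `r2`, `n_bins` (bins used) and `flag`
#'   (`"ok"` or `"degenerate"` when no bins carry signal; then `beta` is `NA`).
#' @export
fit_power_law <- function(spectrum, f_min = 0.1) {
  keep <- spectrum$f >= f_min
  if (sum(keep) < 5)
    stop("need at least 5 frequency bins in [f_min, Nyquist]; got ", sum(keep))
  f <- spectrum$f[keep]; I <- spectrum$I[keep]
  pos <- I > 0
  if (sum(pos) < 2)
    return(list(beta = NA_real_, r2 = NA_real_, n_bins = sum(pos),
                flag = "degenerate"))
  lf <- log10(f[pos]); lI <- log10(I[pos])
  fit <- stats::lm.fit(cbind(1, lf), lI)
  slope <- fit$coefficients[2]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((lI - mean(lI))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(beta = -unname(slope), r2 = r2, n_bins = sum(pos), flag = "ok")
}

#' First-harmonic phasor (g, s) of a spectral decay
#'
#' Decomposes the normalized magnitude spectrum over the retained frequency
#' axis into its first-harmonic real/imaginary coordinates, in the style of
#' lifetime-imaging phasor analysis. The retained axis `[f_min, Nyquist]` is
#' mapped to `x in [0, 1]` and
#' \deqn{g = \sum I(f)\cos(2\pi x(f}) / \sum I(f), \quad
#'       s = \sum I(f)\sin(2\pi x(f)) / \sum I(f).}
#' A temporally constant pixel (no spectral mass) maps to the origin (0, 0);
#' steeper decays (higher beta) concentrate mass at `x = 0` and map further
#' from the origin, so distance from the origin is an activity scalar.
#'
#' @inheritParams fit_power_law
#' @param tol Total spectral mass below which the trace is treated as
#'   constant and (0, 0) returned.
#' @return List with `g` and `s` (unitless).
#' @export
phasor <- function(spectrum, f_min = 0.1, tol = 1e-12) {
  keep <- spectrum$f >= f_min
  if (sum(keep) < 5)
    stop("need at least 5 frequency bins in [f_min, Nyquist]; got ", sum(keep))
  f <- spectrum$f[keep]; I <- spectrum$I[keep]
  tot <- sum(I)
  if (tot < tol) return(list(g = 0, s = 0))
  x <- (f - f_min) / (max(spectrum$f) - f_min)
  list(g = sum(I * cos(2 * pi * x)) / tot, s = sum(I * sin(2 * pi * x)) / tot)
}

#' Pixelwise dynamic maps (phasor g, phasor s, power-law slope) for a stack
#'
#' Computes, for every pixel under the mask, the magnitude spectrum of its
#' temporal trace and from it the phasor coordinates and fitted power-law
#' exponent. Unmasked pixels are `NA` in all maps.
#'
#' @param stack A `uv_stack` (`H x W x T`).
#' @param mask Logical or integer matrix congruent with the stack's spatial
#'   dimensions; nonzero/`TRUE` pixels are analyzed.
#' @param f_min Low-frequency cutoff in Hz passed to the fit and phasor.
#' @return A `dynamic_maps` object: list of matrices `g`, `s`, `beta`, `r2`
#'   plus the `f_min` used.
#' @export
dynamic_maps <- function(stack, mask, f_min = 0.1) {
  d <- dim(stack)
  if (!all(dim(mask) == d[1:2])) stop("mask and stack shapes differ")
  frame_rate <- attr(stack, "frame_rate")
  Tn <- d[3]; nhalf <- Tn %/% 2
  f <- (1:nhalf) * frame_rate / Tn
  keep <- f >= f_min
  if (sum(keep) < 5) stop("fewer than 5 frequency bins at or above f_min")
  g <- s <- beta <- r2 <- matrix(NA_real_, d[1], d[2])
  idx <- which(mask != 0)
  if (!length(idx)) {
    return(structure(list(g = g, s = s, beta = beta, r2 = r2, f_min = f_min),
                     class = "dynamic_maps"))
  }
  # traces as a T x npix matrix; one FFT pass for all pixels
  lin <- outer(idx, (seq_len(Tn) - 1L) * (d[1] * d[2]), `+`)
  tr <- t(matrix(stack[lin], ncol = Tn))
  tr <- sweep(tr, 2, colMeans(tr))
  I <- Mod(mvfft(tr))[2:(nhalf + 1), , drop = FALSE][keep, , drop = FALSE]
  fr <- f[keep]
  x <- (fr - f_min) / (max(f) - f_min)
  tot <- colSums(I)
  live <- tot >= 1e-12
  gv <- sv <- numeric(length(idx))
  gv[live] <- colSums(I[, live, drop = FALSE] * cos(2 * pi * x)) / tot[live]
  sv[live] <- colSums(I[, live, drop = FALSE] * sin(2 * pi * x)) / tot[live]
  # vectorized log-log OLS where all bins are positive; fall back per pixel
  bv <- rv <- rep(NA_real_, length(idx))
  allpos <- colSums(I > 0) == nrow(I)
  if (any(allpos)) {
    lf <- log10(fr)
    lI <- log10(I[, allpos, drop = FALSE])
    mx <- mean(lf); sxx <- sum((lf - mx)^2)
    my <- colMeans(lI)
    sxy <- colSums((lf - mx) * lI)
    slope <- sxy / sxx
    res <- lI - outer(lf - mx, slope) - matrix(my, nrow(lI), ncol(lI), byrow = TRUE)
    ss_tot <- colSums(sweep(lI, 2, my)^2)
    bv[allpos] <- -slope
    rv[allpos] <- ifelse(ss_tot == 0, 1, 1 - colSums(res^2) / ss_tot)
  }
  if (any(!allpos)) {
    for (j in which(!allpos)) {
      sp <- structure(list(f = fr, I = I[, j]), class = "pixel_spectrum")
      ft <- fit_power_law(sp, f_min = f_min)
      bv[j] <- ft$beta; rv[j] <- ft$r2
    }
  }
  g[idx] <- gv; s[idx] <- sv; beta[idx] <- bv; r2[idx] <- rv
  structure(list(g = g, s = s, beta = beta, r2 = r2, f_min = f_min),
            class = "dynamic_maps")
}

# Shannon entropy (bits) of values histogrammed into n_bins over `range`.
.shannon_entropy <- function(v, n_bins = 64, range = NULL) {
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  if (is.null(range)) range <- range(v)
  if (diff(range) == 0) return(0)
  h <- tabulate(pmin(pmax(findInterval(v, seq(range[1], range[2],
                                              length.out = n_bins + 1),
                                       rightmost.closed = TRUE), 1L), n_bins),
                n_bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Cellwise summary of dynamic maps by compartment
#'
#' Averages the pixelwise phasor g, phasor s, power-law slope beta and the
#' activity scalar g*s over the whole cell, its nucleus and its cytoplasm, and
#' adds distribution summaries used as dynamic features: skewness and Shannon
#' entropy of the pixelwise values, and a box-counting texture dimension of the
#' high-activity region (pixels above the cellwise median) of the g and s maps.
#'
#' @param maps A [dynamic_maps()] result.
#' @param cell_mask Logical matrix for the whole cell.
#' @param nucleus_mask Logical matrix, subset of `cell_mask` (may be empty).
#' @return One-row data frame; nucleus/cytoplasm fields are `NA` with
#'   `nucleus_flag = "empty"` when the nucleus mask is empty.
#' @export
aggregate_cell_dynamics <- function(maps, cell_mask, nucleus_mask) {
  cell_mask <- cell_mask != 0
  nucleus_mask <- nucleus_mask != 0
  if (any(nucleus_mask & !cell_mask)) stop("nucleus mask not inside cell mask")
  cyto_mask <- cell_mask & !nucleus_mask
  comp_means <- function(m) {
    vals <- function(mask) if (any(mask)) maps[[m]][mask] else NA_real_
    c(cell = mean(vals(cell_mask)), nucleus = mean(vals(nucleus_mask)),
      cytoplasm = mean(vals(cyto_mask)))
  }
  gs_map <- maps$g * maps$s
  gsm <- function(mask) if (any(mask)) mean(gs_map[mask]) else NA_real_
  bvals <- maps$beta[cell_mask]
  out <- data.frame(
    g_cell = comp_means("g")["cell"], g_nucleus = comp_means("g")["nucleus"],
    g_cytoplasm = comp_means("g")["cytoplasm"],
    s_cell = comp_means("s")["cell"], s_nucleus = comp_means("s")["nucleus"],
    s_cytoplasm = comp_means("s")["cytoplasm"],
    beta_cell = comp_means("beta")["cell"],
    beta_nucleus = comp_means("beta")["nucleus"],
    beta_cytoplasm = comp_means("beta")["cytoplasm"],
    gs_cell = gsm(cell_mask), gs_nucleus = gsm(nucleus_mask),
    gs_cytoplasm = gsm(cyto_mask),
    beta_skewness = e1071::skewness(bvals),
    beta_entropy = .shannon_entropy(bvals),
    g_entropy = .shannon_entropy(maps$g[cell_mask]),
    s_entropy = .shannon_entropy(maps$s[cell_mask]),
    g_texture_dim = box_count_dim(cell_mask & maps$g > median(maps$g[cell_mask])),
    s_texture_dim = box_count_dim(cell_mask & maps$s > median(maps$s[cell_mask])),
    nucleus_flag = if (any(nucleus_mask)) "ok" else "empty",
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Two-sample Student's t test (equal variance, two-sided)
#'
#' @param values_a,values_b Numeric vectors, each of length >= 3.
#' @return List with `t` and `p`. Two constant groups with equal means give
#'   `t = 0, p = 1`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs at least 3 values")
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(values_a) - mean(values_b)) * Inf, p = 0))
  }
  ht <- t.test(values_a, values_b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Pseudo-colorize an activity map (blue = low, red = high)
#'
#' Linear blue-to-red colormap over `value_range`; values outside the range are
#' clipped, `NA`/unmasked pixels are black. The default range `[1, 2]` matches
#' the display convention for power-law slope maps; for phasor g*s maps pass
#' the observed range.
#'
#' @param map Numeric matrix (typically from [dynamic_maps()]).
#' @param value_range Length-2 numeric, low before high, nondegenerate.
#' @param mask Optional logical matrix restricting the colored region.
#' @return An `H x W x 3` RGB array in \[0, 1\].
#' @export
pseudocolor <- function(map, value_range = c(1, 2), mask = NULL) {
  if (length(value_range) != 2 || diff(value_range) <= 0)
    stop("value_range must be increasing and nondegenerate")
  t <- (map - value_range[1]) / diff(value_range)
  t <- pmin(pmax(t, 0), 1)
  if (!is.null(mask)) t[!(mask != 0)] <- NA
  rgb <- array(0, dim = c(dim(map), 3))
  rgb[, , 1] <- ifelse(is.na(t), 0, t)        # red ramps up
  rgb[, , 3] <- ifelse(is.na(t), 0, 1 - t)    # blue ramps down
  rgb
}

#' Horizontal line profile through a cell's center
#'
#' Averages the map over the 10 central horizontal lines of the cell (the rows
#' bracketing the mask centroid row), restricted to mask pixels, one value per
#' column of the cell's bounding box.
#'
#' @param map Numeric matrix.
#' @param cell_mask Logical matrix.
#' @param n_rows Number of central rows to average (default 10).
#' @return List with `profile` (length = bounding-box width; `NA` where no
#'   mask pixel falls in the averaged rows), `columns`, and `flag`
#'   (`"short"` when the cell is fewer than `n_rows` rows tall).
#' @export
line_profile <- function(map, cell_mask, n_rows = 10) {
  cell_mask <- cell_mask != 0
  if (!any(cell_mask)) stop("empty cell mask")
  ij <- which(cell_mask, arr.ind = TRUE)
  rows_range <- range(ij[, 1]); cols_range <- range(ij[, 2])
  height <- diff(rows_range) + 1
  flag <- if (height < n_rows) "short" else "ok"
  c_row <- round(mean(ij[, 1]))
  half <- n_rows %/% 2
  rows <- max(rows_range[1], c_row - half + 1):min(rows_range[2], c_row + half)
  cols <- cols_range[1]:cols_range[2]
  prof <- vapply(cols, function(j) {
    sel <- cell_mask[rows, j]
    if (!any(sel)) NA_real_ else mean(map[rows, j][sel])
  }, numeric(1))
  list(profile = prof, columns = cols, flag = flag)
}

#' Keep the first `n_frames` frames of a stack
#'
#' @param stack A `uv_stack`.
#' @param n_frames Number of leading frames to retain (8 <= n <= length).
#' @return A `uv_stack` with updated length; frame rate unchanged.
#' @export
truncate_stack <- function(stack, n_frames) {
  if (n_frames < 8) stop("n_frames must be >= 8")
  if (n_frames > dim(stack)[3]) stop("n_frames exceeds stack length")
  uv_stack(unclass(stack)[, , seq_len(n_frames), drop = FALSE],
           frame_rate = attr(stack, "frame_rate"),
           pixel_size = attr(stack, "pixel_size"))
}

#' Degrade lateral resolution by blurring and downsampling
#'
#' Gaussian blur (sigma = factor/2 px) followed by subsampling every
#' `factor`-th pixel, per frame; the pixel size scales by `factor`. Mimics
#' acquiring the same field at `factor`-fold worse lateral resolution.
#'
#' @param stack A `uv_stack`.
#' @param factor Integer >= 2.
#' @return A `uv_stack` of size `floor(H/factor) x floor(W/factor) x T`.
#' @export
degrade_resolution <- function(stack, factor = 2) {
  factor <- as.integer(factor)
  if (factor < 2) stop("factor must be an integer >= 2")
  d <- dim(stack)
  keep_r <- seq(1L, d[1], by = factor)
  keep_c <- seq(1L, d[2], by = factor)
  if (length(keep_r) < 16 || length(keep_c) < 16)
    stop("degraded stack would be smaller than 16 px")
  out <- array(0, dim = c(length(keep_r), length(keep_c), d[3]))
  for (t in seq_len(d[3])) {
    bl <- as.matrix(EBImage::gblur(EBImage::Image(unclass(stack)[, , t]),
                                   sigma = factor / 2))
    out[, , t] <- bl[keep_r, keep_c]
  }
  uv_stack(out, frame_rate = attr(stack, "frame_rate"),
           pixel_size = attr(stack, "pixel_size") * factor)
}
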