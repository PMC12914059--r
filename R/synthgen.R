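#' @importFrom stats rnorm runif sd fft mvfft median quantile coef lm t.test
#'   predict setNames dist
#' @importFrom utils head tail write.csv read.csv
NULL

# Cell classes known to the generator. The first three are static phenotypes;
# the last two are activated cells distinguished only by intracellular dynamics.
.uv_classes <- c("activated", "quiescent", "dead", "CD4-like", "CD8-like")

#' Scene configuration for the synthetic deep-UV generator
#'
#' Bundles the acquisition and population parameters of one simulated field of
#' view. Defaults follow the acquisition used throughout the package: ~8 Hz
#' frame rate, 500 frames, 255 nm illumination rendered as background-corrected
#' attenuation in \[0, 1\].
#'
#' @param image_height,image_width Field size in pixels.
#' @param pixel_size Pixel pitch in micrometers per pixel.
#' @param n_cells Number of cells to place.
#' @param class_mix Named proportions over
#'   `c("activated","quiescent","dead","CD4-like","CD8-like")`; must sum to 1.
#'   Unnamed classes default to 0.
#' @param seed Integer seed; identical config + seed gives bit-identical scenes
#'   and stacks.
#' @param frame_rate Acquisition rate in Hz.
#' @param n_frames Number of frames in a rendered stack (>= 2).
#' @param background Static background attenuation level.
#' @param noise_sd Standard deviation of white detector noise added per frame.
#'
#' @return An object of class `scene_config` (a validated list).
#' @export
scene_config <- function(image_height = 512, image_width = 512,
                         pixel_size = 0.2, n_cells = 40,
                         class_mix = c(activated = 0.3, quiescent = 0.4, dead = 0.3),
                         seed = 1L, frame_rate = 8, n_frames = 500,
                         background = 0.02, noise_sd = 0.005) {
  mix <- setNames(numeric(length(.uv_classes)), .uv_classes)
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% .uv_classes))
    stop("class_mix must be named with classes among: ",
         paste(.uv_classes, collapse = ", "))
  mix[names(class_mix)] <- class_mix
  if (abs(sum(mix) - 1) > 1e-9) stop("class_mix proportions must sum to 1")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (n_cells < 0) stop("n_cells must be non-negative")
  structure(list(
    image_height = as.integer(image_height),
    image_width  = as.integer(image_width),
    pixel_size = pixel_size, n_cells = as.integer(n_cells),
    class_mix = mix, seed = as.integer(seed),
    frame_rate = frame_rate, n_frames = as.integer(n_frames),
    background = background, noise_sd = noise_sd
  ), class = "scene_config")
}

# Per-class geometry and attenuation defaults (radii in micrometers,
# attenuations unitless in [0,1]). T cells have a high nucleus:cytoplasm
# ratio; activation increases size and internal texture; dead cells are more
# attenuating with a condensed nucleus and an irregular boundary.
.class_geometry <- function(class) {
  switch(class,
    "quiescent" = list(radius = 3.5, nuc_frac = 0.60, att_nuc = 0.60,
                       att_cyt = 0.32, texture_sd = 0.02, irregular = 0),
    "activated" = ,
    "CD4-like"  = ,
    "CD8-like"  = list(radius = 5.0, nuc_frac = 0.60, att_nuc = 0.72,
                       att_cyt = 0.42, texture_sd = 0.08, irregular = 0),
    "dead"      = list(radius = 3.2, nuc_frac = 0.45, att_nuc = 0.90,
                       att_cyt = 0.55, texture_sd = 0.05, irregular = 0.25),
    stop("unknown class: ", class))
}

# Compartment dynamic parameters: spectral exponent beta and fluctuation
# amplitude (attenuation units). CD4-like cytoplasm is the most active
# (higher beta and 1.5x amplitude); nuclei are identically distributed across
# subtypes. Values are class means; make_scene adds cell-to-cell jitter
# (beta sd 0.05, 10% lognormal amplitude) to emulate biological variability.
.class_dynamics <- function(class) {
  switch(class,
    "CD4-like" = list(beta_cyt = 1.7, amp_cyt = 0.030, beta_nuc = 1.15, amp_nuc = 0.010),
    "CD8-like" = list(beta_cyt = 1.3, amp_cyt = 0.020, beta_nuc = 1.15, amp_nuc = 0.010),
    # static phenotypes get mild dynamics so any stack is analyzable
    list(beta_cyt = 1.3, amp_cyt = 0.015, beta_nuc = 1.15, amp_nuc = 0.008))
}

#' Build a synthetic static scene with ground truth
#'
#' Places non-overlapping disc-shaped cells (reject-and-retry) with a
#' concentric, more attenuating nucleus (255 nm targets nucleic acids), draws
#' the static attenuation frame in \[0, 1\], and returns per-cell ground truth:
#' label mask, nucleus mask and a `CellSpec` table including each cell's
#' compartment dynamic parameters.
#'
#' @param config A [scene_config()].
#' @param max_tries Rejection-sampling attempts per cell before failing.
#' @return A list of class `uv_scene`: `frame` (matrix, attenuation in
#'   \[0, 1\]), `truth` with `label_mask`, `nucleus_mask` (both integer
#'   matrices, 0 = background) and `cells` (one row per cell: center, radii in
#'   pixels, attenuations, class, compartment beta/amplitude).
#' @export
make_scene <- function(config, max_tries = 200L) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  H <- config$image_height; W <- config$image_width
  frame <- matrix(config$background, H, W)
  label_mask <- matrix(0L, H, W)
  nucleus_mask <- matrix(0L, H, W)

  n <- config$n_cells
  classes <- character(0)
  if (n > 0) {
    counts <- floor(config$class_mix * n)
    rem <- n - sum(counts)
    if (rem > 0) {  # distribute the remainder to the largest fractional parts
      frac <- config$class_mix * n - counts
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[add] <- counts[add] + 1
    }
    classes <- sample(rep(names(counts), counts))
  }

  cells <- data.frame(cell = integer(0), class = character(0),
                      center_row = numeric(0), center_col = numeric(0),
                      cell_radius = numeric(0), nucleus_radius = numeric(0),
                      att_nucleus = numeric(0), att_cytoplasm = numeric(0),
                      beta_nucleus = numeric(0), beta_cytoplasm = numeric(0),
                      amp_nucleus = numeric(0), amp_cytoplasm = numeric(0),
                      stringsAsFactors = FALSE)

  placed <- list()
  for (k in seq_along(classes)) {
    geo <- .class_geometry(classes[k])
    dyn <- .class_dynamics(classes[k])
    r_px <- geo$radius / config$pixel_size
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cr <- runif(1, r_px + 3, H - r_px - 3)
      cc <- runif(1, r_px + 3, W - r_px - 3)
      clear <- TRUE
      for (p in placed)
        if ((cr - p[1])^2 + (cc - p[2])^2 < (r_px + p[3] + 3)^2) { clear <- FALSE; break }
      if (clear) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not place cell ", k, " of ", length(classes),
           " after ", max_tries, " tries: cell density too high for a ",
           H, "x", W, " field at these radii")
    placed[[k]] <- c(cr, cc, r_px)

    r_nuc <- geo$nuc_frac * r_px
    # irregular boundary for dead cells: low-order radial perturbation
    nharm <- 5L
    amp_irr <- geo$irregular
    ph_irr <- runif(nharm, 0, 2 * pi)
    amp_h <- if (amp_irr > 0) amp_irr * runif(nharm, 0.2, 1) / sqrt(1:nharm) else numeric(nharm)

    rows <- max(1L, floor(cr - r_px * (1 + amp_irr) - 2)):min(H, ceiling(cr + r_px * (1 + amp_irr) + 2))
    cols <- max(1L, floor(cc - r_px * (1 + amp_irr) - 2)):min(W, ceiling(cc + r_px * (1 + amp_irr) + 2))
    dy <- outer(rows - cr, rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - cc)
    rr <- sqrt(dy^2 + dx^2)
    rad <- r_px
    if (amp_irr > 0) {
      th <- atan2(dy, dx)
      rad <- r_px * (1 + Reduce(`+`, lapply(seq_len(nharm), function(h)
        amp_h[h] * cos(h * th + ph_irr[h]))))
    }
    inside <- rr <= rad
    in_nuc <- rr <= r_nuc

    sub_lab <- label_mask[rows, cols]
    sub_nuc <- nucleus_mask[rows, cols]
    sub_frm <- frame[rows, cols]
    sub_lab[inside] <- k
    sub_nuc[in_nuc & inside] <- k
    tex <- matrix(rnorm(length(sub_frm), 0, geo$texture_sd),
                  nrow(sub_frm), ncol(sub_frm))
    vals <- ifelse(in_nuc & inside, geo$att_nuc, geo$att_cyt) + tex
    sub_frm[inside] <- pmin(pmax(vals[inside], 0), 1)
    label_mask[rows, cols] <- sub_lab
    nucleus_mask[rows, cols] <- sub_nuc
    frame[rows, cols] <- sub_frm

    # cell-to-cell variability of the dynamic parameters
    jb <- function(mu) min(max(rnorm(1, mu, 0.05), 0), 3)
    ja <- function(mu) mu * exp(rnorm(1, 0, 0.1))
    cells <- rbind(cells, data.frame(
      cell = k, class = classes[k], center_row = cr, center_col = cc,
      cell_radius = r_px, nucleus_radius = r_nuc,
      att_nucleus = geo$att_nuc, att_cytoplasm = geo$att_cyt,
      beta_nucleus = jb(dyn$beta_nuc), beta_cytoplasm = jb(dyn$beta_cyt),
      amp_nucleus = ja(dyn$amp_nuc), amp_cytoplasm = ja(dyn$amp_cyt),
      stringsAsFactors = FALSE))
  }
  stopifnot(all(cells$nucleus_radius < cells$cell_radius),
            all(cells$beta_cytoplasm >= 0 & cells$beta_cytoplasm <= 3))
  structure(list(frame = frame, config = config,
                 truth = list(label_mask = label_mask,
                              nucleus_mask = nucleus_mask, cells = cells)),
            class = "uv_scene")
}

#' Synthesize one pixel trace with a power-law magnitude spectrum
#'
#' Builds a real time series whose discrete Fourier magnitudes at positive
#' frequencies are exactly proportional to `f^-beta`, with independent uniform
#' random phases (the Nyquist coefficient, which must be real, keeps its exact
#' magnitude and receives a random sign). The zero-mean fluctuation is rescaled
#' so its standard deviation equals `amplitude`, then added to `baseline`.
#'
#' @param beta Spectral decay exponent (>= 0); beta = 0 gives white fluctuation.
#' @param amplitude Fluctuation standard deviation in attenuation units
#'   (0 gives a constant trace at `baseline`).
#' @param n Number of samples (>= 8).
#' @param frame_rate Sampling rate in Hz.
#' @param baseline Constant level the fluctuation rides on.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
synth_trace <- function(beta, amplitude, n, frame_rate, baseline = 0.5,
                        seed = NULL) {
  if (beta < 0) stop("beta must be >= 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (n < 8) stop("n must be >= 8")
  if (!is.null(seed)) set.seed(seed)
  if (amplitude == 0) return(rep(baseline, n))
  n <- as.integer(n)
  nhalf <- n %/% 2
  f <- (1:nhalf) * frame_rate / n
  mag <- f^(-beta)
  ph <- runif(nhalf, 0, 2 * pi)
  pos <- mag * exp(1i * ph)
  if (n %% 2 == 0) pos[nhalf] <- mag[nhalf] * sign(cos(ph[nhalf]))
  spec <- complex(real = numeric(n))
  spec[2:(nhalf + 1)] <- pos
  if (nhalf > 1) spec[n:(n - nhalf + 2)] <- Conj(pos[1:(nhalf - 1)])
  x <- Re(fft(spec, inverse = TRUE)) / n
  baseline + x / sd(x) * amplitude
}

# Vectorized trace synthesis: one column per pixel, shared magnitude spectrum,
# independent phases. Used by render_stack; returns an n x npix matrix.
.synth_traces <- function(beta, amplitude, n, frame_rate, baselines) {
  npix <- length(baselines)
  nhalf <- n %/% 2
  f <- (1:nhalf) * frame_rate / n
  mag <- f^(-beta)
  ph <- matrix(runif(nhalf * npix, 0, 2 * pi), nhalf, npix)
  pos <- mag * exp(1i * ph)
  if (n %% 2 == 0) pos[nhalf, ] <- mag[nhalf] * sign(cos(ph[nhalf, ]))
  spec <- matrix(complex(real = numeric(n * npix)), n, npix)
  spec[2:(nhalf + 1), ] <- pos
  if (nhalf > 1) spec[n:(n - nhalf + 2), ] <- Conj(pos[1:(nhalf - 1), , drop = FALSE])
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  sds <- apply(x, 2, sd)
  sweep(x, 2, amplitude / sds, `*`) +
    matrix(baselines, n, npix, byrow = TRUE)
}

#' Render a dynamic image stack from a synthetic scene
#'
#' Gives every cell pixel a temporal trace with the power-law spectrum of its
#' compartment (nucleus or cytoplasm, per the scene's `CellSpec` table);
#' background pixels stay at their static value plus white detector noise of
#' the configured standard deviation. Cell pixels carry the pure power-law
#' fluctuation, so the spectral structure the analysis estimates is exactly
#' the configured one.
#'
#' @param config The [scene_config()] used for [make_scene()].
#' @param scene The `uv_scene` to animate.
#' @return A `uv_stack`: numeric array `H x W x n_frames` with attributes
#'   `frame_rate` (Hz) and `pixel_size` (micrometers/pixel).
#' @export
render_stack <- function(config, scene) {
  stopifnot(inherits(config, "scene_config"), inherits(scene, "uv_scene"))
  if (config$n_frames != scene$config$n_frames)
    stop("n_frames in config does not match the scene's configuration")
  set.seed(config$seed + 77003L)  # offset so placement and dynamics decouple
  H <- config$image_height; W <- config$image_width; Tn <- config$n_frames
  stack <- array(rep(scene$frame, Tn), dim = c(H, W, Tn))
  lab <- scene$truth$label_mask
  nuc <- scene$truth$nucleus_mask
  cells <- scene$truth$cells
  for (k in seq_len(nrow(cells))) {
    for (comp in c("nucleus", "cytoplasm")) {
      idx <- if (comp == "nucleus") which(nuc == cells$cell[k]) else
        which(lab == cells$cell[k] & nuc != cells$cell[k])
      if (!length(idx)) next
      beta <- cells[[paste0("beta_", comp)]][k]
      amp  <- cells[[paste0("amp_", comp)]][k]
      if (amp <= 0) next
      tr <- .synth_traces(beta, amp, Tn, config$frame_rate, scene$frame[idx])
      lin <- outer(idx, (seq_len(Tn) - 1L) * (H * W), `+`)  # npix x T linear index
      stack[lin] <- t(tr)
    }
  }
  if (config$noise_sd > 0) {
    bg <- which(lab == 0L)
    lin <- outer(bg, (seq_len(Tn) - 1L) * (H * W), `+`)
    stack[lin] <- stack[lin] + rnorm(length(lin), 0, config$noise_sd)
  }
  uv_stack(stack, frame_rate = config$frame_rate, pixel_size = config$pixel_size)
}

#' Construct an image-stack object
#'
#' @param x Numeric array `H x W x T`.
#' @param frame_rate Frames per second (Hz).
#' @param pixel_size Micrometers per pixel.
#' @return `x` with class `uv_stack` and the two attributes attached.
#' @export
uv_stack <- function(x, frame_rate, pixel_size = 1) {
  stopifnot(is.array(x), length(dim(x)) == 3, frame_rate > 0)
  structure(x, frame_rate = frame_rate, pixel_size = pixel_size,
            class = c("uv_stack", "array"))
}

#' @export
print.uv_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("uv_stack: %d x %d px, %d frames @ %.3g Hz, %.3g um/px\n",
              d[1], d[2], d[3], attr(x, "frame_rate"), attr(x, "pixel_size")))
  invisible(x)
}

#' Write a stack (or label mask) to a multi-page TIFF file
#'
#' Stacks are written as 32-bit float pages; integer label masks as 16-bit.
#'
#' @param x A `uv_stack` or an integer matrix label mask.
#' @param path Output file path.
#' @export
write_stack_tiff <- function(x, path) {
  if (is.matrix(x) && is.integer(x)) {
    tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L)
  } else {
    stopifnot(length(dim(x)) == 3)
    pages <- lapply(seq_len(dim(x)[3]), function(t) x[, , t])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_stack_tiff()]
#'
#' @param path File path.
#' @param frame_rate,pixel_size Metadata to attach (TIFF does not carry them).
#' @return A `uv_stack`.
#' @export
read_stack_tiff <- function(path, frame_rate = 8, pixel_size = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  uv_stack(array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))),
           frame_rate = frame_rate, pixel_size = pixel_size)
}
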