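test_that("pixel spectra honor DC removal and locate tones", {
  tr <- sin(2 * pi * 1 * (0:499) / 8)
  sp <- pixel_spectrum(tr, 8)
  expect_equal(length(sp$f), 250)
  expect_equal(max(sp$f), 4)           # Nyquist for 8 Hz
  expect_true(all(diff(sp$f) > 0))
  expect_lt(abs(sp$f[which.max(sp$I)] - 1), 8 / 500 + 1e-9)
  # constant offset leaves the spectrum unchanged
  sp2 <- pixel_spectrum(tr + 3.7, 8)
  expect_equal(sp$I, sp2$I, tolerance = 1e-9)
  # constant trace has an all-zero spectrum
  expect_true(all(pixel_spectrum(rep(0.5, 100), 8)$I < 1e-10))
  expect_error(pixel_spectrum(1:5, 8), "at least 8")
})

test_that("exact power laws are fitted exactly", {
  for (b in c(0, 1, 2)) {
    ft <- fit_power_law(exact_spectrum(b))
    expect_equal(ft$beta, b, tolerance = 1e-10)
    expect_equal(ft$r2, 1, tolerance = 1e-10)
    expect_equal(ft$flag, "ok")
  }
  # synthesized beta = 2 trace: log-log linear with slope -2
  tr <- synth_trace(2, 0.05, 500, 8, seed = 1)
  ft <- fit_power_law(pixel_spectrum(tr, 8))
  expect_equal(ft$beta, 2, tolerance = 0.02)
  expect_gt(ft$r2, 0.99)
})

test_that("the sub-0.1 Hz exclusion rule is enforced", {
  sp <- exact_spectrum(1.5)            # 500 frames @ 8 Hz, df = 0.016 Hz
  ft <- fit_power_law(sp)
  # retained grid starts at the first bin >= 0.1 Hz: k = 7, f = 0.112 Hz
  expect_equal(ft$n_bins, sum(sp$f >= 0.1))
  expect_equal(min(sp$f[sp$f >= 0.1]), 7 * 8 / 500)
  # corrupting only the sub-0.1 Hz bins changes nothing
  sp2 <- sp; sp2$I[sp2$f < 0.1] <- 1e6
  expect_equal(fit_power_law(sp2)$beta, ft$beta)
  expect_equal(unlist(phasor(sp2)), unlist(phasor(sp)))
  expect_error(fit_power_law(structure(list(f = c(1, 2, 3), I = c(1, 1, 1)),
                                       class = "pixel_spectrum")),
               "at least 5")
})

test_that("degenerate spectra are flagged, zero bins dropped", {
  sp <- exact_spectrum(1)
  sp$I[] <- 0
  ft <- fit_power_law(sp)
  expect_true(is.na(ft$beta))
  expect_equal(ft$flag, "degenerate")
  # isolated zero bins are dropped, not fatal
  sp2 <- exact_spectrum(1)
  sp2$I[100] <- 0
  ft2 <- fit_power_law(sp2)
  expect_equal(ft2$beta, 1, tolerance = 1e-6)
})

test_that("phasor contracts: constant trace at origin, delta decay at (1,0)", {
  p0 <- phasor(pixel_spectrum(rep(0.5, 500), 8))
  expect_equal(phasor_distance(p0), 0)
  # all spectral mass exactly at the start of the retained axis (x = 0)
  f <- c(0.1, 1, 2, 3, 4)
  I <- c(5, 0, 0, 0, 0)
  pd <- phasor(structure(list(f = f, I = I), class = "pixel_spectrum"))
  expect_equal(pd$g, 1, tolerance = 1e-9)
  expect_equal(pd$s, 0, tolerance = 1e-9)
})

test_that("phasor distance from the origin increases with beta", {
  ds <- vapply(c(0.5, 1, 1.5, 2, 2.5, 3),
               function(b) phasor_distance(phasor(exact_spectrum(b))),
               numeric(1))
  expect_true(all(diff(ds) > 0))
  # and the beta = 2 spectrum maps strictly further out than beta = 1
  expect_gt(phasor_distance(phasor(exact_spectrum(2))),
            phasor_distance(phasor(exact_spectrum(1))))
})

test_that("dynamic maps cover exactly the mask and are deterministic", {
  cfg <- scene_config(image_height = 64, image_width = 64, n_cells = 1,
                      class_mix = c("CD4-like" = 1), seed = 3, n_frames = 128)
  sc <- make_scene(cfg)
  stk <- render_stack(cfg, sc)
  cm <- sc$truth$label_mask == 1
  maps <- dynamic_maps(stk, cm)
  expect_equal(sum(is.finite(maps$beta)), sum(cm))
  expect_equal(sum(is.finite(maps$g)), sum(cm))
  expect_true(all(is.na(maps$beta[!cm])))
  maps2 <- dynamic_maps(stk, cm)
  expect_identical(maps, maps2)
  # empty mask: empty maps, no error
  m0 <- dynamic_maps(stk, matrix(0L, 64, 64))
  expect_true(all(is.na(m0$beta)))
  # offset invariance: adding a constant to every frame changes nothing
  stk_off <- uv_stack(unclass(stk) + 0.1, frame_rate = 8, pixel_size = 0.2)
  maps_off <- dynamic_maps(stk_off, cm)
  expect_equal(maps$beta, maps_off$beta, tolerance = 1e-8)
  expect_equal(maps$g, maps_off$g, tolerance = 1e-8)
  # cytoplasm is more active than the nucleus in a CD4-like cell
  nm <- sc$truth$nucleus_mask == 1
  expect_gt(mean(maps$beta[cm & !nm]), mean(maps$beta[nm]))
})

test_that("cellwise aggregation obeys the area-weighted decomposition", {
  cm <- disc_mask(12, side = 41)
  nm <- disc_mask(6, side = 41)
  mk_map <- function(v) {
    m <- matrix(NA_real_, 41, 41); m[cm] <- v; m
  }
  set.seed(8)
  maps <- structure(list(g = mk_map(runif(sum(cm))),
                         s = mk_map(runif(sum(cm))),
                         beta = mk_map(runif(sum(cm), 1, 2)),
                         r2 = mk_map(1), f_min = 0.1), class = "dynamic_maps")
  agg <- aggregate_cell_dynamics(maps, cm, nm)
  w_nuc <- sum(nm) / sum(cm)
  expect_equal(agg$beta_cell,
               w_nuc * agg$beta_nucleus + (1 - w_nuc) * agg$beta_cytoplasm)
  expect_equal(agg$g_cell, w_nuc * agg$g_nucleus + (1 - w_nuc) * agg$g_cytoplasm)
  # uniform maps: every compartment mean equals the uniform value
  mapsu <- structure(list(g = mk_map(0.4), s = mk_map(0.2),
                          beta = mk_map(1.5), r2 = mk_map(1), f_min = 0.1),
                     class = "dynamic_maps")
  aggu <- aggregate_cell_dynamics(mapsu, cm, nm)
  expect_equal(aggu$beta_cell, 1.5); expect_equal(aggu$beta_nucleus, 1.5)
  expect_equal(aggu$beta_cytoplasm, 1.5); expect_equal(aggu$gs_cell, 0.08)
  # empty nucleus flags
  agge <- aggregate_cell_dynamics(mapsu, cm, cm & FALSE)
  expect_equal(agge$nucleus_flag, "empty")
  expect_true(is.na(agge$beta_nucleus))
  expect_error(aggregate_cell_dynamics(mapsu, nm, cm), "inside")
})

test_that("group comparison is a two-sided equal-variance t test", {
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50, 5)
  r <- compare_groups(a, b)
  expect_lt(r$p, 1e-10)
  # antisymmetry
  r2 <- compare_groups(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  # identical groups
  expect_equal(compare_groups(a, a), list(t = 0, p = 1))
  # degenerate equal constants
  expect_equal(compare_groups(rep(1, 5), rep(1, 5)), list(t = 0, p = 1))
  expect_error(compare_groups(1:2, 1:5), "at least 3")
  # agrees with the closed-form pooled-variance statistic
  t_manual <- (mean(a) - mean(b)) /
    sqrt(((49 * var(a) + 49 * var(b)) / 98) * (1 / 50 + 1 / 50))
  expect_equal(r$t, t_manual)
})

test_that("pseudocolor maps the value range linearly from blue to red", {
  m <- matrix(1, 5, 5)
  rgb <- pseudocolor(m, c(1, 2))
  expect_equal(rgb[1, 1, ], c(0, 0, 1))            # low -> blue
  rgb2 <- pseudocolor(matrix(2, 5, 5), c(1, 2))
  expect_equal(rgb2[1, 1, ], c(1, 0, 0))           # high -> red
  rgb3 <- pseudocolor(matrix(1.5, 5, 5), c(1, 2))
  expect_equal(rgb3[1, 1, ], c(0.5, 0, 0.5))       # midpoint
  # clipping
  expect_equal(pseudocolor(matrix(9, 2, 2), c(1, 2))[1, 1, ], c(1, 0, 0))
  expect_error(pseudocolor(m, c(2, 2)), "nondegenerate")
})

test_that("line profiles average the 10 central rows and dip at the nucleus", {
  cm <- disc_mask(15, side = 51)
  m <- matrix(2, 51, 51)
  nm <- disc_mask(7, side = 51)
  m[nm] <- 1                                   # quieter nucleus
  lp <- line_profile(m, cm)
  expect_equal(lp$flag, "ok")
  expect_equal(length(lp$profile), diff(range(which(cm, arr.ind = TRUE)[, 2])) + 1)
  mid <- ceiling(length(lp$profile) / 2)
  expect_lt(lp$profile[mid], lp$profile[2])    # central dip
  # uniform map -> flat profile
  lpu <- line_profile(matrix(3, 51, 51), cm)
  expect_true(all(abs(lpu$profile - 3) < 1e-12))
  # short cells are flagged
  shallow <- matrix(FALSE, 20, 20); shallow[9:12, 5:15] <- TRUE
  expect_equal(line_profile(matrix(1, 20, 20), shallow)$flag, "short")
})

test_that("stack truncation keeps leading frames and validates bounds", {
  cfg <- scene_config(image_height = 32, image_width = 32, pixel_size = 0.5,
                      n_cells = 1, class_mix = c(quiescent = 1), seed = 2,
                      n_frames = 50)
  stk <- render_stack(cfg, make_scene(cfg))
  t300 <- truncate_stack(stk, 20)
  expect_equal(dim(t300)[3], 20)
  expect_equal(unclass(t300), unclass(stk)[, , 1:20], ignore_attr = TRUE)
  expect_identical(unclass(truncate_stack(stk, 50)), unclass(stk))
  expect_error(truncate_stack(stk, 7), ">= 8")
  expect_error(truncate_stack(stk, 51), "exceeds")
})

test_that("resolution degradation halves the grid and rescales pixel size", {
  arr <- array(0.3, dim = c(64, 64, 4))
  stk <- uv_stack(arr, frame_rate = 8, pixel_size = 0.2)
  dg <- degrade_resolution(stk, 2)
  expect_equal(dim(dg), c(32, 32, 4))
  expect_equal(attr(dg, "pixel_size"), 0.4)
  # constant frames are unchanged in value away from the border
  expect_equal(unclass(dg)[8:24, 8:24, 1],
               matrix(0.3, 17, 17), tolerance = 1e-6)
  expect_error(degrade_resolution(stk, 1), "factor")
  expect_error(degrade_resolution(uv_stack(array(0, c(20, 20, 4)), 8), 2),
               "16 px")
})
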