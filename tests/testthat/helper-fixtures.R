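# Shared fixture builders. Everything is generated in code at test time.

# Filled disc mask of radius r centered in a square image.
disc_mask <- function(r, side = 2 * r + 11) {
  c0 <- (side + 1) / 2
  outer(seq_len(side), seq_len(side),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

# Two-level cell crop: inner disc (nucleus analog) at `inner_val`, outer
# annulus at `outer_val`.
two_level_cell <- function(r_cell = 30, r_nuc = 15, inner_val = 0.8,
                           outer_val = 0.4, side = 81) {
  c0 <- (side + 1) / 2
  rr <- sqrt(outer(seq_len(side) - c0, rep(1, side))^2 +
               outer(rep(1, side), seq_len(side) - c0)^2)
  list(crop = ifelse(rr <= r_cell, ifelse(rr <= r_nuc, inner_val, outer_val), 0),
       rr = rr)
}

# Small static scene shared across tests (three phenotypes, no dynamics).
small_static_config <- function(seed = 1, n_cells = 5, side = 220) {
  scene_config(image_height = side, image_width = side, n_cells = n_cells,
               class_mix = c(activated = 0.4, quiescent = 0.4, dead = 0.2),
               seed = seed, n_frames = 2)
}

# Exact power-law spectrum on the 500-frame / 8-Hz frequency grid.
exact_spectrum <- function(beta, n = 500, frame_rate = 8) {
  f <- (1:(n %/% 2)) * frame_rate / n
  structure(list(f = f, I = f^(-beta)), class = "pixel_spectrum")
}

phasor_distance <- function(p) sqrt(p$g^2 + p$s^2)
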