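# Shared fixtures: small phantoms and hand-drawn masks built in code.

small_phantom_2d <- function(frac = 0.4, seed = 1, n_cells = 10,
                             noise_sd = 0.02, ...) {
  make_phago_phantom_2d(phago_phantom_config(
    image_height_px = 320L, image_width_px = 320L, n_cells = n_cells,
    n_background_beads = 40L, engulfment_fraction = frac,
    noise_sd = noise_sd, seed = seed, ...))
}

# long-format repeated-measures table: 2 groups x n animals x k levels,
# group shift on top of animal intercepts and residual noise
sim_rm_table <- function(seed = 7, n_per_group = 12, k = 4, shift = 1,
                         subj_sd = 0.5, resid_sd = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    d <- expand.grid(animal_id = seq_len(n), level = paste0("L", seq_len(k)))
    d$group <- ifelse(d$animal_id <= n_per_group, "sham", "TBI")
    ai <- rnorm(n, 0, subj_sd)
    d$value <- ifelse(d$group == "TBI", shift, 0) + ai[d$animal_id] +
      rnorm(nrow(d), 0, resid_sd)
    d
  })
}

# a filled digitized disk as a logical matrix
disk_mask <- function(r, pad = 3L) {
  n <- 2L * ceiling(r) + 2L * pad
  c0 <- (n + 1) / 2
  outer(1:n, 1:n, function(y, x) (y - c0)^2 + (x - c0)^2 <= r^2)
}

# horizontal 1 x len bar, centered in a padded field
bar_mask <- function(len, pad = 3L) {
  m <- matrix(FALSE, 2L * pad + 1L, len + 2L * pad)
  m[pad + 1L, (pad + 1L):(pad + len)] <- TRUE
  m
}

# place several mask tiles into one labeling field, left to right
compose_masks <- function(masks, gap = 4L) {
  h <- max(vapply(masks, nrow, 1L))
  w <- sum(vapply(masks, ncol, 1L)) + gap * (length(masks) + 1L)
  out <- matrix(FALSE, h + 2L, w)
  x0 <- gap
  for (m in masks) {
    out[1:nrow(m) + 1L, x0 + 1:ncol(m)] <- m
    x0 <- x0 + ncol(m) + gap
  }
  out
}
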