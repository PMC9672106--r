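# shared fixtures: all synthetic, built in code at test time

wt_truth <- function(density = 0.5) {
  ground_truth(fractions = c(0.6, 0.4), monomer_median = 100,
               monomer_gsd = 1.4, active_prob = 1, density = density)
}

# degenerate (zero-variance) monomer law for exact bookkeeping
delta_truth <- function(fractions = c(0.6, 0.4), active_prob = 1) {
  ground_truth(fractions, monomer_median = 100, monomer_gsd = 1,
               active_prob = active_prob, density = 0.5)
}

quiet_camera <- function() camera_model(read_noise_sd = 0)

# render a single spot and return the photon image plus truth
one_spot_image <- function(x, y, brightness = 500, sigma = 1.2,
                           shape = c(48L, 48L), noise = FALSE, seed = 1) {
  cam <- quiet_camera()
  sp <- data.frame(x_px = x, y_px = y, brightness = brightness)
  raw <- render_frame(sp, sigma, cam, shape, seed = seed, noise = noise)
  counts_to_photons(raw, cam)
}

# independent oracle: apparent visible-class fractions by exhaustive
# enumeration of every per-fluorophore bleach state combination
enumerate_apparent_fractions <- function(fractions, q) {
  n_max <- length(fractions)
  w <- numeric(n_max)
  for (n in seq_len(n_max)) {
    if (fractions[n] == 0) next
    states <- expand.grid(rep(list(c(0L, 1L)), n))  # 1 = still active
    for (s in seq_len(nrow(states))) {
      st <- as.integer(states[s, ])
      k <- sum(st)
      if (k == 0) next
      p <- prod(ifelse(st == 1L, q, 1 - q))
      w[k] <- w[k] + fractions[n] * p
    }
  }
  w / sum(w)
}
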