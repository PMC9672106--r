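#' Draw single-fluorophore brightness values
#'
#' Samples i.i.d. brightness values from the configured single-fluorophore
#' law (lognormal with the given median and geometric SD). A geometric SD of
#' exactly 1 yields the degenerate law concentrated at the median, which is
#' useful for exact bookkeeping tests.
#'
#' @param truth a [ground_truth()] (only the monomer law fields are used).
#' @param n number of draws (>= 1).
#' @param seed integer seed; identical seeds give identical output.
#' @return numeric vector of `n` positive brightness values, photons.
#' @export
sim_monomer_brightness <- function(truth, n, seed = NULL) {
  assert(inherits(truth, "ground_truth"), "`truth` must be a ground_truth")
  assert(is_scalar_num(n) && n >= 1, "`n` must be >= 1")
  n <- as.integer(n)
  meanlog <- log(truth$monomer_median)
  sdlog <- log(truth$monomer_gsd)
  with_seed(seed, {
    if (sdlog == 0) rep(truth$monomer_median, n)
    else rlnorm(n, meanlog = meanlog, sdlog = sdlog)
  })
}

#' Simulate a population of mixed-order spots
#'
#' Each spot's oligomeric order is drawn from the truth fractions; the
#' number of active (fluorescent) fluorophores is Binomial(order,
#' active_prob); its brightness is the sum of that many independent
#' single-fluorophore draws. Spots with zero active fluorophores have
#' brightness 0 and are flagged invisible.
#'
#' @param truth a [ground_truth()].
#' @param n number of spots (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `true_order`, `active_count`,
#'   `brightness` (photons), `visible` (logical).
#' @export
sim_mixture_spots <- function(truth, n, seed = NULL) {
  assert(inherits(truth, "ground_truth"), "`truth` must be a ground_truth")
  assert(is_scalar_num(n) && n >= 1, "`n` must be >= 1")
  n <- as.integer(n)
  with_seed(seed, {
    order <- sample.int(length(truth$fractions), n, replace = TRUE,
                        prob = truth$fractions)
    active <- rbinom(n, size = order, prob = truth$active_prob)
    brightness <- numeric(n)
    tot <- sum(active)
    if (tot > 0) {
      draws <- sim_monomer_brightness(truth, tot, seed = NULL)
      idx <- rep.int(seq_len(n), active)
      b <- vapply(split(draws, factor(idx, levels = seq_len(n))), sum,
                  numeric(1))
      brightness <- unname(b)
    }
    data.frame(true_order = order, active_count = active,
               brightness = brightness, visible = active > 0)
  })
}

# expected photon count per pixel for one integrated isotropic Gaussian
# spot: pixel (row r, col c) covers [c-0.5, c+0.5] x [r-0.5, r-0.5+1]
# around 0-based pixel-center coordinates (x = column, y = row)
spot_expectation <- function(shape, x, y, brightness, sigma, trunc_sigma = 6) {
  nr <- shape[1]; nc <- shape[2]
  img <- matrix(0, nr, nc)
  for (i in seq_along(x)) {
    if (brightness[i] <= 0) next
    c0 <- max(0L, floor(x[i] - trunc_sigma * sigma))
    c1 <- min(nc - 1L, ceiling(x[i] + trunc_sigma * sigma))
    r0 <- max(0L, floor(y[i] - trunc_sigma * sigma))
    r1 <- min(nr - 1L, ceiling(y[i] + trunc_sigma * sigma))
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1; rows <- r0:r1
    gx <- pnorm((cols + 0.5 - x[i]) / sigma) - pnorm((cols - 0.5 - x[i]) / sigma)
    gy <- pnorm((rows + 0.5 - y[i]) / sigma) - pnorm((rows - 0.5 - y[i]) / sigma)
    img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] +
      brightness[i] * outer(gy, gx)
  }
  img
}

#' Render a raw 16-bit camera frame from a list of spots
#'
#' Each spot contributes an integrated 2D isotropic Gaussian whose total
#' expected photon count equals its brightness. With `noise = TRUE` the
#' photon image receives per-pixel Poisson shot noise, is converted to
#' counts (`photons / inverse_gain + offset`), receives additive Gaussian
#' read noise, and is rounded and clipped to the 16-bit range. With
#' `noise = FALSE` the exact expected count image is returned un-rounded,
#' for validation against closed-form totals.
#'
#' @param spots data.frame with columns `x_px`, `y_px`, `brightness`
#'   (0-based pixel coordinates, x = column).
#' @param psf_sigma Gaussian PSF width, pixels (> 0).
#' @param camera a [camera_model()].
#' @param shape frame size `c(rows, cols)` in pixels.
#' @param seed integer seed (noise only).
#' @param noise logical; disable to obtain the exact expectation image.
#' @return numeric matrix of camera counts (integers when `noise = TRUE`).
#' @export
render_frame <- function(spots, psf_sigma, camera, shape = c(128L, 128L),
                         seed = NULL, noise = TRUE) {
  assert(inherits(camera, "camera_model"), "`camera` must be a camera_model")
  assert(is_scalar_num(psf_sigma) && psf_sigma > 0, "`psf_sigma` must be > 0")
  assert(length(shape) == 2L && all(shape >= 1), "`shape` must be positive")
  shape <- as.integer(shape)
  if (nrow(spots) > 0) {
    assert(all(spots$x_px >= 0 & spots$x_px <= shape[2] - 1) &&
           all(spots$y_px >= 0 & spots$y_px <= shape[1] - 1),
           "spot positions must lie inside the frame")
  }
  expected <- spot_expectation(shape, spots$x_px, spots$y_px,
                               spots$brightness, psf_sigma)
  if (!noise) return(expected / camera$inverse_gain + camera$offset)
  with_seed(seed, {
    photons <- matrix(rpois(length(expected), expected), shape[1], shape[2])
    counts <- photons / camera$inverse_gain + camera$offset
    if (camera$read_noise_sd > 0)
      counts <- counts + matrix(rnorm(length(counts), 0, camera$read_noise_sd),
                                shape[1], shape[2])
    matrix(pmin(pmax(round(counts), 0), 65535), shape[1], shape[2])
  })
}

# draw a random field of spots: Poisson count at density (per um^2) over
# the field area, uniform continuous positions (0-based pixel coordinates)
sim_spot_field <- function(truth, camera, shape, seed = NULL) {
  with_seed(seed, {
    area <- prod(shape) * camera$pixel_size^2
    n <- rpois(1L, truth$density * area)
    if (n == 0) {
      tab <- sim_mixture_spots(truth, 1L)[0, ]
      return(cbind(data.frame(x_px = numeric(0), y_px = numeric(0)), tab))
    }
    pos <- data.frame(x_px = runif(n, 0, shape[2] - 1),
                      y_px = runif(n, 0, shape[1] - 1))
    cbind(pos, sim_mixture_spots(truth, n))
  })
}

#' Simulate one TOCCSL run (prebleach frame, bleach, recovery, postbleach)
#'
#' A prebleach field is drawn at the configured density and rendered. All
#' spots inside the aperture are then bleached whole (the fluorophores of
#' one oligomer co-localize and co-bleach). Positions evolve by Brownian
#' motion over the recovery time (Gaussian displacements with variance
#' `2 * D * t` per axis), and the postbleach frame shows the unbleached
#' spots that have re-entered the aperture.
#'
#' @param truth a [ground_truth()].
#' @param timing a [toccsl_timing()].
#' @param diffusion_D diffusion coefficient, um^2/s (>= 0).
#' @param aperture aperture rectangle `c(x0, y0, x1, y1)` in 0-based pixel
#'   coordinates, inclusive, inside the frame.
#' @param camera a [camera_model()].
#' @param shape frame size `c(rows, cols)`, pixels.
#' @param psf_sigma PSF width, pixels.
#' @param seed integer seed.
#' @param noise logical, forwarded to [render_frame()].
#' @return list with `prebleach` and `postbleach` count matrices and a
#'   `spots` data.frame (positions at both times, bleach status, ground
#'   truth order/brightness, `in_aperture_post`).
#' @export
sim_toccsl_run <- function(truth, timing = toccsl_timing(), diffusion_D = 0.1,
                           aperture = NULL, camera = camera_model(),
                           shape = c(128L, 128L), psf_sigma = 1.2,
                           seed = NULL, noise = TRUE) {
  assert(is_scalar_num(diffusion_D) && diffusion_D >= 0,
         "`diffusion_D` must be >= 0")
  shape <- as.integer(shape)
  if (is.null(aperture)) {
    mx <- (shape[2] - 1) / 2; my <- (shape[1] - 1) / 2
    aperture <- c(mx - shape[2] / 4, my - shape[1] / 4,
                  mx + shape[2] / 4, my + shape[1] / 4)
  }
  assert(length(aperture) == 4L && aperture[1] < aperture[3] &&
         aperture[2] < aperture[4],
         "`aperture` must be c(x0, y0, x1, y1) with x0 < x1, y0 < y1")
  assert(aperture[1] >= 0 && aperture[2] >= 0 &&
         aperture[3] <= shape[2] - 1 && aperture[4] <= shape[1] - 1,
         "`aperture` must lie inside the frame")
  with_seed(seed, {
    spots <- sim_spot_field(truth, camera, shape)
    pre <- render_frame(spots, psf_sigma, camera, shape, noise = noise)
    in_ap <- spots$x_px >= aperture[1] & spots$x_px <= aperture[3] &
             spots$y_px >= aperture[2] & spots$y_px <= aperture[4]
    spots$bleached <- in_ap
    # Brownian displacement over the recovery window; reflecting the
    # bleach-window motion is ignored (mask applied once)
    t_rec <- timing$recovery_ms / 1000
    sd_px <- sqrt(2 * diffusion_D * t_rec) / camera$pixel_size
    n <- nrow(spots)
    spots$x_post <- spots$x_px + rnorm(n, 0, sd_px)
    spots$y_post <- spots$y_px + rnorm(n, 0, sd_px)
    spots$x_post <- pmin(pmax(spots$x_post, 0), shape[2] - 1)
    spots$y_post <- pmin(pmax(spots$y_post, 0), shape[1] - 1)
    spots$in_aperture_post <-
      spots$x_post >= aperture[1] & spots$x_post <= aperture[3] &
      spots$y_post >= aperture[2] & spots$y_post <= aperture[4]
    vis <- spots$in_aperture_post & !spots$bleached & spots$visible
    post_spots <- data.frame(x_px = spots$x_post[vis],
                             y_px = spots$y_post[vis],
                             brightness = spots$brightness[vis])
    post <- render_frame(post_spots, psf_sigma, camera, shape, noise = noise)
    list(prebleach = pre, postbleach = post, spots = spots,
         aperture = aperture)
  })
}

#' Simulate repeated TOCCSL runs with or without subunit exchange
#'
#' Models the two scenarios distinguishing stable from exchanging dimers.
#' Without exchange, whole spots survive each bleach round with probability
#' `survival_prob_per_run`, so the composition of visible spots never
#' changes. With exchange, individual fluorophores survive with that
#' probability and oligomers re-pair randomly between runs (well-mixed), so
#' after `r` rounds an n-mer carries Binomial(n, s^r) active fluorophores
#' and the apparent monomer fraction grows.
#'
#' @param truth a [ground_truth()].
#' @param survival_prob_per_run per-run survival probability `s` in \[0, 1\].
#' @param exchange logical: do subunits re-pair between runs?
#' @param runs number of runs (>= 1). Run 1 is the unbleached start.
#' @param n_spots spots simulated per cell.
#' @param seed integer seed.
#' @return data.frame with columns `spot_id`, `run`, `true_order`,
#'   `active_count`, `brightness` (photons), `visible`.
#' @export
sim_repeated_runs <- function(truth, survival_prob_per_run = 0.6,
                              exchange = FALSE, runs = 3L, n_spots = 500L,
                              seed = NULL) {
  assert(is_scalar_num(survival_prob_per_run) &&
         survival_prob_per_run >= 0 && survival_prob_per_run <= 1,
         "`survival_prob_per_run` must lie in [0, 1]")
  assert(is_scalar_num(runs) && runs >= 1, "`runs` must be >= 1")
  runs <- as.integer(runs); n_spots <- as.integer(n_spots)
  s <- survival_prob_per_run
  with_seed(seed, {
    base <- sim_mixture_spots(truth, n_spots)
    out <- vector("list", runs)
    # exchange = FALSE: one survival indicator per spot, persisting
    surv_run <- if (s == 1) rep(Inf, n_spots)
                else floor(log(runif(n_spots)) / log(max(s, .Machine$double.xmin)))
    for (r in seq_len(runs)) {
      q_r <- s^(r - 1)
      if (!exchange) {
        alive <- if (r == 1) rep(TRUE, n_spots) else surv_run >= (r - 1)
        active <- ifelse(alive, base$active_count, 0L)
      } else if (q_r == 1) {
        active <- base$active_count
      } else {
        # random re-pairing: each subunit independently active w.p. q_r
        active <- rbinom(n_spots, size = base$true_order, prob =
                           q_r * truth$active_prob)
      }
      brightness <- numeric(n_spots)
      tot <- sum(active)
      if (tot > 0) {
        draws <- sim_monomer_brightness(truth, tot)
        idx <- rep.int(seq_len(n_spots), active)
        b <- vapply(split(draws, factor(idx, levels = seq_len(n_spots))),
                    sum, numeric(1))
        brightness <- unname(b)
      }
      out[[r]] <- data.frame(spot_id = seq_len(n_spots), run = r,
                             true_order = base$true_order,
                             active_count = as.integer(active),
                             brightness = brightness,
                             visible = active > 0)
    }
    do.call(rbind, out)
  })
}

#' Simulate a normalized FRAP recovery trace
#'
#' One-phase association: `I(t)/I0 = mf * (1 - exp(-K * t))`, plus additive
#' Gaussian noise.
#'
#' @param mf mobile fraction in \[0, 1\].
#' @param K recovery rate constant, 1/s (> 0).
#' @param times sampling times, s (nonnegative).
#' @param noise_sd additive Gaussian noise SD (fraction units).
#' @param seed integer seed.
#' @return data.frame with columns `time_s`, `intensity_norm`.
#' @export
sim_frap_trace <- function(mf, K, times = seq(0, 400, by = 10),
                           noise_sd = 0, seed = NULL) {
  assert(is_scalar_num(mf) && mf >= 0 && mf <= 1, "`mf` must lie in [0, 1]")
  assert(is_scalar_num(K) && K > 0, "`K` must be > 0")
  assert(is.numeric(times) && all(is.finite(times)) && all(times >= 0),
         "`times` must be nonnegative")
  assert(is_scalar_num(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0")
  with_seed(seed, {
    y <- mf * (1 - exp(-K * times))
    if (noise_sd > 0) y <- y + rnorm(length(times), 0, noise_sd)
    data.frame(time_s = times, intensity_norm = y)
  })
}
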