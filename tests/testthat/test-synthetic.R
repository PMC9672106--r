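test_that("monomer brightness draws honor the law, the seed, and argument checks", {
  gt <- wt_truth()
  # degenerate law: exact values
  expect_equal(sim_monomer_brightness(delta_truth(), 3, seed = 1),
               rep(100, 3))
  # determinism contract
  expect_identical(sim_monomer_brightness(gt, 50, seed = 7),
                   sim_monomer_brightness(gt, 50, seed = 7))
  # analytic lognormal mean: median * exp(log(gsd)^2 / 2)
  x <- sim_monomer_brightness(gt, 1e5, seed = 2)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) / (100 * exp(log(1.4)^2 / 2)) - 1), 0.01)
  expect_error(sim_monomer_brightness(gt, 0), "n")
  expect_error(ground_truth(monomer_median = -1), "positive")
})

test_that("mixture spots follow the composition and binomial activity model", {
  # pure monomers
  s <- sim_mixture_spots(ground_truth(1), 200, seed = 1)
  expect_true(all(s$true_order == 1) && all(s$active_count == 1))
  # pure dimers at active_prob = 0.5: Binomial(2, 0.5) within 3 sigma
  gt2 <- ground_truth(c(0, 1), active_prob = 0.5)
  s2 <- sim_mixture_spots(gt2, 1e5, seed = 2)
  emp <- tabulate(s2$active_count + 1L, 3) / 1e5
  p <- c(0.25, 0.5, 0.25)
  expect_true(all(abs(emp - p) < 3 * sqrt(p * (1 - p) / 1e5)))
  expect_true(all(s2$brightness[s2$active_count == 0] == 0))
  expect_true(all(!s2$visible[s2$active_count == 0]))
  # degenerate law: brightness exactly 100 or 200, proportions ~ 60/40
  s3 <- sim_mixture_spots(delta_truth(), 2e4, seed = 3)
  expect_true(all(s3$brightness %in% c(100, 200)))
  expect_lt(abs(mean(s3$brightness == 100) - 0.6), 3 * sqrt(0.24 / 2e4))
  expect_error(ground_truth(c(0.5, 0.4)), "sum to 1")
})

test_that("rendered frames integrate to the spot brightness and are reproducible", {
  cam <- quiet_camera()
  none <- data.frame(x_px = numeric(0), y_px = numeric(0),
                     brightness = numeric(0))
  img <- render_frame(none, 1.2, cam, c(32, 32), noise = FALSE)
  expect_true(all(img == cam$offset))
  # one spot, noise disabled: photon sum = brightness within truncation
  pim <- one_spot_image(15.4, 16.2, brightness = 500)
  expect_lt(abs(sum(pim$pixels) - 500) / 500, 0.005)
  # determinism with noise
  sp <- data.frame(x_px = 10, y_px = 12, brightness = 300)
  a <- render_frame(sp, 1.2, camera_model(), c(32, 32), seed = 5)
  b <- render_frame(sp, 1.2, camera_model(), c(32, 32), seed = 5)
  expect_identical(a, b)
  expect_true(all(a == round(a)) && min(a) >= 0 && max(a) <= 65535)
  expect_error(render_frame(sp, 1.2, camera_model(), c(0, 32)), "positive")
  expect_error(render_frame(data.frame(x_px = 99, y_px = 1, brightness = 1),
                            1.2, cam, c(32, 32)), "inside")
})

test_that("TOCCSL runs bleach the aperture and recover by diffusion", {
  gt <- wt_truth(density = 1)
  # D = 0: nothing re-enters the aperture
  run0 <- sim_toccsl_run(gt, diffusion_D = 0, seed = 1, noise = FALSE)
  vis0 <- with(run0$spots, in_aperture_post & !bleached & visible)
  expect_equal(sum(vis0), 0)
  # D > 0: some re-entry, but fewer than prebleach occupancy
  run1 <- sim_toccsl_run(gt, diffusion_D = 0.2, seed = 2, noise = FALSE)
  sp <- run1$spots
  pre_in <- sum(sp$bleached & sp$visible)
  post_in <- sum(sp$in_aperture_post & !sp$bleached & sp$visible)
  expect_lt(post_in, pre_in)
  expect_error(sim_toccsl_run(gt, aperture = c(-5, 0, 300, 300), seed = 1),
               "inside")
})

test_that("prebleach spot counts are Poisson(density x area)", {
  gt <- wt_truth(density = 1)
  cam <- camera_model()
  # 100 um^2 field: 62.5 x 62.5 px at 0.16 um/px
  shape <- c(63L, 63L)
  area <- prod(shape) * cam$pixel_size^2
  counts <- vapply(1:200, function(i)
    nrow(toccsl:::sim_spot_field(gt, cam, shape, seed = i)), numeric(1))
  lambda <- 1 * area
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))
  # chi-square GOF against Poisson, alpha = 0.001
  q <- qpois(seq(0.1, 0.9, by = 0.2), lambda)
  obs <- table(cut(counts, c(-Inf, q, Inf)))
  p <- diff(c(0, ppois(q, lambda), 1))
  chisq <- sum((as.numeric(obs) - 200 * p)^2 / (200 * p))
  expect_lt(chisq, qchisq(0.999, df = length(p) - 1))
})

test_that("repeated runs reproduce the stable vs exchanging dichotomy", {
  gt <- delta_truth()
  # s = 1: every run identical to the first
  rr <- sim_repeated_runs(gt, 1, exchange = TRUE, runs = 3, n_spots = 300,
                          seed = 1)
  r1 <- rr[rr$run == 1, c("true_order", "active_count")]
  for (r in 2:3)
    expect_equal(rr[rr$run == r, c("true_order", "active_count")]$active_count,
                 r1$active_count)
  # no exchange: visible composition stays at truth in every run
  rr2 <- sim_repeated_runs(wt_truth(), 0.6, exchange = FALSE, runs = 3,
                           n_spots = 20000, seed = 2)
  for (r in 1:3) {
    v <- rr2[rr2$run == r & rr2$visible, ]
    mono_frac <- mean(v$true_order == 1)
    expect_lt(abs(mono_frac - 0.6), 3 * sqrt(0.24 / nrow(v)))
  }
  # exchange: visible dimer-brightness fraction matches the enumeration
  # oracle at q = s^2 (third run with s = 0.6)
  rr3 <- sim_repeated_runs(wt_truth(), 0.6, exchange = TRUE, runs = 3,
                           n_spots = 200000, seed = 3)
  v3 <- rr3[rr3$run == 3 & rr3$visible, ]
  expected <- enumerate_apparent_fractions(c(0.6, 0.4), 0.36)
  emp_dimer <- mean(v3$active_count == 2)
  expect_equal(expected[2], 0.05184 / 0.45216, tolerance = 1e-12)
  expect_lt(abs(emp_dimer - expected[2]),
            4 * sqrt(expected[2] * (1 - expected[2]) / nrow(v3)))
})

test_that("expected apparent monomer fraction is nondecreasing across runs", {
  # enumeration oracle, any s < 1 and dimer fraction > 0
  for (s in c(0.3, 0.6, 0.9)) for (a2 in c(0.1, 0.4, 0.8)) {
    app <- vapply(0:3, function(r)
      enumerate_apparent_fractions(c(1 - a2, a2), s^r)[1], numeric(1))
    expect_true(all(diff(app) >= -1e-12))
  }
})

test_that("FRAP traces follow the one-phase association closed form", {
  tr <- sim_frap_trace(0.89, 0.05, times = c(0, 1 / 0.05, 20 / 0.05))
  expect_equal(tr$intensity_norm[1], 0)
  expect_equal(tr$intensity_norm[2], 0.89 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(tr$intensity_norm[3], 0.89, tolerance = 1e-8)
  expect_error(sim_frap_trace(0.89, 0.05, times = c(-1, 0)), "nonnegative")
  expect_identical(sim_frap_trace(0.5, 0.01, noise_sd = 0.02, seed = 4),
                   sim_frap_trace(0.5, 0.01, noise_sd = 0.02, seed = 4))
})
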