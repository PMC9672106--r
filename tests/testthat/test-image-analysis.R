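test_that("photon conversion applies offset, gain, and clipping", {
  cam <- camera_model(offset = 100, inverse_gain = 2, pixel_size = 0.16)
  raw <- matrix(c(100, 150, 90, 100), 2, 2)
  pim <- counts_to_photons(raw, cam)
  expect_equal(pim$pixels, matrix(c(0, 100, 0, 0), 2, 2))
  expect_equal(pim$pixel_size, 0.16)
  # idempotence with a unit camera
  unit <- camera_model(offset = 0, inverse_gain = 1)
  expect_equal(counts_to_photons(pim$pixels, unit)$pixels, pim$pixels)
  expect_error(camera_model(inverse_gain = 0), "inverse_gain")
})

test_that("spot detection finds isolated spots and rejects close pairs", {
  cam <- quiet_camera()
  blank <- counts_to_photons(
    render_frame(data.frame(x_px = numeric(0), y_px = numeric(0),
                            brightness = numeric(0)),
                 1.2, cam, c(32, 32), noise = FALSE), cam)
  expect_equal(nrow(detect_spots(blank, 1.2)), 0)
  # one spot: exactly one candidate within 1 px of truth
  pim <- one_spot_image(20.3, 24.7)
  cand <- detect_spots(pim, 1.2)
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt((cand$x_px - 20.3)^2 + (cand$y_px - 24.7)^2), 1)
  # two resolvable spots 4 px apart (< 4 sigma): unresolvable as separate
  # oligomers, both rejected by the proximity rule. (Below ~3 px the two
  # maxima merge into one blob, which is physically indistinguishable
  # from a dimer and is treated as a single signal.)
  pair <- data.frame(x_px = c(20, 24), y_px = c(20, 20),
                     brightness = c(500, 500))
  pim2 <- counts_to_photons(
    render_frame(pair, 1.2, cam, c(48, 48), noise = FALSE), cam)
  expect_equal(nrow(detect_spots(pim2, 1.2)), 0)
  # well-separated pair: both kept
  far <- data.frame(x_px = c(14, 34), y_px = c(20, 20),
                    brightness = c(500, 500))
  pim3 <- counts_to_photons(
    render_frame(far, 1.2, cam, c(48, 48), noise = FALSE), cam)
  expect_equal(nrow(detect_spots(pim3, 1.2)), 2)
})

test_that("raising the detection threshold never adds spots", {
  gt <- wt_truth(density = 0.15)
  cam <- camera_model()
  tab <- toccsl:::sim_spot_field(gt, cam, c(96L, 96L), seed = 42)
  raw <- render_frame(tab, 1.2, cam, c(96L, 96L), seed = 43)
  pim <- counts_to_photons(raw, cam)
  n <- vapply(c(3, 5, 8, 12), function(k) nrow(detect_spots(pim, 1.2, k)),
              numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("Gaussian spot fits recover brightness and sub-pixel position", {
  pim <- one_spot_image(20.3, 24.7, brightness = 500, sigma = 1.2)
  f <- fit_gaussian_spot(pim, c(20, 25), window = 9L, psf_sigma_hint = 1.2)
  expect_true(f$accepted)
  expect_lt(abs(f$B_photons - 500) / 500, 0.01)
  expect_lt(abs(f$x_px - 20.3), 0.05)
  expect_lt(abs(f$y_px - 24.7), 0.05)
  expect_lt(abs(f$sigma_px - 1.2), 0.05)
  # flat window -> rejected, not an error
  flat <- structure(list(pixels = matrix(5, 32, 32), pixel_size = 0.16),
                    class = "photon_image")
  expect_false(fit_gaussian_spot(flat, c(16, 16))$accepted)
  # window leaving the frame -> rejected, not an error
  expect_false(fit_gaussian_spot(pim, c(1, 1))$accepted)
})

test_that("fitted brightness is unbiased on noiseless frames", {
  cam <- quiet_camera()
  set.seed(99)
  errs <- vapply(1:100, function(i) {
    b <- runif(1, 100, 900)
    x <- runif(1, 10, 30); y <- runif(1, 10, 30)
    pim <- one_spot_image(x, y, brightness = b)
    f <- fit_gaussian_spot(pim, c(round(x), round(y)))
    (f$B_photons - b) / b
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.01)
})

test_that("brightness tables concatenate frames and recover true spots", {
  expect_equal(nrow(extract_brightness_table(list())), 0)
  gt <- wt_truth(density = 0.1)
  cam <- quiet_camera()
  tab <- toccsl:::sim_spot_field(gt, cam, c(96L, 96L), seed = 7)
  raw <- render_frame(tab, 1.2, cam, c(96L, 96L), noise = FALSE)
  bt <- extract_brightness_table(list(raw), cam)
  # noiseless: >= 90% of true visible spots recovered within 1 px.
  # Excluded from the denominator: spots closer than 5 px to the frame
  # edge (cannot hold a 9-px fit window) and spots with a neighbor
  # within 4 sigma (discarded on purpose by the proximity rule).
  interior <- tab$x_px >= 5 & tab$x_px <= 90 & tab$y_px >= 5 & tab$y_px <= 90
  dmat <- as.matrix(dist(tab[, c("x_px", "y_px")]))
  diag(dmat) <- Inf
  isolated <- apply(dmat, 1, min) >= 4 * 1.2
  tin <- tab[interior & isolated, ]
  hits <- vapply(seq_len(nrow(tin)), function(i)
    any(sqrt((bt$x_px - tin$x_px[i])^2 + (bt$y_px - tin$y_px[i])^2) < 1),
    logical(1))
  expect_gte(mean(hits), 0.9)
  # duplicate frame doubles the rows
  bt2 <- extract_brightness_table(list(raw, raw), cam)
  expect_equal(nrow(bt2), 2 * nrow(bt))
  expect_equal(unique(bt2$frame), c(1, 2))
})

test_that("surface density is brightness over area per single molecule", {
  # 100 x 100 px at 0.1 um/px = 100 um^2; 1 photon/px = 10000 photons
  pim <- structure(list(pixels = matrix(1, 100, 100), pixel_size = 0.1),
                   class = "photon_image")
  expect_equal(estimate_surface_density(pim, 100), 1.0)
  zero <- structure(list(pixels = matrix(0, 10, 10), pixel_size = 0.1),
                    class = "photon_image")
  expect_equal(estimate_surface_density(zero, 100), 0)
  expect_error(estimate_surface_density(pim, 0), "single_brightness")
  # linearity: doubling photons doubles the estimate exactly
  pim2 <- pim; pim2$pixels <- pim$pixels * 2
  expect_equal(estimate_surface_density(pim2, 100),
               2 * estimate_surface_density(pim, 100))
  # simulated prebleach at known density: estimate within 10%
  gt <- wt_truth(density = 2)
  cam <- quiet_camera()
  shape <- c(80L, 80L)   # 12.8 um x 12.8 um = 164 um^2
  tab <- toccsl:::sim_spot_field(gt, cam, shape, seed = 11)
  raw <- render_frame(tab, 1.2, cam, shape, noise = FALSE)
  est <- estimate_surface_density(counts_to_photons(raw, cam),
                                  100 * exp(log(1.4)^2 / 2))
  # the estimator counts molecules, not spots: a 60:40 mix carries
  # <n> = 1.4 molecules per spot on average
  mol_dens <- sum(tab$true_order) / (prod(shape) * cam$pixel_size^2)
  expect_lt(abs(est / mol_dens - 1), 0.1)
})

test_that("16-bit TIFF round-trips exactly, including multi-page", {
  m1 <- matrix(sample.int(65536, 300) - 1L, 15, 20)
  m2 <- matrix(sample.int(65536, 300) - 1L, 15, 20)
  path <- tempfile(fileext = ".tif")
  write_tiff16(list(m1, m2), path)
  back <- read_tiff16(path)
  expect_equal(back, list(m1, m2))
  # single matrix in, list of one out
  write_tiff16(m1, path)
  expect_equal(read_tiff16(path), list(m1))
  expect_error(read_tiff16(tempfile()), "not found")
})
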