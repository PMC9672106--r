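#' Ground truth for the synthetic TOCCSL experiment
#'
#' Bundles the simulation truth: the oligomer composition of the labeled
#' transporter population, the single-fluorophore brightness law, the
#' probability that a fluorophore is fluorescent, and the spot density.
#'
#' The single-fluorophore brightness law is lognormal, parameterized by its
#' median (photons) and geometric SD; it is strictly positive and positively
#' skewed, the shape single-GFP brightness histograms show in practice.
#'
#' @param fractions numeric vector of oligomer fractions \eqn{\alpha_n}
#'   (index = oligomeric order); must be nonnegative and sum to 1.
#' @param monomer_median median single-fluorophore brightness, photons.
#' @param monomer_gsd geometric SD of the brightness law (> 1 for spread;
#'   exactly 1 gives a degenerate, zero-variance law).
#' @param active_prob probability that one fluorophore is fluorescent
#'   (maturation/darkness), in \[0, 1\]. Default 1: all labels active.
#' @param density spots per um^2 in the prebleach field.
#' @return an object of class `ground_truth`.
#' @export
#' @examples
#' ground_truth(fractions = c(0.6, 0.4))
ground_truth <- function(fractions = c(0.6, 0.4),
                         monomer_median = 100,
                         monomer_gsd = 1.4,
                         active_prob = 1,
                         density = 0.5) {
  assert(is.numeric(fractions) && length(fractions) >= 1L && all(is.finite(fractions)),
         "`fractions` must be a finite numeric vector")
  assert(all(fractions >= 0), "`fractions` must be nonnegative")
  assert(abs(sum(fractions) - 1) <= 1e-12,
         sprintf("`fractions` must sum to 1 (got %.15g)", sum(fractions)))
  assert(is_scalar_num(monomer_median) && monomer_median > 0,
         "`monomer_median` must be a positive number (photons)")
  assert(is_scalar_num(monomer_gsd) && monomer_gsd >= 1,
         "`monomer_gsd` must be >= 1")
  assert(is_scalar_num(active_prob) && active_prob >= 0 && active_prob <= 1,
         "`active_prob` must lie in [0, 1]")
  assert(is_scalar_num(density) && density >= 0,
         "`density` must be nonnegative (spots per um^2)")
  structure(list(fractions = as.numeric(fractions),
                 monomer_median = monomer_median,
                 monomer_gsd = monomer_gsd,
                 active_prob = active_prob,
                 density = density),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat("  fractions:  ", paste(sprintf("%.3f", x$fractions), collapse = " "), "\n")
  cat("  monomer law: lognormal(median =", x$monomer_median,
      "photons, gsd =", x$monomer_gsd, ")\n")
  cat("  active_prob:", x$active_prob, "  density:", x$density, "/um^2\n")
  invisible(x)
}

#' Camera model for photon conversion and image rendering
#'
#' @param offset camera offset, counts.
#' @param inverse_gain photons per count (> 0).
#' @param read_noise_sd Gaussian read noise SD, counts (>= 0).
#' @param pixel_size pixel side length, um (> 0).
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(offset = 100, inverse_gain = 4,
                         read_noise_sd = 0.5, pixel_size = 0.16) {
  assert(is_scalar_num(offset) && offset >= 0, "`offset` must be >= 0 counts")
  assert(is_scalar_num(inverse_gain) && inverse_gain > 0,
         "`inverse_gain` must be > 0 photons/count")
  assert(is_scalar_num(read_noise_sd) && read_noise_sd >= 0,
         "`read_noise_sd` must be >= 0 counts")
  assert(is_scalar_num(pixel_size) && pixel_size > 0,
         "`pixel_size` must be > 0 um")
  structure(list(offset = offset, inverse_gain = inverse_gain,
                 read_noise_sd = read_noise_sd, pixel_size = pixel_size),
            class = "camera_model")
}

#' Timing protocol of a TOCCSL run
#'
#' Defaults follow the published protocol: 2,000 ms bleach at ~2 kW/cm^2,
#' 5,000 ms recovery, 5 ms stroboscopic excitation at 0.5 kW/cm^2.
#'
#' @param t_bl bleach duration, ms.
#' @param I_bl bleach intensity, kW/cm^2.
#' @param recovery_ms recovery time before the postbleach frame, ms.
#' @param t_exp excitation time, ms.
#' @param I_im imaging intensity, kW/cm^2.
#' @return an object of class `toccsl_timing`.
#' @export
toccsl_timing <- function(t_bl = 2000, I_bl = 2, recovery_ms = 5000,
                          t_exp = 5, I_im = 0.5) {
  vals <- c(t_bl = t_bl, I_bl = I_bl, recovery_ms = recovery_ms,
            t_exp = t_exp, I_im = I_im)
  assert(all(vapply(vals, is_scalar_num, logical(1))) && all(vals > 0),
         "all timing parameters must be positive")
  structure(as.list(vals), class = "toccsl_timing")
}

#' Tabulated empirical probability density over brightness
#'
#' A unit-normalized density on a uniform brightness grid. The trapezoidal
#' integral is forced to 1 on construction.
#'
#' @param grid uniform, increasing brightness grid (photons).
#' @param values nonnegative density values at the grid points (1/photons).
#' @return an object of class `empirical_pdf`.
#' @export
empirical_pdf <- function(grid, values) {
  assert(is.numeric(grid) && length(grid) >= 2L, "`grid` needs >= 2 points")
  dg <- diff(grid)
  assert(all(dg > 0) && diff(range(dg)) <= 1e-9 * mean(dg),
         "`grid` must be uniform and increasing")
  assert(length(values) == length(grid), "`values` must match `grid` length")
  assert(all(is.finite(values)) && all(values >= -1e-12),
         "`values` must be finite and nonnegative")
  values <- pmax(values, 0)
  z <- trapz(grid, values)
  assert(z > 0, "density integrates to zero")
  structure(list(grid = as.numeric(grid), values = as.numeric(values) / z),
            class = "empirical_pdf")
}

#' @export
print.empirical_pdf <- function(x, ...) {
  cat("<empirical_pdf> ", length(x$grid), " points on [",
      format(min(x$grid)), ", ", format(max(x$grid)), "] photons; mean ",
      format(pdf_mean(x)), "\n", sep = "")
  invisible(x)
}

#' Mean brightness of a tabulated density
#' @param pdf an `empirical_pdf`.
#' @return mean brightness, photons.
#' @export
pdf_mean <- function(pdf) trapz(pdf$grid, pdf$grid * pdf$values)

#' Fitted oligomer distribution
#'
#' Mixture weights \eqn{\alpha_1..\alpha_{n_{max}}} with optional bootstrap
#' SDs, the sample size of the fit, and the average oligomeric state
#' \eqn{\langle n\rangle = \sum_n n \alpha_n}.
#'
#' @param alphas numeric vector of fractions, nonnegative, summing to 1.
#' @param alpha_sds bootstrap SDs (same length) or `NULL`.
#' @param n_samples number of brightness samples used in the fit.
#' @param n_clipped number of samples clipped to the grid support.
#' @return an object of class `oligomer_distribution`.
#' @export
oligomer_distribution <- function(alphas, alpha_sds = NULL,
                                  n_samples = NA_integer_,
                                  n_clipped = 0L) {
  assert(is.numeric(alphas) && length(alphas) >= 1L, "`alphas` required")
  assert(all(alphas >= -1e-12), "`alphas` must be nonnegative")
  assert(abs(sum(alphas) - 1) <= 1e-9,
         sprintf("`alphas` must sum to 1 within 1e-9 (got %.12g)", sum(alphas)))
  alphas <- pmax(as.numeric(alphas), 0)
  if (!is.null(alpha_sds))
    assert(length(alpha_sds) == length(alphas) && all(alpha_sds >= 0),
           "`alpha_sds` must match `alphas` and be nonnegative")
  structure(list(alphas = alphas,
                 alpha_sds = alpha_sds,
                 n_max = length(alphas),
                 avg_state = sum(seq_along(alphas) * alphas),
                 n_samples = n_samples,
                 n_clipped = n_clipped),
            class = "oligomer_distribution")
}

#' @export
print.oligomer_distribution <- function(x, ...) {
  cat("<oligomer_distribution> n_max =", x$n_max,
      " n_samples =", x$n_samples, "\n")
  for (n in seq_len(x$n_max)) {
    cat(sprintf("  alpha_%d = %.4f", n, x$alphas[n]))
    if (!is.null(x$alpha_sds)) cat(sprintf(" (sd %.4f)", x$alpha_sds[n]))
    cat("\n")
  }
  cat(sprintf("  average oligomeric state <n> = %.4f\n", x$avg_state))
  invisible(x)
}

#' Average oligomeric state of a fitted distribution
#'
#' Defined as the weighted mean \eqn{\langle n\rangle = \sum_n n\,\alpha_n}
#' of the oligomeric order over the fitted fractions.
#'
#' @param dist an `oligomer_distribution`.
#' @return scalar \eqn{\langle n\rangle} in \[1, n_max\].
#' @export
#' @examples
#' average_oligomeric_state(oligomer_distribution(c(0.6, 0.4)))  # 1.4
average_oligomeric_state <- function(dist) {
  assert(inherits(dist, "oligomer_distribution"),
         "`dist` must be an oligomer_distribution")
  sum(seq_along(dist$alphas) * dist$alphas)
}
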