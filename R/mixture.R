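#' Estimate the monomer brightness PDF from a calibration sample
#'
#' Kernel density estimate (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth) of the single-fluorophore brightness distribution
#' \eqn{\rho_1(B)}, evaluated on a uniform grid spanning
#' `[0, n_max * max(samples) * 1.2]` so that the autoconvolutions
#' \eqn{\rho_n} up to order `n_max` fit on the same grid. The result is
#' renormalized to unit trapezoidal integral (the small KDE mass leaking
#' below zero is discarded).
#'
#' @param samples positive brightness values, photons; at least 50.
#' @param n_max largest oligomer order the grid must support (default 3).
#' @param grid_n number of grid points (default 1024).
#' @param bw bandwidth override; default Silverman's rule (`"nrd0"`).
#' @return an [empirical_pdf()].
#' @export
estimate_monomer_pdf <- function(samples, n_max = 3L, grid_n = 1024L,
                                 bw = "nrd0") {
  assert(is.numeric(samples) && length(samples) >= 50L,
         "at least 50 brightness samples are required")
  assert(all(is.finite(samples)) && all(samples > 0),
         "all brightness samples must be positive and finite")
  assert(is_scalar_num(n_max) && n_max >= 1, "`n_max` must be >= 1")
  hi <- n_max * max(samples) * 1.2
  d <- density(samples, bw = bw, from = 0, to = hi, n = as.integer(grid_n))
  empirical_pdf(d$x, pmax(d$y, 0))
}

#' Autoconvolve a brightness density to higher oligomer order
#'
#' The brightness of an n-mer with n active fluorophores is the sum of n
#' independent single-fluorophore brightnesses, so its density is the
#' (n-1)-fold autoconvolution of \eqn{\rho_1}:
#' \eqn{\rho_n = \rho_1 * \cdots * \rho_1}. The convolution is computed on
#' the tabulated grid (FFT-based), truncated back to the grid, and
#' renormalized. `n = 1` returns the input unchanged.
#'
#' @param rho1 an [empirical_pdf()] for the monomer.
#' @param n oligomer order (>= 1).
#' @return an [empirical_pdf()] for \eqn{\rho_n} on the same grid.
#' @export
autoconvolve_pdf <- function(rho1, n) {
  assert(inherits(rho1, "empirical_pdf"), "`rho1` must be an empirical_pdf")
  assert(is_scalar_num(n) && n >= 1 && n == round(n), "`n` must be an integer >= 1")
  if (n == 1) return(rho1)
  dx <- rho1$grid[2] - rho1$grid[1]
  m <- length(rho1$grid)
  v <- rho1$values
  acc <- v
  for (k in seq_len(n - 1)) {
    # discrete convolution: acc_i = dx * sum_j acc_j * v_{i-j}
    full <- convolve(acc, rev(v), type = "open") * dx
    acc <- full[seq_len(m)]
    acc[acc < 0] <- 0   # FFT roundoff
  }
  # grid starts at rho1$grid[1] (normally 0); same grid is reused
  empirical_pdf(rho1$grid, acc)
}

#' Brute-force discrete autoconvolution (reference oracle)
#'
#' Direct summation \eqn{\rho_n(b_i) = \Delta x \sum_j \rho_{n-1}(b_j)
#' \rho_1(b_{i-j})}, with the same truncation and renormalization as
#' [autoconvolve_pdf()], but without FFTs. Quadratic in the grid size;
#' intended for validation on grids of a few hundred points.
#'
#' @inheritParams autoconvolve_pdf
#' @return an [empirical_pdf()].
#' @export
autoconvolve_pdf_bruteforce <- function(rho1, n) {
  assert(inherits(rho1, "empirical_pdf"), "`rho1` must be an empirical_pdf")
  assert(is_scalar_num(n) && n >= 1 && n == round(n), "`n` must be an integer >= 1")
  if (n == 1) return(rho1)
  dx <- rho1$grid[2] - rho1$grid[1]
  m <- length(rho1$grid)
  v <- rho1$values
  acc <- v
  for (k in seq_len(n - 1)) {
    out <- numeric(m)
    for (i in seq_len(m)) {
      j <- seq_len(i)
      out[i] <- dx * sum(acc[j] * v[i - j + 1L])
    }
    acc <- out
  }
  empirical_pdf(rho1$grid, acc)
}

# evaluate each rho_n at the sample points by linear interpolation;
# samples outside the grid support are clipped to the support edge
component_density_matrix <- function(samples, rho1, n_max) {
  lo <- min(rho1$grid); hi <- max(rho1$grid)
  n_clipped <- sum(samples < lo | samples > hi)
  x <- pmin(pmax(samples, lo), hi)
  rhos <- lapply(seq_len(n_max), function(n) autoconvolve_pdf(rho1, n))
  D <- vapply(rhos, function(r) approx(r$grid, r$values, xout = x,
                                       rule = 2)$y,
              numeric(length(x)))
  list(D = matrix(D, nrow = length(x)), n_clipped = n_clipped, rhos = rhos)
}

softmax <- function(theta) {
  e <- exp(theta - max(theta))
  e / sum(e)
}

# maximize sum_i log sum_n alpha_n D[i, n] over the simplex via a
# normalized-exponential (softmax) reparameterization, BFGS with
# analytic gradient
fit_simplex_ml <- function(D) {
  n_max <- ncol(D)
  if (n_max == 1) return(1)
  negll <- function(theta) {
    a <- softmax(c(0, theta))
    r <- as.numeric(D %*% a)
    if (any(r <= 0)) return(.Machine$double.xmax)
    -sum(log(r))
  }
  grad <- function(theta) {
    a <- softmax(c(0, theta))
    r <- pmax(as.numeric(D %*% a), .Machine$double.xmin)
    ga <- -colSums(D / r)               # d(-ll)/d alpha_n
    # chain rule through softmax: d a_n / d theta_k = a_n (1[n=k+1] - a_{k+1})
    vapply(seq_len(n_max - 1), function(k)
      a[k + 1] * (ga[k + 1] - sum(ga * a)), numeric(1))
  }
  best <- NULL
  for (start in list(rep(0, n_max - 1), rep(-2, n_max - 1))) {
    fit <- tryCatch(optim(start, negll, grad, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("mixture fit failed to converge", "toccsl_fit_failure")
  softmax(c(0, best$par))
}

#' Fit the oligomer mixture to observed spot brightness values
#'
#' Models the observed single-spot brightness density as the constrained
#' linear combination \eqn{\rho(B) = \sum_{n=1}^{n_{max}} \alpha_n
#' \rho_n(B)} with \eqn{\alpha_n \ge 0, \sum_n \alpha_n = 1}, where
#' \eqn{\rho_n} is the n-fold autoconvolution of the monomer density. The
#' weights are estimated by maximum likelihood over the simplex
#' (softmax reparameterization); see [fit_mixture_lsq()] for the
#' histogram least-squares cross-check route.
#'
#' @param samples observed spot brightness values, photons; at least 100.
#' @param rho1 monomer density from [estimate_monomer_pdf()].
#' @param n_max largest oligomer order fitted (default 3).
#' @return an [oligomer_distribution()] (without bootstrap SDs; see
#'   [bootstrap_fractions()]). Samples outside the grid support are
#'   clipped to the support edge and counted in `n_clipped`.
#' @export
fit_mixture <- function(samples, rho1, n_max = 3L) {
  assert(is.numeric(samples) && length(samples) >= 100L,
         "at least 100 brightness samples are required")
  assert(all(is.finite(samples)), "samples must be finite")
  assert(inherits(rho1, "empirical_pdf"), "`rho1` must be an empirical_pdf")
  assert(is_scalar_num(n_max) && n_max >= 1, "`n_max` must be >= 1")
  n_max <- as.integer(n_max)
  cd <- component_density_matrix(samples, rho1, n_max)
  dead <- rowSums(cd$D) <= 0
  if (any(dead))
    abort(sprintf("%d samples have zero density under every component",
                  sum(dead)), "toccsl_fit_failure")
  alphas <- fit_simplex_ml(cd$D)
  oligomer_distribution(alphas, n_samples = length(samples),
                        n_clipped = cd$n_clipped)
}

#' Least-squares-on-histogram mixture fit (cross-check oracle)
#'
#' Alternative estimator of the mixture weights: bins the observed
#' brightness values into a density histogram and minimizes the squared
#' deviation between the histogram and \eqn{\sum_n \alpha_n \rho_n} at the
#' bin centers, under the same simplex constraint. Kept as an independent
#' route to cross-check [fit_mixture()]; the two must agree closely on
#' well-sized samples.
#'
#' @inheritParams fit_mixture
#' @param n_bins number of histogram bins (default 64).
#' @return an [oligomer_distribution()].
#' @export
fit_mixture_lsq <- function(samples, rho1, n_max = 3L, n_bins = 64L) {
  assert(is.numeric(samples) && length(samples) >= 100L,
         "at least 100 brightness samples are required")
  n_max <- as.integer(n_max)
  h <- hist(samples, breaks = n_bins, plot = FALSE)
  centers <- h$mids
  dens <- h$density
  rhos <- lapply(seq_len(n_max), function(n) autoconvolve_pdf(rho1, n))
  M <- vapply(rhos, function(r) approx(r$grid, r$values, xout = centers,
                                       rule = 2)$y,
              numeric(length(centers)))
  M <- matrix(M, nrow = length(centers))
  if (n_max == 1) return(oligomer_distribution(1, n_samples = length(samples)))
  obj <- function(theta) {
    a <- softmax(c(0, theta))
    sum((as.numeric(M %*% a) - dens)^2)
  }
  fit <- optim(rep(0, n_max - 1), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  oligomer_distribution(softmax(c(0, fit$par)),
                        n_samples = length(samples))
}

#' Bootstrap SDs of the fitted oligomer fractions
#'
#' Refits the mixture on random subsamples (drawn without replacement,
#' default 50% of the data, 100 repetitions) and reports the SD of each
#' \eqn{\alpha_n} over the repetitions.
#'
#' @inheritParams fit_mixture
#' @param subsample_frac fraction of the data per repetition, in (0, 1).
#' @param reps number of repetitions (>= 2).
#' @param seed integer seed.
#' @return an [oligomer_distribution()] whose `alphas` are the full-sample
#'   fit and whose `alpha_sds` are the bootstrap SDs.
#' @export
bootstrap_fractions <- function(samples, rho1, n_max = 3L,
                                subsample_frac = 0.5, reps = 100L,
                                seed = NULL) {
  assert(is_scalar_num(reps) && reps >= 2, "`reps` must be >= 2")
  assert(is_scalar_num(subsample_frac) && subsample_frac > 0 &&
         subsample_frac < 1, "`subsample_frac` must lie in (0, 1)")
  full <- fit_mixture(samples, rho1, n_max)
  m <- max(100L, floor(subsample_frac * length(samples)))
  m <- min(m, length(samples) - 1L)
  A <- with_seed(seed, {
    t(vapply(seq_len(as.integer(reps)), function(r) {
      sub <- samples[sample.int(length(samples), m)]
      fit_mixture(sub, rho1, n_max)$alphas
    }, numeric(as.integer(n_max))))
  })
  sds <- apply(A, 2, sd)
  oligomer_distribution(full$alphas, alpha_sds = sds,
                        n_samples = full$n_samples,
                        n_clipped = full$n_clipped)
}
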