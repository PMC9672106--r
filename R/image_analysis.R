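#' Convert raw camera counts to a photon image
#'
#' Applies the camera calibration: `photons = max(counts - offset, 0) *
#' inverse_gain`, elementwise. Negative offset-subtracted values are
#' clipped to zero.
#'
#' @param raw numeric matrix of camera counts.
#' @param camera a [camera_model()].
#' @return an object of class `photon_image`: list with `pixels` (photon
#'   matrix) and `pixel_size` (um).
#' @export
counts_to_photons <- function(raw, camera) {
  assert(is.matrix(raw) && length(raw) > 0, "`raw` must be a nonempty matrix")
  assert(inherits(camera, "camera_model"), "`camera` must be a camera_model")
  structure(list(pixels = pmax(raw - camera$offset, 0) * camera$inverse_gain,
                 pixel_size = camera$pixel_size),
            class = "photon_image")
}

#' @export
print.photon_image <- function(x, ...) {
  cat("<photon_image> ", nrow(x$pixels), "x", ncol(x$pixels),
      " px, pixel size ", x$pixel_size, " um, total ",
      format(sum(x$pixels), digits = 6), " photons\n", sep = "")
  invisible(x)
}

# separable 2D convolution with a normalized Gaussian kernel,
# replicate-padded at the edges (matched filter for spot detection)
gaussian_filter2 <- function(img, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-h, h), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {
    # m filtered along rows (dimension 1), replicate padding
    nr <- nrow(m)
    padded <- rbind(m[rep(1L, h), , drop = FALSE], m,
                    m[rep(nr, h), , drop = FALSE])
    out <- matrix(0, nr, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * padded[(j - 1L) + seq_len(nr), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Detect candidate diffraction-limited spots
#'
#' Matched-filters the photon image with a Gaussian of the expected PSF
#' width, thresholds at `median + k_sigma * 1.4826 * MAD` of the filtered
#' image (robust background statistics), and keeps strict local maxima in
#' a 3x3 neighborhood. Candidate pairs closer than `4 * psf_sigma_hint`
#' are both discarded: two overlapping oligomers cannot be resolved, and
#' the brightness analysis assumes one oligomer per signal.
#'
#' @param img a `photon_image` (or bare photon matrix).
#' @param psf_sigma_hint expected PSF width, pixels (> 0).
#' @param k_sigma threshold multiplier (default 5).
#' @return data.frame with columns `x_px`, `y_px` (0-based integer pixel
#'   positions of the local maxima).
#' @export
detect_spots <- function(img, psf_sigma_hint = 1.2, k_sigma = 5) {
  px <- if (inherits(img, "photon_image")) img$pixels else img
  assert(is_scalar_num(psf_sigma_hint) && psf_sigma_hint > 0,
         "`psf_sigma_hint` must be > 0")
  f <- gaussian_filter2(px, psf_sigma_hint)
  thr <- median(f) + k_sigma * mad(f)   # mad() includes the 1.4826 factor
  nr <- nrow(f); nc <- ncol(f)
  if (nr < 3 || nc < 3) return(data.frame(x_px = integer(0), y_px = integer(0)))
  ctr <- f[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- f[2:(nr - 1) + dr, 2:(nc - 1) + dc]
    # strict inequality for later-in-scan-order neighbors breaks plateau
    # ties, keeping one candidate per flat-topped maximum
    strict <- dr > 0 || (dr == 0 && dc > 0)
    is_max <- is_max & if (strict) ctr > nb else ctr >= nb
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(data.frame(x_px = integer(0), y_px = integer(0)))
  # interior index j corresponds to matrix row/col j + 1, i.e. 0-based j
  cand <- data.frame(x_px = unname(idx[, 2]), y_px = unname(idx[, 1]))
  # mutual proximity rejection
  if (nrow(cand) > 1) {
    d <- as.matrix(dist(cand[, c("x_px", "y_px")]))
    diag(d) <- Inf
    keep <- apply(d, 1, min) >= 4 * psf_sigma_hint
    cand <- cand[keep, , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

# integrated-Gaussian model over a fit window (0-based coordinates)
window_model <- function(cols, rows, x, y, sigma, B, bg) {
  gx <- pnorm((cols + 0.5 - x) / sigma) - pnorm((cols - 0.5 - x) / sigma)
  gy <- pnorm((rows + 0.5 - y) / sigma) - pnorm((rows - 0.5 - y) / sigma)
  bg + B * outer(gy, gx)
}

#' Fit one spot with an integrated 2D Gaussian
#'
#' Least-squares fit of `background + B * Gaussian` over a square window
#' around the candidate. The brightness `B` is the analytically integrated
#' Gaussian volume (total photons above background), which is robust to
#' window truncation. The background is a free constant per window.
#'
#' @param img a `photon_image` (or photon matrix).
#' @param pos candidate position `c(x_px, y_px)`, 0-based.
#' @param window window side length, pixels (odd, >= 7).
#' @param psf_sigma_hint initial PSF width, pixels; the accepted range is
#'   `sigma_range * psf_sigma_hint`.
#' @param sigma_range acceptance interval for sigma as multiples of the
#'   hint (default `c(0.5, 2.5)`).
#' @return one-row data.frame: `x_px`, `y_px`, `sigma_px`, `background`,
#'   `B_photons`, `residual_rms`, `accepted`. A window that leaves the
#'   frame, a flat window, or a diverged fit yields `accepted = FALSE`
#'   rather than an error.
#' @export
fit_gaussian_spot <- function(img, pos, window = 9L, psf_sigma_hint = 1.2,
                              sigma_range = c(0.5, 2.5)) {
  px <- if (inherits(img, "photon_image")) img$pixels else img
  assert(window >= 7, "`window` must be >= 7 px")
  half <- floor(window / 2)
  x0 <- round(pos[1]); y0 <- round(pos[2])
  rejected <- data.frame(x_px = NA_real_, y_px = NA_real_,
                         sigma_px = NA_real_, background = NA_real_,
                         B_photons = NA_real_, residual_rms = NA_real_,
                         accepted = FALSE)
  if (x0 - half < 0 || y0 - half < 0 ||
      x0 + half > ncol(px) - 1 || y0 + half > nrow(px) - 1)
    return(rejected)
  cols <- (x0 - half):(x0 + half)
  rows <- (y0 - half):(y0 + half)
  w <- px[rows + 1L, cols + 1L]
  # initialization: edge median as background, residual sum as brightness
  edge <- c(w[1, ], w[nrow(w), ], w[, 1], w[, ncol(w)])
  bg0 <- median(edge)
  B0 <- sum(w - bg0)
  if (!is.finite(B0) || B0 <= .Machine$double.eps) return(rejected)
  wpos <- w - min(w)
  x_init <- sum(outer(rep(1, length(rows)), cols) * wpos) / sum(wpos)
  y_init <- sum(outer(rows, rep(1, length(cols))) * wpos) / sum(wpos)
  obj <- function(p) {
    m <- window_model(cols, rows, p[1], p[2], exp(p[3]), exp(p[4]), p[5])
    sum((m - w)^2)
  }
  grad <- function(p) {
    x <- p[1]; y <- p[2]; sigma <- exp(p[3]); B <- exp(p[4]); bg <- p[5]
    ax <- (cols + 0.5 - x) / sigma; bx <- (cols - 0.5 - x) / sigma
    ay <- (rows + 0.5 - y) / sigma; by <- (rows - 0.5 - y) / sigma
    gx <- pnorm(ax) - pnorm(bx); gy <- pnorm(ay) - pnorm(by)
    dgx_dx <- -(dnorm(ax) - dnorm(bx)) / sigma
    dgy_dy <- -(dnorm(ay) - dnorm(by)) / sigma
    dgx_ds <- -(ax * dnorm(ax) - bx * dnorm(bx)) / sigma
    dgy_ds <- -(ay * dnorm(ay) - by * dnorm(by)) / sigma
    r <- 2 * (bg + B * outer(gy, gx) - w)
    c(sum(r * (B * outer(gy, dgx_dx))),
      sum(r * (B * outer(dgy_dy, gx))),
      sigma * sum(r * (B * (outer(dgy_ds, gx) + outer(gy, dgx_ds)))),
      sum(r * (B * outer(gy, gx))),     # d/d logB = B * d/dB
      sum(r))
  }
  fit <- tryCatch(
    optim(c(x_init, y_init, log(psf_sigma_hint), log(B0), bg0), obj, grad,
          method = "BFGS",
          control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(rejected)
  p <- fit$par
  sigma <- exp(p[3]); B <- exp(p[4])
  rms <- sqrt(fit$value / length(w))
  ok <- fit$convergence == 0 &&
    sigma >= sigma_range[1] * psf_sigma_hint &&
    sigma <= sigma_range[2] * psf_sigma_hint &&
    B > 0 && is.finite(B) &&
    p[1] >= min(cols) && p[1] <= max(cols) &&
    p[2] >= min(rows) && p[2] <= max(rows)
  data.frame(x_px = p[1], y_px = p[2], sigma_px = sigma, background = p[5],
             B_photons = B, residual_rms = rms, accepted = isTRUE(ok))
}

#' Extract a single-spot brightness table from a set of frames
#'
#' Runs photon conversion, spot detection, and Gaussian fitting on each
#' frame and concatenates the accepted fits.
#'
#' @param frames list of raw count matrices (or `photon_image`s).
#' @param camera a [camera_model()] (ignored for `photon_image` input).
#' @param psf_sigma_hint,k_sigma,window detection/fit parameters, see
#'   [detect_spots()] and [fit_gaussian_spot()].
#' @param keep_rejected logical: keep rejected fits (flagged) in the table?
#' @return data.frame with columns `frame`, `x_px`, `y_px`, `sigma_px`,
#'   `background`, `B_photons`, `residual_rms`, `accepted`.
#' @export
extract_brightness_table <- function(frames, camera = camera_model(),
                                     psf_sigma_hint = 1.2, k_sigma = 5,
                                     window = 9L, keep_rejected = FALSE) {
  empty <- data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), sigma_px = numeric(0),
                      background = numeric(0), B_photons = numeric(0),
                      residual_rms = numeric(0), accepted = logical(0))
  if (length(frames) == 0) return(empty)
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    pim <- if (inherits(fr, "photon_image")) fr else counts_to_photons(fr, camera)
    cand <- detect_spots(pim, psf_sigma_hint, k_sigma)
    if (nrow(cand) == 0) { out[[i]] <- empty; next }
    fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(j)
      fit_gaussian_spot(pim, c(cand$x_px[j], cand$y_px[j]), window,
                        psf_sigma_hint)))
    if (!keep_rejected) fits <- fits[fits$accepted, , drop = FALSE]
    if (nrow(fits) > 0) fits <- cbind(frame = i, fits)
    else fits <- empty
    out[[i]] <- fits
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate transporter surface density from a prebleach image
#'
#' Density = mean background-corrected photons per um^2 over the cell mask,
#' divided by the single-molecule brightness.
#'
#' @param prebleach a `photon_image`.
#' @param single_brightness single-fluorophore brightness, photons (> 0).
#' @param mask logical matrix selecting the cell region (default: whole
#'   frame).
#' @param background constant background photon level per pixel to
#'   subtract (default 0; photon images are already offset-subtracted).
#' @return estimated density, molecules per um^2.
#' @export
estimate_surface_density <- function(prebleach, single_brightness,
                                     mask = NULL, background = 0) {
  assert(inherits(prebleach, "photon_image"),
         "`prebleach` must be a photon_image")
  assert(is_scalar_num(single_brightness) && single_brightness > 0,
         "`single_brightness` must be > 0")
  px <- prebleach$pixels
  if (is.null(mask)) mask <- matrix(TRUE, nrow(px), ncol(px))
  assert(any(mask), "`mask` must select at least one pixel")
  vals <- pmax(px[mask] - background, 0)
  photons_per_um2 <- mean(vals) / prebleach$pixel_size^2
  photons_per_um2 / single_brightness
}
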