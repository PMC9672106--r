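#' Fit a FRAP recovery trace with the one-phase association model
#'
#' Nonlinear least squares of `I(t)/I0 = mf * (1 - exp(-K * t))`, where
#' `mf` is the mobile fraction and `K` the recovery rate constant.
#' Initialization: `mf0` = mean of the last 10% of intensities, `K0` =
#' `ln(2) / t_half` with `t_half` the first time the trace reaches half of
#' `mf0`. The 95% CI comes from the parameter covariance of the fit.
#' A trace that is constant (no recovery signal) is reported as
#' `mf = max(0, mean)` with `K = NA` rather than an error.
#'
#' @param trace data.frame with columns `time_s` (strictly increasing,
#'   >= 0) and `intensity_norm`, at least 5 points.
#' @return object of class `frap_fit`: list with `mf`, `K`, `ci95_mf`,
#'   `ci95_K`, `rss`, `converged`.
#' @export
fit_frap <- function(trace) {
  assert(is.data.frame(trace) &&
         all(c("time_s", "intensity_norm") %in% names(trace)),
         "`trace` needs columns time_s and intensity_norm")
  t <- trace$time_s; y <- trace$intensity_norm
  assert(length(t) >= 5L, "at least 5 points are required")
  assert(all(diff(t) > 0) && t[1] >= 0, "times must be increasing and >= 0")
  assert(all(is.finite(y)), "intensities must be finite")
  n_tail <- max(1L, ceiling(0.1 * length(y)))
  mf0 <- mean(utils::tail(y, n_tail))
  if (sd(y) < 1e-12 || mf0 <= 1e-12) {
    res <- list(mf = max(0, mean(y)), K = NA_real_,
                ci95_mf = c(NA_real_, NA_real_),
                ci95_K = c(NA_real_, NA_real_),
                rss = sum((y - mean(y))^2), converged = FALSE)
    return(structure(res, class = "frap_fit"))
  }
  i_half <- which(y >= mf0 / 2)[1]
  t_half <- if (!is.na(i_half) && t[i_half] > 0) t[i_half] else max(t) / 4
  K0 <- log(2) / t_half
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    nls(y ~ mf * (1 - exp(-K * t)), data = dat,
        start = list(mf = min(max(mf0, 1e-3), 1.1), K = K0),
        algorithm = "port", lower = c(mf = 0, K = 1e-8),
        upper = c(mf = 1.5, K = Inf),
        control = nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit))
    abort(sprintf(
      "FRAP fit did not converge (start mf0 = %.4g, K0 = %.4g)", mf0, K0),
      "toccsl_fit_failure")
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  if (log(2) / cf[["K"]] > max(t))
    warning("recovery half-time exceeds the observation window; ",
            "mf is poorly constrained")
  res <- list(mf = unname(cf[["mf"]]), K = unname(cf[["K"]]),
              ci95_mf = unname(cf[["mf"]] + c(-1, 1) * 1.96 * se[1]),
              ci95_K = unname(cf[["K"]] + c(-1, 1) * 1.96 * se[2]),
              rss = sum(residuals(fit)^2), converged = TRUE)
  structure(res, class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> mf = %.4f [%.4f, %.4f], K = %.4g /s, rss = %.3g\n",
              x$mf, x$ci95_mf[1], x$ci95_mf[2], x$K, x$rss))
  invisible(x)
}

#' Predict apparent oligomer fractions after partial photobleaching
#'
#' In a repeated-photobleach assay with active-molecule fraction `q`
#' (probability an individual fluorophore is still unbleached), two
#' scenarios are distinguished. Without subunit exchange, oligomers bleach
#' as units, so the composition of the spots that remain visible equals
#' the truth for any `q > 0`. With exchange, subunits re-pair randomly, so
#' an n-mer carries Binomial(n, q) active fluorophores and a dimer with
#' one active subunit *appears* as a monomer: the apparent monomer
#' fraction grows as `q` falls.
#'
#' @param fractions true oligomer fractions (index = order, sums to 1).
#' @param q active-molecule fraction in \[0, 1\].
#' @param exchange logical: do subunits re-pair?
#' @return numeric vector of apparent fractions over visible brightness
#'   classes 1..n_max (normalized over visible spots).
#' @export
predict_apparent_fractions <- function(fractions, q, exchange) {
  assert(is.numeric(fractions) && all(fractions >= 0) &&
         abs(sum(fractions) - 1) <= 1e-9, "`fractions` must sum to 1")
  assert(is_scalar_num(q) && q >= 0 && q <= 1, "`q` must lie in [0, 1]")
  n_max <- length(fractions)
  if (!exchange || q == 1) {
    if (q == 0) abort("q = 0 leaves no visible spots", "toccsl_undefined_result")
    return(fractions / sum(fractions))
  }
  # visible class k (>= 1 active fluorophores): sum_n alpha_n * P(Binom(n,q)=k)
  w <- vapply(seq_len(n_max), function(k)
    sum(fractions * dbinom(k, size = seq_len(n_max), prob = q)),
    numeric(1))
  tot <- sum(w)
  if (tot <= 0) abort("q = 0 leaves no visible spots", "toccsl_undefined_result")
  w / tot
}

#' Decline in active fluorophores across repeated runs
#'
#' Percent decrease of visible-spot (active-fluorophore) counts relative
#' to the first run: `100 * (1 - count_r / count_0)`.
#'
#' @param counts vector of per-run counts; `counts[1]` is the reference.
#' @return percent decreases for runs 2..R.
#' @export
#' @examples
#' active_fluorophore_decline(c(100, 36, 20))  # 64, 80
active_fluorophore_decline <- function(counts) {
  assert(is.numeric(counts) && length(counts) >= 2L,
         "`counts` needs at least two runs")
  assert(counts[1] > 0, "reference count (run 1) must be > 0")
  100 * (1 - counts[-1] / counts[1])
}

#' Test for subunit exchange across repeated runs
#'
#' Takes a per-cell matrix of average oligomeric states over repeated
#' runs, compares runs with the Friedman test (cells as blocks), and runs
#' Dunn's multiple-comparison posthoc of each later run against run 1
#' (z statistics on within-cell rank means, Bonferroni-style correction
#' over the number of comparisons, as in Dunn's procedure).
#'
#' @param avg_states numeric matrix, rows = cells (>= 6), columns = runs
#'   (>= 3): average oligomeric state \eqn{\langle n\rangle} per cell and
#'   run. Rows with missing values are not allowed (unequal cell sets).
#' @param alpha significance level for the posthoc flags (default 0.05).
#' @return list with `per_run_mean` (mean \eqn{\langle n\rangle} per run),
#'   `friedman_chisq`, `friedman_p`, and `posthoc` (data.frame: run,
#'   z, p_adj, significant).
#' @export
exchange_test <- function(avg_states, alpha = 0.05) {
  assert(is.matrix(avg_states) && ncol(avg_states) >= 3L,
         "`avg_states` must be a matrix with >= 3 runs (columns)")
  assert(nrow(avg_states) >= 6L, "at least 6 cells (rows) are required")
  assert(all(is.finite(avg_states)),
         "all cells must be measured in all runs (no missing values)")
  k <- ncol(avg_states); n <- nrow(avg_states)
  fr <- friedman.test(avg_states)
  # Dunn's posthoc on within-block ranks, runs 2..k vs run 1
  R <- t(apply(avg_states, 1, rank))
  rbar <- colMeans(R)
  se <- sqrt(k * (k + 1) / (6 * n))
  z <- (rbar[1] - rbar[-1]) / se
  p <- pmin(2 * pnorm(-abs(z)) * (k - 1), 1)
  list(per_run_mean = colMeans(avg_states),
       friedman_chisq = unname(fr$statistic),
       friedman_p = if (is.nan(fr$statistic) || fr$statistic == 0) 1
                    else fr$p.value,
       posthoc = data.frame(run = 2:k, z = unname(z), p_adj = unname(p),
                            significant = unname(p) < alpha))
}
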