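# Completeness-of-labeling analysis on a homo-oligomeric counting standard:
# blink-event extraction, log-normal single-fluorophore calibration,
# binomial-mixture convolution of the fully-labeled intensity distribution,
# and the median-ratio completeness estimate.

#' Log-normal single-fluorophore intensity parameters
#' @param mu location of ln(intensity) (log AD counts).
#' @param sigma scale (> 0).
#' @return list of class `log_normal_params`.
#' @export
log_normal_params <- function(mu = 5.68, sigma = 0.4) {
  stopifnot(sigma > 0)
  structure(list(mu = mu, sigma = sigma), class = "log_normal_params")
}

#' Binomial labeling model of a homo-oligomer
#'
#' Holds the subunit count n (24 for the FtnA ferritin standard), the
#' degree of labeling p with its uncertainty, the single-fluorophore
#' intensity calibration, and the derived binomial state probabilities
#' `P(k) = C(n,k) p^k (1-p)^(n-k)`.
#'
#' @param n_subunits subunits per oligomer.
#' @param dol degree of labeling (binomial p); 0.7 for the bivalent
#'   nanobody, 0.95 for the SNAP substrate.
#' @param dol_sd uncertainty of `dol` (0.15 / 0.05 respectively), used for
#'   the sensitivity band of [completeness()].
#' @param single a [log_normal_params()].
#' @return list of class `labeling_model` with `P_k` (k = 0..n).
#' @export
labeling_model <- function(n_subunits = 24, dol = 0.7, dol_sd = 0.15,
                           single = log_normal_params()) {
  stopifnot(n_subunits >= 1, dol >= 0, dol <= 1)
  structure(list(n_subunits = n_subunits, dol = dol, dol_sd = dol_sd,
                 single = single,
                 P_k = stats::dbinom(0:n_subunits, n_subunits, dol)),
            class = "labeling_model")
}

#' Default intensity grid for convolution
#'
#' Uniform grid from 0 with step 10 AD counts up to
#' `40 * exp(mu + 3 sigma)`, wide enough to hold the 24-fold convolution
#' with negligible mass loss.
#'
#' @param single a [log_normal_params()].
#' @param step grid step in AD counts.
#' @return list `x` (grid values), `step`.
#' @export
intensity_grid <- function(single, step = 10) {
  upper <- 40 * exp(single$mu + 3 * single$sigma)
  list(x = seq(0, upper, by = step), step = step)
}

# discretize the log-normal as atoms at grid values using exact cell masses
lognormal_pmf <- function(single, grid) {
  h <- grid$step / 2
  m <- stats::plnorm(grid$x + h, single$mu, single$sigma) -
    stats::plnorm(pmax(grid$x - h, 0), single$mu, single$sigma)
  m / sum(m)
}

#' Extract blink events from an intensity trace
#'
#' Detects step-like events in the trailing `window` frames: frames rising
#' above the window baseline (median) by more than `k_sd` noise standard
#' deviations form events; events separated by fewer than `min_sep` frames
#' are merged. The amplitude is the baseline-to-peak difference. Traces
#' with fewer than `min_blinks` events are rejected (molecule not selected),
#' which is not an error.
#'
#' @param trace numeric intensity trace (AD counts).
#' @param window number of trailing frames searched (default 100).
#' @param min_blinks minimal number of events for acceptance (default 2).
#' @param k_sd detection threshold in noise standard deviations.
#' @param min_sep minimal separation (frames) between distinct events.
#' @param noise_sd known noise sigma; estimated robustly (MAD) if `NULL`.
#'
#' @details Baseline and noise are estimated from the quiet mid-section of
#' the trace (after the initial frames, before the blink window) whenever
#' the trace is longer than the window; a trace dense with overlapping
#' blinks would otherwise inflate its own baseline. For traces exactly as
#' long as the window the window median/MAD are used.
#'
#' @return list of class `blink_events`: `accepted`, `events` (data.frame
#'   `start, end, amplitude`; frames 0-based within the full trace),
#'   `baseline`, `noise_sd`.
#' @export
extract_blinks <- function(trace, window = 100, min_blinks = 2, k_sd = 3,
                           min_sep = 3, noise_sd = NULL) {
  n <- length(trace)
  stopifnot(n >= window)
  w0 <- n - window              # 0-based index of first window frame
  w <- trace[(w0 + 1):n]
  quiet <- if (w0 > 3) trace[3:w0] else w
  baseline <- stats::median(quiet)
  if (is.null(noise_sd)) noise_sd <- stats::mad(quiet)
  if (noise_sd <= 0) noise_sd <- 1e-9
  above <- w > baseline + k_sd * noise_sd
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge events closer than min_sep frames
  if (nrow(ev) > 1) {
    keep <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      if (ev$start[i] - keep$end[nrow(keep)] < min_sep)
        keep$end[nrow(keep)] <- ev$end[i]
      else keep <- rbind(keep, ev[i, ])
    }
    ev <- keep
  }
  if (nrow(ev) > 0) {
    ev$amplitude <- vapply(seq_len(nrow(ev)), function(i)
      max(w[ev$start[i]:ev$end[i]]) - baseline, numeric(1))
    ev$start <- ev$start + w0 - 1L   # back to 0-based full-trace frames
    ev$end <- ev$end + w0 - 1L
  } else ev$amplitude <- numeric(0)
  structure(list(accepted = nrow(ev) >= min_blinks, events = ev,
                 baseline = baseline, noise_sd = noise_sd),
            class = "blink_events")
}

#' Calibrate the single-fluorophore intensity distribution
#'
#' Bins blink amplitudes (default 100 AD counts), forms the relative
#' frequency histogram, and least-squares fits the log-normal pdf
#' `f(x) = 1/(x sigma sqrt(2 pi)) exp(-(ln x - mu)^2 / (2 sigma^2))`
#' (scaled by the bin width) to it.
#'
#' @param amplitudes blink amplitudes in AD counts (>= 50 values).
#' @param bin_ad histogram bin width in AD counts.
#' @return list of class `log_normal_fit`: `mu`, `sigma`, standard errors,
#'   the `nls` fit object.
#' @export
fit_single_fluorophore <- function(amplitudes, bin_ad = 100) {
  amplitudes <- amplitudes[amplitudes > 0]
  if (length(amplitudes) < 50)
    stop("need >= 50 blink amplitudes for calibration")
  lg <- log(amplitudes)
  if (stats::sd(lg) < 1e-3)
    stop("degenerate amplitude distribution (zero spread)")
  br <- seq(0, (max(amplitudes) %/% bin_ad + 1) * bin_ad, by = bin_ad)
  h <- graphics::hist(amplitudes, breaks = br, plot = FALSE, right = FALSE)
  x <- h$mids
  y <- h$counts / sum(h$counts)      # relative frequency
  fit <- minpack.lm::nlsLM(
    y ~ bin_ad * stats::dlnorm(x, mu, sigma),
    data = list(x = x, y = y, bin_ad = bin_ad),
    start = list(mu = mean(lg), sigma = stats::sd(lg)),
    lower = c(0, 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(mu = NA_real_, sigma = NA_real_))
  structure(list(mu = unname(cf[["mu"]]), sigma = unname(cf[["sigma"]]),
                 se = se, fit = fit),
            class = "log_normal_fit")
}

#' Oligomer spot intensity (second frame, baseline subtracted)
#'
#' The oligomer's intensity readout is the integrated ROI intensity at the
#' second frame (0-based frame index 1), when all labeled subunits are on
#' simultaneously, minus the trace baseline. The baseline is estimated as
#' the median of the quiet mid-section of the trace (after the initial
#' frames, before the trailing blink window), which contains neither the
#' initial burst nor sparse late blinks.
#'
#' @param trace numeric intensity trace.
#' @param subtract_baseline subtract the trace baseline (default TRUE).
#' @param blink_window number of trailing frames excluded from the
#'   baseline estimate (the blink search window).
#' @return intensity in AD counts.
#' @export
oligomer_intensity <- function(trace, subtract_baseline = TRUE,
                               blink_window = 100) {
  n <- length(trace)
  stopifnot(n >= 2)
  v <- trace[2]
  if (!subtract_baseline) return(v)
  lo <- min(3L, n)
  hi <- max(lo, n - blink_window)
  v - stats::median(trace[lo:hi])
}

#' k-fold self-convolution of the single-fluorophore distribution
#'
#' Numeric k-fold convolution of the discretized single-fluorophore
#' log-normal density on a uniform grid, computed recursively
#' (`conv(k) = conv(k-1) * single`). Errors out if the grid cannot hold the
#' k-fold support (truncated mass > 1e-4).
#'
#' @param single a [log_normal_params()].
#' @param k convolution order (>= 1).
#' @param grid an [intensity_grid()].
#' @return list of class `intensity_dist`: `x`, `density` (integrates to
#'   1), `step`.
#' @export
kfold_convolution <- function(single, k, grid = intensity_grid(single)) {
  stopifnot(k >= 1)
  p1 <- lognormal_pmf(single, grid)
  pk <- p1
  lost <- 0
  if (k > 1) for (j in 2:k) {
    full <- stats::convolve(pk, rev(p1), type = "open")
    pk <- full[seq_along(p1)]
    lost <- lost + sum(full[-seq_along(p1)])
    pk[pk < 0] <- 0            # FFT round-off
  }
  if (lost > 1e-4)
    stop(sprintf("grid too short for %d-fold convolution (mass loss %.2g)",
                 k, lost))
  pk <- pk / sum(pk)
  structure(list(x = grid$x, density = pk / grid$step, step = grid$step),
            class = "intensity_dist")
}

dist_median <- function(dist) {
  cdf <- cumsum(dist$density) * dist$step
  i <- which(cdf >= 0.5)[1]
  if (i == 1) return(dist$x[1])
  x0 <- dist$x[i - 1]; x1 <- dist$x[i]
  c0 <- cdf[i - 1]; c1 <- cdf[i]
  x0 + (0.5 - c0) / (c1 - c0) * (x1 - x0)
}

dist_mean <- function(dist) sum(dist$x * dist$density) * dist$step

#' Binomial mixture intensity distribution of a labeled oligomer
#'
#' The fully-labeled reference distribution: a linear combination of the
#' k-fold convolutions of the single-fluorophore distribution, weighted by
#' the binomial state probabilities P(k). Unlabeled oligomers (k = 0)
#' produce no selectable spot, so the mixture is renormalized over k >= 1.
#'
#' @param model a [labeling_model()].
#' @param grid an [intensity_grid()].
#' @return list of class `intensity_mixture`: `dist` (an
#'   `intensity_dist`), `median`, `mean`, `P_k` (renormalized, k >= 1).
#' @export
mixture_distribution <- function(model,
                                 grid = intensity_grid(model$single)) {
  n <- model$n_subunits
  Pk <- model$P_k[-1]                 # drop k = 0
  Pk <- Pk / sum(Pk)
  p1 <- lognormal_pmf(model$single, grid)
  acc <- numeric(length(p1))
  pk <- p1
  lost <- 0
  for (k in 1:n) {
    if (k > 1) {
      full <- stats::convolve(pk, rev(p1), type = "open")
      pk <- full[seq_along(p1)]
      lost <- lost + sum(full[-seq_along(p1)])
      pk[pk < 0] <- 0
    }
    acc <- acc + Pk[k] * pk / sum(pk)
  }
  if (lost > 1e-4)
    stop("grid too short to hold the n-fold convolution")
  acc <- acc / sum(acc)
  dist <- structure(list(x = grid$x, density = acc / grid$step,
                         step = grid$step), class = "intensity_dist")
  structure(list(dist = dist, median = dist_median(dist),
                 mean = dist_mean(dist), P_k = Pk),
            class = "intensity_mixture")
}

#' Completeness of labeling
#'
#' The headline statistic: the median measured oligomer intensity as a
#' percentage of the median of the simulated fully-labeled mixture
#' distribution. A bootstrap confidence interval over the measured set and
#' a sensitivity band from the degree-of-labeling uncertainty
#' (p +/- dol_sd) are reported alongside.
#'
#' @param measured_intensities measured oligomer intensities (AD counts,
#'   >= 30 values).
#' @param model a [labeling_model()].
#' @param n_boot bootstrap replicates for the CI.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `completeness_estimate`: `percent`, `ci`,
#'   `sensitivity_band` (percent at p -/+ dol_sd), `model_median`,
#'   `measured_median`.
#' @export
completeness <- function(measured_intensities, model, n_boot = 200,
                         conf = 0.95, seed = NULL) {
  stopifnot(length(measured_intensities) >= 30)
  if (!is.null(seed)) set.seed(seed)
  ref <- mixture_distribution(model)
  med <- stats::median(measured_intensities)
  pct <- 100 * med / ref$median
  boots <- vapply(seq_len(n_boot), function(i)
    stats::median(sample(measured_intensities, replace = TRUE)),
    numeric(1))
  ci <- 100 * stats::quantile(boots, c((1 - conf) / 2, (1 + conf) / 2)) /
    ref$median
  band <- vapply(c(-1, 1), function(s) {
    p <- min(max(model$dol + s * model$dol_sd, 1e-6), 1)
    m2 <- labeling_model(model$n_subunits, p, model$dol_sd, model$single)
    100 * med / mixture_distribution(m2)$median
  }, numeric(1))
  structure(list(percent = pct, ci = unname(ci),
                 sensitivity_band = sort(band),
                 model_median = ref$median, measured_median = med),
            class = "completeness_estimate")
}
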