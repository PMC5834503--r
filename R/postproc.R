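# Shared preprocessing of every imaging experiment: fiducial-based drift
# correction, NeNA precision, blink merging, rendering, FIRE resolution.

#' Per-frame drift curve
#' @param frame 0-based frame indices (complete range).
#' @param dx_nm,dy_nm drift in nm; zero at the reference frame.
#' @return data.frame of class `drift_curve`.
#' @export
drift_curve <- function(frame, dx_nm, dy_nm) {
  df <- data.frame(frame = as.integer(frame), dx_nm = dx_nm, dy_nm = dy_nm)
  if (any(!is.finite(df$dx_nm)) || any(!is.finite(df$dy_nm)))
    stop("drift_curve: non-finite values")
  class(df) <- c("drift_curve", "data.frame")
  df
}

#' Detect fiducial beads in a localization table
#'
#' A bead is a spatial cluster (within `gather_radius_nm`) whose members
#' appear in at least `min_presence` of all frames — sample fluorophores
#' blink and never reach that presence. Missing frames in a detected bead
#' track are linearly interpolated.
#'
#' @param table a [loc_table()].
#' @param min_presence minimal fraction of frames a bead must appear in.
#' @param gather_radius_nm radius used to gather a bead's localizations.
#' @return list with `tracks` (list of data.frames `frame, x_nm, y_nm`, one
#'   per bead, covering every frame) and `is_bead` (logical mask over the
#'   table's rows).
#' @export
detect_fiducials <- function(table, min_presence = 0.9,
                             gather_radius_nm = 500) {
  if (nrow(table) == 0) stop("empty localization table")
  n_frames <- attr(table, "n_frames")
  # coarse grid cells; a bead dominates its cell
  cell <- gather_radius_nm
  ix <- floor(table$x_nm / cell)
  iy <- floor(table$y_nm / cell)
  key <- paste(ix, iy)
  counts <- table(key)
  cand <- names(counts)[counts >= min_presence * n_frames * 0.5]
  tracks <- list()
  is_bead <- rep(FALSE, nrow(table))
  used <- rep(FALSE, nrow(table))
  for (k in cand) {
    idx <- which(key == k & !used)
    if (length(idx) == 0) next
    center <- c(stats::median(table$x_nm[idx]), stats::median(table$y_nm[idx]))
    # gather across neighboring cells too
    near <- which(!used &
                    abs(table$x_nm - center[1]) <= gather_radius_nm &
                    abs(table$y_nm - center[2]) <= gather_radius_nm)
    d2 <- (table$x_nm[near] - center[1])^2 + (table$y_nm[near] - center[2])^2
    near <- near[d2 <= gather_radius_nm^2]
    frames_present <- unique(table$frame[near])
    if (length(frames_present) < min_presence * n_frames) next
    # one position per frame: the localization nearest the (refined) bead
    # center, so nearby blinking sample emitters cannot contaminate the track
    sel <- near
    for (it in 1:3) {
      d2 <- (table$x_nm[sel] - center[1])^2 + (table$y_nm[sel] - center[2])^2
      ord <- order(table$frame[sel], d2)
      keep <- ord[!duplicated(table$frame[sel][ord])]
      picked <- sel[keep]
      center <- c(stats::median(table$x_nm[picked]),
                  stats::median(table$y_nm[picked]))
      # drop picks far from the track's own spread (robust outlier cut)
      r <- sqrt((table$x_nm[picked] - center[1])^2 +
                  (table$y_nm[picked] - center[2])^2)
      cut <- stats::median(r) + 5 * stats::mad(r) + 1
      sel <- picked[r <= max(cut, 10)]
    }
    used[near] <- TRUE
    is_bead[near] <- TRUE
    agg <- data.frame(frame = table$frame[sel], x_nm = table$x_nm[sel],
                      y_nm = table$y_nm[sel])
    agg <- agg[order(agg$frame), ]
    fr_all <- seq_len(n_frames) - 1L
    tracks[[length(tracks) + 1L]] <- data.frame(
      frame = fr_all,
      x_nm = stats::approx(agg$frame, agg$x_nm, fr_all, rule = 2)$y,
      y_nm = stats::approx(agg$frame, agg$y_nm, fr_all, rule = 2)$y)
  }
  if (length(tracks) == 0)
    stop("no fiducial found: drift correction cannot run")
  list(tracks = tracks, is_bead = is_bead)
}

#' Estimate drift from fiducial bead tracks
#'
#' Per frame, drift is the mean over beads of the bead's displacement from
#' its position at the reference frame, smoothed by a centered moving
#' average.
#'
#' @param tracks list of per-bead data.frames `frame, x_nm, y_nm` covering
#'   all frames (as returned by [detect_fiducials()]).
#' @param window moving-average window in frames.
#' @param reference_frame frame at which drift is defined as zero.
#' @return a [drift_curve()].
#' @export
estimate_drift <- function(tracks, window = 10, reference_frame = 0L) {
  stopifnot(length(tracks) >= 1)
  fr <- tracks[[1]]$frame
  ref_i <- match(reference_frame, fr)
  dx <- rowMeans(vapply(tracks, function(t) t$x_nm - t$x_nm[ref_i],
                        numeric(length(fr))))
  dy <- rowMeans(vapply(tracks, function(t) t$y_nm - t$y_nm[ref_i],
                        numeric(length(fr))))
  if (window > 1) {
    dx <- moving_average(dx, window)
    dy <- moving_average(dy, window)
  }
  # keep the reference frame exactly at zero
  drift_curve(fr, dx - dx[ref_i], dy - dy[ref_i])
}

# centered moving average with shrinking windows at the edges
moving_average <- function(v, window) {
  h <- floor(window / 2)
  n <- length(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Apply a drift curve to a localization table
#'
#' Subtracts the per-frame drift from every localization. Record count and
#' intensities are conserved.
#'
#' @param table a [loc_table()].
#' @param curve a [drift_curve()] covering all frames of the table.
#' @return corrected [loc_table()].
#' @export
correct_drift <- function(table, curve) {
  if (nrow(table) == 0) return(table)
  i <- match(table$frame, curve$frame)
  if (anyNA(i)) stop("drift curve does not cover all frames")
  df <- as.data.frame(table)
  df$x_nm <- df$x_nm - curve$dx_nm[i]
  df$y_nm <- df$y_nm - curve$dy_nm[i]
  as_loc_table(df, table)
}

# for each point in (x1,y1), distance to nearest point in (x2,y2) within rmax
nn_dist_between <- function(x1, y1, x2, y2, rmax) {
  n1 <- length(x1)
  out <- rep(NA_real_, n1)
  if (n1 == 0 || length(x2) == 0) return(out)
  cell <- rmax
  ix2 <- floor(x2 / cell); iy2 <- floor(y2 / cell)
  keys2 <- split(seq_along(x2), paste(ix2, iy2))
  ix1 <- floor(x1 / cell); iy1 <- floor(y1 / cell)
  for (i in seq_len(n1)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(ix1[i] + dx, iy1[i] + dy)
      c2 <- keys2[[k]]
      if (!is.null(c2)) cand <- c(cand, c2)
    }
    if (length(cand) == 0) next
    d2 <- (x2[cand] - x1[i])^2 + (y2[cand] - y1[i])^2
    m <- min(d2)
    if (m <= rmax^2) out[i] <- sqrt(m)
  }
  out
}

#' NeNA localization precision estimate
#'
#' Collects, for every localization, the nearest-neighbor distance among the
#' localizations of the *next* frame (within `search_radius_nm`) and fits
#' the binned distance distribution with the same-molecule model
#' `p(d) = d/(2 sigma^2) * exp(-d^2 / (4 sigma^2))` plus a background term
#' (linear in d plus one broad Gaussian ridge), following common NeNA
#' practice. The correlated (same-molecule) component's sigma is the
#' localization precision.
#'
#' @param table a [loc_table()].
#' @param exclude_rois optional list of [roi()]s to drop (e.g. regions
#'   containing fiducial markers).
#' @param search_radius_nm maximal next-frame neighbor distance considered.
#' @param bin_nm histogram bin width in nm.
#' @param min_pairs minimal number of next-frame pairs required.
#' @return list of class `nena_estimate`: `sigma_loc_nm`, `n_pairs`,
#'   `correlated_fraction` (mass in the same-molecule term; small values
#'   flag an unreliable fit), `reliable`, `fit`.
#' @export
estimate_nena <- function(table, exclude_rois = NULL,
                          search_radius_nm = 500, bin_nm = 2,
                          min_pairs = 1000) {
  df <- as.data.frame(table)
  if (!is.null(exclude_rois))
    for (r in exclude_rois) df <- df[!in_roi(df, r), ]
  byf <- split(seq_len(nrow(df)), df$frame)
  frames <- as.integer(names(byf))
  d_all <- numeric(0)
  for (j in seq_along(frames)) {
    nxt <- match(frames[j] + 1L, frames)
    if (is.na(nxt)) next
    i1 <- byf[[j]]; i2 <- byf[[nxt]]
    d <- nn_dist_between(df$x_nm[i1], df$y_nm[i1],
                         df$x_nm[i2], df$y_nm[i2], search_radius_nm)
    d_all <- c(d_all, d[!is.na(d)])
  }
  if (length(d_all) < min_pairs)
    stop(sprintf("estimate_nena: only %d next-frame pairs (need >= %d)",
                 length(d_all), min_pairs))
  # degenerate limit: essentially all mass at zero distance
  if (stats::quantile(d_all, 0.9) < 2 * bin_nm) {
    return(structure(list(sigma_loc_nm = stats::sd(d_all) / sqrt(2),
                          n_pairs = length(d_all),
                          correlated_fraction = 1, reliable = TRUE,
                          fit = NULL), class = "nena_estimate"))
  }
  br <- seq(0, search_radius_nm + bin_nm, by = bin_nm)
  h <- graphics::hist(d_all, breaks = br, plot = FALSE)
  x <- h$mids
  y <- h$counts / (sum(h$counts) * bin_nm)  # empirical density
  rmax <- search_radius_nm
  corr_term <- function(d, s) d / (2 * s^2) * exp(-d^2 / (4 * s^2))
  s0 <- x[which.max(y)] / sqrt(2)
  if (!is.finite(s0) || s0 <= 0) s0 <- 10
  fit <- NULL
  for (start_s in unique(c(s0, 5, 10, 20, 50))) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ ac * (d / (2 * s^2) * exp(-d^2 / (4 * s^2))) +
        ab * 2 * d / rmax^2 +
        ag * d * exp(-(d - dc)^2 / (2 * w^2)),
      data = list(d = x, y = y, rmax = rmax),
      start = list(ac = 0.7, s = start_s, ab = 0.2, ag = 1e-4,
                   dc = rmax / 2, w = rmax / 4),
      lower = c(0, 0.1, 0, 0, 0, 1),
      upper = c(10, rmax, 10, 1, rmax, rmax),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # no same-molecule component fittable: report an unreliable estimate
    # rather than failing, so callers can inspect the diagnostics
    return(structure(list(sigma_loc_nm = NA_real_,
                          n_pairs = length(d_all),
                          correlated_fraction = 0, reliable = FALSE,
                          fit = NULL), class = "nena_estimate"))
  }
  cf <- stats::coef(fit)
  total <- sum(stats::predict(fit)) * bin_nm
  corr_mass <- sum(cf[["ac"]] * corr_term(x, cf[["s"]])) * bin_nm / total
  structure(list(sigma_loc_nm = unname(cf[["s"]]),
                 n_pairs = length(d_all),
                 correlated_fraction = unname(corr_mass),
                 reliable = corr_mass > 0.25,
                 fit = fit),
            class = "nena_estimate")
}

#' Merge repeated blinks of one molecule into single localizations
#'
#' Localizations appearing within `radius_nm` (typically the NeNA value) on
#' consecutive frames (frame gaps up to `max_gap_frames` allowed) are
#' chained and replaced by one record: intensity-weighted mean position,
#' summed intensity, first frame. Within one frame nothing is merged.
#'
#' @param table a [loc_table()].
#' @param radius_nm chaining radius in nm (> 0).
#' @param max_gap_frames maximal number of dark frames inside a chain.
#' @return merged [loc_table()]; total intensity is conserved exactly.
#' @export
merge_blinks <- function(table, radius_nm, max_gap_frames = 0) {
  stopifnot(radius_nm > 0)
  df <- as.data.frame(table)
  n <- nrow(df)
  if (n == 0) return(table)
  ord <- order(df$frame, seq_len(n))
  chain_of <- integer(n)
  # active chains: running sums and last position/frame
  cx <- cy <- cw <- clx <- cly <- numeric(0)
  clast <- cfirst <- integer(0)
  n_chain <- 0L
  byf <- split(ord, df$frame[ord])
  for (fgroup in byf) {
    f <- df$frame[fgroup[1]]
    active <- which(clast >= f - 1L - max_gap_frames & clast < f)
    taken <- rep(FALSE, length(active))
    for (i in fgroup) {
      best <- 0L; bestd <- Inf
      if (length(active) > 0) {
        d2 <- (clx[active] - df$x_nm[i])^2 + (cly[active] - df$y_nm[i])^2
        d2[taken] <- Inf
        j <- which.min(d2)  # ties: lowest chain index wins
        if (d2[j] <= radius_nm^2) { best <- j; bestd <- d2[j] }
      }
      if (best > 0L) {
        ch <- active[best]
        taken[best] <- TRUE
        w <- df$intensity[i]
        cx[ch] <- cx[ch] + w * df$x_nm[i]
        cy[ch] <- cy[ch] + w * df$y_nm[i]
        cw[ch] <- cw[ch] + w
        clx[ch] <- df$x_nm[i]; cly[ch] <- df$y_nm[i]
        clast[ch] <- f
        chain_of[i] <- ch
      } else {
        n_chain <- n_chain + 1L
        w <- df$intensity[i]
        cx[n_chain] <- w * df$x_nm[i]; cy[n_chain] <- w * df$y_nm[i]
        cw[n_chain] <- w
        clx[n_chain] <- df$x_nm[i]; cly[n_chain] <- df$y_nm[i]
        clast[n_chain] <- f; cfirst[n_chain] <- f
        chain_of[i] <- n_chain
      }
    }
  }
  # zero-intensity members: fall back to unweighted means
  wsum <- cw
  zero <- wsum == 0
  if (any(zero)) {
    for (ch in which(zero)) {
      mem <- which(chain_of == ch)
      cx[ch] <- mean(df$x_nm[mem]); cy[ch] <- mean(df$y_nm[mem])
      wsum[ch] <- 1
    }
  }
  loc_table(cx / wsum, cy / wsum, cfirst, cw,
            pixel_size_nm = attr(table, "pixel_size_nm"),
            exposure_ms = attr(table, "exposure_ms"),
            n_frames = attr(table, "n_frames"))
}

# separable normalized Gaussian convolution; the image must carry enough
# margin for the kernel so that total mass is conserved
gaussian_blur <- function(m, sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-r:r, 0, sigma_px)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(0, r), v, rep(0, r))
    out <- stats::filter(vp, k, method = "convolution", sides = 2)
    out[(r + 1):(r + n)]
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(m2, 1, pad_conv))
}

#' Reconstruct a super-resolution image from localizations
#'
#' 2D histogram of positions at the given pixel size (half-open pixels,
#' origin snapped to the pixel grid). With `blur_sigma_nm` set, a normalized
#' Gaussian blur is applied (sigma in nm, typically the NeNA value); a
#' margin is added so the blur conserves total mass.
#'
#' @param table a [loc_table()].
#' @param pixel_nm reconstruction pixel size (default 10).
#' @param blur_sigma_nm optional Gaussian blur sigma in nm.
#' @param extent optional `c(x_min, x_max, y_min, y_max)` in nm; default is
#'   the data bounding box snapped to the pixel grid.
#' @return a [raster_image()] whose values sum to the record count.
#' @export
reconstruct_image <- function(table, pixel_nm = 10, blur_sigma_nm = NULL,
                              extent = NULL) {
  if (nrow(table) == 0) stop("empty localization table")
  if (is.null(extent))
    extent <- c(floor(min(table$x_nm) / pixel_nm) * pixel_nm,
                ceiling((max(table$x_nm) + 1e-9) / pixel_nm) * pixel_nm,
                floor(min(table$y_nm) / pixel_nm) * pixel_nm,
                ceiling((max(table$y_nm) + 1e-9) / pixel_nm) * pixel_nm)
  margin <- if (is.null(blur_sigma_nm)) 0 else
    ceiling(4 * blur_sigma_nm / pixel_nm + 1) * pixel_nm
  extent <- extent + c(-margin, margin, -margin, margin)
  nx <- round((extent[2] - extent[1]) / pixel_nm)
  ny <- round((extent[4] - extent[3]) / pixel_nm)
  ix <- floor((table$x_nm - extent[1]) / pixel_nm)
  iy <- floor((table$y_nm - extent[3]) / pixel_nm)
  inside <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
  m <- matrix(0, nrow = ny, ncol = nx)
  idx <- iy[inside] + 1L + ix[inside] * ny
  tabcnt <- tabulate(idx, nbins = nx * ny)
  m[] <- tabcnt
  if (!is.null(blur_sigma_nm) && blur_sigma_nm > 0)
    m <- gaussian_blur(m, blur_sigma_nm / pixel_nm)
  raster_image(m, pixel_nm, origin_nm = c(extent[1], extent[3]))
}

#' FIRE resolution by Fourier ring correlation
#'
#' Splits the localizations into two half-images by alternating frames
#' (frame parity), rasterizes both on a common grid, computes the Fourier
#' ring correlation over radial frequency, and reads the resolution at the
#' first crossing of the fixed 1/7 threshold (linear interpolation between
#' rings).
#'
#' @param table a [loc_table()] with at least 2 distinct frames.
#' @param threshold FRC threshold (fixed 1/7).
#' @param pixel_nm rasterization pixel size for the half-images.
#' @param size_px side of the (square) Fourier image in pixels; default the
#'   next power of two covering the data, capped at 2048.
#' @return list of class `fire_result`: `resolution_nm` (`NA` if the curve
#'   never crosses the threshold — "unresolved"), `frc` (data.frame
#'   `freq_per_nm, frc`), `threshold`.
#' @export
fire_resolution <- function(table, threshold = 1 / 7, pixel_nm = 10,
                            size_px = NULL) {
  if (length(unique(table$frame)) < 2)
    stop("fire_resolution needs >= 2 distinct frames")
  df <- as.data.frame(table)
  even <- df$frame %% 2L == 0L
  ext <- c(floor(min(df$x_nm) / pixel_nm) * pixel_nm,
           ceiling((max(df$x_nm) + 1e-9) / pixel_nm) * pixel_nm,
           floor(min(df$y_nm) / pixel_nm) * pixel_nm,
           ceiling((max(df$y_nm) + 1e-9) / pixel_nm) * pixel_nm)
  need <- max(ext[2] - ext[1], ext[4] - ext[3]) / pixel_nm
  if (is.null(size_px)) size_px <- min(2048, 2^ceiling(log2(max(need, 2))))
  S <- size_px
  rasterize_half <- function(sub) {
    m <- matrix(0, S, S)
    ix <- floor((sub$x_nm - ext[1]) / pixel_nm)
    iy <- floor((sub$y_nm - ext[3]) / pixel_nm)
    ok <- ix >= 0 & ix < S & iy >= 0 & iy < S
    idx <- iy[ok] + 1L + ix[ok] * S
    m[] <- tabulate(idx, nbins = S * S)
    m
  }
  I1 <- rasterize_half(df[even, ])
  I2 <- rasterize_half(df[!even, ])
  F1 <- stats::fft(I1)
  F2 <- stats::fft(I2)
  fx <- c(0:(S %/% 2), -((S - S %/% 2 - 1):1)) / S
  k <- sqrt(outer(fx^2, fx^2, "+"))      # cycles per pixel
  ring <- round(k * S)                   # integer ring index
  num <- Re(F1 * Conj(F2))
  d1 <- Mod(F1)^2
  d2 <- Mod(F2)^2
  rmaxi <- S %/% 2
  sel <- ring <= rmaxi
  rn <- rowsum(num[sel], ring[sel])
  r1 <- rowsum(d1[sel], ring[sel])
  r2 <- rowsum(d2[sel], ring[sel])
  rings <- as.integer(rownames(rn))
  frc <- as.numeric(rn) / sqrt(as.numeric(r1) * as.numeric(r2))
  frc[!is.finite(frc)] <- 0
  freq <- rings / (S * pixel_nm)         # cycles per nm
  keep <- rings > 0
  curve <- data.frame(freq_per_nm = freq[keep], frc = frc[keep])
  below <- which(curve$frc < threshold)
  res <- NA_real_
  if (length(below) > 0) {
    j <- below[1]
    if (j == 1) {
      res <- 1 / curve$freq_per_nm[1]
    } else {
      f0 <- curve$frc[j - 1]; f1 <- curve$frc[j]
      q0 <- curve$freq_per_nm[j - 1]; q1 <- curve$freq_per_nm[j]
      qc <- q0 + (f0 - threshold) / (f0 - f1) * (q1 - q0)
      res <- 1 / qc
    }
  }
  structure(list(resolution_nm = res, frc = curve, threshold = threshold),
            class = "fire_result")
}
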