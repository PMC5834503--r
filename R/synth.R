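# Ground-truth-annotated simulators for every downstream stage. All
# generators take an integer `seed`; a fixed seed gives identical output.

#' Photoswitching (blink) model of a single fluorophore
#'
#' Integrated single-blink intensity is log-normal; the defaults are the
#' AF647 calibration values obtained on single-fluorophore blinking events
#' (location 5.68, scale 0.4, in log AD counts). On-times are geometric in
#' frames (memoryless), blink counts per fluorophore are 1 + Poisson.
#'
#' @param mean_blinks mean number of blink events per fluorophore (>= 1).
#' @param on_frames mean consecutive on-frames per blink event.
#' @param logI_mu,logI_sigma log-normal location/scale of the single-blink
#'   peak intensity (AD counts).
#' @return list of class `blink_model`.
#' @export
blink_model <- function(mean_blinks = 3, on_frames = 2,
                        logI_mu = 5.68, logI_sigma = 0.4) {
  stopifnot(mean_blinks >= 1, on_frames >= 1, logI_sigma > 0)
  structure(list(mean_blinks = mean_blinks, on_frames = on_frames,
                 logI_mu = logI_mu, logI_sigma = logI_sigma),
            class = "blink_model")
}

rblinks <- function(n, blink) 1L + stats::rpois(n, blink$mean_blinks - 1)
ron_frames <- function(n, blink) {
  if (blink$on_frames <= 1) rep(1L, n)
  else 1L + stats::rgeom(n, 1 / blink$on_frames)
}

# arclength parametrization of a polyline: position + unit tangent at s
poly_cumlen <- function(xy) {
  d <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
  c(0, cumsum(d))
}

poly_point <- function(xy, s) {
  cl <- poly_cumlen(xy)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  seg <- findInterval(s, cl, rightmost.closed = TRUE)
  seg <- pmin(seg, nrow(xy) - 1L)
  t0 <- xy[seg, , drop = FALSE]
  t1 <- xy[seg + 1L, , drop = FALSE]
  len <- cl[seg + 1L] - cl[seg]
  f <- (s - cl[seg]) / len
  pos <- t0 + (t1 - t0) * f
  tang <- (t1 - t0) / len
  list(pos = pos, tangent = tang)
}

# expand blink events of emitters into per-frame localizations
emit_localizations <- function(emitters, blink, sigma_loc_nm, n_frames) {
  n_e <- nrow(emitters)
  if (n_e == 0)
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      frame = integer(0), intensity = numeric(0),
                      emitter_id = integer(0)))
  nb <- rblinks(n_e, blink)
  eid <- rep(seq_len(n_e), nb)
  n_bl <- length(eid)
  start <- sample.int(n_frames, n_bl, replace = TRUE) - 1L
  on <- ron_frames(n_bl, blink)
  amp <- stats::rlnorm(n_bl, blink$logI_mu, blink$logI_sigma)
  bid <- rep(seq_len(n_bl), on)
  fr <- start[bid] + (sequence(on) - 1L)
  keep <- fr < n_frames
  bid <- bid[keep]; fr <- fr[keep]
  n_loc <- length(bid)
  data.frame(
    x_nm = emitters$x_nm[eid[bid]] + stats::rnorm(n_loc, 0, sigma_loc_nm),
    y_nm = emitters$y_nm[eid[bid]] + stats::rnorm(n_loc, 0, sigma_loc_nm),
    frame = as.integer(fr),
    intensity = amp[bid],
    emitter_id = eid[bid])
}

#' Simulate blinking emitters decorating filament centerlines
#'
#' Emitters sit on the given centerlines, offset transversely by
#' `Normal(0, width_nm / 2.35)` so that the analysis-side FWHM convention
#' (2.35 sigma) recovers the nominal width exactly. A fraction
#' `1 - coverage` of contiguous centerline segments (length `seg_len_nm`)
#' carries no emitters, emulating incomplete lengthwise labeling.
#'
#' @param centerlines list of [polyline()]s.
#' @param width_nm true filament width (FWHM convention), recycled.
#' @param coverage lengthwise labeled fraction in `[0, 1]`, recycled.
#' @param label_density emitters per micrometre of labeled centerline.
#' @param blink a [blink_model()].
#' @param sigma_loc_nm true localization precision (per-axis sigma, nm).
#' @param n_frames number of acquisition frames.
#' @param seg_len_nm centerline segment length used for coverage gaps.
#' @param seed integer RNG seed.
#' @return list with `table` (a [loc_table()] carrying `emitter_id`) and
#'   `truth` (emitters, per-filament parameters, `sigma_loc_nm`).
#' @export
sim_filament_field <- function(centerlines, width_nm = 75, coverage = 1,
                               label_density = 100, blink = blink_model(),
                               sigma_loc_nm = 10, n_frames = 10000,
                               seg_len_nm = 500, seed = NULL) {
  if (any(coverage < 0 | coverage > 1))
    stop("coverage must be within [0, 1]")
  if (any(width_nm < 0)) stop("widths must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  nf <- length(centerlines)
  width_nm <- rep_len(width_nm, nf)
  coverage <- rep_len(coverage, nf)
  emitters <- NULL
  for (i in seq_len(nf)) {
    xy <- unclass(centerlines[[i]])
    L <- poly_cumlen(xy)
    L <- L[length(L)]
    n_seg <- max(1L, ceiling(L / seg_len_nm))
    n_off <- round((1 - coverage[i]) * n_seg)
    labeled <- rep(TRUE, n_seg)
    if (n_off > 0) labeled[sample.int(n_seg, n_off)] <- FALSE
    n_em <- stats::rpois(1, label_density * L / 1000 * mean(labeled))
    if (n_em == 0) next
    seg_edges <- seq(0, L, length.out = n_seg + 1)
    seg_of <- function(s) pmin(findInterval(s, seg_edges,
                                            rightmost.closed = TRUE), n_seg)
    # rejection-sample arclengths restricted to labeled segments
    s <- numeric(0)
    while (length(s) < n_em) {
      cand <- stats::runif(2 * n_em, 0, L)
      cand <- cand[labeled[seg_of(cand)]]
      s <- c(s, cand)
    }
    s <- s[seq_len(n_em)]
    pp <- poly_point(xy, s)
    normal <- cbind(-pp$tangent[, 2], pp$tangent[, 1])
    off <- stats::rnorm(n_em, 0, width_nm[i] / 2.35)
    pos <- pp$pos + normal * off
    emitters <- rbind(emitters, data.frame(
      x_nm = pos[, 1], y_nm = pos[, 2], filament = i,
      segment = seg_of(s)))
  }
  if (is.null(emitters))
    emitters <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                           filament = integer(0), segment = integer(0))
  locs <- emit_localizations(emitters, blink, sigma_loc_nm, n_frames)
  tab <- loc_table(locs$x_nm, locs$y_nm, locs$frame, locs$intensity,
                   n_frames = n_frames,
                   extra = data.frame(emitter_id = locs$emitter_id))
  list(table = tab,
       truth = list(emitters = emitters, width_nm = width_nm,
                    coverage = coverage, sigma_loc_nm = sigma_loc_nm,
                    centerlines = centerlines))
}

#' Simulate localizations on a nanobody-labeled microtubule
#'
#' Emitters are uniform on the surface of a cylinder of the given diameter
#' (microtubules: 25 nm), displaced radially outward by
#' `Uniform(0, probe_displacement_nm)` to model the probe linkage error,
#' projected to 2D, and blurred by per-axis Gaussian localization error.
#' The cylinder axis runs along x at `y = y0_nm`.
#'
#' @param n_localizations number of localizations to draw.
#' @param diameter_nm cylinder diameter (default 25, a microtubule).
#' @param probe_displacement_nm maximal radial probe displacement (nm).
#' @param sigma_loc_nm per-axis localization error sigma (nm).
#' @param length_nm cylinder length along x.
#' @param y0_nm transverse position of the axis.
#' @param n_frames frames the localizations are spread over.
#' @param seed integer RNG seed.
#' @return a [loc_table()].
#' @export
sim_microtubule <- function(n_localizations, diameter_nm = 25,
                            probe_displacement_nm = 5, sigma_loc_nm = 10,
                            length_nm = 2000, y0_nm = 200,
                            n_frames = 1000, seed = NULL) {
  stopifnot(diameter_nm >= 0, probe_displacement_nm >= 0, length_nm > 0)
  if (n_localizations < 100)
    warning("fewer than 100 localizations: width fit will be unstable")
  if (!is.null(seed)) set.seed(seed)
  n <- n_localizations
  r <- diameter_nm / 2 + stats::runif(n, 0, probe_displacement_nm)
  theta <- stats::runif(n, 0, 2 * pi)
  x <- stats::runif(n, 0, length_nm) + stats::rnorm(n, 0, sigma_loc_nm)
  y <- y0_nm + r * cos(theta) + stats::rnorm(n, 0, sigma_loc_nm)
  loc_table(x, y, sample.int(n_frames, n, replace = TRUE) - 1L,
            stats::rlnorm(n, 5.68, 0.4), n_frames = n_frames)
}

#' Simulate clustered localizations over uniform background
#'
#' Cluster members are `Normal(center, cluster_radius_nm)` per axis;
#' background is homogeneous Poisson over the ROI.
#'
#' @param roi an [roi()].
#' @param clusters number of clusters (centers drawn uniformly in the ROI,
#'   away from the edges) or a two-column matrix of centers in nm.
#' @param locs_per_cluster localizations per cluster (recycled).
#' @param cluster_radius_nm per-axis Gaussian sigma of member positions.
#' @param background_density background localizations per square micrometre.
#' @param n_frames frames the localizations are spread over.
#' @param seed integer RNG seed.
#' @return list with `table` (a [loc_table()] carrying `cluster_id`, 0 for
#'   background) and `truth` (centers, radius, counts).
#' @export
sim_cluster_field <- function(roi, clusters = 10, locs_per_cluster = 50,
                              cluster_radius_nm = 30,
                              background_density = 0, n_frames = 1000,
                              seed = NULL) {
  stopifnot(background_density >= 0, cluster_radius_nm >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(clusters)) {
    centers <- clusters
  } else if (clusters > 0) {
    pad <- 4 * cluster_radius_nm
    centers <- cbind(stats::runif(clusters, roi["x_min"] + pad, roi["x_max"] - pad),
                     stats::runif(clusters, roi["y_min"] + pad, roi["y_max"] - pad))
  } else centers <- matrix(numeric(0), 0, 2)
  k <- nrow(centers)
  npc <- rep_len(locs_per_cluster, k)
  cid <- rep(seq_len(k), npc)
  xc <- centers[cid, 1] + stats::rnorm(length(cid), 0, cluster_radius_nm)
  yc <- centers[cid, 2] + stats::rnorm(length(cid), 0, cluster_radius_nm)
  n_bg <- stats::rpois(1, background_density * roi_area_um2(roi))
  xb <- stats::runif(n_bg, roi["x_min"], roi["x_max"])
  yb <- stats::runif(n_bg, roi["y_min"], roi["y_max"])
  n <- length(xc) + n_bg
  tab <- loc_table(c(xc, xb), c(yc, yb),
                   sample.int(n_frames, n, replace = TRUE) - 1L,
                   n_frames = n_frames,
                   extra = data.frame(cluster_id = c(cid, rep(0L, n_bg))))
  list(table = tab,
       truth = list(centers = centers, radius_nm = cluster_radius_nm,
                    locs_per_cluster = npc, n_background = n_bg))
}

#' Build a per-frame drift curve
#'
#' @param n_frames number of frames.
#' @param type `"none"`, `"linear"` (`v_nm_per_frame`, length-2) or
#'   `"walk"` (cumulative Gaussian random walk, per-frame step sigma
#'   `step_sd_nm` per axis).
#' @param v_nm_per_frame drift velocity for `"linear"`.
#' @param step_sd_nm per-frame step sigma for `"walk"`.
#' @param seed integer RNG seed.
#' @return data.frame `frame, dx_nm, dy_nm` of class `drift_curve`, zero at
#'   frame 0.
#' @export
make_drift <- function(n_frames, type = c("walk", "linear", "none"),
                       v_nm_per_frame = c(0.05, -0.03), step_sd_nm = 0.5,
                       seed = NULL) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  fr <- seq_len(n_frames) - 1L
  d <- switch(type,
    none = cbind(0 * fr, 0 * fr),
    linear = cbind(v_nm_per_frame[1] * fr, v_nm_per_frame[2] * fr),
    walk = cbind(cumsum(c(0, stats::rnorm(n_frames - 1, 0, step_sd_nm))),
                 cumsum(c(0, stats::rnorm(n_frames - 1, 0, step_sd_nm)))))
  drift_curve(fr, d[, 1], d[, 2])
}

#' Add fiducial beads and common drift to a localization table
#'
#' Beads are bright, present in (nearly) every frame, and displaced by the
#' same drift curve as the sample localizations — the geometry drift
#' correction assumes.
#'
#' @param table a [loc_table()] of sample localizations (undrifted).
#' @param n_beads number of fiducial beads (>= 1).
#' @param drift a `drift_curve` (e.g. from [make_drift()]) covering the
#'   table's frames.
#' @param sigma_loc_nm bead localization error sigma (beads are bright, so
#'   small; default 2 nm).
#' @param presence per-frame detection probability of each bead.
#' @param bead_intensity mean bead intensity (AD counts).
#' @param seed integer RNG seed.
#' @return list with `table` (sample + beads, drifted; beads flagged by the
#'   `bead_id` column, 0 for sample) and `truth` (drift curve, bead
#'   positions).
#' @export
sim_fiducials_with_drift <- function(table, n_beads = 2,
                                     drift = make_drift(attr(table, "n_frames")),
                                     sigma_loc_nm = 2, presence = 0.998,
                                     bead_intensity = 5e4, seed = NULL) {
  stopifnot(n_beads >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_frames <- attr(table, "n_frames")
  if (nrow(drift) < n_frames) stop("drift curve shorter than n_frames")
  xr <- if (nrow(table) > 0) range(table$x_nm) else c(0, 10000)
  yr <- if (nrow(table) > 0) range(table$y_nm) else c(0, 10000)
  span <- max(xr[2] - xr[1], yr[2] - yr[1], 2000)
  bead_xy <- cbind(stats::runif(n_beads, xr[1] - 0.2 * span, xr[2] + 0.2 * span),
                   stats::runif(n_beads, yr[1] - 0.2 * span, yr[2] + 0.2 * span))
  rows <- NULL
  for (b in seq_len(n_beads)) {
    present <- stats::runif(n_frames) < presence
    fr <- which(present) - 1L
    rows <- rbind(rows, data.frame(
      x_nm = bead_xy[b, 1] + drift$dx_nm[fr + 1L] +
        stats::rnorm(length(fr), 0, sigma_loc_nm),
      y_nm = bead_xy[b, 2] + drift$dy_nm[fr + 1L] +
        stats::rnorm(length(fr), 0, sigma_loc_nm),
      frame = fr,
      intensity = bead_intensity * stats::runif(length(fr), 0.9, 1.1),
      bead_id = b))
  }
  samp <- as.data.frame(table)
  samp$x_nm <- samp$x_nm + drift$dx_nm[samp$frame + 1L]
  samp$y_nm <- samp$y_nm + drift$dy_nm[samp$frame + 1L]
  samp <- samp[c("x_nm", "y_nm", "frame", "intensity")]
  samp$bead_id <- 0L
  all <- rbind(samp, rows)
  tab <- loc_table(all$x_nm, all$y_nm, all$frame, all$intensity,
                   pixel_size_nm = attr(table, "pixel_size_nm"),
                   exposure_ms = attr(table, "exposure_ms"),
                   n_frames = n_frames,
                   extra = data.frame(bead_id = all$bead_id))
  list(table = tab, truth = list(drift = drift, bead_xy = bead_xy))
}

#' Simulate per-oligomer intensity traces under binomial labeling
#'
#' Each oligomer of `n_subunits` subunits carries
#' `k ~ Binomial(n_subunits, dol * occupancy)` labeled subunits. The trace
#' is `baseline + Gaussian noise`; at the second frame all k fluorophores
#' are on simultaneously (each contributing one log-normal peak intensity),
#' and each fluorophore additionally produces blink pulses in the last 100
#' frames (rectangular pulses whose baseline-to-peak height is log-normal).
#'
#' @param n_oligomers number of traces.
#' @param dol degree of labeling (binomial p), in `[0, 1]`.
#' @param occupancy fraction of the nominal degree of labeling actually
#'   achieved (1 = the model's own conditions); used for closure tests.
#' @param n_subunits subunits per oligomer (default 24, the FtnA standard).
#' @param blink a [blink_model()].
#' @param n_frames trace length in frames (default 200).
#' @param baseline baseline level in AD counts.
#' @param noise_sd Gaussian noise sigma in AD counts.
#' @param blink_window number of trailing frames in which blinks occur.
#' @param seed integer RNG seed.
#' @return `trace_set` (named list of numeric vectors) with attributes
#'   `truth` (data.frame of per-trace k) and `n_frames`.
#' @export
sim_oligomer_traces <- function(n_oligomers, dol, occupancy = 1,
                                n_subunits = 24, blink = blink_model(),
                                n_frames = 200, baseline = 100,
                                noise_sd = 10, blink_window = 100,
                                seed = NULL) {
  stopifnot(dol >= 0, dol <= 1, n_subunits >= 1, occupancy >= 0,
            occupancy <= 1)
  if (!is.null(seed)) set.seed(seed)
  ks <- stats::rbinom(n_oligomers, n_subunits, dol * occupancy)
  w0 <- n_frames - blink_window  # first frame (0-based) of the blink window
  traces <- vector("list", n_oligomers)
  for (i in seq_len(n_oligomers)) {
    tr <- baseline + stats::rnorm(n_frames, 0, noise_sd)
    k <- ks[i]
    if (k > 0) {
      tr[2] <- tr[2] + sum(stats::rlnorm(k, blink$logI_mu, blink$logI_sigma))
      nb <- rblinks(k, blink)
      for (j in seq_len(sum(nb))) {
        start <- w0 + sample.int(blink_window, 1) - 1L
        on <- ron_frames(1, blink)
        amp <- stats::rlnorm(1, blink$logI_mu, blink$logI_sigma)
        fr <- start:min(start + on - 1L, n_frames - 1L)
        tr[fr + 1L] <- tr[fr + 1L] + amp
      }
    }
    traces[[i]] <- tr
  }
  names(traces) <- sprintf("olig_%d", seq_len(n_oligomers))
  structure(traces, n_frames = n_frames,
            truth = data.frame(trace = names(traces), k = ks),
            class = "trace_set")
}

#' Simulate 2D Brownian membrane trajectories
#'
#' Per-axis steps are `Normal(0, sqrt(2 * D * dt))`; localization noise is
#' added on top of the true positions.
#'
#' @param n_particles number of particles.
#' @param D_um2_s diffusion coefficient(s) in square micrometres per second,
#'   recycled over particles.
#' @param dt_s frame time in seconds (default 0.04).
#' @param n_frames frames per trajectory.
#' @param sigma_loc_nm localization error sigma (nm).
#' @param extent_nm particles start uniformly in `[0, extent_nm]^2`.
#' @param seed integer RNG seed.
#' @return list with `table` (a [loc_table()] carrying `particle_id`) and
#'   `truth` (per-particle D).
#' @export
sim_membrane_diffusion <- function(n_particles, D_um2_s, dt_s = 0.04,
                                   n_frames = 21, sigma_loc_nm = 20,
                                   extent_nm = 10000, seed = NULL) {
  stopifnot(all(D_um2_s >= 0), dt_s > 0)
  if (!is.null(seed)) set.seed(seed)
  D <- rep_len(D_um2_s, n_particles)
  step_nm <- sqrt(2 * D * dt_s) * 1000  # per-axis step sigma in nm
  out <- vector("list", n_particles)
  for (p in seq_len(n_particles)) {
    x <- cumsum(c(stats::runif(1, 0, extent_nm),
                  stats::rnorm(n_frames - 1, 0, step_nm[p])))
    y <- cumsum(c(stats::runif(1, 0, extent_nm),
                  stats::rnorm(n_frames - 1, 0, step_nm[p])))
    out[[p]] <- data.frame(
      x_nm = x + stats::rnorm(n_frames, 0, sigma_loc_nm),
      y_nm = y + stats::rnorm(n_frames, 0, sigma_loc_nm),
      frame = seq_len(n_frames) - 1L, particle_id = p)
  }
  df <- do.call(rbind, out)
  tab <- loc_table(df$x_nm, df$y_nm, df$frame, exposure_ms = dt_s * 1000,
                   n_frames = n_frames,
                   extra = data.frame(particle_id = df$particle_id))
  list(table = tab, truth = list(D_um2_s = D, dt_s = dt_s,
                                 sigma_loc_nm = sigma_loc_nm))
}
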