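# Single-particle track building, MSD diffusion estimation, and the
# immobile/mobile classification.

#' Link localizations into single-particle trajectories
#'
#' Greedy nearest-neighbor frame-to-frame linking: each localization is
#' attached to the nearest active trajectory whose last position is within
#' `max_disp_nm` and whose last frame is at most `max_gap_frames + 1`
#' frames back. Conflicts are resolved in record-index order (equidistant
#' candidates: lower trajectory index wins); every localization joins at
#' most one trajectory.
#'
#' @param table a [loc_table()].
#' @param max_disp_nm maximal frame-to-frame displacement in nm.
#' @param max_gap_frames maximal number of skipped (dark) frames inside a
#'   trajectory.
#' @return list of trajectories (class `trajectory_set`), each a data.frame
#'   `frame, x_nm, y_nm` ordered by frame.
#' @export
link_tracks <- function(table, max_disp_nm = 500, max_gap_frames = 1) {
  stopifnot(max_disp_nm > 0)
  df <- as.data.frame(table)
  n <- nrow(df)
  trajs <- list()
  if (n == 0) return(structure(trajs, class = "trajectory_set"))
  ord <- order(df$frame, seq_len(n))
  lastx <- lasty <- numeric(0)
  lastf <- integer(0)
  members <- list()
  byf <- split(ord, df$frame[ord])
  for (fgroup in byf) {
    f <- df$frame[fgroup[1]]
    active <- which(lastf >= f - 1L - max_gap_frames & lastf < f)
    taken <- rep(FALSE, length(active))
    for (i in fgroup) {
      tr <- 0L
      if (length(active) > 0) {
        d2 <- (lastx[active] - df$x_nm[i])^2 + (lasty[active] - df$y_nm[i])^2
        d2[taken] <- Inf
        j <- which.min(d2)
        if (d2[j] <= max_disp_nm^2) tr <- j
      }
      if (tr > 0L) {
        t_id <- active[tr]
        taken[tr] <- TRUE
      } else {
        t_id <- length(members) + 1L
        members[[t_id]] <- integer(0)
      }
      members[[t_id]] <- c(members[[t_id]], i)
      lastx[t_id] <- df$x_nm[i]; lasty[t_id] <- df$y_nm[i]
      lastf[t_id] <- f
    }
  }
  trajs <- lapply(members, function(m)
    data.frame(frame = df$frame[m], x_nm = df$x_nm[m], y_nm = df$y_nm[m]))
  structure(trajs, class = "trajectory_set")
}

#' Keep trajectories with a minimal number of steps
#' @param trajectories a `trajectory_set` (or plain list of trajectory
#'   data.frames).
#' @param min_steps minimal step count (points - 1); default 5.
#' @return filtered `trajectory_set`.
#' @export
filter_tracks <- function(trajectories, min_steps = 5) {
  keep <- vapply(trajectories, function(t) nrow(t) - 1L >= min_steps,
                 logical(1))
  structure(trajectories[keep], class = "trajectory_set")
}

#' Apparent diffusion coefficient from MSD analysis
#'
#' Computes the time-averaged mean squared displacement at lags
#' `1..n_fit_points` frames and fits a straight line over lag time. In the
#' default mode the line is constrained through the origin (`MSD = 4 D t`);
#' with `offset = TRUE` an intercept absorbs the constant localization
#' noise floor (`MSD = 4 D t + 4 sigma_loc^2`), which is the mode to use
#' when classifying slow particles measured with appreciable localization
#' error. Negative slopes are clipped to zero.
#'
#' @param traj trajectory data.frame `frame, x_nm, y_nm`.
#' @param dt_s frame time in seconds.
#' @param n_fit_points number of MSD lags fitted (default 4).
#' @param offset fit an intercept (noise floor) as well.
#' @return `D_app` in square micrometres per second.
#' @export
msd_diffusion <- function(traj, dt_s, n_fit_points = 4, offset = FALSE) {
  n <- nrow(traj)
  stopifnot(n - 1 >= n_fit_points)
  x <- traj$x_nm / 1000; y <- traj$y_nm / 1000   # um
  fr <- traj$frame
  msd <- vapply(seq_len(n_fit_points), function(lag) {
    # time-averaged over all point pairs exactly `lag` frames apart
    i <- match(fr + lag, fr)
    ok <- !is.na(i)
    if (!any(ok)) return(NA_real_)
    mean((x[i[ok]] - x[ok])^2 + (y[i[ok]] - y[ok])^2)
  }, numeric(1))
  tau <- seq_len(n_fit_points) * dt_s
  ok <- !is.na(msd)
  slope <- if (offset) {
    stats::coef(stats::lm(msd[ok] ~ tau[ok]))[[2]]
  } else {
    sum(msd[ok] * tau[ok]) / sum(tau[ok]^2)
  }
  max(slope / 4, 0)
}

#' Mobility classification by diffusion-coefficient threshold
#'
#' Particles below the threshold are immobile, at or above it mobile
#' (documented tie rule: exactly at the threshold counts as mobile).
#'
#' @param D_app apparent diffusion coefficient(s), square micrometres per
#'   second, non-negative.
#' @param threshold classification bound (default 0.02).
#' @return character vector `"immobile"` / `"mobile"`.
#' @export
classify_mobility <- function(D_app, threshold = 0.02) {
  stopifnot(all(D_app >= 0))
  ifelse(D_app < threshold, "immobile", "mobile")
}
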