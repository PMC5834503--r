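# Configuration and end-to-end orchestration of the four study-level
# analyses (filament morphometry, cluster quantification, stoichiometry,
# live tracking). A thin command-line front-end over these functions is
# installed at exec/smlmq.

#' Default pipeline configuration
#'
#' Every parameter defaults to the study's printed setting where one
#' exists: camera pixel 129 nm, exposure 70 ms, reconstruction pixel 10 nm,
#' FWHM factor 2.35, width histogram bin 75 nm, cluster-size bin 100 nm,
#' single-fluorophore bin 100 and oligomer bin 1000 AD counts, DBSCAN
#' eps/MinPts 50/40 (clusters) and 40/6 (nanobody counting), FRC threshold
#' 1/7, mobility threshold 0.02 um^2/s, n = 24 subunits, degree of
#' labeling 0.7 +/- 0.15 (nanobody) or 0.95 +/- 0.05 (SNAP).
#'
#' @return nested named list of class `pipeline_config`.
#' @export
pipeline_config <- function() {
  structure(list(
    global = list(pixel_size_nm = 129, exposure_ms = 70,
                  render_pixel_nm = 10, seed = 1),
    drift = list(min_presence = 0.9, gather_radius_nm = 500, window = 10),
    nena = list(search_radius_nm = 500, bin_nm = 2, min_pairs = 1000),
    merge = list(max_gap_frames = 0),
    fire = list(threshold = 1 / 7),
    filaments = list(thickness_px = 15, fwhm_factor = 2.35,
                     width_bin_nm = 75, section_um = 10, per_section = 15,
                     category_breaks = c(0, 75, 150, Inf)),
    clusters = list(eps_nm = 50, min_pts = 40, size_bin_nm = 100),
    nanobody = list(eps_nm = 40, min_pts = 6),
    stoich = list(n_subunits = 24, dol = 0.7, dol_sd = 0.15,
                  single_bin_ad = 100, oligomer_bin_ad = 1000,
                  grid_step_ad = 10, blink_window = 100, min_blinks = 2),
    tracking = list(dt_s = 0.04, max_disp_nm = 500, max_gap_frames = 1,
                    min_steps = 5, n_fit_points = 4, offset = TRUE,
                    threshold = 0.02)),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#' @param path file path.
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(unclass(pipeline_config()),
                           yaml::read_yaml(path))
  cfg$fire$threshold <- eval(parse(text = as.character(cfg$fire$threshold)))
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  # keep full precision for non-terminating defaults such as 1/7
  cfg$fire$threshold <- sprintf("%.17g", cfg$fire$threshold)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

write_run_log <- function(out_dir, name, config, extra = list()) {
  log <- c(list(pipeline = name, timestamp = format(Sys.time()),
                config = unclass(config)), extra)
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
}

resolve_table <- function(x) {
  if (is.character(x)) read_localization_table(x) else x
}

#' Run a study-level analysis pipeline
#'
#' Executes the full module chain of one of the four analyses and writes
#' its CSV/TIFF outputs plus a run log (`run_log.yaml`) recording every
#' parameter into `out_dir`. Inputs are passed as a named list:
#'
#' * `"filaments"`: `table` (loc_table or CSV path), `lines` (polyline
#'   list or CSV path); chain drift -> NeNA -> merge -> render ->
#'   wobble-averaged width/coverage per sampled filament.
#' * `"clusters"`: `table`; chain DBSCAN -> cluster summary.
#' * `"stoich"`: `traces` (trace_set or CSV path), optional calibration
#'   `amplitudes`; chain blink extraction -> calibration -> oligomer
#'   intensities -> completeness.
#' * `"tracking"`: `table`; chain link -> filter -> MSD -> classification.
#'
#' @param name one of `"filaments"`, `"clusters"`, `"stoich"`,
#'   `"tracking"`.
#' @param inputs named list of inputs (see above).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a named list of result objects (also written to
#'   disk).
#' @export
run_pipeline <- function(name = c("filaments", "clusters", "stoich",
                                  "tracking"),
                         inputs, config = pipeline_config(),
                         out_dir = ".") {
  name <- match.arg(name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$global$seed)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline '%s' failed at stage '%s': %s",
                   name, what, conditionMessage(e)), call. = FALSE))
  }
  res <- switch(name,
    filaments = {
      tab <- stage("input", resolve_table(inputs$table))
      lines <- stage("input", if (is.character(inputs$lines))
        read_polylines(inputs$lines) else inputs$lines)
      has_beads <- !is.null(inputs$has_fiducials) && inputs$has_fiducials
      if (has_beads) {
        fid <- stage("drift", detect_fiducials(tab,
                       config$drift$min_presence,
                       config$drift$gather_radius_nm))
        curve <- stage("drift", estimate_drift(fid$tracks,
                         config$drift$window))
        tab <- stage("drift", correct_drift(tab, curve))
        tab <- as_loc_table(as.data.frame(tab)[!fid$is_bead, ], tab)
      }
      nena <- stage("nena", estimate_nena(tab,
                      search_radius_nm = config$nena$search_radius_nm,
                      bin_nm = config$nena$bin_nm,
                      min_pairs = config$nena$min_pairs))
      merged <- stage("merge", merge_blinks(tab, nena$sigma_loc_nm,
                        config$merge$max_gap_frames))
      # render an extent covering data and annotation lines, so straightened
      # strips never fall off the image edge
      allv <- do.call(rbind, lapply(lines, unclass))
      p <- config$global$render_pixel_nm
      pad <- (config$filaments$thickness_px + 2) * p
      ext <- c(min(merged$x_nm, allv[, 1]) - pad,
               max(merged$x_nm, allv[, 1]) + pad,
               min(merged$y_nm, allv[, 2]) - pad,
               max(merged$y_nm, allv[, 2]) + pad)
      img <- stage("render", reconstruct_image(merged, p, extent = ext))
      write_image_tiff(img, file.path(out_dir, "reconstruction.tif"))
      sel <- sample_filaments(lines, config$filaments$section_um,
                              config$filaments$per_section,
                              seed = config$global$seed)
      meas <- stage("measure", lapply(sel, function(l)
        wobble_measure(img, l, config$filaments$thickness_px)))
      per_fil <- data.frame(
        line_id = names(sel),
        width_nm = vapply(meas, `[[`, numeric(1), "width_nm"),
        coverage = vapply(meas, `[[`, numeric(1), "coverage"),
        flagged = vapply(meas, `[[`, logical(1), "flagged"))
      utils::write.csv(per_fil, file.path(out_dir, "filaments.csv"),
                       row.names = FALSE)
      w <- per_fil$width_nm[!is.na(per_fil$width_nm)]
      bw <- config$filaments$width_bin_nm
      br <- seq(0, (max(c(w, bw)) %/% bw + 1) * bw, by = bw)
      h <- graphics::hist(w, breaks = br, plot = FALSE, right = FALSE)
      utils::write.csv(data.frame(bin_lo = utils::head(br, -1),
                                  bin_hi = br[-1], count = h$counts),
                       file.path(out_dir, "width_histogram.csv"),
                       row.names = FALSE)
      list(nena = nena, measurements = per_fil)
    },
    clusters = {
      tab <- stage("input", resolve_table(inputs$table))
      asg <- stage("dbscan", dbscan(tab, config$clusters$eps_nm,
                     config$clusters$min_pts))
      st <- stage("stats", cluster_stats(asg, tab,
                    config$clusters$size_bin_nm))
      utils::write.csv(data.frame(id = seq_len(nrow(tab)),
                                  label = asg$labels, role = asg$role),
                       file.path(out_dir, "assignment.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(cluster = seq_along(st$sizes_nm),
                                  size_nm = st$sizes_nm),
                       file.path(out_dir, "cluster_sizes.csv"),
                       row.names = FALSE)
      st
    },
    stoich = {
      traces <- stage("input", if (is.character(inputs$traces))
        read_traces(inputs$traces) else inputs$traces)
      cfgs <- config$stoich
      single <- if (!is.null(inputs$amplitudes)) {
        fitres <- stage("calibrate", fit_single_fluorophore(
          inputs$amplitudes, cfgs$single_bin_ad))
        log_normal_params(fitres$mu, fitres$sigma)
      } else log_normal_params()
      accepted <- stage("blinks", Filter(function(tr)
        extract_blinks(tr, cfgs$blink_window,
                       cfgs$min_blinks)$accepted, traces))
      ints <- vapply(accepted, oligomer_intensity, numeric(1))
      model <- labeling_model(cfgs$n_subunits, cfgs$dol, cfgs$dol_sd,
                              single)
      comp <- stage("completeness", completeness(ints, model,
                      seed = config$global$seed))
      utils::write.csv(data.frame(trace = names(ints),
                                  intensity_ad = ints),
                       file.path(out_dir, "oligomer_intensities.csv"),
                       row.names = FALSE)
      yaml::write_yaml(list(percent = comp$percent, ci = comp$ci,
                            sensitivity_band = comp$sensitivity_band),
                       file.path(out_dir, "completeness.yaml"))
      comp
    },
    tracking = {
      tab <- stage("input", resolve_table(inputs$table))
      cfgt <- config$tracking
      trajs <- stage("link", link_tracks(tab, cfgt$max_disp_nm,
                       cfgt$max_gap_frames))
      trajs <- filter_tracks(trajs, cfgt$min_steps)
      D <- vapply(trajs, msd_diffusion, numeric(1),
                  dt_s = cfgt$dt_s, n_fit_points = cfgt$n_fit_points,
                  offset = cfgt$offset)
      cls <- classify_mobility(D, cfgt$threshold)
      out <- data.frame(particle_id = seq_along(trajs),
                        n_steps = vapply(trajs, nrow, integer(1)) - 1L,
                        D_um2_s = D, class = cls)
      utils::write.csv(out, file.path(out_dir, "mobility.csv"),
                       row.names = FALSE)
      traj_df <- do.call(rbind, lapply(seq_along(trajs), function(i)
        cbind(particle_id = i, trajs[[i]])))
      utils::write.csv(traj_df, file.path(out_dir, "trajectories.csv"),
                       row.names = FALSE)
      out
    })
  write_run_log(out_dir, name, config)
  invisible(res)
}
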