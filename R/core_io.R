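# All coordinates inside the package are nanometres; px -> nm conversion is
# allowed only at the I/O boundary (read_localization_table with a px dialect).

#' Construct a localization table
#'
#' The central container of the package: one row per single-molecule
#' localization, with coordinates in nanometres. Extra columns (e.g. ground
#' truth annotations from the simulators, particle ids from tracking) are
#' carried along untouched.
#'
#' @param x_nm,y_nm numeric, emitter coordinates in nm (finite).
#' @param frame integer frame index, 0-based, non-negative.
#' @param intensity non-negative emission intensity (photons or AD counts;
#'   the unit is metadata only).
#' @param precision_nm optional per-localization precision in nm.
#' @param pixel_size_nm camera pixel size in nm (default 129).
#' @param exposure_ms frame exposure time in ms (default 70).
#' @param n_frames total number of acquisition frames; defaults to
#'   `max(frame) + 1`.
#' @param extra optional data.frame of additional columns (same row count).
#' @return A data.frame of class `loc_table` with attributes
#'   `pixel_size_nm`, `exposure_ms`, `n_frames`.
#' @export
loc_table <- function(x_nm, y_nm, frame, intensity = NULL,
                      precision_nm = NULL, pixel_size_nm = 129,
                      exposure_ms = 70, n_frames = NULL, extra = NULL) {
  n <- length(x_nm)
  if (is.null(intensity)) intensity <- rep(1, n)
  df <- data.frame(x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                   frame = as.integer(frame),
                   intensity = as.numeric(intensity))
  if (!is.null(precision_nm)) df$precision_nm <- as.numeric(precision_nm)
  if (!is.null(extra) && ncol(as.data.frame(extra)) > 0) {
    extra <- as.data.frame(extra)
    stopifnot(nrow(extra) == n)
    df <- cbind(df, extra)
  }
  if (is.null(n_frames)) n_frames <- if (n > 0) max(df$frame) + 1L else 0L
  attr(df, "pixel_size_nm") <- pixel_size_nm
  attr(df, "exposure_ms") <- exposure_ms
  attr(df, "n_frames") <- as.integer(n_frames)
  class(df) <- c("loc_table", "data.frame")
  validate_loc_table(df)
}

validate_loc_table <- function(tab) {
  if (nrow(tab) > 0) {
    if (!all(is.finite(tab$x_nm)) || !all(is.finite(tab$y_nm)))
      stop("loc_table: non-finite coordinates")
    if (any(tab$frame < 0L)) stop("loc_table: negative frame index")
    if (any(tab$intensity < 0)) stop("loc_table: negative intensity")
    if (any(tab$frame >= attr(tab, "n_frames")))
      stop("loc_table: frame index >= n_frames")
  }
  tab
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations, %d frames, pixel %g nm\n",
              nrow(x), attr(x, "n_frames"), attr(x, "pixel_size_nm")))
  NextMethod()
}

# rebuild a loc_table after subsetting/modifying the underlying data.frame
as_loc_table <- function(df, template) {
  loc_table(df$x_nm, df$y_nm, df$frame, df$intensity,
            precision_nm = df$precision_nm,
            pixel_size_nm = attr(template, "pixel_size_nm"),
            exposure_ms = attr(template, "exposure_ms"),
            n_frames = attr(template, "n_frames"),
            extra = df[setdiff(names(df),
                               c("x_nm", "y_nm", "frame", "intensity",
                                 "precision_nm"))])
}

#' Column-mapping dialect for localization files
#'
#' Describes how a delimited localization file maps onto the canonical
#' columns. The canonical dialect is comma-separated with header
#' `x_nm,y_nm,frame,intensity[,precision_nm]`; foreign exports (e.g. from
#' upstream localizers that write camera-pixel coordinates) are declared by
#' naming their columns and units here.
#'
#' @param x,y,frame,intensity,precision column names in the file; `intensity`
#'   and `precision` may be `NULL` (absent).
#' @param units `"nm"` or `"px"`; `"px"` coordinates are multiplied by
#'   `pixel_size_nm` on read.
#' @param sep field separator.
#' @return list of class `loc_dialect`.
#' @export
loc_dialect <- function(x = "x_nm", y = "y_nm", frame = "frame",
                        intensity = "intensity", precision = "precision_nm",
                        units = c("nm", "px"), sep = ",") {
  units <- match.arg(units)
  structure(list(x = x, y = y, frame = frame, intensity = intensity,
                 precision = precision, units = units, sep = sep),
            class = "loc_dialect")
}

num_col <- function(raw, col, path) {
  v <- raw[[col]]
  if (is.numeric(v)) return(as.numeric(v))
  suppressWarnings(num <- as.numeric(v))
  bad <- which(is.na(num) & !is.na(v) & nzchar(v))
  if (length(bad) > 0)
    stop(sprintf("parse error in '%s', column '%s', row %d: '%s'",
                 path, col, bad[1], v[bad[1]]))
  num
}

#' Read a localization table from delimited text
#'
#' @param path file path.
#' @param dialect a [loc_dialect()] naming at least the x, y and frame
#'   columns and declaring the coordinate unit.
#' @param pixel_size_nm camera pixel size used for `px -> nm` conversion and
#'   stored as metadata.
#' @param exposure_ms,n_frames acquisition metadata.
#' @return a [loc_table()] in nm.
#' @export
read_localization_table <- function(path, dialect = loc_dialect(),
                                    pixel_size_nm = 129, exposure_ms = 70,
                                    n_frames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(dialect$x, dialect$y, dialect$frame))
    if (!col %in% names(raw))
      stop(sprintf("format error in '%s': missing mandatory column '%s'",
                   path, col))
  scale <- if (dialect$units == "px") pixel_size_nm else 1
  x <- num_col(raw, dialect$x, path) * scale
  y <- num_col(raw, dialect$y, path) * scale
  fr <- num_col(raw, dialect$frame, path)
  int <- if (!is.null(dialect$intensity) && dialect$intensity %in% names(raw))
    num_col(raw, dialect$intensity, path) else NULL
  prec <- if (!is.null(dialect$precision) && dialect$precision %in% names(raw))
    num_col(raw, dialect$precision, path) else NULL
  known <- unlist(dialect[c("x", "y", "frame", "intensity", "precision")])
  extra_cols <- setdiff(names(raw), known)
  extra <- if (length(extra_cols) && nrow(raw) > 0) raw[extra_cols] else NULL
  if (length(extra_cols) && nrow(raw) == 0) extra <- NULL
  loc_table(x, y, fr, int, precision_nm = prec,
            pixel_size_nm = pixel_size_nm, exposure_ms = exposure_ms,
            n_frames = n_frames, extra = extra)
}

#' Write a localization table as canonical CSV
#'
#' Writes the canonical dialect `x_nm,y_nm,frame,intensity[,precision_nm]`
#' plus any extra columns. [read_localization_table()] inverts it exactly.
#'
#' @param table a [loc_table()].
#' @param path output path.
#' @export
write_localization_table <- function(table, path) {
  df <- as.data.frame(table)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read intensity traces (long format)
#'
#' Reads a long-format CSV `trace_id,frame,counts` holding the integrated
#' intensity trace of one fixed circular ROI per molecule. All traces must
#' cover the same complete frame range.
#'
#' @param path file path.
#' @return named list of numeric vectors (class `trace_set`), one per trace,
#'   with attribute `n_frames`.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("trace_id", "frame", "counts"))
    if (!col %in% names(raw))
      stop(sprintf("format error in '%s': missing column '%s'", path, col))
  ids <- unique(raw$trace_id)
  lens <- vapply(split(raw$frame, raw$trace_id)[as.character(ids)],
                 length, integer(1))
  n_frames <- max(lens)
  traces <- vector("list", length(ids))
  names(traces) <- as.character(ids)
  for (id in as.character(ids)) {
    sub <- raw[raw$trace_id == id, ]
    if (nrow(sub) != n_frames ||
        !setequal(sub$frame, seq_len(n_frames) - 1L))
      stop(sprintf("format error in '%s': trace '%s' has missing or ragged frames",
                   path, id))
    traces[[id]] <- sub$counts[order(sub$frame)]
  }
  structure(traces, n_frames = n_frames, class = "trace_set")
}

#' Write intensity traces (long format)
#' @param traces named list of equal-length numeric vectors.
#' @param path output path.
#' @export
write_traces <- function(traces, path) {
  lens <- lengths(traces)
  if (length(unique(lens)) > 1) stop("ragged trace lengths")
  ids <- names(traces)
  if (is.null(ids)) ids <- as.character(seq_along(traces))
  df <- data.frame(
    trace_id = rep(ids, each = lens[1]),
    frame = rep(seq_len(lens[1]) - 1L, times = length(traces)),
    counts = unlist(traces, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Polyline in nm
#' @param xy two-column matrix (x_nm, y_nm) of ordered vertices.
#' @param thickness_px line thickness in pixels of the target image.
#' @return matrix of class `polyline`.
#' @export
polyline <- function(xy, thickness_px = 9) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2) stop("polyline needs >= 2 vertices")
  if (any(rowSums((xy[-1, , drop = FALSE] -
                   xy[-nrow(xy), , drop = FALSE])^2) == 0))
    stop("polyline has coincident consecutive vertices")
  colnames(xy) <- c("x_nm", "y_nm")
  structure(xy, thickness_px = thickness_px, class = c("polyline", "matrix"))
}

#' Read polylines from CSV (`line_id,x_nm,y_nm`)
#' @param path file path.
#' @param thickness_px thickness attached to every polyline.
#' @return list of [polyline()] objects.
#' @export
read_polylines <- function(path, thickness_px = 9) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(raw, raw$line_id), function(sub)
    polyline(cbind(sub$x_nm, sub$y_nm), thickness_px))
}

#' Write polylines to CSV
#' @param lines list of polylines.
#' @param path output path.
#' @export
write_polylines <- function(lines, path) {
  ids <- names(lines)
  if (is.null(ids)) ids <- as.character(seq_along(lines))
  df <- do.call(rbind, lapply(seq_along(lines), function(i)
    data.frame(line_id = ids[i], x_nm = lines[[i]][, 1],
               y_nm = lines[[i]][, 2])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Axis-aligned rectangular ROI in nm
#' @param x_min,y_min,x_max,y_max rectangle bounds in nm.
#' @return numeric vector of class `roi`.
#' @export
roi <- function(x_min, y_min, x_max, y_max) {
  if (x_max <= x_min || y_max <= y_min) stop("degenerate ROI")
  structure(c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "roi")
}

#' ROI area in square micrometres
#' @param r an [roi()].
#' @export
roi_area_um2 <- function(r) {
  unname((r["x_max"] - r["x_min"]) * (r["y_max"] - r["y_min"]) / 1e6)
}

in_roi <- function(tab, r) {
  tab$x_nm >= r["x_min"] & tab$x_nm < r["x_max"] &
    tab$y_nm >= r["y_min"] & tab$y_nm < r["y_max"]
}

#' Raster image with physical pixel size
#'
#' Values are stored as a matrix with rows indexing y and columns indexing x.
#' The coordinate convention is 0-based with the origin at the top-left pixel
#' corner and half-open pixels `[k*p, (k+1)*p)`.
#'
#' @param values non-negative numeric matrix.
#' @param pixel_nm pixel edge length in nm (> 0).
#' @param origin_nm `(x, y)` of the corner of pixel (0, 0).
#' @return matrix of class `raster_image`.
#' @export
raster_image <- function(values, pixel_nm, origin_nm = c(0, 0)) {
  stopifnot(pixel_nm > 0)
  structure(as.matrix(values), pixel_nm = pixel_nm,
            origin_nm = origin_nm, class = c("raster_image", "matrix"))
}

#' Write a raster image as 16-bit grayscale TIFF
#'
#' Counts are clamped to `[0, 65535]`; the physical pixel size is recorded
#' in the TIFF resolution tags (pixels per cm).
#' @param img a [raster_image()].
#' @param path output path.
#' @export
write_image_tiff <- function(img, path) {
  v <- pmin(pmax(unclass(img), 0), 65535) / 65535
  tiff::writeTIFF(v, path, bits.per.sample = 16,
                  reduce = TRUE)
  invisible(path)
}

#' Read a 16-bit grayscale TIFF as a raster image
#' @param path file path.
#' @param pixel_nm physical pixel size of the image (nm).
#' @param origin_nm corner of pixel (0,0) in nm.
#' @export
read_image_tiff <- function(path, pixel_nm, origin_nm = c(0, 0)) {
  v <- tiff::readTIFF(path)
  raster_image(round(v * 65535), pixel_nm, origin_nm)
}
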