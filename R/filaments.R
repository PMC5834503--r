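# Width (FWHM), lengthwise coverage and category statistics of filaments on
# reconstructed images.

#' Bilinear sampling of a raster image at physical coordinates
#' @noRd
bilinear_sample <- function(img, x_nm, y_nm) {
  p <- attr(img, "pixel_nm")
  o <- attr(img, "origin_nm")
  m <- unclass(img)
  ny <- nrow(m); nx <- ncol(m)
  # continuous pixel-center coordinates
  px <- (x_nm - o[1]) / p - 0.5
  py <- (y_nm - o[2]) / p - 0.5
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  val <- function(ix, iy) {
    v <- rep(0, length(ix))
    ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
    v[ok] <- m[cbind(iy[ok] + 1L, ix[ok] + 1L)]
    v
  }
  val(x0, y0) * (1 - fx) * (1 - fy) + val(x0 + 1, y0) * fx * (1 - fy) +
    val(x0, y0 + 1) * (1 - fx) * fy + val(x0 + 1, y0 + 1) * fx * fy
}

#' Straighten a polyline selection from an image
#'
#' Samples the image along the polyline at one-pixel arclength steps; at
#' each step, `thickness_px` perpendicular samples (one-pixel spacing,
#' bilinear interpolation) form one column of the output strip. Rows of the
#' strip are transverse offsets (centre row = the centerline), columns run
#' along the filament.
#'
#' @param image a [raster_image()].
#' @param line a [polyline()] (vertices in nm); must lie inside the image.
#' @param thickness_px strip height in pixels (odd values keep the
#'   centerline on the middle row).
#' @return numeric matrix `thickness_px x L` of class `filament_strip` with
#'   attribute `pixel_nm`.
#' @export
straighten <- function(image, line, thickness_px = attr(line, "thickness_px")) {
  p <- attr(image, "pixel_nm")
  o <- attr(image, "origin_nm")
  m <- unclass(image)
  xy <- unclass(line)
  inside <- xy[, 1] >= o[1] & xy[, 1] <= o[1] + ncol(m) * p &
    xy[, 2] >= o[2] & xy[, 2] <= o[2] + nrow(m) * p
  if (!all(inside))
    stop("polyline exits image at vertex ", which(!inside)[1])
  cl <- poly_cumlen(xy)
  L_px <- max(2L, floor(cl[length(cl)] / p) + 1L)
  s <- seq(0, cl[length(cl)], length.out = L_px)
  pp <- poly_point(xy, s)
  nrm <- cbind(-pp$tangent[, 2], pp$tangent[, 1])
  offs <- (seq_len(thickness_px) - (thickness_px + 1) / 2) * p
  strip <- matrix(0, nrow = thickness_px, ncol = L_px)
  for (j in seq_len(thickness_px)) {
    strip[j, ] <- bilinear_sample(image,
                                  pp$pos[, 1] + nrm[, 1] * offs[j],
                                  pp$pos[, 2] + nrm[, 2] * offs[j])
  }
  structure(strip, pixel_nm = p, class = c("filament_strip", "matrix"))
}

#' Gaussian FWHM width of a straightened filament
#'
#' The transverse profile is the mean across the strip length (one value
#' per strip row); it is fitted with a Gaussian plus constant offset by
#' least squares and the width is reported as `2.35 * sigma * pixel_nm`
#' (the FWHM convention, 2.35 truncating 2 sqrt(2 ln 2)).
#'
#' @param strip a `filament_strip` from [straighten()] (height >= 5 px).
#' @param pixel_nm pixel size; defaults to the strip's own.
#' @return list of class `filament_measurement`: `width_nm`, `fit`
#'   (amplitude, center_px, sigma_px, offset), `converged`.
#' @export
profile_width <- function(strip, pixel_nm = attr(strip, "pixel_nm")) {
  if (nrow(strip) < 5) stop("strip height must be >= 5 px")
  y <- rowMeans(strip)
  i <- seq_along(y)
  c0 <- min(y)
  A0 <- max(y) - c0
  if (A0 <= 0) return(failed_measurement())
  w <- pmax(y - c0, 0)
  m0 <- sum(i * w) / sum(w)
  s0 <- sqrt(sum((i - m0)^2 * w) / sum(w))
  s0 <- max(s0, 0.5)
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ A * exp(-(i - m)^2 / (2 * s^2)) + c0,
    data = list(i = i, y = y),
    start = list(A = A0, m = m0, s = s0, c0 = c0),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed_measurement())
  cf <- stats::coef(fit)
  sigma_px <- abs(cf[["s"]])
  structure(list(width_nm = 2.35 * sigma_px * pixel_nm,
                 fit = c(amplitude = unname(cf[["A"]]),
                         center_px = unname(cf[["m"]]),
                         sigma_px = sigma_px,
                         offset = unname(cf[["c0"]])),
                 converged = TRUE),
            class = "filament_measurement")
}

failed_measurement <- function() {
  structure(list(width_nm = NA_real_, fit = NULL, converged = FALSE),
            class = "filament_measurement")
}

#' Lengthwise coverage of a straightened filament
#'
#' Binarizes the strip (`value > binarize_threshold`) and returns the
#' fraction of covered pixels among the middle 3 rows. On unblurred
#' reconstructions the default threshold 0 ("any localization present") is
#' appropriate; for blurred images use a fraction of the profile peak.
#'
#' @param strip a `filament_strip` (height >= 3 px).
#' @param binarize_threshold binarization threshold (strict `>`).
#' @return coverage fraction in `[0, 1]`.
#' @export
lengthwise_coverage <- function(strip, binarize_threshold = 0) {
  h <- nrow(strip)
  if (h < 3) stop("strip height must be >= 3 px")
  mid0 <- (h - 3) %/% 2
  rows <- mid0 + (1:3)
  mean(strip[rows, , drop = FALSE] > binarize_threshold)
}

#' Wobble-averaged filament measurement
#'
#' Measures width and coverage on the original line and on four copies
#' translated by half a pixel in +x, -x, +y and -y, and averages the five
#' measurements — reducing the sensitivity of the result to the exact line
#' placement.
#'
#' @param image a [raster_image()].
#' @param line a [polyline()].
#' @param thickness_px strip height.
#' @param binarize_threshold passed to [lengthwise_coverage()].
#' @return list of class `filament_measurement`: mean `width_nm`, mean
#'   `coverage`, `n_ok` (sub-measurements used), `flagged` (TRUE when any
#'   sub-measurement failed).
#' @export
wobble_measure <- function(image, line,
                           thickness_px = attr(line, "thickness_px"),
                           binarize_threshold = 0) {
  p <- attr(image, "pixel_nm")
  shifts <- list(c(0, 0), c(0.5, 0) * p, c(-0.5, 0) * p,
                 c(0, 0.5) * p, c(0, -0.5) * p)
  widths <- covs <- numeric(0)
  n_fail <- 0L
  for (sh in shifts) {
    res <- tryCatch({
      l2 <- polyline(sweep(unclass(line), 2, -sh), thickness_px)
      strip <- straighten(image, l2, thickness_px)
      list(w = profile_width(strip)$width_nm,
           c = lengthwise_coverage(strip, binarize_threshold))
    }, error = function(e) NULL)
    if (is.null(res) || is.na(res$w)) n_fail <- n_fail + 1L
    else { widths <- c(widths, res$w); covs <- c(covs, res$c) }
  }
  structure(list(width_nm = if (length(widths)) mean(widths) else NA_real_,
                 coverage = if (length(covs)) mean(covs) else NA_real_,
                 n_ok = length(widths), flagged = n_fail > 0L),
            class = "filament_measurement")
}

#' Randomly sample filaments per image section
#'
#' Partitions the field of view into square sections (default 10 x 10 um)
#' and samples up to `per_section` polylines per section without
#' replacement. A polyline belongs to the section containing its arclength
#' midpoint.
#'
#' @param lines list of [polyline()]s.
#' @param section_um section edge length in micrometres.
#' @param per_section maximal polylines sampled per section.
#' @param seed integer RNG seed.
#' @return subset of `lines` (named by original index).
#' @export
sample_filaments <- function(lines, section_um = 10, per_section = 15,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  side <- section_um * 1000
  mids <- t(vapply(lines, function(l) {
    cl <- poly_cumlen(unclass(l))
    as.numeric(poly_point(unclass(l), cl[length(cl)] / 2)$pos)
  }, numeric(2)))
  tile <- paste(floor(mids[, 1] / side), floor(mids[, 2] / side))
  sel <- integer(0)
  for (t in unique(tile)) {
    idx <- which(tile == t)
    if (length(idx) > per_section)
      idx <- sort(sample(idx, per_section))
    sel <- c(sel, idx)
  }
  sel <- sort(sel)
  out <- lines[sel]
  names(out) <- as.character(sel)
  out
}

#' Width categories and chi-square test of homogeneity
#'
#' Bins filament widths into half-open categories (default thin `[0, 75)`,
#' medium `[75, 150)`, thick `[150, Inf)` nm) per condition and tests
#' category-proportion homogeneity across conditions with a standard
#' chi-square test on the contingency table (no continuity correction). The
#' two-category variant is selected via `breaks = c(0, 150, Inf)`.
#'
#' @param widths_by_condition named list (>= 2 conditions) of width vectors
#'   in nm.
#' @param breaks category bounds in nm (half-open intervals).
#' @return list of class `width_category_test`: `counts` (condition x
#'   category matrix), `statistic`, `df`, `p_value`, `warning` (set when an
#'   expected cell is < 1).
#' @export
categorize_and_test <- function(widths_by_condition,
                                breaks = c(0, 75, 150, Inf)) {
  stopifnot(length(widths_by_condition) >= 2)
  labs <- paste0("[", utils::head(breaks, -1), ",",
                 c(utils::head(breaks, -1)[-1], "Inf"), ")")
  counts <- t(vapply(widths_by_condition, function(w) {
    stopifnot(length(w) >= 1)
    table(cut(w, breaks, right = FALSE, labels = labs))
  }, numeric(length(breaks) - 1)))
  keep <- colSums(counts) > 0
  test <- suppressWarnings(stats::chisq.test(counts[, keep, drop = FALSE],
                                             correct = FALSE))
  warn <- any(test$expected < 1)
  structure(list(counts = counts,
                 statistic = unname(test$statistic),
                 df = unname(test$parameter),
                 p_value = unname(test$p.value),
                 warning = if (warn) "expected cell count < 1" else NULL),
            class = "width_category_test")
}
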