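# Density-based clustering (classical DBSCAN) and the cluster summary
# statistics used for nanobody density and autophagosome quantification.

# neighbor lists within eps using grid hashing (cells of side eps, 3x3 scan)
eps_neighbors <- function(x, y, eps) {
  n <- length(x)
  cellx <- floor(x / eps); celly <- floor(y / eps)
  key <- paste(cellx, celly)
  bucket <- split(seq_len(n), key)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- bucket[[paste(cellx[i] + dx, celly[i] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    out[[i]] <- sort(cand[d2 <= eps^2])  # includes i itself
  }
  out
}

#' DBSCAN clustering of 2D localizations
#'
#' Classical density-based spatial clustering of applications with noise.
#' A point is a core point when its eps-neighborhood (inclusive of the
#' point itself) contains at least `min_pts` points; clusters grow from
#' core points in point-index order, so the result is deterministic for a
#' fixed input order.
#'
#' @param points two-column matrix / data.frame of (x, y) in nm, or a
#'   [loc_table()].
#' @param eps_nm neighborhood radius in nm (> 0).
#' @param min_pts minimal neighborhood size of a core point (>= 1).
#' @return list of class `cluster_assignment`: `labels` (integer, 0 =
#'   noise), `role` (`"core"`, `"border"`, `"noise"`), `eps_nm`, `min_pts`.
#' @export
dbscan <- function(points, eps_nm, min_pts) {
  stopifnot(eps_nm > 0, min_pts >= 1)
  pts <- as_points(points)
  n <- nrow(pts)
  if (n == 0)
    return(structure(list(labels = integer(0), role = character(0),
                          eps_nm = eps_nm, min_pts = min_pts),
                     class = "cluster_assignment"))
  nb <- eps_neighbors(pts[, 1], pts[, 2], eps_nm)
  is_core <- lengths(nb) >= min_pts
  labels <- integer(n)          # 0 = unassigned / noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (is_core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  role <- ifelse(is_core, "core", ifelse(labels > 0L, "border", "noise"))
  structure(list(labels = labels, role = role,
                 eps_nm = eps_nm, min_pts = min_pts),
            class = "cluster_assignment")
}

as_points <- function(points) {
  if (inherits(points, "loc_table") ||
      (is.data.frame(points) && all(c("x_nm", "y_nm") %in% names(points))))
    cbind(points$x_nm, points$y_nm)
  else as.matrix(points)
}

#' Cluster summary statistics
#'
#' Per-cluster size is the mean Euclidean distance of member localizations
#' from the cluster's center of mass. The degree of clustering is the
#' fraction of localizations assigned to any cluster (core + border).
#' Cluster sizes are additionally histogrammed (default 100-nm bins).
#'
#' @param assignment a `cluster_assignment` from [dbscan()].
#' @param points the clustered points (same order).
#' @param bin_nm histogram bin width for cluster sizes.
#' @return list of class `cluster_summary`: `n_clusters`, `sizes_nm`,
#'   `degree_of_clustering`, `histogram` (data.frame `bin_lo, bin_hi,
#'   count`).
#' @export
cluster_stats <- function(assignment, points, bin_nm = 100) {
  pts <- as_points(points)
  labels <- assignment$labels
  ids <- sort(unique(labels[labels > 0L]))
  sizes <- vapply(ids, function(cl) {
    mem <- labels == cl
    com <- colMeans(pts[mem, , drop = FALSE])
    mean(sqrt((pts[mem, 1] - com[1])^2 + (pts[mem, 2] - com[2])^2))
  }, numeric(1))
  degree <- if (length(labels)) mean(labels > 0L) else 0
  if (length(sizes)) {
    br <- seq(0, (max(sizes) %/% bin_nm + 1) * bin_nm, by = bin_nm)
    h <- graphics::hist(sizes, breaks = br, plot = FALSE, right = FALSE)
    hd <- data.frame(bin_lo = utils::head(br, -1), bin_hi = br[-1],
                     count = h$counts)
  } else hd <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                          count = integer(0))
  structure(list(n_clusters = length(ids), sizes_nm = sizes,
                 degree_of_clustering = degree, histogram = hd),
            class = "cluster_summary")
}

#' Nanobody density within an ROI
#'
#' Restricts to the ROI, identifies single nanobodies as DBSCAN clusters of
#' their repeated blink localizations, and reports clusters per square
#' micrometre.
#'
#' @param table a [loc_table()].
#' @param roi an [roi()].
#' @param eps_nm,min_pts DBSCAN parameters (defaults 40 nm / 6).
#' @param merge_radius_nm optional [merge_blinks()] pre-step radius
#'   (default off).
#' @return density in clusters per square micrometre.
#' @export
nanobody_density <- function(table, roi, eps_nm = 40, min_pts = 6,
                             merge_radius_nm = NULL) {
  area <- roi_area_um2(roi)
  if (area <= 0) stop("zero-area ROI")
  df <- as.data.frame(table)[in_roi(table, roi), ]
  if (!is.null(merge_radius_nm)) {
    tab <- loc_table(df$x_nm, df$y_nm, df$frame, df$intensity,
                     n_frames = attr(table, "n_frames"))
    df <- as.data.frame(merge_blinks(tab, merge_radius_nm))
  }
  if (nrow(df) == 0) return(0)
  asg <- dbscan(df, eps_nm, min_pts)
  max(asg$labels) / area
}

#' Localization density per square micrometre
#' @param table a [loc_table()].
#' @param area_um2 reference area (e.g. a cell mask) in square micrometres.
#' @export
localization_density <- function(table, area_um2) {
  stopifnot(area_um2 > 0)
  nrow(table) / area_um2
}
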