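# Independent oracles used across the suite. These deliberately use the
# dumbest correct algorithm (full distance matrices, grid search,
# union-find, Monte Carlo) so they share no code with the implementation.

# classical DBSCAN from the full O(n^2) distance matrix
brute_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(pts))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    stack <- i
    while (length(stack)) {
      j <- stack[1]; stack <- stack[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) stack <- c(stack, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

# noise-invariant comparison of two clusterings (same partition up to label
# permutation, identical noise set)
same_clustering <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ok <- a != 0L
  ta <- table(paste(a[ok], b[ok]))
  length(unique(a[ok])) == length(ta) &&
    length(unique(b[ok])) == length(ta)
}

# number of blink chains by union-find over the pair graph
union_find_chains <- function(df, radius, max_gap = 0) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    dfr <- abs(df$frame[i] - df$frame[j])
    if (dfr >= 1 && dfr <= max_gap + 1 &&
        (df$x_nm[i] - df$x_nm[j])^2 + (df$y_nm[i] - df$y_nm[j])^2 <= radius^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# dense grid-search Gaussian + offset fit over (center, sigma); amplitude
# and offset solved by linear least squares at each grid node
grid_gaussian_fit <- function(y) {
  i <- seq_along(y)
  best <- list(rss = Inf)
  for (m in seq(1, length(y), by = 0.05)) {
    for (s in seq(0.5, length(y) / 2, by = 0.02)) {
      g <- exp(-(i - m)^2 / (2 * s^2))
      X <- cbind(g, 1)
      cf <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                     error = function(e) NULL)
      if (is.null(cf)) next
      rss <- sum((y - X %*% cf)^2)
      if (rss < best$rss)
        best <- list(rss = rss, m = m, s = s, A = cf[1], c0 = cf[2])
    }
  }
  best
}

# straight horizontal filament table used by several tests
make_filament <- function(width_nm = 75, coverage = 1, sigma_loc = 10,
                          density = 400, n_frames = 4000, seed = 1,
                          y = 2000) {
  line <- polyline(rbind(c(500, y), c(9500, y)))
  sim <- sim_filament_field(list(line), width_nm = width_nm,
                            coverage = coverage, label_density = density,
                            sigma_loc_nm = sigma_loc, n_frames = n_frames,
                            seed = seed)
  sim$line <- line
  sim
}
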