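test_that("straightening a horizontal line reproduces the image rows", {
  m <- matrix(runif(20 * 40), nrow = 20, ncol = 40)
  img <- raster_image(m, 10)
  # line along the centre of row 10 (y = 95 nm), sampled at pixel centres
  line <- polyline(rbind(c(5, 95), c(395, 95)))
  strip <- straighten(img, line, 5)
  expect_equal(dim(strip), c(5, 40))
  expect_equal(strip[3, ], m[10, ], tolerance = 1e-9)
  expect_equal(strip[1, ], m[8, ], tolerance = 1e-9)
})

test_that("straightening a curved line over a constant image is constant", {
  img <- raster_image(matrix(7, 50, 50), 10)
  th <- seq(0, pi / 2, length.out = 30)
  arc <- polyline(cbind(250 + 150 * cos(th), 250 + 150 * sin(th)))
  strip <- straighten(img, arc, 5)
  expect_equal(unique(round(as.numeric(strip), 9)), 7)
  out <- polyline(rbind(c(100, 100), c(2000, 100)))
  expect_error(straighten(img, out, 5), "vertex 2")
})

test_that("a noiseless Gaussian profile returns width 2.35 * sigma * pixel", {
  i <- 1:21
  prof <- 50 * exp(-(i - 11)^2 / (2 * 2^2)) + 5
  strip <- structure(matrix(rep(prof, 10), nrow = 21),
                     pixel_nm = 10, class = c("filament_strip", "matrix"))
  w <- profile_width(strip)
  expect_equal(w$width_nm, 2.35 * 2 * 10, tolerance = 1e-6)
  expect_equal(w$fit[["offset"]], 5, tolerance = 1e-6)
  expect_error(profile_width(strip[1:4, , drop = FALSE]), ">= 5")
})

test_that("Gaussian profile fits agree with a dense grid-search oracle", {
  set.seed(40)
  for (rep in 1:5) {
    i <- 1:25
    truth <- c(A = runif(1, 20, 80), m = runif(1, 10, 16),
               s = runif(1, 1.5, 4), c0 = runif(1, 0, 10))
    prof <- truth["A"] * exp(-(i - truth["m"])^2 / (2 * truth["s"]^2)) +
      truth["c0"] + rnorm(25, 0, 1)
    strip <- structure(matrix(prof, ncol = 1), pixel_nm = 10,
                       class = c("filament_strip", "matrix"))
    w <- profile_width(strip)
    oracle <- grid_gaussian_fit(prof)
    expect_lt(abs(w$fit[["sigma_px"]] - oracle$s) / oracle$s, 0.01)
  }
})

test_that("coverage counts the middle three rows of the binarized strip", {
  full <- structure(matrix(1, 9, 50), pixel_nm = 10,
                    class = c("filament_strip", "matrix"))
  expect_equal(lengthwise_coverage(full), 1)
  alt <- full
  alt[, seq(1, 50, by = 2)] <- 0
  expect_equal(lengthwise_coverage(alt), 0.5)
  # rows outside the middle three are ignored
  edge <- full
  edge[c(1:3, 7:9), ] <- 0
  expect_equal(lengthwise_coverage(edge), 1)
})

test_that("coverage measured on rendered filaments recovers the truth", {
  for (cov in c(0.5, 0.8, 1.0)) {
    sim <- make_filament(coverage = cov, density = 600, sigma_loc = 10,
                         n_frames = 4000, seed = 41 + round(10 * cov))
    img <- reconstruct_image(sim$table, 10, extent = c(0, 1e4, 0, 4000))
    meas <- lengthwise_coverage(straighten(img, sim$line, 9))
    expect_lt(abs(meas - cov), 0.05)
  }
})

test_that("wobble averaging is the mean of the five sub-measurements", {
  sim <- make_filament(seed = 42, density = 300, n_frames = 2000)
  img <- reconstruct_image(sim$table, 10, blur_sigma_nm = 10)
  p <- attr(img, "pixel_nm")
  wm <- wobble_measure(img, sim$line, 15)
  shifts <- list(c(0, 0), c(0.5, 0) * p, c(-0.5, 0) * p,
                 c(0, 0.5) * p, c(0, -0.5) * p)
  manual <- vapply(shifts, function(sh) {
    l2 <- polyline(sweep(unclass(sim$line), 2, -sh), 15)
    profile_width(straighten(img, l2, 15))$width_nm
  }, numeric(1))
  expect_equal(wm$width_nm, mean(manual), tolerance = 1e-9)
  expect_false(wm$flagged)
  # image constant along the line: wobble stays at the single measurement
  # (up to half-pixel interpolation of the smooth transverse profile)
  flat <- raster_image(matrix(rep(dnorm(1:21, 11, 3), 30), nrow = 21), 10)
  line <- polyline(rbind(c(20, 105), c(280, 105)))
  wflat <- wobble_measure(flat, line, 15)
  single <- profile_width(straighten(flat, line, 15))$width_nm
  expect_lt(abs(wflat$width_nm - single) / single, 0.02)
})

test_that("filament sampling respects sections, caps and the midpoint rule", {
  mk <- function(x, y) polyline(rbind(c(x, y), c(x + 500, y)))
  one_tile <- lapply(seq_len(15), function(i) mk(1000 + 100 * i, 2000))
  expect_length(sample_filaments(one_tile, seed = 1), 15)
  many <- lapply(seq_len(40), function(i) mk(500 + 200 * (i %% 20), 3000))
  s1 <- sample_filaments(many, seed = 2)
  s2 <- sample_filaments(many, seed = 2)
  expect_length(s1, 15)
  expect_identical(names(s1), names(s2))
  # line spanning two tiles is assigned by its arclength midpoint
  spanning <- list(polyline(rbind(c(9000, 500), c(12000, 500))),  # mid 10500
                   polyline(rbind(c(8000, 500), c(11000, 500))))  # mid 9500
  crowded <- c(spanning, lapply(seq_len(20), function(i)
    mk(200 + 400 * (i %% 20), 800)))
  sel <- sample_filaments(crowded, per_section = 20, seed = 3)
  expect_true("1" %in% names(sel))   # alone in tile (1, 0), always kept
})

test_that("width categories and the chi-square homogeneity test are exact", {
  same <- list(a = c(rep(50, 10), rep(100, 10)),
               b = c(rep(60, 30), rep(120, 30)))
  t0 <- categorize_and_test(same)
  expect_equal(t0$statistic, 0)
  # hand-computed chi-square for [[50,50,0],[0,50,50]]
  w1 <- c(rep(30, 50), rep(100, 50))
  w2 <- c(rep(100, 50), rep(200, 50))
  t1 <- categorize_and_test(list(a = w1, b = w2))
  expect_equal(unname(t1$counts), rbind(c(50, 50, 0), c(0, 50, 50)))
  # expected cells all 25; chi2 = sum (o-e)^2/e = 4 * 25 = 100
  expect_equal(t1$statistic, 100)
  expect_equal(t1$df, 2)
  # boundary: exactly 75 nm is medium (half-open intervals)
  tb <- categorize_and_test(list(a = c(75, 75), b = c(80, 80)))
  expect_equal(unname(tb$counts[, 2]), c(2, 2))
  # two-category variant
  t2 <- categorize_and_test(list(a = w1, b = w2),
                            breaks = c(0, 150, Inf))
  expect_equal(t2$df, 1)
})
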