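test_that("degenerate filament parameters put localizations on the centerline", {
  line <- polyline(rbind(c(0, 500), c(5000, 500)))
  sim <- sim_filament_field(list(line), width_nm = 0, coverage = 1,
                            label_density = 20, sigma_loc_nm = 0,
                            n_frames = 100, seed = 1)
  expect_gt(nrow(sim$table), 0)
  expect_true(all(abs(sim$table$y_nm - 500) < 1e-9))
  expect_error(sim_filament_field(list(line), coverage = 1.2), "coverage")
})

test_that("filament transverse spread follows the Gaussian convolution law", {
  sim <- make_filament(width_nm = 75, sigma_loc = 10, density = 400,
                       seed = 2)
  # transverse positions ~ Normal(0, sqrt((w/2.35)^2 + sigma^2))
  expected_fwhm <- sqrt(75^2 + (2.35 * 10)^2)
  measured_fwhm <- 2.35 * sd(sim$table$y_nm)
  expect_lt(abs(measured_fwhm - expected_fwhm) / expected_fwhm, 0.03)
})

test_that("generators are deterministic under a fixed seed", {
  line <- polyline(rbind(c(0, 500), c(5000, 500)))
  a <- sim_filament_field(list(line), seed = 7)
  b <- sim_filament_field(list(line), seed = 7)
  expect_identical(a$table, b$table)
  m1 <- sim_microtubule(1000, seed = 3)
  m2 <- sim_microtubule(1000, seed = 3)
  expect_identical(m1, m2)
  t1 <- sim_oligomer_traces(10, 0.7, seed = 5)
  t2 <- sim_oligomer_traces(10, 0.7, seed = 5)
  expect_identical(unclass(t1), unclass(t2))
})

test_that("every filament localization carries a ground-truth label", {
  sim <- make_filament(seed = 3, density = 50, n_frames = 500)
  expect_true(all(sim$table$emitter_id %in%
                    seq_len(nrow(sim$truth$emitters))))
  clu <- sim_cluster_field(roi(0, 0, 5000, 5000), clusters = 3,
                           background_density = 1, seed = 4)
  expect_false(anyNA(clu$table$cluster_id))
})

test_that("microtubule geometry limits behave analytically", {
  # no displacement, no noise: transverse positions span the 25-nm circle
  mt <- sim_microtubule(20000, probe_displacement_nm = 0, sigma_loc_nm = 0,
                        y0_nm = 0, seed = 5)
  expect_lte(max(abs(mt$y_nm)), 12.5 + 1e-9)
  # projection of a uniform circle: sd = r / sqrt(2)
  expect_lt(abs(sd(mt$y_nm) - 12.5 / sqrt(2)), 0.2)
  # pure-precision limit: fitted FWHM = 2.35 * sigma_loc (fine bins so
  # pixelation adds < 1% to the fitted sigma)
  mt2 <- sim_microtubule(50000, diameter_nm = 0, probe_displacement_nm = 0,
                         sigma_loc_nm = 10, y0_nm = 200, seed = 6)
  h <- hist(mt2$y_nm, breaks = seq(140, 260, by = 5), plot = FALSE)
  strip <- structure(matrix(h$counts, ncol = 1), pixel_nm = 5,
                     class = c("filament_strip", "matrix"))
  expect_lt(abs(profile_width(strip)$width_nm - 23.5), 1)
  expect_warning(sim_microtubule(50, seed = 1), "unstable")
})

test_that("cluster field matches its Poisson background and truth labels", {
  r <- roi(0, 0, 15000, 15000)
  sim <- sim_cluster_field(r, clusters = 0, background_density = 4,
                           seed = 8)
  n <- nrow(sim$table)
  expect_lt(abs(n - 900), 4 * sqrt(900))   # Poisson mean 225 * 4
  # Gaussian members: ~50 points land within eps of a member only when the
  # cluster holds ~100 draws at sigma 30 nm, so that is the regime in which
  # DBSCAN(50, 40) must recover every seeded cluster
  sim2 <- sim_cluster_field(r, clusters = 10, locs_per_cluster = 100,
                            cluster_radius_nm = 30,
                            background_density = 0, seed = 9)
  asg <- dbscan(sim2$table, eps_nm = 50, min_pts = 40)
  expect_equal(max(asg$labels), 10)
})

test_that("fiducial beads trace the imposed drift", {
  tab <- loc_table(runif(200, 0, 5000), runif(200, 0, 5000),
                   sample(0:499, 200, replace = TRUE), n_frames = 500)
  still <- sim_fiducials_with_drift(tab, n_beads = 2,
                                    drift = make_drift(500, "none"),
                                    sigma_loc_nm = 2, seed = 10)
  bead1 <- subset(as.data.frame(still$table), bead_id == 1)
  expect_lt(sd(bead1$x_nm), 3 * 2)
  lin <- sim_fiducials_with_drift(tab, n_beads = 1,
                                  drift = make_drift(500, "linear",
                                                     v_nm_per_frame = c(0.2, 0)),
                                  sigma_loc_nm = 0, seed = 11)
  b <- subset(as.data.frame(lin$table), bead_id == 1)
  expect_equal(b$x_nm - b$x_nm[b$frame == 0], 0.2 * b$frame,
               tolerance = 1e-9)
  # beads present in >= 99% of frames
  expect_gte(length(unique(b$frame)), 0.99 * 500)
})

test_that("oligomer traces obey their deterministic limits", {
  bm <- blink_model(logI_sigma = 1e-9)
  tr <- sim_oligomer_traces(5, dol = 1, blink = bm, noise_sd = 1e-12,
                            baseline = 100, seed = 12)
  expect_equal(tr[[1]][2], 100 + 24 * exp(5.68), tolerance = 1e-4)
  tr0 <- sim_oligomer_traces(5, dol = 0, baseline = 100, noise_sd = 10,
                             seed = 13)
  expect_lt(max(abs(tr0[[2]] - 100)), 6 * 10)
  # log-normal mean identity at dol = 0.7
  trm <- sim_oligomer_traces(2000, dol = 0.7, noise_sd = 5, seed = 14)
  m <- mean(vapply(trm, function(t) t[2], numeric(1))) - 100
  expected <- 24 * 0.7 * exp(5.68 + 0.4^2 / 2)
  se <- sd(vapply(trm, function(t) t[2], numeric(1))) / sqrt(2000)
  expect_lt(abs(m - expected), 3 * se)
})

test_that("membrane diffusion steps follow the Brownian identity", {
  sim0 <- sim_membrane_diffusion(3, 0, sigma_loc_nm = 0, n_frames = 10,
                                 seed = 15)
  expect_true(all(tapply(sim0$table$x_nm, sim0$table$particle_id, sd) == 0))
  sim <- sim_membrane_diffusion(200, 0.1, dt_s = 0.04, sigma_loc_nm = 0,
                                n_frames = 21, seed = 16)
  df <- as.data.frame(sim$table)
  steps <- do.call(rbind, lapply(split(df, df$particle_id), function(p) {
    cbind(diff(p$x_nm), diff(p$y_nm)) / 1000
  }))
  msd1 <- mean(steps[, 1]^2 + steps[, 2]^2)
  expect_lt(abs(msd1 - 4 * 0.1 * 0.04) / (4 * 0.1 * 0.04), 0.05)
})
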