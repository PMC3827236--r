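# Gaussian dispersal kernels, sticky coastal boundary, recruitment metrics

test_that("gaussian_density is the normal density in displacement", {
  expect_equal(gaussian_density(0, 0, 1), 0.3989423, tolerance = 1e-6)
  expect_equal(gaussian_density(-3, -3, 7), 1 / (sqrt(2 * pi) * 7))
  grid <- seq(-200, 200, by = 0.1)
  expect_equal(sum(gaussian_density(grid, -12, 9)) * 0.1, 1, tolerance = 1e-6)
  expect_error(gaussian_density(0, 0, 0), "LS must be > 0")
})

test_that("kernels conserve mass and carry no inland cells", {
  set.seed(31)
  for (i in 1:25) {
    ev <- list(LA_x = runif(1, -80, 80), LS_x = runif(1, 1, 50),
               LA_y = runif(1, -80, 80), LS_y = runif(1, 1, 50))
    k <- event_kernel(ev)
    expect_equal(sum(k$prob), 1, tolerance = 1e-9)
    expect_true(all(k$prob >= 0))
    expect_true(all(k$y >= 0))          # no cells south of the coastal row
    expect_equal(k$y[1], 0)             # coastal row centred on the shoreline
  }
})

test_that("an unbiased symmetric kernel splits mass at the shoreline as expected", {
  k <- event_kernel(list(LA_x = 0, LS_x = 10, LA_y = 0, LS_y = 10))
  # symmetric in x about the emission point
  i0 <- which(k$x == 0)
  coastal <- k$prob[, 1]
  expect_equal(coastal[i0 - 5], coastal[i0 + 5], tolerance = 1e-12)
  expect_equal(peak_recruitment(k)$offset_km, 0)
  # coastal-row mass: all mass below the row's upper edge at dy/2
  expect_equal(recruitment_success(k), pnorm(2.5 / 10), tolerance = 1e-12)
})

test_that("recruitment success halves for an unbiased shoreline as dy -> 0", {
  k <- event_kernel(list(LA_x = 0, LS_x = 10, LA_y = 0, LS_y = 10),
                    kernel_grid_spec(dy = 0.01))
  expect_equal(recruitment_success(k), 0.5, tolerance = 1e-3)
})

test_that("high-upwelling season-mean scales give strong westward coastal recruitment", {
  k <- event_kernel(scales_2009)
  expect_equal(recruitment_success(k),
               pnorm((2.5 + 67.79) / 46.645), tolerance = 1e-9)
  pk <- peak_recruitment(k)
  expect_equal(pk$offset_km, -56)
  # closed-form oracle: x-cell mass at the mode times coastal mass / area
  oracle <- (pnorm(-55.5, -56.12, 42.79) - pnorm(-56.5, -56.12, 42.79)) *
    pnorm((2.5 + 67.79) / 46.645) / 5
  expect_equal(pk$density_per_km2, oracle, tolerance = 1e-9)
  # the coastal peak is also the global maximum
  expect_equal(max_density(k, "anywhere")$density_per_km2,
               pk$density_per_km2)
})

test_that("low-upwelling season-mean scales give weak eastward recruitment and an offshore mode", {
  k <- event_kernel(scales_2011)
  expect_equal(recruitment_success(k),
               pnorm((2.5 - 31.61) / 28.478), tolerance = 1e-9)
  pk <- peak_recruitment(k)
  expect_equal(pk$offset_km, 13)
  off <- max_density(k, "offshore")
  expect_equal(off$x_km, 13)
  expect_equal(off$y_km, 30)
  # closed-form 2-D mode density (within the discretisation of the cell)
  expect_equal(off$density_per_km2, 1 / (2 * pi * 24.294 * 28.478),
               tolerance = 0.005)
})

test_that("a zero-spread event collapses to a point mass in the containing cell", {
  k <- event_kernel(list(LA_x = -7.3, LS_x = 0, LA_y = -20, LS_y = 0))
  expect_equal(sum(k$prob), 1)
  expect_equal(recruitment_success(k), 1)    # landward advection all settles
  expect_equal(peak_recruitment(k)$offset_km, -7)
})

test_that("ensemble of one or identical events equals the single-event kernel", {
  ev <- data.frame(LA_x = -20, LS_x = 15, LA_y = -10, LS_y = 12,
                   valid = TRUE)
  k1 <- event_kernel(ev)
  ke <- ensemble_kernel(ev)
  expect_equal(ke$prob, k1$prob, tolerance = 1e-12)
  ke2 <- ensemble_kernel(rbind(ev, ev))
  expect_equal(ke2$prob, k1$prob, tolerance = 1e-12)
  expect_identical(ke2$n_events, 2L)
  expect_error(ensemble_kernel(ev[0, ]), "at least one valid event")
})

test_that("ensemble kernel converges to the mean-parameter kernel as event spread shrinks", {
  set.seed(33)
  n <- 60
  events <- data.frame(LA_x = rnorm(n, -56.12, 2), LS_x = rnorm(n, 42.79, 0.5),
                       LA_y = rnorm(n, -67.79, 2), LS_y = rnorm(n, 46.645, 0.5),
                       valid = TRUE)
  ke <- ensemble_kernel(events, kernel_grid_spec(x_range = c(-500, 400)))
  km <- event_kernel(scales_2009, kernel_grid_spec(x_range = c(-500, 400)))
  expect_equal(sum(ke$prob), 1, tolerance = 1e-9)
  expect_lt(abs(recruitment_success(ke) - recruitment_success(km)), 0.03)
})

test_that("recruitment success decreases monotonically with offshore advection", {
  la_y <- seq(-60, 60, by = 10)
  rec <- vapply(la_y, function(l)
    recruitment_success(event_kernel(list(LA_x = 0, LS_x = 20,
                                          LA_y = l, LS_y = 25))),
    numeric(1))
  expect_true(all(diff(rec) < 0))
})

test_that("coastal mass is independent of the alongshore cell width", {
  ev <- list(LA_x = -30, LS_x = 25, LA_y = -15, LS_y = 20)
  r1 <- recruitment_success(event_kernel(ev, kernel_grid_spec(dx = 1)))
  r2 <- recruitment_success(event_kernel(ev, kernel_grid_spec(dx = 0.5)))
  expect_lt(abs(r1 - r2), 1e-9)
})

test_that("the particle oracle reproduces the analytic kernel within Monte-Carlo error", {
  ev <- list(LA_x = -10, LS_x = 12, LA_y = -5, LS_y = 9)
  k <- event_kernel(ev)
  po <- particle_oracle(ev, n_particles = 1e6, seed = 11, grid = k)
  expect_lt(tv_distance(k, po), 0.01)
  # reproducible histogram
  po2 <- particle_oracle(ev, n_particles = 1e6, seed = 11, grid = k)
  expect_identical(po$prob, po2$prob)

  # widely dispersed events: distance matches the multinomial expectation
  for (sc in list(scales_2009, scales_2011)) {
    kk <- event_kernel(sc)
    pp <- particle_oracle(sc, n_particles = 1e6, seed = 13, grid = kk)
    expect_lt(tv_distance(kk, pp), 1.5 * tv_expected(kk, 1e6))
  }
})

test_that("a zero-spread oracle puts every particle in the advection cell", {
  ev <- list(LA_x = 4, LS_x = 0, LA_y = -12, LS_y = 0)
  po <- particle_oracle(ev, n_particles = 1000, seed = 1)
  expect_equal(sum(po$prob), 1)
  expect_equal(peak_recruitment(po)$offset_km, 4)
  expect_equal(recruitment_success(po), 1)
})

test_that("kernel export is tidy and density uses the cell area", {
  k <- event_kernel(list(LA_x = 0, LS_x = 5, LA_y = 0, LS_y = 5))
  df <- as.data.frame(k)
  expect_named(df, c("x_km", "y_km", "prob", "density_per_km2"))
  expect_equal(df$density_per_km2, df$prob / 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_kernel_csv(k, path)
  expect_equal(nrow(read.csv(path)), length(k$x) * length(k$y))
})
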