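test_that("bridge mean runs straight between the endpoints", {
  b <- stm_bridge(c(0, 0), c(1000, 0), start_day = 1, total_time = 10,
                  diffusion = 100)
  expect_equal(bridge_mean(b, 0)[1, ], c(0, 0))
  expect_equal(bridge_mean(b, 10)[1, ], c(1000, 0))
  expect_equal(bridge_mean(b, 5)[1, ], c(500, 0))
  expect_error(stm_bridge(c(0, 0), c(1, 1), 1, total_time = 0, diffusion = 1),
               "positive")
})

test_that("bridge variance vanishes at both endpoints and peaks at T/2", {
  b <- stm_bridge(c(0, 0), c(1000, 0), start_day = 1, total_time = 10,
                  diffusion = 100)
  expect_equal(bridge_variance(b, 0), 0)
  expect_equal(bridge_variance(b, 10), 0)
  expect_equal(bridge_variance(b, 5), 250)  # 5 * 5 / 10 * 100
  tt <- seq(0, 10, by = 0.1)
  expect_equal(tt[which.max(bridge_variance(b, tt))], 5)
  expect_equal(bridge_variance(b, 0, floor = 1e6), 1e6)
  expect_error(stm_bridge(c(0, 0), c(1, 1), 1, 10, diffusion = -1),
               "nonnegative")
})

test_that("temporal mode densities evaluate the (wrapped) normal laws", {
  m <- toy_group_stm()
  # single-component peak value 1 / (sigma sqrt(2 pi))
  expect_equal(temporal_mode_density(m, "M1", 10), 1 / (3 * sqrt(2 * pi)),
               tolerance = 1e-6)
  # equal-weight mixture is symmetric in its two occurrences
  expect_equal(temporal_mode_density(m, "M3", 60),
               temporal_mode_density(m, "M3", 300), tolerance = 1e-9)
  expect_true(all(temporal_mode_density(m, "M2", 1:365) >= 0))
  # wrapping: a mean fitted on the unwrapped scale peaks at its wrapped day
  tc <- stm_temporal(-20, 25)
  m2 <- m; m2$temporal$M1 <- tc
  dens <- temporal_mode_density(m2, "M1", 1:365)
  expect_equal(which.max(dens), 345L)
})

test_that("mode probabilities form a distribution over modes each day", {
  for (g in 1:3) {
    model <- test_fit(g)$model
    p <- vapply(1:365, function(t) sum(mode_probabilities(model, t)),
                numeric(1))
    expect_true(all(abs(p - 1) < 1e-9))
  }
  # separation limit: far from every other mode, one mode dominates
  m <- toy_group_stm()
  expect_gt(mode_probabilities(m, 10)[["M1"]], 0.99)
  # late dry season: several modes plausible at once for group 3
  m3 <- test_fit(3)$model
  p290 <- mode_probabilities(m3, 290)
  expect_true(all(p290[c("M2", "M3", "M4")] > 1e-6))
})

test_that("spatial densities match their closed forms", {
  s <- 3000
  m <- toy_group_stm(sd1 = s)
  expect_equal(spatial_density(m, "M1", 10, matrix(c(0, 0), 1)),
               1 / (2 * pi * s^2), tolerance = 1e-9)
  # bridge density is unimodal about the bridge mean at any day
  mid <- bridge_mean(m$spatial$M3[[1]], 75)[1, ]
  d0 <- spatial_density(m, "M3", 85, matrix(mid, 1))
  off <- sweep(matrix(stats::rnorm(40, 0, 3e4), 20, 2), 2, mid, "+")
  expect_true(all(spatial_density(m, "M3", 85, off) <= d0))
})

test_that("the group-3 dry-season mixture integrates to one", {
  model <- test_fit(3)$model
  sp <- model$spatial$M2
  mus <- vapply(sp$components, `[[`, numeric(2), "mu")
  sds <- sqrt(vapply(sp$components, function(cm) max(diag(cm$Sigma)),
                     numeric(1)))
  xs <- seq(min(mus[1, ]) - 8 * max(sds), max(mus[1, ]) + 8 * max(sds), by = 500)
  ys <- seq(min(mus[2, ]) - 8 * max(sds), max(mus[2, ]) + 8 * max(sds), by = 500)
  grid <- cbind(rep(xs, length(ys)), rep(ys, each = length(xs)))
  mass <- sum(spatial_density(model, "M2", 150, grid)) * 500^2
  expect_equal(mass, 1, tolerance = 1e-3)
})

test_that("daily probability grids are normalised and peak where they should", {
  model <- test_fit(1)$model
  spec <- stm_grid_spec(model, cellsize = 2000)
  for (t in c(10, 60, 150, 305)) {
    g <- location_probability_grid(model, t, spec)
    expect_equal(sum(g$p), 1, tolerance = 1e-6)
    expect_true(all(g$p >= 0))
  }
  # deep in the rainy-season mode the argmax cell contains mu1
  m <- toy_group_stm()
  spec2 <- grid_spec(-50000, -50000, nx = 100, ny = 300, cellsize = 1000)
  g10 <- location_probability_grid(m, 10, spec2)
  i <- which.max(g10$p)
  cx <- spec2$xmin + ((i - 1) %% spec2$nx + 0.5) * spec2$cellsize
  cy <- spec2$ymin + ((i - 1) %/% spec2$nx + 0.5) * spec2$cellsize
  expect_true(abs(cx - 0) <= 500 && abs(cy - 0) <= 500)
})

test_that("enlarging the grid extent leaves interior probabilities unchanged", {
  model <- test_fit(1)$model
  spec <- stm_grid_spec(model, cellsize = 2000)
  big <- stm_grid_spec(model, cellsize = 2000,
                       pad = 20000 + spec$nx * spec$cellsize / 2)
  g1 <- location_probability_grid(model, 100, spec)
  g2 <- location_probability_grid(model, 100, big)
  # match cells of the small grid inside the large one by coordinates
  off_x <- (spec$xmin - big$xmin) / spec$cellsize
  off_y <- (spec$ymin - big$ymin) / spec$cellsize
  idx_small <- seq_along(g1$p)
  col <- (idx_small - 1) %% spec$nx + off_x
  row <- (idx_small - 1) %/% spec$nx + off_y
  idx_big <- row * big$nx + col + 1
  expect_lt(max(abs(g1$p - g2$p[idx_big])), 1e-6)
})

test_that("highest-density regions take cells in descending probability", {
  uni <- prob_grid(rep(1, 100), grid_spec(0, 0, 10, 10, 1))
  h <- hdr_region(uni, 0.95)
  expect_equal(length(h$cells), 95L)

  point <- prob_grid(c(1, rep(0, 99)), grid_spec(0, 0, 10, 10, 1))
  hp <- hdr_region(point, 0.95)
  expect_equal(length(hp$cells), 1L)
  expect_equal(hp$enclosed_mass, 1)

  m <- toy_group_stm()
  g <- location_probability_grid(m, 10, grid_spec(-30000, -30000, 60, 60, 1000))
  hg <- hdr_region(g, 0.95)
  expect_gte(hg$enclosed_mass, 0.95)
  expect_lt(hg$enclosed_mass - g$p[hg$cells[length(hg$cells)]], 0.95)
  expect_error(hdr_region(g, 1.2), "mass")
})

test_that("the parameter inventory counts 18 + 18 + 30 = 66 symbols", {
  counts <- vapply(1:3, function(g) stm_parameter_count(test_fit(g)$model),
                   integer(1))
  expect_equal(counts, c(18L, 18L, 30L))
  expect_equal(sum(counts), 66L)
})

test_that("ESRI ASCII export writes a readable raster", {
  m <- toy_group_stm()
  spec <- grid_spec(0, 0, 20, 30, 1000)
  g <- suppressWarnings(location_probability_grid(m, 10, spec))
  path <- tempfile(fileext = ".asc")
  write_esri_ascii(g, path)
  lines <- readLines(path)
  expect_equal(lines[1], "ncols 20")
  expect_equal(lines[2], "nrows 30")
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  expect_equal(sum(vals), 1, tolerance = 1e-6)
  unlink(path)
})
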