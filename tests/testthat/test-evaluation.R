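test_that("daily closeness is the mean pairwise distance", {
  co <- rbind(route_df(1, 365, x = 0, y = 0, id = "a"),
              route_df(1, 365, x = 0, y = 0, id = "b"))
  expect_equal(daily_closeness(daily_positions(co))[1], 0)

  apart <- rbind(route_df(1, 365, x = 0, y = 0, id = "a"),
                 route_df(1, 365, x = 10000, y = 0, id = "b"))
  expect_equal(daily_closeness(daily_positions(apart))[100], 10000)

  # equilateral triangle of side s: brute force over the three pairs gives s
  s <- 7000
  tri <- rbind(route_df(1, 365, x = 0, y = 0, id = "a"),
               route_df(1, 365, x = s, y = 0, id = "b"),
               route_df(1, 365, x = s / 2, y = s * sqrt(3) / 2, id = "c"))
  pos <- daily_positions(tri)
  d1 <- pos[pos$day == 1, ]
  brute <- mean(c(
    sqrt((d1$x_m[1] - d1$x_m[2])^2 + (d1$y_m[1] - d1$y_m[2])^2),
    sqrt((d1$x_m[1] - d1$x_m[3])^2 + (d1$y_m[1] - d1$y_m[3])^2),
    sqrt((d1$x_m[2] - d1$x_m[3])^2 + (d1$y_m[2] - d1$y_m[3])^2)))
  cl <- daily_closeness(pos)
  expect_equal(cl[50], brute)
  expect_equal(cl[50], s, tolerance = 1e-9)
})

test_that("daily moving distance averages per-pastoralist displacements", {
  still <- rbind(route_df(1, 365, id = "a"), route_df(1, 365, id = "b"))
  md <- daily_moving_distance(daily_positions(still))
  expect_true(all(md[-1] == 0))
  expect_true(is.na(md[1]))

  jump <- rbind(route_df(c(1, 100), c(99, 266), x = c(0, 8000), id = "a"),
                route_df(1, 365, id = "b"))
  md2 <- daily_moving_distance(daily_positions(jump))
  expect_equal(md2[100], 4000)
  expect_equal(md2[101], 0)
  # order of pastoralists is irrelevant
  md3 <- daily_moving_distance(daily_positions(jump[rev(seq_len(nrow(jump))), ]))
  expect_equal(md2, md3)
})

test_that("the 20-day moving average smooths as specified", {
  expect_equal(smooth_series(rep(3, 365)), rep(3, 365))
  imp <- rep(0, 365); imp[100] <- 1
  sm <- smooth_series(imp, 20)
  expect_equal(sum(sm > 0), 20L)
  expect_equal(max(sm), 1 / 20)
  x <- stats::runif(365)
  expect_lt(abs(mean(smooth_series(x, 20)) - mean(x)) / mean(x), 0.02)
  expect_error(smooth_series(x, 0), "window")
})

test_that("series differences are relative, nonnegative and tight at zero", {
  d <- stats::runif(365, 1, 2)
  expect_equal(metric_difference(d, d), 0)
  expect_equal(metric_difference(2 * d, d), 1)
  expect_lt(metric_difference(d + 1e-9, d), 1e-8)
  expect_error(metric_difference(d, rep(0, 365)), "zero")
})

test_that("hull overlap matches hand-computed polygon areas", {
  sq1 <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(hull_overlap(sq1, sq1), 1)
  far <- sq1 + 10
  expect_equal(hull_overlap(sq1, far), 0)
  # unit square inside a 2x2 square sharing a corner: 1 / (1 + 4 - 1)
  big <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_equal(hull_overlap(sq1, big), 0.25)
  expect_equal(hull_overlap(big, sq1), 0.25)  # symmetric
  # half-offset squares: intersection 0.5 x 1, union 1.5
  off <- sq1; off[, 1] <- off[, 1] + 0.5
  expect_equal(hull_overlap(sq1, off), 0.5 / 1.5)
  expect_error(hull_overlap(rbind(c(0, 0), c(1, 1), c(2, 2)), sq1),
               "degenerate")
})

test_that("model comparison scores ensembles and runs one-tailed tests", {
  ds <- test_dataset()
  data1 <- ds$routes[ds$routes$group == 1, ]
  # an "ensemble" that replays the data exactly is a perfect model
  perfect <- structure(list(model_id = "STM", group = 1,
                            sets = rep(list(data1), 4), master_seed = 0),
                       class = "sim_ensemble")
  noisy_set <- data1
  noisy_set$x_m <- noisy_set$x_m + rep(c(2000, -2000), length.out = nrow(data1))
  noisy <- structure(list(model_id = "REF", group = 1,
                          sets = rep(list(noisy_set), 4), master_seed = 0),
                     class = "sim_ensemble")
  rep_ <- compare_models(list(STM = perfect, REF = noisy), ds$routes, 1)
  stm_row <- rep_$summary[rep_$summary$model == "STM", ]
  expect_equal(stm_row$closeness_diff, 0)
  expect_equal(stm_row$moving_diff, 0)
  expect_equal(stm_row$hull_overlap, 1)
  # a sample tested against itself: one-tailed p = 0.5
  self <- compare_models(list(STM = perfect, REF = perfect), ds$routes, 1)
  expect_true(all(self$tests$p_value == 0.5))
  expect_error(compare_models(list(REF = noisy), ds$routes, 1), "STM")
})

test_that("the STM simulations track moving distance better than KRN20", {
  ds <- test_dataset()
  routes <- ds$routes
  model <- test_fit(1)$model
  spec <- data_grid_spec(routes[routes$group == 1, ], cellsize = 4000,
                         pad = 80000)
  krn20 <- fit_reference(routes, 1, "KRN20")
  ens_stm <- simulate_ensemble(model, routes, 1, spec, n_sets = 8,
                               master_seed = 2, model_id = "STM")
  ens_krn <- simulate_ensemble(krn20, routes, 1, spec, n_sets = 8,
                               master_seed = 3, model_id = "KRN20")
  rep_ <- compare_models(list(STM = ens_stm, KRN20 = ens_krn), routes, 1)
  s <- rep_$summary
  expect_lt(s$moving_diff[s$model == "STM"], s$moving_diff[s$model == "KRN20"])
  p <- rep_$tests$p_value[rep_$tests$metric == "moving_diff"]
  expect_lt(p, 0.05)
})
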