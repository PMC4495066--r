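test_that("season windows partition the year with no gaps or overlaps", {
  cal <- season_calendar()
  covered <- unlist(mapply(seq, cal$start, cal$end, SIMPLIFY = FALSE))
  expect_setequal(covered, 1:365)
  expect_equal(length(covered), 365L)  # no overlap
  s <- assign_season(1:365)
  expect_false(anyNA(s))
  expect_equal(assign_season(100), "cold_dry")
  expect_equal(assign_season(300), "begin_rains")
  expect_equal(assign_season(350), "rainy")
  expect_equal(assign_season(c(17, 18, 78, 79, 170, 171, 290, 291, 320, 321)),
               c("rainy", "end_of_rains", "end_of_rains", "cold_dry",
                 "cold_dry", "hot_dry", "hot_dry", "begin_rains",
                 "begin_rains", "rainy"))
  expect_error(assign_season(0), "must be in")
  expect_error(assign_season(366), "must be in")
})

test_that("stays at or above the 20-day threshold are sojourn camps", {
  expect_equal(classify_stay(25), "sojourn")
  expect_equal(classify_stay(20), "sojourn")
  expect_equal(classify_stay(19), "transit")
  expect_equal(classify_stay(c(5, 20), threshold_days = 5), c("sojourn", "sojourn"))
})

test_that("duration normalisation adjusts the single longest stay", {
  r <- route_df(arrival = c(1, 101, 301), duration = c(100, 200, 60))
  out <- normalize_routes(r)
  expect_equal(out$duration_days, c(100L, 205L, 60L))
  expect_equal(out$arrival_day, c(1L, 101L, 306L))

  r2 <- route_df(arrival = c(1, 121), duration = c(120, 245))
  expect_equal(normalize_routes(r2)$duration_days, c(120L, 245L))

  r3 <- route_df(arrival = c(1, 11), duration = c(10, 360))
  expect_equal(normalize_routes(r3)$duration_days, c(10L, 355L))

  # ties broken by earliest arrival
  r4 <- route_df(arrival = c(1, 101, 201), duration = c(100, 100, 60))
  expect_equal(normalize_routes(r4)$duration_days, c(205L, 100L, 60L))

  # rejection when the adjustment would consume the longest stay
  r5 <- route_df(arrival = c(1, 301, 601), duration = c(300, 300, 300))
  expect_error(normalize_routes(r5), "non-positive")
})

test_that("normalisation is idempotent and rechains arrival days", {
  routes <- test_dataset()$routes
  once <- normalize_routes(routes)
  expect_equal(normalize_routes(once), once)
  # arrival chaining invariant
  for (r in split(once, once$pastoralist_id)) {
    expect_equal(r$arrival_day[-1],
                 wrap_day(r$arrival_day[-nrow(r)] + r$duration_days[-nrow(r)]))
  }
})

test_that("daily positions use half-open stay intervals and conserve counts", {
  one <- route_df(arrival = 1, duration = 365, x = 5, y = 7)
  pos <- daily_positions(one)
  expect_equal(nrow(pos), 365L)
  expect_true(all(pos$x_m == 5 & pos$y_m == 7))

  two <- route_df(arrival = c(1, 11), duration = c(10, 355),
                  x = c(0, 100), y = 0)
  pos2 <- daily_positions(two)
  expect_equal(pos2$x_m[pos2$day == 10], 0)
  expect_equal(pos2$x_m[pos2$day == 11], 100)

  pair <- rbind(route_df(arrival = 1, duration = 365, id = "a"),
                route_df(arrival = 1, duration = 365, id = "b"))
  pos3 <- daily_positions(pair)
  expect_true(all(table(pos3$day) == 2L))

  overlap <- route_df(arrival = c(1, 5), duration = c(10, 360))
  expect_error(daily_positions(overlap), "overlap")
})

test_that("route tables round-trip through CSV", {
  routes <- test_dataset()$routes
  path <- tempfile(fileext = ".csv")
  write_routes(routes, path)
  back <- read_routes(path)
  unlink(path)
  expect_equal(back, routes[, setdiff(names(routes), "mode_true")])
})
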