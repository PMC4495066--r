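test_that("selection rules route the right stays into each fit", {
  r <- rbind(
    route_df(arrival = c(1, 50, 60, 100, 300, 305, 335),
             duration = c(49, 10, 40, 200, 5, 30, 31),
             x = c(0, 1, 2, 3, 4, 5, 6) * 1000, id = "a"),
    route_df(arrival = c(1, 100, 300),
             duration = c(99, 200, 66), x = c(0, 10, 20) * 1000, id = "b")
  )
  m1 <- select_fit_data(r, 1, "M1")
  # sojourn at day 60 included (rainy-season fitting window runs to day 78);
  # the transit stay at day 50 and the begin-rains sojourn at 305 are not
  expect_setequal(m1$arrival_day[m1$pastoralist_id == "a"], c(1, 60, 335))
  expect_equal(m1$unwrapped_day[m1$arrival_day == 335], -30)

  m2 <- select_fit_data(r, 1, "M2")
  expect_setequal(m2$arrival_day, c(100, 100))

  # all short stays feed the M3 dates; sojourn stays never do
  m3 <- select_fit_data(r, 1, "M3")
  expect_setequal(m3$arrival_day, c(50, 300))
  expect_error(select_fit_data(r, 1, "M4"), "group 3")

  # farthest-point rule: one dry-season location per pastoralist
  rr <- rbind(
    route_df(arrival = c(1, 100, 180), duration = c(99, 80, 186),
             x = c(0, 80000, 95000), id = "p"),
    route_df(arrival = c(1, 100, 180), duration = c(99, 80, 186),
             x = c(0, 70000, 60000), id = "q")
  )
  far <- select_farthest_dry(rr, 1, mu1 = c(0, 0))
  expect_equal(sort(far$x_m), c(70000, 95000))
})

test_that("normal date fits are exact maximum likelihood", {
  tc <- fit_normal_1d(c(10, 20, 30))
  expect_equal(tc$tau, 20)
  expect_equal(tc$sigma2, 200 / 3)  # divisor n
  expect_warning(flat <- fit_normal_1d(c(5, 5, 5)), "floored")
  expect_equal(flat$sigma2, 1)
  expect_error(fit_normal_1d(7), "at least 2")
  set.seed(3)
  tc2 <- fit_normal_1d(rnorm(500, 19, 8))
  expect_lt(abs(tc2$tau - 19), 1.5)
})

test_that("EM recovers a well-separated date mixture", {
  set.seed(10)
  x <- c(rnorm(200, 60, 5), rnorm(200, 300, 5))
  fit <- fit_mixture_1d(x, 2, seed = 2)
  expect_equal(fit$lambda, c(0.5, 0.5), tolerance = 0.05)
  expect_lt(abs(fit$tau[1] - 60), 2)
  expect_lt(abs(fit$tau[2] - 300), 2)
  expect_equal(sqrt(fit$sigma2), c(5, 5), tolerance = 1)
  # log-likelihood is nondecreasing across EM iterations
  expect_true(all(diff(attr(fit, "loglik_trace")) > -1e-8))
  # canonical ordering is stable across seeds
  fit2 <- fit_mixture_1d(x, 2, seed = 77)
  expect_lt(abs(fit2$tau[1] - fit$tau[1]), 0.5)
  # one component reduces to the single-normal fit
  one <- fit_mixture_1d(x, 1)
  expect_equal(one$tau, mean(x))
  # independent EM implementation agrees
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$tau), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.5)
})

test_that("bivariate normal location fits recover mean and covariance", {
  sq <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)) * 1000
  sq <- sweep(sq, 2, c(5000, 7000), "+")
  g <- fit_gaussian_2d(sq)
  expect_equal(g$mu, c(5000, 7000))
  set.seed(4)
  Sigma <- matrix(c(4e6, 1.5e6, 1.5e6, 9e6), 2)
  pts <- stmob:::rmvn2(1000, c(0, 0), Sigma)
  g2 <- fit_gaussian_2d(pts)
  expect_lt(norm(g2$Sigma - Sigma, "F") / norm(Sigma, "F"), 0.1)
  expect_warning(fit_gaussian_2d(cbind(1:5, 2 * (1:5))), "singular")
})

test_that("2-D EM separates two location clusters", {
  set.seed(5)
  pts <- rbind(stmob:::rmvn2(150, c(0, 0), diag(1e6, 2)),
               stmob:::rmvn2(50, c(50000, 0), diag(1e6, 2)))
  mix <- fit_mixture_2d(pts, 2, seed = 3)
  expect_equal(sort(mix$weights), c(0.25, 0.75), tolerance = 0.05)
  mus <- vapply(mix$components, `[[`, numeric(2), "mu")
  expect_lt(min(abs(mus[1, ] - 0)), 500)
  expect_lt(min(abs(mus[1, ] - 50000)), 500)
  expect_true(all(diff(attr(mix, "loglik_trace")) > -1e-8))
  # independent EM implementation agrees on the means
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  mc <- mclust::Mclust(pts, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(sort(mus[1, ]), sort(mc$parameters$mean[1, ]), tolerance = 1000)
})

test_that("bridge diffusion estimation matches its closed-form MLE", {
  set.seed(6)
  times <- sort(sample(1:99, 40))
  xy <- simulate_bb_track(c(0, 0), c(80000, 10000), 100, times, 3e6)
  track <- data.frame(x_m = xy[, 1], y_m = xy[, 2], day = times)
  est <- estimate_bb_diffusion(track)
  # closed form: the likelihood is maximised at sum(d^2/c) / (2m)
  n <- length(times)
  idx <- seq(2, n - 1, by = 2)
  dt1 <- times[idx] - times[idx - 1]; dt2 <- times[idx + 1] - times[idx]
  ci <- dt1 * dt2 / (dt1 + dt2)
  w <- dt1 / (dt1 + dt2)
  mx <- xy[idx - 1, 1] + (xy[idx + 1, 1] - xy[idx - 1, 1]) * w
  my <- xy[idx - 1, 2] + (xy[idx + 1, 2] - xy[idx - 1, 2]) * w
  d2 <- (xy[idx, 1] - mx)^2 + (xy[idx, 2] - my)^2
  closed <- sum(d2 / ci) / (2 * length(idx))
  expect_equal(est, closed, tolerance = 0.01)

  # a perfectly linear uniformly-timed track pins the estimate at the floor
  lin <- data.frame(x_m = seq(0, 1e5, length.out = 11),
                    y_m = 0, day = seq(0, 100, by = 10))
  expect_warning(low <- estimate_bb_diffusion(lin), "lower bound")
  expect_equal(low, 1)
  expect_error(estimate_bb_diffusion(lin[1:2, ]), "at least 3")
})

test_that("bridge endpoints and durations derive from the sojourn fits", {
  br <- derive_bridges(c(0, 0), c(1e5, 0), tau1 = 10, tau2 = 160,
                       diff_out = 4e6, diff_ret = 4e6)
  expect_equal(br$M3[[1]]$total_time, 150)
  expect_equal(br$M3[[2]]$total_time, 215)
  expect_equal(bridge_mean(br$M3[[1]], 0)[1, ], c(0, 0))
  expect_equal(br$M3[[2]]$a, c(1e5, 0))

  br3 <- derive_bridges(c(0, 0), list(c(0, 1e5), c(0, 5e4)), tau1 = 10,
                        tau2 = c(120, 240), diff_out = 4e6, diff_ret = 4e6,
                        diff_m4 = 2e6)
  expect_equal(br3$M4$total_time, 120)
  expect_equal(br3$M4$a, c(0, 1e5))
  expect_equal(br3$M3[[2]]$total_time, 365 - 230)
  expect_error(derive_bridges(c(0, 0), c(1, 0), tau1 = 200, tau2 = 100,
                              diff_out = 1, diff_ret = 1), "out of order")
})

test_that("the full group fit assembles the right structure", {
  f1 <- test_fit(1)
  expect_s3_class(f1$model, "group_stm")
  expect_setequal(f1$model$modes, c("M1", "M2", "M3"))
  expect_null(f1$model$spatial$M4)
  f3 <- test_fit(3)
  expect_setequal(f3$model$modes, c("M1", "M2", "M3", "M4"))
  expect_s3_class(f3$model$spatial$M2, "stm_mixture")
  expect_s3_class(f3$model$spatial$M4, "stm_bridge")
  # north component first, and dates ordered to match
  mus <- vapply(f3$model$spatial$M2$components, `[[`, numeric(2), "mu")
  expect_gt(mus[2, 1], mus[2, 2])
  expect_lt(f3$model$temporal$M2$tau[1], f3$model$temporal$M2$tau[2])
})
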