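# Synthetic transhumance routes from a known ground truth.
#
# The survey data this package's methods were designed for are not publicly
# deposited, so the generator emulates their statistical structure: three
# pastoralist groups (~71 annual routes in total), each route an ordered
# sequence of campsite stays summing to 365 days. Long (>= 20 d) sojourn
# stays cluster in a group's rainy-season area and dry-season area(s);
# short transit stays follow the straight corridor between them with
# Brownian-bridge-shaped lateral noise. Group 3 additionally occupies a
# northern then a southern dry-season area, linked by a mid-dry-season
# transit leg. Hidden per-stay mode labels and the generating parameters are
# returned so downstream fitting can be tested by parameter recovery.

#' Default ground-truth configuration
#'
#' Geography lives on a UTM-33N-like metric plane. Groups 1 and 2 have
#' distinct rainy-season centroids (south-west and north-east) and nearby
#' dry-season floodplain areas in the north; group 3 shares the floodplain
#' as its first (northern) dry-season component and adds a southern second
#' component. Timing is anchored inside the seasonal calendar: routes leave
#' the rainy-season lands around day 38, reach the dry-season areas around
#' day 90 (early cold dry season), head back around day 295-299, and arrive
#' in the last rainy-season window of the year. Route counts default to
#' 30/26/15.
#'
#' @param n_routes integer vector of route counts per group.
#' @return a `ground_truth_config` list; see [generate_dataset()].
#' @export
default_config <- function(n_routes = c(30L, 26L, 15L)) {
  sojourn_dur <- list(mean = 50, jitter_sd = 8, min = 21)
  rainy_dur <- list(mean = 35, jitter_sd = 8, min = 21)
  transit_dur <- list(mean = 5, jitter_sd = 1.5, min = 1, max = 19)
  cfg <- list(
    n_routes = as.integer(n_routes),
    year_label = "Y1",
    threshold_days = 20L,
    sojourn_dur = sojourn_dur, rainy_dur = rainy_dur, transit_dur = transit_dur,
    groups = list(
      list( # group 1: south-western rainy lands, north-western floodplain
        mu_rainy = c(408000, 1147000), Sigma_rainy = diag(5000^2, 2),
        mu_dry = c(432000, 1262000), Sigma_dry = diag(3000^2, 2),
        diffusion = c(out = 4e6, ret = 4e6),
        dep_rainy = c(mean = 38, sd = 6), travel_out = c(mean = 52, sd = 6),
        dep_dry = c(mean = 295, sd = 5), travel_ret = c(mean = 28, sd = 4)
      ),
      list( # group 2: north-eastern rainy lands
        mu_rainy = c(465000, 1195000), Sigma_rainy = diag(5000^2, 2),
        mu_dry = c(455000, 1268000), Sigma_dry = diag(3000^2, 2),
        diffusion = c(out = 4e6, ret = 4e6),
        dep_rainy = c(mean = 38, sd = 6), travel_out = c(mean = 52, sd = 6),
        dep_dry = c(mean = 295, sd = 5), travel_ret = c(mean = 28, sd = 4)
      ),
      list( # group 3: triangular cycle with a southern second dry-season area
        mu_rainy = c(425000, 1152000), Sigma_rainy = diag(5000^2, 2),
        mu_dry_north = c(446000, 1258000), Sigma_dry_north = diag(4000^2, 2),
        mu_dry_south = c(441000, 1203000), Sigma_dry_south = diag(4000^2, 2),
        diffusion = c(out = 4e6, ret = 4e6, m4 = 2e6),
        dep_rainy = c(mean = 38, sd = 6), travel_out = c(mean = 52, sd = 6),
        dep_north = c(mean = 190, sd = 6), travel_m4 = c(mean = 25, sd = 4),
        dep_dry = c(mean = 299, sd = 4), travel_ret = c(mean = 28, sd = 4)
      )
    )
  )
  class(cfg) <- "ground_truth_config"
  validate_config(cfg)
  cfg
}

#' Validate a ground-truth configuration
#'
#' Checks covariance positive-definiteness, route counts, the ordering of
#' the mean transition days, and that transit durations stay below the
#' sojourn threshold.
#'
#' @param cfg a `ground_truth_config`.
#' @return the configuration, invisibly; errors describe the violation.
#' @export
validate_config <- function(cfg) {
  if (length(cfg$n_routes) != 3L || any(cfg$n_routes < 1L)) {
    stop("config: n_routes must give a positive count for each of 3 groups")
  }
  for (g in 1:3) {
    gc <- cfg$groups[[g]]
    for (nm in grep("^Sigma", names(gc), value = TRUE)) {
      ev <- eigen(gc[[nm]], symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) stop("config: ", nm, " must be positive definite")
    }
    sched <- c(gc$dep_rainy["mean"],
               gc$dep_rainy["mean"] + gc$travel_out["mean"])
    if (g == 3L) {
      sched <- c(sched, gc$dep_north["mean"],
                 gc$dep_north["mean"] + gc$travel_m4["mean"])
    }
    sched <- c(sched, gc$dep_dry["mean"],
               gc$dep_dry["mean"] + gc$travel_ret["mean"])
    if (any(diff(sched) <= 0) || sched[length(sched)] > 365) {
      stop("config: group ", g, " mean transition days are out of order")
    }
  }
  if (cfg$transit_dur$max >= cfg$threshold_days) {
    stop("config: transit durations must stay below the sojourn threshold")
  }
  invisible(cfg)
}

# split a block of L days into near-equal integer stays around mean_dur,
# with jittered breakpoints; deterministic = the expected (unjittered) split
partition_block <- function(L, dur, deterministic = FALSE) {
  n <- max(1L, round(L / dur$mean))
  bp <- round(seq(0, L, length.out = n + 1))
  if (!deterministic && n > 1L) {
    inner <- bp[2:n] + round(stats::rnorm(n - 1L, 0, dur$jitter_sd))
    bp <- sort(c(0, pmin(pmax(inner, 0), L), L))
  }
  durs <- diff(bp)
  # merge segments that fell under the minimum duration
  while (any(durs < dur$min) && length(durs) > 1L) {
    i <- which.min(durs)
    j <- if (i == 1L) 2L else i - 1L
    durs[j] <- durs[j] + durs[i]
    durs <- durs[-i]
  }
  # transit stays must stay below the sojourn threshold: split long ones
  if (!is.null(dur$max)) {
    while (any(durs > dur$max)) {
      i <- which.max(durs)
      half <- durs[i] %/% 2L
      durs <- append(durs[-i], c(half, durs[i] - half), after = i - 1L)
    }
  }
  as.integer(durs)
}

draw_day <- function(par, deterministic, lower = -Inf, upper = Inf) {
  d <- if (deterministic) par[["mean"]] else stats::rnorm(1, par[["mean"]], par[["sd"]])
  as.integer(min(max(round(d), lower), upper))
}

# one annual route for a group; returns stays with hidden mode labels
generate_one_route <- function(cfg, g, deterministic = FALSE) {
  gc <- cfg$groups[[g]]
  dep1 <- draw_day(gc$dep_rainy, deterministic, lower = 24, upper = 55)
  # arrival in the dry-season areas falls in the cold dry season (day >= 80):
  # the floodplain only opens up once the flood water recedes
  arr_dry <- dep1 + draw_day(gc$travel_out, deterministic,
                             lower = max(12, 80 - dep1))
  legs <- list()
  add_leg <- function(start, durs, mode, locfun) {
    arr <- as.integer(start + c(0L, cumsum(durs[-length(durs)])))
    list(arrival = arr, duration = durs, mode = rep(mode, length(durs)),
         loc = locfun(arr))
  }
  soj_loc <- function(mu, Sigma) {
    function(arr) {
      if (deterministic) {
        matrix(rep(mu, each = length(arr)), ncol = 2L)
      } else rmvn2(length(arr), mu, Sigma)
    }
  }
  # transit campsites: a Brownian bridge from a to b sampled sequentially at
  # the stay arrival times, so each campsite's marginal is the bridge normal
  # at its arrival time and consecutive campsites are path-correlated
  transit_loc <- function(a, b, t0, Tt, diffusion) {
    function(arr) {
      tr <- arr - t0
      if (deterministic) {
        return(cbind(a[1] + (b[1] - a[1]) * tr / Tt,
                     a[2] + (b[2] - a[2]) * tr / Tt))
      }
      out <- matrix(NA_real_, length(tr), 2L)
      prev <- a; tprev <- 0
      for (i in seq_along(tr)) {
        w <- (tr[i] - tprev) / (Tt - tprev)
        mu <- prev + (b - prev) * w
        v <- diffusion * (tr[i] - tprev) * (Tt - tr[i]) / (Tt - tprev)
        out[i, ] <- mu + stats::rnorm(2L, 0, sqrt(max(v, 0)))
        prev <- out[i, ]; tprev <- tr[i]
      }
      out
    }
  }
  # rainy-season stay opening the year, then the outbound transit leg
  legs$m1a <- add_leg(1L, dep1 - 1L, "M1", soj_loc(gc$mu_rainy, gc$Sigma_rainy))
  first_dry_mu <- if (g == 3L) gc$mu_dry_north else gc$mu_dry
  legs$m3out <- add_leg(dep1,
                        partition_block(arr_dry - dep1, cfg$transit_dur, deterministic),
                        "M3",
                        transit_loc(gc$mu_rainy, first_dry_mu, dep1,
                                    arr_dry - dep1, gc$diffusion[["out"]]))
  if (g == 3L) {
    dep_n <- draw_day(gc$dep_north, deterministic, lower = arr_dry + 42)
    arr_s <- dep_n + draw_day(gc$travel_m4, deterministic, lower = 10)
    dep_dry <- draw_day(gc$dep_dry, deterministic, lower = arr_s + 42, upper = 330)
    legs$m2n <- add_leg(arr_dry,
                        partition_block(dep_n - arr_dry, cfg$sojourn_dur, deterministic),
                        "M2", soj_loc(gc$mu_dry_north, gc$Sigma_dry_north))
    legs$m4 <- add_leg(dep_n,
                       partition_block(arr_s - dep_n, cfg$transit_dur, deterministic),
                       "M4",
                       transit_loc(gc$mu_dry_north, gc$mu_dry_south, dep_n,
                                   arr_s - dep_n, gc$diffusion[["m4"]]))
    legs$m2s <- add_leg(arr_s,
                        partition_block(dep_dry - arr_s, cfg$sojourn_dur, deterministic),
                        "M2", soj_loc(gc$mu_dry_south, gc$Sigma_dry_south))
    last_dry_mu <- gc$mu_dry_south
  } else {
    dep_dry <- draw_day(gc$dep_dry, deterministic, lower = arr_dry + 42, upper = 330)
    legs$m2 <- add_leg(arr_dry,
                       partition_block(dep_dry - arr_dry, cfg$sojourn_dur, deterministic),
                       "M2", soj_loc(gc$mu_dry, gc$Sigma_dry))
    last_dry_mu <- gc$mu_dry
  }
  arr_back <- dep_dry + draw_day(gc$travel_ret, deterministic,
                                 lower = 12, upper = 360 - dep_dry)
  legs$m3ret <- add_leg(dep_dry,
                        partition_block(arr_back - dep_dry, cfg$transit_dur, deterministic),
                        "M3",
                        transit_loc(last_dry_mu, gc$mu_rainy, dep_dry,
                                    arr_back - dep_dry, gc$diffusion[["ret"]]))
  legs$m1b <- add_leg(arr_back,
                      partition_block(366L - arr_back, cfg$rainy_dur, deterministic),
                      "M1", soj_loc(gc$mu_rainy, gc$Sigma_rainy))
  loc <- do.call(rbind, lapply(legs, `[[`, "loc"))
  data.frame(
    arrival_day = unlist(lapply(legs, `[[`, "arrival"), use.names = FALSE),
    duration_days = unlist(lapply(legs, `[[`, "duration"), use.names = FALSE),
    mode_true = unlist(lapply(legs, `[[`, "mode"), use.names = FALSE),
    x_m = loc[, 1], y_m = loc[, 2],
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic route dataset
#'
#' Draws one annual route per pastoralist under the configuration's ground
#' truth. Every route's durations sum to exactly 365 days and arrival days
#' chain contiguously from day 1, so [normalize_routes()] is the identity on
#' the output. Hidden ground-truth mode labels are kept in a `mode_true`
#' column (dropped by [write_routes()]).
#'
#' @param config a `ground_truth_config`, e.g. [default_config()].
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return list with `routes` (route table plus `mode_true`), `config`, and
#'   `truth` (see [ground_truth_summary()]).
#' @export
generate_dataset <- function(config = default_config(), seed = 1L) {
  validate_config(config)
  set.seed(seed)
  out <- list()
  for (g in 1:3) {
    for (i in seq_len(config$n_routes[g])) {
      r <- generate_one_route(config, g)
      r$pastoralist_id <- sprintf("G%d_P%02d", g, i)
      r$year_label <- config$year_label
      r$group <- g
      r$campsite_id <- sprintf("%s_C%02d", r$pastoralist_id[1], seq_len(nrow(r)))
      out[[length(out) + 1L]] <- r
    }
  }
  routes <- do.call(rbind, out)
  routes <- routes[, c(ROUTE_COLUMNS, "mode_true")]
  rownames(routes) <- NULL
  stopifnot(all(tapply(routes$duration_days, routes$pastoralist_id, sum) == 365L))
  list(routes = routes, config = config, truth = ground_truth_summary(config))
}

#' Ground-truth parameter summary for recovery tests
#'
#' Temporal ground truths are read off the generator's deterministic mean
#' schedule (every random draw at its mean), passed through the same
#' stay-selection rules the fitting module applies ([select_fit_data()]),
#' so fitted parameters can be compared to them without bias from the
#' scheduling arithmetic. Spatial ground truths are the configured
#' component means.
#'
#' @param config a `ground_truth_config`.
#' @return nested list, one entry per group, with elements `mu` (named list
#'   of spatial means), `tau` (named list of temporal mean dates; M1 on the
#'   circularly unwrapped scale) and `diffusion`.
#' @export
ground_truth_summary <- function(config) {
  lapply(1:3, function(g) {
    r <- generate_one_route(config, g, deterministic = TRUE)
    r$pastoralist_id <- "truth"; r$year_label <- config$year_label
    r$group <- g; r$campsite_id <- as.character(seq_len(nrow(r)))
    gc <- config$groups[[g]]
    thr <- config$threshold_days
    tau <- list(M1 = mean(select_fit_data(r, g, "M1", thr)$unwrapped_day))
    if (g == 3L) {
      m2 <- select_fit_data(r, g, "M2", thr)
      north <- m2$y_m > mean(c(gc$mu_dry_north[2], gc$mu_dry_south[2]))
      tau$M2 <- c(mean(m2$arrival_day[north]), mean(m2$arrival_day[!north]))
      tau$M4 <- mean(select_fit_data(r, g, "M4", thr)$arrival_day)
      mu <- list(M1 = gc$mu_rainy, M2 = list(gc$mu_dry_north, gc$mu_dry_south))
    } else {
      tau$M2 <- mean(select_fit_data(r, g, "M2", thr)$arrival_day)
      mu <- list(M1 = gc$mu_rainy, M2 = gc$mu_dry)
    }
    m3 <- select_fit_data(r, g, "M3", thr)
    tau$M3 <- c(mean(m3$arrival_day[m3$arrival_day < 200L]),
                mean(m3$arrival_day[m3$arrival_day >= 200L]))
    list(mu = mu, tau = tau, diffusion = gc$diffusion)
  })
}
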