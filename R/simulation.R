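# Route simulation from any fitted daily-probability model: sample a
# campsite from the day's grid, hold it for a normally distributed number of
# days estimated from the data, and repeat until the year is filled.

#' Per-day stay-duration statistics
#'
#' For each day of the year, the mean and standard deviation of the
#' durations of the data's stays whose occupancy interval covers that day.
#' The standard deviation is floored at 0.5 days; days covered by no stay
#' (not possible for normalised routes) fall back to the nearest covered
#' day.
#'
#' @param routes a normalised route table with `group` filled.
#' @param group group id.
#' @return data.frame with columns `day`, `mean_days`, `sd_days`.
#' @export
estimate_stay_stats <- function(routes, group) {
  r <- routes[routes$group == group, , drop = FALSE]
  if (!nrow(r)) stop("no routes in group ", group)
  idx <- rep.int(seq_len(nrow(r)), r$duration_days)
  day <- wrap_day(r$arrival_day[idx] + (sequence(r$duration_days) - 1L))
  dur <- r$duration_days[idx]
  mean_days <- tapply(dur, day, mean)
  sd_days <- tapply(dur, day, stats::sd)
  out <- data.frame(day = 1:365, mean_days = NA_real_, sd_days = NA_real_)
  got <- as.integer(names(mean_days))
  out$mean_days[got] <- as.numeric(mean_days)
  out$sd_days[got] <- as.numeric(sd_days)
  if (anyNA(out$mean_days)) {
    warning("some days are covered by no stay; using the nearest covered day")
    for (t in which(is.na(out$mean_days))) {
      nb <- got[which.min(abs(got - t))]
      out$mean_days[t] <- out$mean_days[nb]
      out$sd_days[t] <- out$sd_days[nb]
    }
  }
  out$sd_days[is.na(out$sd_days)] <- 0
  out$sd_days <- pmax(out$sd_days, 0.5)
  out
}

#' Simulate one annual route from daily probability grids
#'
#' Starting at day 1: draw a cell from the day's grid with probability
#' proportional to the cell probabilities, place the campsite at the cell
#' centre, draw a stay duration from the day's normal duration law (rounded,
#' at least 1 day, truncated so the year sums to 365), then advance to the
#' next stay.
#'
#' @param grids list of 365 `prob_grid`s (entries may share one object).
#' @param stay_stats output of [estimate_stay_stats()].
#' @param seed optional integer seed.
#' @param pastoralist_id,year_label,group identifiers for the output rows.
#' @return a one-route table (durations sum to 365).
#' @export
simulate_route <- function(grids, stay_stats, seed = NULL,
                           pastoralist_id = "sim", year_label = "sim",
                           group = NA_integer_) {
  if (!is.null(seed)) set.seed(seed)
  t <- 1L
  arr <- integer(0); dur <- integer(0); xs <- numeric(0); ys <- numeric(0)
  while (t <= 365L) {
    g <- grids[[t]]
    if (abs(sum(g$p) - 1) > 1e-6) stop("grid for day ", t, " is not normalised")
    cell <- sample.int(length(g$p), 1L, prob = g$p)
    spec <- g$spec
    col <- (cell - 1L) %% spec$nx + 1L
    row <- (cell - 1L) %/% spec$nx + 1L
    d <- max(1L, as.integer(round(stats::rnorm(1, stay_stats$mean_days[t],
                                               stay_stats$sd_days[t]))))
    d <- min(d, 366L - t)
    arr <- c(arr, t); dur <- c(dur, d)
    xs <- c(xs, spec$xmin + (col - 0.5) * spec$cellsize)
    ys <- c(ys, spec$ymin + (row - 0.5) * spec$cellsize)
    t <- t + d
  }
  data.frame(pastoralist_id = pastoralist_id, year_label = year_label,
             group = group,
             campsite_id = sprintf("%s_S%02d", pastoralist_id, seq_along(arr)),
             x_m = xs, y_m = ys, arrival_day = arr, duration_days = dur,
             stringsAsFactors = FALSE)
}

#' Precompute the 365 daily grids of a model
#'
#' @param model a [group_stm()] or `daily_model`.
#' @param spec a [grid_spec()].
#' @return list of 365 `prob_grid`s.
#' @export
daily_grid_stack <- function(model, spec) {
  lapply(1:365, function(t) model_grid(model, t, spec))
}

#' Simulate an ensemble of route sets
#'
#' Each set contains as many simulated routes as the data has pastoralists
#' in the group; child seeds derive deterministically from the master seed,
#' so the ensemble is reproducible.
#'
#' @param model a [group_stm()] or `daily_model`.
#' @param routes the data route table (defines the per-set route count and
#'   the stay statistics).
#' @param group group id.
#' @param spec a [grid_spec()]; a common extent should be used when several
#'   models are compared.
#' @param n_sets number of simulation sets (the comparison protocol uses
#'   100).
#' @param master_seed integer master seed.
#' @param model_id label stored with the ensemble.
#' @return an object of class `sim_ensemble`: list of route tables in
#'   `$sets`.
#' @export
simulate_ensemble <- function(model, routes, group, spec, n_sets = 100L,
                              master_seed = 1L, model_id = "model") {
  ids <- unique(routes$pastoralist_id[routes$group == group])
  if (!length(ids)) stop("no routes in group ", group)
  stats <- estimate_stay_stats(routes, group)
  grids <- daily_grid_stack(model, spec)
  sets <- lapply(seq_len(n_sets), function(s) {
    set.seed((master_seed * 1009L + s) %% 2147483647L)
    out <- lapply(seq_along(ids), function(i) {
      simulate_route(grids, stats,
                     pastoralist_id = sprintf("sim%03d_%02d", s, i),
                     year_label = "sim", group = group)
    })
    do.call(rbind, out)
  })
  structure(list(model_id = model_id, group = group, sets = sets,
                 master_seed = master_seed),
            class = "sim_ensemble")
}
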