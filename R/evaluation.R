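# Comparison of simulation ensembles against route data: daily closeness,
# daily moving distance (raw and 20-day smoothed), convex-hull overlap, and
# one-tailed Welch t-tests of the STM ensemble against each reference.

#' Daily mean pairwise closeness
#'
#' For each day, the mean Euclidean distance over unordered pairs of
#' same-day pastoralist positions. Days with fewer than two positions are
#' undefined (NA).
#'
#' @param positions output of [daily_positions()].
#' @return numeric vector of length 365 (metres).
#' @export
daily_closeness <- function(positions) {
  out <- rep(NA_real_, 365L)
  for (d in split(positions, positions$day)) {
    if (nrow(d) >= 2L) {
      out[d$day[1L]] <- mean(stats::dist(cbind(d$x_m, d$y_m)))
    }
  }
  if (anyNA(out)) warning("days with fewer than 2 pastoralists are excluded")
  out
}

#' Daily mean moving distance
#'
#' For each day t >= 2, the mean over pastoralists of the displacement
#' between their day t-1 and day t positions (zero while encamped). Day 1
#' has no predecessor and is NA.
#'
#' @param positions output of [daily_positions()].
#' @return numeric vector of length 365 (metres).
#' @export
daily_moving_distance <- function(positions) {
  p <- positions[order(positions$pastoralist_id, positions$day), , drop = FALSE]
  dx <- c(NA, diff(p$x_m)); dy <- c(NA, diff(p$y_m))
  same <- c(FALSE, p$pastoralist_id[-1L] == p$pastoralist_id[-nrow(p)] &
              diff(p$day) == 1L)
  step <- ifelse(same, sqrt(dx^2 + dy^2), NA_real_)
  out <- rep(NA_real_, 365L)
  means <- tapply(step[same], p$day[same], mean)
  out[as.integer(names(means))] <- as.numeric(means)
  out
}

#' Centered moving-average smoothing
#'
#' A `window`-day centred moving average (window truncated at the ends of
#' the series); used with the default 20-day window to smooth the daily
#' moving-distance series.
#'
#' @param series numeric vector (NAs are ignored within each window).
#' @param window window width in days, >= 1.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_series <- function(series, window = 20L) {
  if (window < 1L) stop("window must be >= 1")
  n <- length(series)
  half_lo <- ceiling((window - 1L) / 2)
  half_hi <- window - 1L - half_lo
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half_lo); hi <- min(n, i + half_hi)
    mean(series[lo:hi], na.rm = TRUE)
  }, numeric(1L))
}

#' Mean relative difference between a simulated and a data series
#'
#' Mean over days of `|sim - data| / data`; days where the data value is
#' zero or either series is undefined are excluded.
#'
#' @param sim,data numeric vectors on the same days.
#' @return nonnegative scalar.
#' @export
metric_difference <- function(sim, data) {
  if (length(sim) != length(data)) stop("series must cover the same days")
  ok <- is.finite(sim) & is.finite(data) & data > 0
  if (!any(ok)) stop("no usable days: the data series is zero or undefined everywhere")
  mean(abs(sim[ok] - data[ok]) / data[ok])
}

# convex polygon utilities ---------------------------------------------------

# signed area (shoelace); positive for counterclockwise vertex order
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

convex_hull <- function(xy) {
  xy <- unique(matrix(xy, ncol = 2L))
  idx <- grDevices::chull(xy)
  h <- xy[idx, , drop = FALSE]
  if (nrow(h) < 3L || abs(polygon_area(h)) < 1e-9) {
    stop("degenerate convex hull: need at least 3 non-collinear locations")
  }
  if (polygon_area(h) < 0) h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
  h
}

# Sutherland-Hodgman clipping of convex polygon `subject` by convex `clip`
# (both counterclockwise); returns the intersection polygon (possibly empty)
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    inside <- function(p) {
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-9
    }
    isect <- function(p, q) {
      dc <- a - b; dp <- p - q
      n1 <- a[1] * b[2] - a[2] * b[1]
      n2 <- p[1] * q[2] - p[2] * q[1]
      den <- dc[1] * dp[2] - dc[2] * dp[1]
      c(n1 * dp[1] - n2 * dc[1], n1 * dp[2] - n2 * dc[2]) / den
    }
    inp <- out
    out <- matrix(numeric(0), ncol = 2L)
    np <- nrow(inp)
    for (j in seq_len(np)) {
      p <- inp[j, ]; q <- inp[if (j == np) 1L else j + 1L, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) out <- rbind(out, p)
      if (pin != qin) out <- rbind(out, isect(p, q))
    }
  }
  out
}

#' Convex-hull overlap ratio of two location sets
#'
#' Ratio of the intersection area to the union area (Jaccard) of the convex
#' hulls of the two sets of campsite locations; 1 for identical hulls, 0 for
#' disjoint ones.
#'
#' @param xy_a,xy_b n x 2 matrices of locations (each with at least 3
#'   non-collinear points).
#' @return overlap ratio in `[0, 1]`.
#' @export
hull_overlap <- function(xy_a, xy_b) {
  ha <- convex_hull(xy_a)
  hb <- convex_hull(xy_b)
  inter <- clip_convex(ha, hb)
  ai <- if (nrow(inter) >= 3L) abs(polygon_area(inter)) else 0
  aa <- polygon_area(ha); ab <- polygon_area(hb)
  ratio <- ai / (aa + ab - ai)
  min(max(ratio, 0), 1)
}

# one-tailed Welch test that is defined when both samples are identical
safe_t_test <- function(x, y, alternative) {
  if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 0.5
           else if ((alternative == "less") == (mean(x) < mean(y))) 0 else 1)
  }
  stats::t.test(x, y, alternative = alternative)$p.value
}

metrics_for_set <- function(sim_routes, data_series, data_xy, window) {
  pos <- daily_positions(sim_routes, validate = FALSE)
  cl <- suppressWarnings(daily_closeness(pos))
  md <- daily_moving_distance(pos)
  data.frame(
    closeness_diff = metric_difference(cl, data_series$closeness),
    moving_diff = metric_difference(md, data_series$moving),
    smoothed_moving_diff = metric_difference(smooth_series(md, window),
                                             data_series$smoothed),
    hull_overlap = hull_overlap(cbind(sim_routes$x_m, sim_routes$y_m), data_xy)
  )
}

#' Score simulation ensembles against the data
#'
#' For every simulation set of every model: the mean relative difference in
#' daily closeness and daily moving distance (raw and 20-day smoothed)
#' against the data's series, and the convex-hull overlap ratio with the
#' data's campsites. Models are then compared with one-tailed Welch t-tests
#' of the STM ensemble against each reference (alternative: STM has smaller
#' differences, larger overlap).
#'
#' @param ensembles named list of `sim_ensemble`s with equal set counts; one
#'   name must be `stm_name`.
#' @param routes the data route table.
#' @param group group id.
#' @param stm_name name of the ensemble treated as the model under test.
#' @param window smoothing window (days).
#' @return an object of class `metrics_report`: `per_set` (one row per
#'   model and set), `summary` (means per model), `tests` (p-values per
#'   reference model and metric).
#' @export
compare_models <- function(ensembles, routes, group, stm_name = "STM",
                           window = 20L) {
  if (!stm_name %in% names(ensembles)) {
    stop("ensembles must contain one named ", stm_name)
  }
  nsets <- vapply(ensembles, function(e) length(e$sets), integer(1L))
  if (length(unique(nsets)) != 1L) stop("all ensembles must have equal set counts")
  data_routes <- routes[routes$group == group, , drop = FALSE]
  pos <- daily_positions(data_routes)
  md <- daily_moving_distance(pos)
  data_series <- list(closeness = suppressWarnings(daily_closeness(pos)),
                      moving = md, smoothed = smooth_series(md, window))
  data_xy <- cbind(data_routes$x_m, data_routes$y_m)
  per_set <- do.call(rbind, lapply(names(ensembles), function(nm) {
    rows <- do.call(rbind, lapply(seq_along(ensembles[[nm]]$sets), function(s) {
      cbind(model = nm, set = s,
            metrics_for_set(ensembles[[nm]]$sets[[s]], data_series, data_xy,
                            window))
    }))
    rows
  }))
  metrics <- c("closeness_diff", "moving_diff", "smoothed_moving_diff",
               "hull_overlap")
  summary <- do.call(rbind, lapply(split(per_set, per_set$model), function(d) {
    cbind(data.frame(model = d$model[1L]),
          as.data.frame(lapply(d[metrics], mean)))
  }))
  rownames(summary) <- NULL
  stm <- per_set[per_set$model == stm_name, ]
  tests <- do.call(rbind, lapply(setdiff(names(ensembles), stm_name), function(nm) {
    ref <- per_set[per_set$model == nm, ]
    data.frame(
      reference = nm, metric = metrics,
      p_value = vapply(metrics, function(mt) {
        alt <- if (mt == "hull_overlap") "greater" else "less"
        safe_t_test(stm[[mt]], ref[[mt]], alternative = alt)
      }, numeric(1L)),
      row.names = NULL
    )
  }))
  structure(list(per_set = per_set, summary = summary, tests = tests,
                 group = group),
            class = "metrics_report")
}
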