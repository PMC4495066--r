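# Core domain: routes, the seasonal calendar, normalisation, and table I/O.
#
# A "route table" is a plain data.frame with one row per campsite stay and
# columns pastoralist_id, year_label, group, campsite_id, x_m, y_m,
# arrival_day, duration_days. Coordinates are planar metres (the survey data
# this emulates were projected to UTM zone 33N); no geodesy is performed.
# Days are numbered 1..365 with day 1 = August 16, no leap years.

ROUTE_COLUMNS <- c("pastoralist_id", "year_label", "group", "campsite_id",
                   "x_m", "y_m", "arrival_day", "duration_days")

#' Wrap a day number into the annual cycle 1..365
#'
#' @param day integer vector (any integers, including non-positive).
#' @return integer vector in `[1, 365]`.
#' @export
wrap_day <- function(day) {
  ((as.integer(day) - 1L) %% 365L) + 1L
}

#' The five-season calendar of the study region
#'
#' Day 1 is August 16, so the year opens in the rainy season. The five
#' windows partition 1..365: rainy (1-17 and 321-365), end of rains (18-78),
#' cold dry (79-170), hot dry (171-290), beginning of rains (291-320).
#'
#' @return a data.frame with columns `season`, `start`, `end` (one row per
#'   contiguous day window; `rainy` appears twice because it straddles the
#'   year boundary).
#' @export
season_calendar <- function() {
  data.frame(
    season = c("rainy", "end_of_rains", "cold_dry", "hot_dry",
               "begin_rains", "rainy"),
    start = c(1L, 18L, 79L, 171L, 291L, 321L),
    end   = c(17L, 78L, 170L, 290L, 320L, 365L),
    stringsAsFactors = FALSE
  )
}

#' Assign days to seasons
#'
#' @param day integer vector of days in `[1, 365]`.
#' @return character vector of season labels.
#' @export
assign_season <- function(day) {
  day <- as.integer(day)
  if (any(is.na(day)) || any(day < 1L | day > 365L)) {
    stop("day must be in [1, 365]")
  }
  cal <- season_calendar()
  out <- rep(NA_character_, length(day))
  for (i in seq_len(nrow(cal))) {
    sel <- day >= cal$start[i] & day <= cal$end[i]
    out[sel] <- cal$season[i]
  }
  out
}

#' Classify stays as sojourn or transit
#'
#' A stay of at least `threshold_days` (default 20) is a sojourn camp;
#' shorter stays are transit camps along a directional path.
#'
#' @param duration_days integer vector of stay durations (days, >= 1).
#' @param threshold_days sojourn threshold in days.
#' @return character vector, `"sojourn"` or `"transit"`.
#' @export
classify_stay <- function(duration_days, threshold_days = 20L) {
  if (any(duration_days < 1)) stop("duration_days must be >= 1")
  ifelse(duration_days >= threshold_days, "sojourn", "transit")
}

#' Normalise route durations to a 365-day year
#'
#' Survey-reported stay durations do not always add up to 365 days. The
#' discrepancy is absorbed by the single longest stay of the route (ties
#' broken by earliest arrival), and arrival days are then recomputed by
#' chaining from the first stay. Routes whose longest stay would become
#' non-positive are rejected.
#'
#' @param routes a route table (one or many pastoralists).
#' @return the route table with durations summing to exactly 365 per route
#'   and arrival days rechained from each route's first stay.
#' @export
normalize_routes <- function(routes) {
  check_route_columns(routes)
  parts <- split(routes, routes$pastoralist_id)
  out <- lapply(parts, normalize_one_route)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

normalize_one_route <- function(route) {
  if (nrow(route) < 1L) stop("route has no stays")
  if (any(route$duration_days < 1L)) {
    stop("all stay durations must be positive before normalisation")
  }
  total <- sum(route$duration_days)
  disc <- 365L - total
  if (disc != 0L) {
    longest <- which(route$duration_days == max(route$duration_days))
    # ties: earliest arrival
    longest <- longest[which.min(route$arrival_day[longest])]
    newdur <- route$duration_days[longest] + disc
    if (newdur < 1L) {
      stop(sprintf(
        "route %s: 365-day adjustment of %d days would make its longest stay non-positive",
        route$pastoralist_id[1], disc))
    }
    route$duration_days[longest] <- newdur
  }
  # rechain arrival days from the first stay
  route$arrival_day <- wrap_day(route$arrival_day[1L] +
                                  c(0L, cumsum(route$duration_days[-nrow(route)])))
  route
}

check_route_columns <- function(routes) {
  missing <- setdiff(ROUTE_COLUMNS, names(routes))
  if (length(missing)) {
    stop("route table is missing columns: ", paste(missing, collapse = ", "))
  }
  invisible(routes)
}

#' Expand routes to one position per pastoralist per day
#'
#' Each stay occupies the half-open day interval
#' `[arrival, arrival + duration)`, wrapped at the year boundary. For
#' normalised routes every pastoralist therefore has exactly one location on
#' each of the 365 days.
#'
#' @param routes a normalised route table.
#' @param validate check the one-position-per-day invariant (on by default).
#' @return data.frame with columns `day`, `pastoralist_id`, `group`,
#'   `x_m`, `y_m`, sorted by day then pastoralist.
#' @export
daily_positions <- function(routes, validate = TRUE) {
  check_route_columns(routes)
  n <- nrow(routes)
  reps <- routes$duration_days
  idx <- rep.int(seq_len(n), reps)
  offs <- sequence(reps) - 1L
  out <- data.frame(
    day = wrap_day(routes$arrival_day[idx] + offs),
    pastoralist_id = routes$pastoralist_id[idx],
    group = routes$group[idx],
    x_m = routes$x_m[idx],
    y_m = routes$y_m[idx],
    stringsAsFactors = FALSE
  )
  if (validate) {
    counts <- table(out$pastoralist_id, out$day)
    if (any(counts != 1L)) {
      stop("stay intervals overlap or leave gaps: expected exactly one position per pastoralist per day")
    }
  }
  out[order(out$day, out$pastoralist_id), , drop = FALSE]
}

#' Read / write route tables
#'
#' The on-disk format is a headered CSV with one row per stay and columns
#' `pastoralist_id, year_label, group, campsite_id, x_m, y_m, arrival_day,
#' duration_days`. Extra columns (e.g. hidden ground-truth mode labels) are
#' dropped on write.
#'
#' @param path file path.
#' @return `read_routes`: a route table.
#' @export
read_routes <- function(path) {
  routes <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(pastoralist_id = "character",
                                           campsite_id = "character",
                                           year_label = "character"))
  check_route_columns(routes)
  routes$arrival_day <- as.integer(routes$arrival_day)
  routes$duration_days <- as.integer(routes$duration_days)
  routes$group <- as.integer(routes$group)
  routes
}

#' @rdname read_routes
#' @param routes a route table.
#' @export
write_routes <- function(routes, path) {
  check_route_columns(routes)
  utils::write.csv(routes[, ROUTE_COLUMNS], path, row.names = FALSE)
  invisible(path)
}
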