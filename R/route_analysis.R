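# Descriptive route analysis: stay-duration distributions by season,
# clustering of routes into the three movement groups, and per-stay
# transhumance-mode labels.

#' Empirical CDF of stay durations within a season
#'
#' Stays are attributed to the season of their arrival day (camps are dated
#' by when they are set up).
#'
#' @param routes a route table.
#' @param season a season label from [season_calendar()].
#' @return data.frame with columns `duration` and `cum_fraction`
#'   (nondecreasing, reaching 1), empty (with a warning) if the season has
#'   no stays.
#' @export
duration_cdf <- function(routes, season) {
  check_route_columns(routes)
  sel <- assign_season(routes$arrival_day) == season
  if (!any(sel)) {
    warning("no stays arrive in season ", season)
    return(data.frame(duration = integer(0), cum_fraction = numeric(0)))
  }
  d <- sort(routes$duration_days[sel])
  ud <- unique(d)
  data.frame(duration = ud,
             cum_fraction = cumsum(tabulate(match(d, ud))) / length(d))
}

#' Per-route clustering features
#'
#' For each pastoralist: the rainy-season centroid (mean location of sojourn
#' stays arriving in the rainy window), the dry-season centroid (sojourn
#' stays arriving in the cold/hot dry window), the mean signed east-west
#' offset of transit campsites from the straight line joining the two
#' centroids (east positive, metres), and the fraction of dry-season days
#' spent south of the dry-season centroid.
#'
#' @param routes a normalised route table.
#' @param threshold_days sojourn threshold (days).
#' @return data.frame, one row per pastoralist.
#' @export
route_features <- function(routes, threshold_days = 20L) {
  check_route_columns(routes)
  parts <- split(routes, routes$pastoralist_id)
  rows <- lapply(parts, function(r) {
    soj <- r$duration_days >= threshold_days
    rainy <- r$arrival_day <= 17L | r$arrival_day >= 321L
    dry <- r$arrival_day >= 79L & r$arrival_day <= 290L
    if (!any(soj & rainy) || !any(soj & dry)) {
      stop("route ", r$pastoralist_id[1],
           ": cannot compute features (needs sojourn stays in both the rainy and dry windows)")
    }
    rc <- c(mean(r$x_m[soj & rainy]), mean(r$y_m[soj & rainy]))
    dc <- c(mean(r$x_m[soj & dry]), mean(r$y_m[soj & dry]))
    # signed east-west offset of the transit path from the centroid axis
    trans <- !soj
    ew <- 0
    if (any(trans)) {
      d <- dc - rc
      nrm <- sqrt(sum(d^2))
      nvec <- if (nrm > 0) c(d[2], -d[1]) / nrm else c(1, 0)
      if (nvec[1] < 0) nvec <- -nvec
      ew <- mean((r$x_m[trans] - rc[1]) * nvec[1] +
                   (r$y_m[trans] - rc[2]) * nvec[2])
    }
    # day-weighted share of the dry season spent south of the dry centroid
    dd <- r[dry, , drop = FALSE]
    frac_south <- sum(dd$duration_days * (dd$y_m < dc[2])) / sum(dd$duration_days)
    data.frame(pastoralist_id = r$pastoralist_id[1],
               rainy_x = rc[1], rainy_y = rc[2],
               dry_x = dc[1], dry_y = dc[2],
               ew_offset = ew, frac_south = frac_south,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster routes into movement groups
#'
#' k-means (25 restarts) on standardised [route_features()]. For the default
#' k = 3 the clusters are relabelled canonically by centroid geometry:
#' group 3 is the cluster with the southernmost mean dry-season centroid
#' (its second, southern dry-season area pulls the centroid down); of the
#' remaining two, group 1 has the more south-western rainy-season centroid
#' and group 2 the more north-eastern one.
#'
#' @param routes a normalised route table.
#' @param k number of groups.
#' @param seed integer seed for the k-means restarts.
#' @return data.frame with columns `pastoralist_id` and `group`.
#' @export
cluster_routes <- function(routes, k = 3L, seed = 1L) {
  feats <- route_features(routes)
  if (nrow(feats) < k) stop("need at least k routes to form k groups")
  if (k == 1L) {
    return(data.frame(pastoralist_id = feats$pastoralist_id, group = 1L,
                      stringsAsFactors = FALSE))
  }
  x <- as.matrix(feats[, c("rainy_x", "rainy_y", "dry_x", "dry_y",
                           "ew_offset", "frac_south")])
  sds <- apply(x, 2L, stats::sd)
  if (all(sds < 1e-12)) stop("degenerate features: all routes are identical")
  x <- scale(x, scale = ifelse(sds > 1e-12, sds, 1))
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 25L, iter.max = 100L)
  grp <- km$cluster
  if (k == 3L) {
    dry_y <- tapply(feats$dry_y, grp, mean)
    g3 <- as.integer(names(which.min(dry_y)))
    rest <- setdiff(sort(unique(grp)), g3)
    sw <- tapply(feats$rainy_x + feats$rainy_y, grp, mean)[as.character(rest)]
    g1 <- rest[which.min(sw)]
    g2 <- rest[which.max(sw)]
    relabel <- integer(3L)
    relabel[c(g1, g2, g3)] <- 1:3
    grp <- relabel[grp]
  }
  data.frame(pastoralist_id = feats$pastoralist_id, group = as.integer(grp),
             stringsAsFactors = FALSE)
}

#' Fill the group column of a route table from a cluster assignment
#'
#' @param routes a route table.
#' @param assignment output of [cluster_routes()].
#' @return the route table with `group` replaced.
#' @export
apply_groups <- function(routes, assignment) {
  check_route_columns(routes)
  m <- match(routes$pastoralist_id, assignment$pastoralist_id)
  if (any(is.na(m))) stop("assignment is missing some pastoralists")
  routes$group <- assignment$group[m]
  routes
}

#' Label each stay with its transhumance mode
#'
#' Sojourn stays (>= `threshold_days`) map to the rainy-season mode M1 when
#' they arrive near the rainy window and to the dry-season mode M2 when they
#' arrive near the dry windows (the split falls at the midpoints of the two
#' transition windows, days 48 and 305). Transit stays map to M3, except for
#' group 3 where transit stays arriving in the cold/hot dry window (days
#' 79-290) are the intra-dry-season mode M4.
#'
#' @param routes a route table with `group` filled (1, 2 or 3).
#' @param threshold_days sojourn threshold (days).
#' @return the route table with a `mode` column added.
#' @export
assign_modes <- function(routes, threshold_days = 20L) {
  check_route_columns(routes)
  if (any(is.na(routes$group)) || !all(routes$group %in% 1:3)) {
    stop("all routes must have a group in {1, 2, 3}; run cluster_routes first")
  }
  soj <- routes$duration_days >= threshold_days
  arr <- routes$arrival_day
  mode <- ifelse(soj,
                 ifelse(arr >= 48L & arr <= 305L, "M2", "M1"),
                 ifelse(routes$group == 3L & arr >= 79L & arr <= 290L,
                        "M4", "M3"))
  routes$mode <- mode
  routes
}
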