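# The spatial-temporal mobility (STM) model.
#
# A pastoralist group's annual cycle is decomposed into transhumance modes:
#   M1  rainy-season sojourn  (bivariate normal)
#   M2  dry-season sojourn    (bivariate normal; two-component mixture for
#                              group 3, which uses a northern and a southern
#                              dry-season area)
#   M3  inter-seasonal transit (Brownian-bridge corridor, two occurrences:
#                              outbound and return)
#   M4  intra-dry-season transit, group 3 only (one Brownian bridge)
# Each mode also carries a temporal distribution over the day of year
# (normal, or a two-component normal mixture for the twice-occurring modes).
# The day-t location probability is the total-probability combination of the
# per-mode spatial densities weighted by the per-mode probabilities at t.

MODE_LABELS <- c("M1", "M2", "M3", "M4")

#' Gaussian spatial component
#'
#' @param mu length-2 mean location (m).
#' @param Sigma 2x2 symmetric positive-definite covariance (m^2).
#' @return an object of class `stm_gaussian`.
#' @export
stm_gaussian <- function(mu, Sigma) {
  Sigma <- matrix(as.numeric(Sigma), 2L, 2L)
  if (max(abs(Sigma - t(Sigma))) > 1e-6 * max(abs(Sigma))) {
    stop("Sigma must be symmetric")
  }
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("Sigma must be positive definite")
  }
  structure(list(mu = as.numeric(mu), Sigma = Sigma), class = "stm_gaussian")
}

#' Two-component (or k-component) bivariate normal mixture
#'
#' @param components list of [stm_gaussian()] objects.
#' @param weights nonnegative weights summing to 1.
#' @return an object of class `stm_mixture`.
#' @export
stm_mixture <- function(components, weights) {
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(weights < 0)) stop("mixture weights must be nonnegative")
  structure(list(components = components, weights = as.numeric(weights)),
            class = "stm_mixture")
}

#' Brownian-bridge transit model
#'
#' A directional transit corridor from origin `a` to destination `b` over
#' `total_time` days, starting at day `start_day`. The position at bridge
#' time t is normal with mean on the straight line between the endpoints and
#' isotropic variance `t (T - t) / T * diffusion`, zero at both endpoints.
#'
#' @param a,b length-2 origin and destination (m).
#' @param start_day day of year when the bridge starts (may be outside
#'   `[1, 365]` when a mean date was fitted on circularly unwrapped days).
#' @param total_time bridge duration T in days, > 0.
#' @param diffusion scalar diffusion parameter (m^2 per day), >= 0.
#' @return an object of class `stm_bridge`.
#' @export
stm_bridge <- function(a, b, start_day, total_time, diffusion) {
  if (total_time <= 0) stop("bridge total_time must be positive")
  if (diffusion < 0) stop("bridge diffusion must be nonnegative")
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 start_day = as.numeric(start_day),
                 total_time = as.numeric(total_time),
                 diffusion = as.numeric(diffusion)),
            class = "stm_bridge")
}

#' Bridge mean location at bridge time t
#'
#' @param bridge an [stm_bridge()].
#' @param t bridge time(s) in days since the bridge start, in `[0, T]`.
#' @return numeric matrix (length(t) x 2) of mean locations.
#' @export
bridge_mean <- function(bridge, t) {
  frac <- t / bridge$total_time
  cbind(bridge$a[1] + (bridge$b[1] - bridge$a[1]) * frac,
        bridge$a[2] + (bridge$b[2] - bridge$a[2]) * frac)
}

#' Bridge positional variance at bridge time t
#'
#' Evaluates `t (T - t) / T * diffusion`: 0 at both endpoints, maximal at
#' T/2. A variance floor can be supplied for density evaluation so the
#' endpoint distributions are not degenerate; the default reports the raw
#' law.
#'
#' @param bridge an [stm_bridge()].
#' @param t bridge time(s) in `[0, T]`.
#' @param floor minimum returned variance (m^2), default 0 (no flooring).
#' @return numeric vector of variances (m^2).
#' @export
bridge_variance <- function(bridge, t, floor = 0) {
  v <- t * (bridge$total_time - t) / bridge$total_time * bridge$diffusion
  pmax(v, floor)
}

#' Temporal mode component
#'
#' A normal (or two-component normal mixture) distribution over the day of
#' year for one transhumance mode. Mixture components are ordered by mean
#' date.
#'
#' @param tau mean date(s), day of year (possibly unwrapped outside
#'   `[1, 365]`).
#' @param sigma2 variance(s), day^2, > 0.
#' @param lambda component weight(s), summing to 1.
#' @return an object of class `stm_temporal`.
#' @export
stm_temporal <- function(tau, sigma2, lambda = rep(1 / length(tau), length(tau))) {
  if (length(tau) != length(sigma2) || length(tau) != length(lambda)) {
    stop("tau, sigma2 and lambda must have equal length")
  }
  if (any(sigma2 <= 0)) stop("temporal variances must be positive")
  if (abs(sum(lambda) - 1) > 1e-9) stop("temporal weights must sum to 1")
  o <- order(tau)
  structure(list(tau = as.numeric(tau)[o], sigma2 = as.numeric(sigma2)[o],
                 lambda = as.numeric(lambda)[o]),
            class = "stm_temporal")
}

# circular (wrapped) normal density over the 365-day year, three-term wrap:
# handles modes that straddle the year boundary (e.g. the rainy-season mode)
wrapped_dnorm <- function(t, tau, sigma2, log = FALSE) {
  sd <- sqrt(sigma2)
  shifts <- c(-365, 0, 365)
  lp <- vapply(shifts, function(s) stats::dnorm(t - s, tau, sd, log = TRUE),
               numeric(length(t)))
  lp <- matrix(lp, nrow = length(t))
  out <- apply(lp, 1L, logsumexp)
  if (log) out else exp(out)
}

temporal_log_density <- function(tc, t) {
  k <- length(tc$tau)
  lp <- vapply(seq_len(k), function(j) {
    log(tc$lambda[j]) + wrapped_dnorm(t, tc$tau[j], tc$sigma2[j], log = TRUE)
  }, numeric(length(t)))
  lp <- matrix(lp, nrow = length(t))
  apply(lp, 1L, logsumexp)
}

#' Fitted STM model for one pastoralist group
#'
#' @param group group id, 1, 2 or 3.
#' @param spatial named list of per-mode spatial models: `M1`
#'   ([stm_gaussian()]), `M2` ([stm_gaussian()] or [stm_mixture()]), `M3`
#'   (list of two [stm_bridge()]s: outbound then return), and for group 3
#'   `M4` (a single [stm_bridge()]).
#' @param temporal named list of per-mode [stm_temporal()] objects, with the
#'   same mode set as `spatial`.
#' @return an object of class `group_stm`.
#' @export
group_stm <- function(group, spatial, temporal) {
  modes <- if (group == 3L) MODE_LABELS else MODE_LABELS[1:3]
  if (!setequal(names(spatial), modes) || !setequal(names(temporal), modes)) {
    stop("mode set must be {M1, M2, M3} for groups 1-2 and {M1, M2, M3, M4} for group 3")
  }
  if (!inherits(spatial$M3[[1]], "stm_bridge") ||
      !inherits(spatial$M3[[2]], "stm_bridge")) {
    stop("spatial$M3 must be a list of two stm_bridge objects")
  }
  structure(list(group = as.integer(group), modes = modes,
                 spatial = spatial, temporal = temporal),
            class = "group_stm")
}

#' Temporal mode density
#'
#' Density of the day-of-year distribution of a mode (mixture-weighted for
#' the twice-occurring modes), evaluated with circular wrapping.
#'
#' @param model a [group_stm()].
#' @param mode one of `"M1".."M4"`.
#' @param t day(s) of year.
#' @return nonnegative density values (per day).
#' @export
temporal_mode_density <- function(model, mode, t) {
  tc <- model$temporal[[mode]]
  if (is.null(tc)) stop("no temporal parameters for mode ", mode)
  exp(temporal_log_density(tc, t))
}

#' Per-day mode probabilities
#'
#' Per-mode temporal densities renormalised across the group's mode set so
#' they sum to one at every day, evaluated in log space for stability.
#'
#' @param model a [group_stm()].
#' @param t a single day of year.
#' @return named numeric vector over the group's modes, summing to 1.
#' @export
mode_probabilities <- function(model, t) {
  stopifnot(length(t) == 1L)
  lp <- vapply(model$modes,
               function(m) temporal_log_density(model$temporal[[m]], t),
               numeric(1L))
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

# posterior weight of each occurrence of a twice-occurring mode at day t
occurrence_posterior <- function(tc, t) {
  k <- length(tc$tau)
  lp <- vapply(seq_len(k), function(j) {
    log(tc$lambda[j]) + wrapped_dnorm(t, tc$tau[j], tc$sigma2[j], log = TRUE)
  }, numeric(1L))
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

# bridge time for calendar day t: position along the bridge, circularly
# unwrapped relative to the start day and clamped to [0, T]
bridge_time <- function(bridge, t) {
  rel <- (t - bridge$start_day) %% 365
  pmin(rel, bridge$total_time)
}

# variance floor (m^2) used when a bridge density is evaluated at (or
# clamped to) its endpoints, where the raw law is degenerate
BRIDGE_VAR_FLOOR <- 1e6

bridge_density <- function(bridge, t, x) {
  bt <- bridge_time(bridge, t)
  mu <- bridge_mean(bridge, bt)[1L, ]
  v <- bridge_variance(bridge, bt, floor = BRIDGE_VAR_FLOOR)
  dmvn2(x, mu, diag(v, 2L))
}

#' Spatial density of one mode at day t
#'
#' M1 and M2 densities are (mixtures of) bivariate normals and do not depend
#' on t. M3 combines its outbound and return bridges with weights equal to
#' the temporal posterior of each occurrence at t; bridge time is clamped to
#' the bridge's span and the endpoint variance is floored at 1 km^2.
#'
#' @param model a [group_stm()].
#' @param mode one of the group's modes.
#' @param t a single day of year.
#' @param x numeric n x 2 matrix of locations (m).
#' @return density values (per m^2) at the rows of `x`.
#' @export
spatial_density <- function(model, mode, t, x) {
  x <- matrix(x, ncol = 2L)
  if (any(!is.finite(x))) stop("locations must be finite")
  sp <- model$spatial[[mode]]
  if (is.null(sp)) stop("no spatial model for mode ", mode)
  if (inherits(sp, "stm_gaussian")) {
    return(dmvn2(x, sp$mu, sp$Sigma))
  }
  if (inherits(sp, "stm_mixture")) {
    dens <- vapply(seq_along(sp$components), function(k) {
      sp$weights[k] * dmvn2(x, sp$components[[k]]$mu, sp$components[[k]]$Sigma)
    }, numeric(nrow(x)))
    return(rowSums(matrix(dens, nrow = nrow(x))))
  }
  if (inherits(sp, "stm_bridge")) {
    return(bridge_density(sp, t, x))
  }
  # list of the two M3 occurrence bridges, posterior-weighted
  gam <- occurrence_posterior(model$temporal[[mode]], t)
  dens <- vapply(seq_along(sp), function(k) {
    gam[k] * bridge_density(sp[[k]], t, x)
  }, numeric(nrow(x)))
  rowSums(matrix(dens, nrow = nrow(x)))
}

#' Grid specification
#'
#' @param xmin,ymin lower-left corner of the grid (m).
#' @param nx,ny number of columns / rows.
#' @param cellsize cell edge in metres (default 1000, i.e. a 1 x 1 km grid).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(xmin, ymin, nx, ny, cellsize = 1000) {
  structure(list(xmin = xmin, ymin = ymin, nx = as.integer(nx),
                 ny = as.integer(ny), cellsize = cellsize),
            class = "grid_spec")
}

grid_centers <- function(spec) {
  xs <- spec$xmin + (seq_len(spec$nx) - 0.5) * spec$cellsize
  ys <- spec$ymin + (seq_len(spec$ny) - 0.5) * spec$cellsize
  cbind(rep(xs, times = spec$ny), rep(ys, each = spec$nx))
}

#' Default grid extent for a fitted group model
#'
#' Bounding box of the fitted component means and bridge endpoints, padded
#' by four standard deviations of the widest component (including the
#' mid-bridge corridor spread) plus 20 km, snapped to whole cells.
#'
#' @param model a [group_stm()].
#' @param cellsize cell edge (m).
#' @param pad extra padding (m) beyond the 4-sd margin.
#' @return a [grid_spec()].
#' @export
stm_grid_spec <- function(model, cellsize = 1000, pad = 20000) {
  pts <- list(); sds <- 0
  for (m in model$modes) {
    sp <- model$spatial[[m]]
    if (inherits(sp, "stm_gaussian")) {
      pts <- c(pts, list(sp$mu))
      sds <- max(sds, sqrt(max(diag(sp$Sigma))))
    } else if (inherits(sp, "stm_mixture")) {
      for (cm in sp$components) {
        pts <- c(pts, list(cm$mu))
        sds <- max(sds, sqrt(max(diag(cm$Sigma))))
      }
    } else {
      brs <- if (inherits(sp, "stm_bridge")) list(sp) else sp
      for (b in brs) {
        pts <- c(pts, list(b$a), list(b$b))
        sds <- max(sds, sqrt(b$total_time / 4 * b$diffusion))
      }
    }
  }
  pts <- do.call(rbind, pts)
  margin <- 4 * sds + pad
  xmin <- floor((min(pts[, 1]) - margin) / cellsize) * cellsize
  ymin <- floor((min(pts[, 2]) - margin) / cellsize) * cellsize
  nx <- ceiling((max(pts[, 1]) + margin - xmin) / cellsize)
  ny <- ceiling((max(pts[, 2]) + margin - ymin) / cellsize)
  grid_spec(xmin, ymin, nx, ny, cellsize)
}

#' Build a probability grid from nonnegative cell values
#'
#' Normalises the values to sum to one over cells; used by the model grid
#' constructors and handy for hand-built grids.
#'
#' @param values nonnegative vector, one value per cell in row-major order
#'   (x varying fastest, south to north).
#' @param spec a [grid_spec()] with `nx * ny == length(values)`.
#' @return a `prob_grid`.
#' @export
prob_grid <- function(values, spec) {
  if (length(values) != spec$nx * spec$ny) stop("values do not fill the grid")
  if (any(values < 0)) stop("cell values must be nonnegative")
  new_prob_grid(values, spec, warn_coverage = FALSE)
}

new_prob_grid <- function(values, spec, renormalize = TRUE, warn_coverage = TRUE) {
  raw_mass <- sum(values) * spec$cellsize^2
  if (warn_coverage && raw_mass < 0.99) {
    warning(sprintf(
      paste("grid captures only %.1f%% of the model's probability mass;",
            "enlarge the extent, or refine the cells if they are coarser",
            "than the model's length scale"),
      100 * raw_mass))
  }
  p <- values / sum(values)
  structure(list(p = p, spec = spec, raw_mass = raw_mass),
            class = "prob_grid")
}

#' Daily location-probability grid of the STM model
#'
#' Evaluates the total-probability combination of the per-mode spatial
#' densities at the cell centres, weighted by the day's mode probabilities,
#' and renormalises over cells so the grid is a probability distribution.
#'
#' @param model a [group_stm()].
#' @param t a single day of year.
#' @param spec a [grid_spec()]; defaults to [stm_grid_spec()] of the model.
#' @return an object of class `prob_grid`: cell probabilities `p` (vector in
#'   row-major order, x varying fastest), the `spec`, and `raw_mass`, the
#'   pre-normalisation mass captured by the extent.
#' @export
location_probability_grid <- function(model, t, spec = stm_grid_spec(model)) {
  centers <- grid_centers(spec)
  mp <- mode_probabilities(model, t)
  vals <- numeric(nrow(centers))
  for (m in model$modes) {
    if (mp[[m]] > 1e-12) {
      vals <- vals + mp[[m]] * spatial_density(model, m, t, centers)
    }
  }
  new_prob_grid(vals, spec)
}

#' Highest-density region of a probability grid
#'
#' The smallest set of cells, taken in descending probability order, whose
#' total mass reaches the requested level (default the 95% contour used for
#' daily occupancy maps).
#'
#' @param grid a `prob_grid`.
#' @param mass target probability mass in (0, 1).
#' @return list with `cells` (indices into `grid$p`, descending
#'   probability), `mask` (logical vector over cells) and `enclosed_mass`.
#' @export
hdr_region <- function(grid, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  o <- order(grid$p, decreasing = TRUE)
  cum <- cumsum(grid$p[o])
  ncells <- which(cum >= mass)[1L]
  cells <- o[seq_len(ncells)]
  mask <- logical(length(grid$p))
  mask[cells] <- TRUE
  list(cells = cells, mask = mask, enclosed_mass = cum[ncells])
}

#' Count the estimable parameter symbols of a fitted group model
#'
#' Enumerates the parameter inventory of the model structure: per spatial
#' component a mean and a covariance symbol (plus mixture weights), per
#' bridge a time-varying mean symbol and a diffusion symbol, and per
#' temporal component a mean date and a variance symbol (plus mixture
#' weights). Groups 1 and 2 carry 18 symbols each and group 3 carries 30,
#' 66 in total across the three groups.
#'
#' @param model a [group_stm()].
#' @return integer symbol count.
#' @export
stm_parameter_count <- function(model) {
  n <- 0L
  for (m in model$modes) {
    sp <- model$spatial[[m]]
    if (inherits(sp, "stm_gaussian")) {
      n <- n + 2L                        # mu, Sigma
    } else if (inherits(sp, "stm_mixture")) {
      n <- n + 2L * length(sp$components) + length(sp$weights)
    } else {
      brs <- if (inherits(sp, "stm_bridge")) list(sp) else sp
      n <- n + 2L * length(brs)          # mu_{i,k,t}, Sigma_{i,k} per bridge
    }
    tc <- model$temporal[[m]]
    n <- n + 2L * length(tc$tau)         # tau, sigma^2 per component
    if (length(tc$tau) > 1L) n <- n + length(tc$lambda)
  }
  n
}

#' Export a probability grid as an ESRI ASCII raster
#'
#' @param grid a `prob_grid`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  spec <- grid$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$nx),
    sprintf("nrows %d", spec$ny),
    sprintf("xllcorner %.3f", spec$xmin),
    sprintf("yllcorner %.3f", spec$ymin),
    sprintf("cellsize %.3f", spec$cellsize),
    "NODATA_value -9999"
  ), con)
  m <- matrix(grid$p, nrow = spec$ny, ncol = spec$nx, byrow = TRUE)
  for (r in rev(seq_len(spec$ny))) {   # ASCII grids list north to south
    writeLines(paste(format(m[r, ], digits = 10, trim = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}
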