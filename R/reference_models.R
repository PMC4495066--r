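# Per-day reference models: kernel smoothing of the day's positions (KRN)
# at a fixed isotropic bandwidth, and a per-day bivariate normal (MVN).

#' Kernel density of a day's positions
#'
#' Average of bivariate normal kernels centred at the day's positions with
#' isotropic bandwidth matrix `diag(h^2, h^2)`; the kernel is the standard
#' bivariate normal, so it integrates to one.
#'
#' @param positions n x 2 matrix of same-day locations (m).
#' @param bandwidth_m kernel standard deviation h per axis (m), > 0.
#' @param x m x 2 matrix of evaluation locations.
#' @return density values (per m^2) at the rows of `x`.
#' @export
krn_density <- function(positions, bandwidth_m, x) {
  positions <- matrix(positions, ncol = 2L)
  x <- matrix(x, ncol = 2L)
  if (bandwidth_m <= 0) stop("bandwidth must be positive")
  h2 <- bandwidth_m^2
  d2 <- outer(x[, 1], positions[, 1], "-")^2 +
    outer(x[, 2], positions[, 2], "-")^2
  rowMeans(exp(-d2 / (2 * h2))) / (2 * pi * h2)
}

#' Fit a per-day reference model
#'
#' For every day of the year the model stores either the day's positions
#' plus a bandwidth (`KRN1`, `KRN5`, `KRN10`, `KRN20`; the digits are the
#' bandwidth in km) or a per-day bivariate normal MLE (`MVN`). MVN days with
#' fewer than 3 positions carry the previous day's fit forward (with a
#' warning); days with no positions at all reuse the nearest populated day.
#'
#' @param routes a normalised route table with `group` filled.
#' @param group group id.
#' @param model one of `"KRN1"`, `"KRN5"`, `"KRN10"`, `"KRN20"`, `"MVN"`,
#'   or `"KRN"` with an explicit `bandwidth_m`.
#' @param bandwidth_m kernel bandwidth in metres (overrides the model name).
#' @return an object of class `daily_model`.
#' @export
fit_reference <- function(routes, group, model = "MVN", bandwidth_m = NULL) {
  model <- toupper(model)
  pos <- daily_positions(routes[routes$group == group, , drop = FALSE])
  bydays <- split(pos, pos$day)
  daymap <- as.integer(names(bydays))
  nearest <- function(t) daymap[which.min(abs(daymap - t))]
  if (length(daymap) < 365L) {
    warning("some days have no positions; reusing the nearest populated day")
  }
  if (startsWith(model, "KRN")) {
    if (is.null(bandwidth_m)) {
      bw_km <- suppressWarnings(as.numeric(sub("KRN", "", model)))
      if (!is.finite(bw_km)) stop("give a bandwidth, e.g. model = 'KRN5'")
      bandwidth_m <- bw_km * 1000
    }
    days <- lapply(1:365, function(t) {
      d <- bydays[[as.character(nearest(t))]]
      cbind(d$x_m, d$y_m)
    })
    out <- list(type = "KRN", bandwidth_m = bandwidth_m, days = days,
                group = group)
  } else if (model == "MVN") {
    days <- vector("list", 365L)
    prev <- NULL
    carried <- 0L
    for (t in 1:365) {
      d <- bydays[[as.character(t)]]
      if (!is.null(d) && nrow(d) >= 3L) {
        xy <- cbind(d$x_m, d$y_m)
        mu <- colMeans(xy)
        Sigma <- regularize_cov(crossprod(sweep(xy, 2L, mu)) / nrow(xy), 1)
        prev <- list(mu = mu, Sigma = Sigma)
      } else {
        carried <- carried + 1L
      }
      days[[t]] <- prev
    }
    if (is.null(days[[1L]])) {
      first <- which(!vapply(days, is.null, logical(1L)))[1L]
      for (t in seq_len(first - 1L)) days[[t]] <- days[[first]]
    }
    if (carried > 0L) {
      warning(carried, " days had fewer than 3 positions; carried the nearest fit forward")
    }
    out <- list(type = "MVN", days = days, group = group)
  } else {
    stop("unknown reference model ", model)
  }
  class(out) <- "daily_model"
  out
}

#' Daily probability grid of a reference model
#'
#' Evaluates the model's day-t density at the cell centres of the same grid
#' specification used for the STM model and renormalises over cells.
#'
#' @param model a `daily_model`.
#' @param t day of year.
#' @param spec a [grid_spec()].
#' @return a `prob_grid`.
#' @export
reference_grid <- function(model, t, spec) {
  centers <- grid_centers(spec)
  vals <- if (model$type == "KRN") {
    krn_density(model$days[[t]], model$bandwidth_m, centers)
  } else {
    d <- model$days[[t]]
    dmvn2(centers, d$mu, d$Sigma)
  }
  new_prob_grid(vals, spec)
}

#' Grid extent covering a route table
#'
#' Bounding box of all campsite locations padded by `pad` metres, snapped to
#' whole cells; a common extent for comparing STM and reference grids.
#'
#' @param routes a route table.
#' @param cellsize cell edge (m).
#' @param pad padding (m); cover at least ~4 bandwidths for kernel models.
#' @return a [grid_spec()].
#' @export
data_grid_spec <- function(routes, cellsize = 1000, pad = 30000) {
  xmin <- floor((min(routes$x_m) - pad) / cellsize) * cellsize
  ymin <- floor((min(routes$y_m) - pad) / cellsize) * cellsize
  nx <- ceiling((max(routes$x_m) + pad - xmin) / cellsize)
  ny <- ceiling((max(routes$y_m) + pad - ymin) / cellsize)
  grid_spec(xmin, ymin, nx, ny, cellsize)
}

#' Daily grid for any fitted model
#'
#' Dispatches to [location_probability_grid()] for STM group models and to
#' [reference_grid()] for per-day reference models.
#'
#' @param model a [group_stm()] or `daily_model`.
#' @param t day of year.
#' @param spec a [grid_spec()].
#' @return a `prob_grid`.
#' @export
model_grid <- function(model, t, spec) {
  if (inherits(model, "group_stm")) {
    location_probability_grid(model, t, spec)
  } else if (inherits(model, "daily_model")) {
    reference_grid(model, t, spec)
  } else {
    stop("model must be a group_stm or daily_model")
  }
}
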