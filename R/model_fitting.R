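# Estimation of all STM parameters from grouped route data: selection rules
# for which stays feed which fit, maximum-likelihood normal fits, EM for the
# 1-D and 2-D two-component mixtures, Brownian-bridge diffusion estimation,
# and the derived bridge endpoints.

#' Circularly unwrap rainy-season dates
#'
#' The rainy-season mode straddles the year boundary (windows 1-17 and
#' 321-365). Days above 320 are shifted by -365 before fitting so the mode's
#' mean date near the year boundary is representable on a single axis.
#'
#' @param days integer days of year.
#' @return numeric vector on the unwrapped scale.
#' @export
unwrap_rainy_days <- function(days) {
  ifelse(days > 320, days - 365, days)
}

#' Select the stays that feed one fit
#'
#' Implements the data-selection rules: the M1 fits use sojourn stays
#' arriving in the extended rainy-season window, days 1-78 or 321-365 (with
#' temporal dates circularly unwrapped); M2 uses sojourn stays arriving in the
#' cold/hot dry window, days 79-290 for groups 1-2 and days 78-290 for
#' group 3 (both its temporal and spatial mixtures); the M4 temporal fit
#' uses group-3 transit stays arriving in days 79-290; the M3 temporal fit
#' uses the dates of the short (transit) stays assigned mode M3 across the
#' year.
#'
#' @param routes a route table with `group` filled.
#' @param group group id in {1, 2, 3}.
#' @param rule one of `"M1"`, `"M2"`, `"M4"`, `"M3"`.
#' @param threshold_days sojourn threshold (days).
#' @return the selected stays (rows of `routes`), with an `unwrapped_day`
#'   column for rule `"M1"`.
#' @export
select_fit_data <- function(routes, group, rule = c("M1", "M2", "M3", "M4"),
                            threshold_days = 20L) {
  rule <- match.arg(rule)
  r <- routes[routes$group == group, , drop = FALSE]
  if (!nrow(r)) stop("no routes in group ", group)
  r <- assign_modes(r, threshold_days)
  soj <- r$duration_days >= threshold_days
  arr <- r$arrival_day
  sel <- switch(rule,
    M1 = soj & (arr <= 78L | arr >= 321L),
    M2 = if (group == 3L) soj & arr >= 78L & arr <= 290L
         else soj & arr >= 79L & arr <= 290L,
    M3 = r$mode == "M3",
    M4 = {
      if (group != 3L) stop("mode M4 exists only for group 3")
      !soj & arr >= 79L & arr <= 290L
    })
  out <- r[sel, , drop = FALSE]
  if (!nrow(out)) stop("selection rule ", rule, " matched no stays in group ", group)
  if (rule == "M1") out$unwrapped_day <- unwrap_rainy_days(out$arrival_day)
  out
}

#' Per-pastoralist farthest dry-season stay
#'
#' The M2 spatial model for groups 1 and 2 is fitted on the set of each
#' pastoralist's single dry-season sojourn location farthest from the
#' group's rainy-season mean.
#'
#' @param routes a route table with `group` filled.
#' @param group group id (1 or 2).
#' @param mu1 fitted rainy-season mean location.
#' @param threshold_days sojourn threshold.
#' @return one selected stay per pastoralist.
#' @export
select_farthest_dry <- function(routes, group, mu1, threshold_days = 20L) {
  dry <- select_fit_data(routes, group, "M2", threshold_days)
  parts <- split(dry, dry$pastoralist_id)
  out <- do.call(rbind, lapply(parts, function(r) {
    d2 <- (r$x_m - mu1[1])^2 + (r$y_m - mu1[2])^2
    r[which.max(d2), , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' Maximum-likelihood normal fit of dates
#'
#' @param dates numeric dates (possibly unwrapped).
#' @param var_floor minimum variance (day^2) for degenerate samples.
#' @return an [stm_temporal()] with one component; the MLE uses divisor n.
#' @export
fit_normal_1d <- function(dates, var_floor = 1) {
  if (length(dates) < 2L) stop("need at least 2 dates to fit a normal")
  tau <- mean(dates)
  sigma2 <- mean((dates - tau)^2)
  if (sigma2 < var_floor) {
    warning("near-zero date variance; floored at ", var_floor, " day^2")
    sigma2 <- var_floor
  }
  stm_temporal(tau, sigma2)
}

# one EM run for a 1-D k-component normal mixture from given initial values
em_1d <- function(x, tau, sigma2, lambda, max_iter = 500L, tol = 1e-8,
                  var_floor = 1e-6) {
  n <- length(x)
  k <- length(tau)
  trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lp <- vapply(seq_len(k), function(j) {
      log(lambda[j]) + stats::dnorm(x, tau[j], sqrt(sigma2[j]), log = TRUE)
    }, numeric(n))
    lp <- matrix(lp, nrow = n)
    m <- apply(lp, 1L, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-10)) return(list(ok = FALSE))
    lambda <- nk / n
    tau <- colSums(resp * x) / nk
    sigma2 <- colSums(resp * outer(x, tau, "-")^2) / nk
    if (any(sigma2 < var_floor)) return(list(ok = FALSE))
    if (ll - ll_old < tol && iter > 1L) break
    ll_old <- ll
  }
  list(ok = TRUE, tau = tau, sigma2 = sigma2, lambda = lambda,
       loglik = ll, trace = trace)
}

#' EM fit of a two-component normal mixture of dates
#'
#' Expectation-maximisation with k-means initialisation (10 restarts kept by
#' likelihood), convergence when the log-likelihood improves by less than
#' 1e-8 or after 500 iterations, restarting from random responsibilities on
#' degenerate collapse. Components are returned ordered by mean date.
#'
#' @param dates numeric dates.
#' @param n_components number of components (1 reduces to [fit_normal_1d()]).
#' @param seed seed for the initialisations.
#' @return an [stm_temporal()]; attributes `loglik` and `loglik_trace` carry
#'   the final log-likelihood and its (nondecreasing) iteration trace.
#' @export
fit_mixture_1d <- function(dates, n_components = 2L, seed = 1L) {
  if (n_components == 1L) return(fit_normal_1d(dates))
  k <- n_components
  if (length(dates) < 2L * k) stop("need at least ", 2L * k, " dates for a ", k,
                                   "-component mixture")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(10L)) {
    if (r == 1L) {
      km <- stats::kmeans(dates, centers = k, nstart = 10L)
      grp <- km$cluster
    } else {
      grp <- sample.int(k, length(dates), replace = TRUE)
    }
    tau <- tapply(dates, grp, mean)
    sigma2 <- pmax(tapply(dates, grp, function(v) mean((v - mean(v))^2)), 1)
    lambda <- tabulate(grp, k) / length(dates)
    if (any(lambda == 0)) next
    fit <- em_1d(dates, as.numeric(tau), as.numeric(sigma2), lambda)
    if (fit$ok && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop("EM failed: degenerate collapse in all restarts")
  out <- stm_temporal(best$tau, best$sigma2, best$lambda)
  attr(out, "loglik") <- best$loglik
  attr(out, "loglik_trace") <- best$trace
  out
}

#' Maximum-likelihood bivariate normal fit of locations
#'
#' @param points n x 2 matrix of locations (n >= 3, not all collinear).
#' @param delta diagonal regularisation (m^2) applied to near-singular
#'   covariances.
#' @return an [stm_gaussian()]; covariance uses MLE divisor n.
#' @export
fit_gaussian_2d <- function(points, delta = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points")
  mu <- colMeans(points)
  cc <- sweep(points, 2L, mu)
  Sigma <- crossprod(cc) / nrow(points)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev, 1)) {
    warning("near-singular location covariance; regularised")
    Sigma <- Sigma + diag(delta, 2L)
  }
  stm_gaussian(mu, Sigma)
}

em_2d <- function(x, mus, Sigmas, lambda, max_iter = 500L, tol = 1e-8,
                  delta = 1) {
  n <- nrow(x)
  k <- length(lambda)
  trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lp <- vapply(seq_len(k), function(j) {
      log(lambda[j]) + dmvn2(x, mus[[j]], Sigmas[[j]], log = TRUE)
    }, numeric(n))
    lp <- matrix(lp, nrow = n)
    m <- apply(lp, 1L, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(list(ok = FALSE))
    lambda <- nk / n
    for (j in seq_len(k)) {
      mus[[j]] <- colSums(resp[, j] * x) / nk[j]
      cc <- sweep(x, 2L, mus[[j]])
      S <- crossprod(cc * sqrt(resp[, j])) / nk[j]
      S <- regularize_cov(S, delta)
      if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
        return(list(ok = FALSE))
      }
      Sigmas[[j]] <- S
    }
    if (ll - ll_old < tol && iter > 1L) break
    ll_old <- ll
  }
  list(ok = TRUE, mus = mus, Sigmas = Sigmas, lambda = lambda,
       loglik = ll, trace = trace)
}

#' EM fit of a two-component bivariate normal mixture of locations
#'
#' Same EM policy as [fit_mixture_1d()]; k-means initialisation, covariance
#' regularisation on near-singularity. Components are ordered north to
#' south (descending mean northing), matching the convention that the first
#' dry-season component is the northern one.
#'
#' @param points n x 2 matrix of locations (n >= 6 for two components).
#' @param n_components number of components.
#' @param seed seed for the initialisations.
#' @return an [stm_mixture()] with attributes `loglik`, `loglik_trace`.
#' @export
fit_mixture_2d <- function(points, n_components = 2L, seed = 1L) {
  x <- as.matrix(points)
  k <- n_components
  if (nrow(x) < 3L * k) stop("need at least ", 3L * k, " points")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(10L)) {
    grp <- if (r == 1L) stats::kmeans(x, centers = k, nstart = 10L)$cluster
           else sample.int(k, nrow(x), replace = TRUE)
    if (length(unique(grp)) < k) next
    mus <- lapply(seq_len(k), function(j) colMeans(x[grp == j, , drop = FALSE]))
    Sigmas <- lapply(seq_len(k), function(j) {
      xs <- x[grp == j, , drop = FALSE]
      regularize_cov(crossprod(sweep(xs, 2L, colMeans(xs))) / nrow(xs), 1)
    })
    lambda <- tabulate(grp, k) / nrow(x)
    fit <- em_2d(x, mus, Sigmas, lambda)
    if (fit$ok && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop("EM failed: degenerate collapse in all restarts")
  o <- order(vapply(best$mus, `[`, numeric(1), 2L), decreasing = TRUE)
  comps <- lapply(o, function(j) stm_gaussian(best$mus[[j]], best$Sigmas[[j]]))
  out <- stm_mixture(comps, best$lambda[o])
  attr(out, "loglik") <- best$loglik
  attr(out, "loglik_trace") <- best$trace
  out
}

#' Brownian-bridge diffusion estimate from one transit track
#'
#' Leave-out-odd-points bridge likelihood: every second interior point is
#' modelled as bivariate normal about the time-linear interpolation of its
#' two neighbours, with isotropic variance
#' `diffusion * (t_i - t_{i-1}) (t_{i+1} - t_i) / (t_{i+1} - t_{i-1})`.
#' The likelihood is maximised by bounded 1-D search on the log scale over
#' `[1, 1e9]` m^2/day.
#'
#' @param track data.frame with columns `x_m`, `y_m` and `day` (or
#'   `arrival_day`), at least 3 time-ordered points.
#' @return scalar diffusion estimate (m^2 per day).
#' @export
estimate_bb_diffusion <- function(track) {
  day <- if ("day" %in% names(track)) track$day else track$arrival_day
  o <- order(day)
  x <- track$x_m[o]; y <- track$y_m[o]; tt <- as.numeric(day[o])
  n <- length(tt)
  if (n < 3L) stop("need at least 3 points to estimate a bridge diffusion")
  idx <- seq(2L, n - 1L, by = 2L)
  dt1 <- tt[idx] - tt[idx - 1L]
  dt2 <- tt[idx + 1L] - tt[idx]
  span <- tt[idx + 1L] - tt[idx - 1L]
  keep <- dt1 > 0 & dt2 > 0
  if (!any(keep)) stop("track has no usable interior points (duplicate times)")
  ci <- (dt1 * dt2 / span)[keep]
  w <- (dt1 / span)[keep]
  mx <- x[idx - 1L] + (x[idx + 1L] - x[idx - 1L]) * w
  my <- y[idx - 1L] + (y[idx + 1L] - y[idx - 1L]) * w
  d2 <- ((x[idx] - mx)^2 + (y[idx] - my)^2)[keep]
  negll <- function(logS) {
    v <- exp(logS) * ci
    sum(log(2 * pi * v) + d2 / (2 * v))
  }
  if (sum(d2) < 1e-12) {
    warning("track deviates nowhere from the linear path; diffusion at lower bound")
    return(1)
  }
  opt <- stats::optimize(negll, interval = log(c(1, 1e9)), tol = 1e-3)
  exp(opt$minimum)
}

#' Derive the transit bridges from the fitted sojourn modes
#'
#' Bridge endpoints are the mean locations of the modes immediately
#' preceding and following each transit occurrence; bridge durations are the
#' differences of the corresponding temporal means; start days are the
#' preceding mode's temporal mean. For groups 1-2: outbound from the
#' rainy-season mean to the dry-season mean over `tau2 - tau1` days, return
#' over the remaining `365 - (tau2 - tau1)`. Group 3 substitutes the first
#' (northern) and second (southern) dry-season components, and adds the M4
#' bridge between them.
#'
#' @param mu1 rainy-season mean; `tau1` its temporal mean.
#' @param mu2 dry-season mean (groups 1-2) or list of the two components
#'   (group 3); `tau2` likewise a scalar or length-2 vector.
#' @param tau1,tau2 temporal means (days; `tau1` may be unwrapped).
#' @param diff_out,diff_ret,diff_m4 diffusion estimates (m^2/day).
#' @return list with `M3` (list of outbound and return [stm_bridge()]s) and,
#'   for group 3, `M4`.
#' @export
derive_bridges <- function(mu1, mu2, tau1, tau2, diff_out, diff_ret,
                           diff_m4 = NULL) {
  if (is.list(mu2)) {
    if (length(tau2) != 2L) stop("group 3 needs two dry-season temporal means")
    T1 <- tau2[1] - tau1
    T2 <- 365 - (tau2[2] - tau1)
    if (T1 <= 0 || T2 <= 0 || tau2[2] <= tau2[1]) {
      stop("temporal means out of order: bridge durations must be positive")
    }
    out <- list(M3 = list(
      stm_bridge(mu1, mu2[[1]], start_day = tau1, total_time = T1,
                 diffusion = diff_out),
      stm_bridge(mu2[[2]], mu1, start_day = tau2[2], total_time = T2,
                 diffusion = diff_ret)))
    if (!is.null(diff_m4)) {
      out$M4 <- stm_bridge(mu2[[1]], mu2[[2]], start_day = tau2[1],
                           total_time = tau2[2] - tau2[1], diffusion = diff_m4)
    }
    return(out)
  }
  T1 <- tau2 - tau1
  T2 <- 365 - T1
  if (T1 <= 0 || T2 <= 0) {
    stop("temporal means out of order: bridge durations must be positive")
  }
  list(M3 = list(
    stm_bridge(mu1, mu2, start_day = tau1, total_time = T1,
               diffusion = diff_out),
    stm_bridge(mu2, mu1, start_day = tau2, total_time = T2,
               diffusion = diff_ret)))
}

# split one pastoralist's M3 transit stays into the outbound / return
# occurrence by the fitted temporal posterior, and estimate a diffusion for
# each occurrence track with >= 3 points
occurrence_diffusions <- function(stays, temporal_m3) {
  post1 <- vapply(stays$arrival_day, function(t) {
    occurrence_posterior(temporal_m3, t)[1L]
  }, numeric(1L))
  occ <- ifelse(post1 >= 0.5, 1L, 2L)
  vapply(1:2, function(k) {
    tr <- stays[occ == k, , drop = FALSE]
    if (nrow(tr) < 3L) return(NA_real_)
    estimate_bb_diffusion(data.frame(x_m = tr$x_m, y_m = tr$y_m,
                                     day = tr$arrival_day))
  }, numeric(1L))
}

#' Fit the full STM model for one group
#'
#' Runs every selection rule and fit: single-normal temporal fits for M1
#' (dates circularly unwrapped), M2 (groups 1-2) and M4; EM mixtures for the
#' M3 dates and the group-3 M2 dates and locations; bivariate normal fits
#' for the M1 and M2 locations (groups 1-2 use each pastoralist's farthest
#' dry-season point); per-pastoralist Brownian-bridge diffusions averaged
#' into the group values; and the derived bridges.
#'
#' @param routes a normalised route table with `group` filled.
#' @param group group id in {1, 2, 3}.
#' @param seed seed for the EM initialisations.
#' @param threshold_days sojourn threshold (days).
#' @return list with `model` (a [group_stm()]) and `report` (data counts and
#'   log-likelihoods per fit).
#' @export
fit_group_stm <- function(routes, group, seed = 1L, threshold_days = 20L) {
  report <- list()
  m1 <- select_fit_data(routes, group, "M1", threshold_days)
  t_m1 <- fit_normal_1d(m1$unwrapped_day)
  s_m1 <- fit_gaussian_2d(cbind(m1$x_m, m1$y_m))
  report$M1 <- c(n = nrow(m1))

  if (group == 3L) {
    m2 <- select_fit_data(routes, group, "M2", threshold_days)
    t_m2 <- fit_mixture_1d(m2$arrival_day, 2L, seed = seed)
    s_m2 <- fit_mixture_2d(cbind(m2$x_m, m2$y_m), 2L, seed = seed)
    m4 <- select_fit_data(routes, group, "M4", threshold_days)
    t_m4 <- fit_normal_1d(m4$arrival_day)
    report$M2 <- c(n = nrow(m2)); report$M4 <- c(n = nrow(m4))
  } else {
    m2 <- select_fit_data(routes, group, "M2", threshold_days)
    t_m2 <- fit_normal_1d(m2$arrival_day)
    far <- select_farthest_dry(routes, group, s_m1$mu, threshold_days)
    s_m2 <- fit_gaussian_2d(cbind(far$x_m, far$y_m))
    report$M2 <- c(n = nrow(m2), n_spatial = nrow(far))
  }

  m3 <- select_fit_data(routes, group, "M3", threshold_days)
  t_m3 <- fit_mixture_1d(m3$arrival_day, 2L, seed = seed)
  report$M3 <- c(n = nrow(m3))

  diffs <- t(vapply(split(m3, m3$pastoralist_id), occurrence_diffusions,
                    numeric(2L), temporal_m3 = t_m3))
  diff_out <- mean(diffs[, 1L], na.rm = TRUE)
  diff_ret <- mean(diffs[, 2L], na.rm = TRUE)
  if (!is.finite(diff_out) || !is.finite(diff_ret)) {
    stop("too few transit points per pastoralist to estimate bridge diffusions")
  }

  if (group == 3L) {
    diff_m4 <- mean(vapply(split(m4, m4$pastoralist_id), function(tr) {
      if (nrow(tr) < 3L) return(NA_real_)
      estimate_bb_diffusion(data.frame(x_m = tr$x_m, y_m = tr$y_m,
                                       day = tr$arrival_day))
    }, numeric(1L)), na.rm = TRUE)
    mus2 <- lapply(s_m2$components, `[[`, "mu")
    bridges <- derive_bridges(s_m1$mu, mus2, t_m1$tau, t_m2$tau,
                              diff_out, diff_ret, diff_m4)
    spatial <- list(M1 = s_m1, M2 = s_m2, M3 = bridges$M3, M4 = bridges$M4)
    temporal <- list(M1 = t_m1, M2 = t_m2, M3 = t_m3, M4 = t_m4)
  } else {
    bridges <- derive_bridges(s_m1$mu, s_m2$mu, t_m1$tau, t_m2$tau,
                              diff_out, diff_ret)
    spatial <- list(M1 = s_m1, M2 = s_m2, M3 = bridges$M3)
    temporal <- list(M1 = t_m1, M2 = t_m2, M3 = t_m3)
  }
  list(model = group_stm(group, spatial, temporal), report = report)
}
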