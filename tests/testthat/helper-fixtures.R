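# Shared fixtures: datasets and fitted models are generated once per run
# and memoised, keyed by seed and route counts.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# reduced dataset for unit tests
test_dataset <- function(seed = 1L, n_routes = c(12L, 10L, 8L)) {
  key <- paste0("ds_", seed, "_", paste(n_routes, collapse = "_"))
  memo(key, generate_dataset(default_config(n_routes), seed = seed))
}

# study-scale dataset (~71 routes) for end-to-end checks
full_dataset <- function(seed = 1L) {
  memo(paste0("full_", seed), generate_dataset(default_config(), seed = seed))
}

test_fit <- function(group, seed = 1L, full = FALSE) {
  key <- paste0("fit_", group, "_", seed, "_", full)
  memo(key, {
    ds <- if (full) full_dataset(seed) else test_dataset(seed)
    fit_group_stm(ds$routes, group, seed = 1L)
  })
}

# a route table from parallel vectors, one row per stay
route_df <- function(arrival, duration, x = 0, y = 0, id = "p1",
                     group = 1L, year = "Y") {
  n <- length(arrival)
  data.frame(pastoralist_id = rep_len(id, n), year_label = rep_len(year, n),
             group = rep_len(as.integer(group), n),
             campsite_id = paste0("c", seq_len(n)),
             x_m = rep_len(x, n), y_m = rep_len(y, n),
             arrival_day = as.integer(arrival),
             duration_days = as.integer(duration),
             stringsAsFactors = FALSE)
}

# sequential sample of a true Brownian bridge at the given times
simulate_bb_track <- function(a, b, total_time, times, sigma2) {
  out <- matrix(NA_real_, length(times), 2L)
  prev <- a; tp <- 0
  for (i in seq_along(times)) {
    w <- (times[i] - tp) / (total_time - tp)
    v <- sigma2 * (times[i] - tp) * (total_time - times[i]) / (total_time - tp)
    out[i, ] <- prev + (b - prev) * w + stats::rnorm(2L, 0, sqrt(max(v, 0)))
    prev <- out[i, ]; tp <- times[i]
  }
  out
}

# toy three-mode model with well-separated components, handy for closed-form
# checks: M1 at the origin-area, M2 far north, bridges between them
toy_group_stm <- function(sd1 = 3000) {
  b1 <- stm_bridge(c(0, 0), c(0, 2e5), start_day = 10, total_time = 150,
                   diffusion = 4e6)
  b2 <- stm_bridge(c(0, 2e5), c(0, 0), start_day = 160, total_time = 215,
                   diffusion = 4e6)
  group_stm(1L,
    spatial = list(M1 = stm_gaussian(c(0, 0), diag(sd1^2, 2)),
                   M2 = stm_gaussian(c(0, 2e5), diag(4000^2, 2)),
                   M3 = list(b1, b2)),
    temporal = list(M1 = stm_temporal(10, 9),
                    M2 = stm_temporal(160, 100),
                    M3 = stm_temporal(c(60, 300), c(25, 25), c(0.5, 0.5))))
}
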