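#!/usr/bin/env Rscript
# Step 5 -- simulate transhumance routes from every fitted model and score
# them against the data.
#
# For each group, ensembles of simulated route sets (each set as large as
# the data's route count) are drawn from the STM model and the reference
# models, then compared with the data on daily closeness, daily moving
# distance (raw and 20-day smoothed) and convex-hull overlap, with
# one-tailed Welch t-tests of STM against each reference. The comparison
# protocol uses 100 sets; 20 sets on a 3 km grid keep this driver quick
# while leaving the test decisions stable.

library(stmob)

routes <- read_routes("results/routes_classified.csv")
n_sets <- 20L
cellsize <- 3000

summaries <- list(); tests <- list()
for (g in 1:3) {
  fit <- fit_group_stm(routes, g, seed = 1)
  spec <- data_grid_spec(routes[routes$group == g, ], cellsize = cellsize,
                         pad = 85000)
  models <- c(list(STM = fit$model),
              sapply(c("KRN1", "KRN5", "KRN20", "MVN"),
                     function(nm) fit_reference(routes, g, nm),
                     simplify = FALSE))
  # KRN1's 1 km kernel is under-resolved on the 3 km driver grid (cell-centre
  # quadrature captures ~99% of its mass before renormalisation); the
  # coverage warnings this triggers are expected here
  ens <- lapply(names(models), function(nm) {
    suppressWarnings(
      simulate_ensemble(models[[nm]], routes, g, spec, n_sets = n_sets,
                        master_seed = 100L + g, model_id = nm))
  })
  names(ens) <- names(models)
  rep_ <- compare_models(ens, routes, g)
  summaries[[g]] <- cbind(group = g, rep_$summary)
  tests[[g]] <- cbind(group = g, rep_$tests)
  cat(sprintf("group %d:\n", g))
  print(rep_$summary, row.names = FALSE, digits = 3)
}

summary_tab <- do.call(rbind, summaries)
tests_tab <- do.call(rbind, tests)
write.csv(summary_tab, "results/metrics_summary.csv", row.names = FALSE)
write.csv(tests_tab, "results/metrics_tests.csv", row.names = FALSE)

better <- sapply(1:3, function(g) {
  s <- summaries[[g]]
  s$moving_diff[s$model == "STM"] <= s$moving_diff[s$model == "MVN"]
})
cat(sprintf("\nSTM moving-distance difference no worse than MVN in %d of 3 groups\n",
            sum(better)))
cat("tables written to results/metrics_summary.csv and results/metrics_tests.csv\n")
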