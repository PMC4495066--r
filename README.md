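# stmob — spatial–temporal mobility modelling of pastoral transhumance

`stmob` models the annual migration cycle of mobile pastoralists from
campsite-level survey records: ordered sequences of stays (location,
arrival day, duration) that sum to a 365-day year starting on August 16.
It is written for movement ecologists and epidemiological modellers who
need the probability that a herd camps at location *x* on day *t* — the
quantity that links seasonal livestock movements to contact and disease
transmission models.

## The model

Routes fall into three movement groups (distinct rainy-season areas and
return paths). Within a group the year decomposes into *transhumance
modes*: rainy-season sojourn (M1), dry-season sojourn (M2; a northern +
southern two-component mixture for group 3), inter-seasonal transit (M3,
outbound and return), and group 3's intra-dry-season transit (M4). The
spatial–temporal mobility (STM) model combines per-mode spatial laws with
per-mode temporal laws by total probability:

    P(x_t = x) = Σ_i  P(x_t = x | s_t = M_i) · P(s_t = M_i)

with `x | M1, M2  ~  N(μ_i, Σ_i)` (or a mixture `Σ_k w_k N(μ_{2,k},
Σ_{2,k})`), Brownian-bridge transit `x | M3, M4 ~ N(a + (b − a) t/T,
σ²(t) I)`, `σ²(t) = t(T − t)/T · Σ_i`, and normal (or two-component
mixture) temporal laws `N(τ_i, σ_i²)` over the day of year. Fitting uses
fixed stay-selection rules (sojourn = stays of ≥ 20 days), maximum
likelihood, EM for the mixtures and a leave-out-odd-points bridge
likelihood for the diffusions — 66 parameter symbols across the three
groups. Daily probability fields are discretised on a 1 × 1 km grid and
summarised by 95% highest-density regions. Two per-day reference models
(kernel smoothing at 1/5/10/20 km bandwidths; a daily bivariate normal)
are fitted on the same grid, and all models are compared by simulating
route ensembles and scoring daily closeness, daily moving distance (raw
and 20-day smoothed) and convex-hull overlap, with one-tailed Welch
t-tests.

The survey data the method was designed around are not publicly deposited,
so the package ships a first-class synthetic-data generator
(`generate_dataset()`, `default_config()`) that emulates the study design
from a documented ground truth and retains hidden mode labels, making the
whole pipeline testable end to end. See the methods vignette
(`vignettes/stm-transhumance.Rmd`) for the model, the estimation rules and
the generator's assumptions.

## Worked example

```r
library(stmob)

ds     <- generate_dataset(default_config(), seed = 1)   # 71 synthetic routes
routes <- apply_groups(ds$routes, cluster_routes(ds$routes, k = 3, seed = 1))
fit    <- fit_group_stm(routes, group = 1, seed = 1)
m      <- fit$model

round(c(tau1 = m$temporal$M1$tau, tau2 = m$temporal$M2$tau,
        tau3 = m$temporal$M3$tau), 1)
#>  tau1  tau2 tau31 tau32
#> -12.9 166.3  62.1 306.3
```

Group 1's rainy-season mode peaks at day −12.9 (≈ day 352: early August,
just before the epoch — rainy-season dates are fitted on a circularly
unwrapped axis), the dry-season mode at day 166, and the two transit
occurrences at days 62 and 306 — departure at the end of the rains,
return at the start of them. The fitted rainy-season centre is

```r
round(m$spatial$M1$mu / 1000, 1)   # km, UTM-33N-like plane
#> [1]  407.2 1147.0
```

within ~1 km of the generator's ground truth (408, 1147). On day 40 the
temporal model puts the group in transit,

```r
round(mode_probabilities(m, t = 40), 3)
#>    M1    M2    M3
#> 0.037 0.083 0.879
```

and the daily occupancy surface on the 1 km grid encloses 95% probability
in 3,504 km²:

```r
grid <- location_probability_grid(m, t = 40)
hdr  <- hdr_region(grid, mass = 0.95)
c(cells = length(hdr$cells), mass = round(hdr$enclosed_mass, 4))
#>  cells   mass
#>   3504   0.95
```

## The analysis workflow

The numbered drivers under `analysis/` run the study pipeline and write
their tables under `results/`:

1. `01_generate_data.R` — draw the synthetic survey (71 routes) and write
   the route table.
2. `02_describe_modes.R` — seasonal stay-duration CDFs, route clustering
   into the three groups, per-stay mode labels.
3. `03_fit_models.R` — fit the STM model per group; write the 66-symbol
   parameter table and the recovery check against the ground truth.
4. `04_predict_surfaces.R` — daily probability surfaces and 95% region
   areas for STM and the reference models; example ESRI ASCII export.
5. `05_compare_models.R` — simulation ensembles for every model, metric
   tables and one-tailed t-tests.

Each script prints what it found; run them in order from the repository
root with `Rscript analysis/0X_....R`.

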