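# aquadyn

Spatio-temporal dynamics and occupancy–abundance modeling of drinking-water
microbiomes.

Drinking water leaving a treatment plant (DWTP) carries a diverse planktonic
bacterial community into the distribution system (DWDS). Utilities that want
to *predict* that community — rather than just monitor it — need to know how
much of its variation is spatial (pipe layout, biofilm seeding along the
water path), how much is temporal (seasonal cycling of source water,
temperature and treatment chemistry), and whether simple macroecological
laws link how *abundant* a taxon is to how *often* it is detected. `aquadyn`
implements the complete analysis chain for a monthly, multi-location
16S-amplicon survey of such a system, plus a synthetic-survey generator so
every stage runs and is tested without external data.

## What the package computes

- **Rarefied diversity** (`rarefy`, `alpha_metrics`, `beta_matrix`,
  `average_beta`, `pcoa`): subsampling without replacement to a common
  depth over many events; richness, Shannon H, the Chao–Shen coverage-adjusted
  ("nonparametric") Shannon, evenness; Bray-Curtis, Jaccard, and weighted /
  unweighted UniFrac (native branch-mass implementation, cross-checked
  against phyloseq), averaged over subsampling events.
- **Permutation statistics** (`permanova`, `anosim`, `mantel`,
  `beta_dispersion`): one-way PERMANOVA (pseudo-F, R² = SS_between/SS_total),
  ANOSIM on tied ranks, Mantel matrix correlation — each with the
  (1+b)/(1+n) permutation p-value and an exact exhaustive-enumeration mode —
  and distance-to-centroid beta dispersion with ANOVA + Tukey HSD.
- **Pipe-network distance decay** (`pipe_network`, `shortest_water_path`,
  `distance_decay`, `site_specific_otus`): shortest water paths over the
  pipe inventory; total length, total surface area (π·d·L) and age-weighted
  variants correlated with time-averaged community dissimilarity between
  locations.
- **Temporal dynamics** (`time_lag_curve`, `dwtp_divergence`): within-location
  beta diversity binned by month lag (an annually cycling community peaks at
  lag 6–7 and dips at lag 11–12), and per-location divergence from the
  same-month DWTP sample.
- **Robust MIC association networks** (`mic`, `robust_associations`,
  `extract_clusters`, `network_stats`, `cluster_timeseries`,
  `cluster_unifrac_test`): the maximal information coefficient
  (MIC = max over a×b grids, a·b ≤ n^0.6, of I/log min(a,b); Rcpp kernel,
  exhaustive oracle for n ≤ 10); an edge is kept only if discovered with
  MIC > 0.4 and Bonferroni-corrected p < 0.05 in enough rarefaction events
  with a consistent regression-slope sign; positive-edge components define
  seasonal clusters.
- **Interspecific occupancy–abundance models (IOAM)** (`occupancy_points`,
  `ioam_fit`, `compare_models`, `monthly_alpha_envelope`): per-OTU-per-month
  mean relative abundance μ and detection frequency f, averaged over
  subsampling events; maximum-likelihood fits (binomial log-likelihood,
  Brent search over ln α) of

  | model | P(μ) |
  |---|---|
  | Poisson | 1 − e^(−μ) |
  | Nachman | 1 − e^(−αμ) |
  | Hanski-Gyllenberg | αμ / (1 + αμ) |
  | power | min(αμ, 1) |
  | negative binomial | 1 − (1 + μ/k)^(−k) |

  (β fixed at 1 throughout), ranked by log-likelihood with mean absolute
  deviance; plus a month-randomization permutation envelope for the monthly
  Hanski-Gyllenberg α.
- **Synthetic surveys** (`synthetic_spec`, `generate`, `worked_fixture`,
  `simulate_occupancy`): a stated-world generator — 15 months × (DWTP + 9
  locations in 3 sectors), lognormal abundances, two anti-phase 12-month
  seasonal clusters, an 881-section ~46 km pipe inventory, distance-scaled
  multiplicative perturbation, location-specific OTU pools, and presence
  thinning that imposes a chosen occupancy law (default Hanski-Gyllenberg,
  α = 896) at the analysis depth — with full ground-truth bookkeeping.
- **Orchestration** (`run_config`, `run_all`): all stages in dependency
  order with derived per-stage seeds and a JSON manifest of md5-hashed
  outputs.

## Worked example

```r
library(aquadyn)

g  <- generate(synthetic_spec(n_otus = 600, seed = 19))
ev <- rarefy(g$table, rarefaction_plan(depth = 834, n_events = 10, base_seed = 4))
pts <- occupancy_points(ev, g$meta)
compare_models(pts)
```

```
              model        alpha      logL        mad       sad    convergence
1 hanski_gyllenberg    813.24317 -18264.88 0.02735122  163.5603      converged
2           nachman    473.18117 -19781.00 0.04710561  281.6915      converged
3             power     99.38439 -28949.80 0.10597137  633.7088      converged
4           poisson           NA -71885.18 0.19885703 1189.1650 not_applicable
5 negative_binomial 229578.63700 -71885.18 0.19885703 1189.1650      converged
```

The generator planted a Hanski-Gyllenberg occupancy law with α = 896: the
fit ranks that model first and recovers α ≈ 813, a ~9% underestimate from
sequencing-loss truncation at this scale (half-occupancy at
μ ≈ 1/α ≈ 0.11% relative abundance). Nachman, its close cousin, ranks
second; Poisson (no free parameter — its poor fit indicates the community is
not a random draw from one abundance distribution, i.e. it is dispersal
limited), power and negative binomial trail far behind, the latter drifting
to a huge k where it degenerates into Poisson.

The numbered scripts under `analysis/` run the full workflow on a generated
survey (`01_simulate.R` → `05_occupancy_models.R`), writing tables under
`results/` and narrating what each stage finds.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the pipeline's main computations from scratch against the installed
package — a full `run_all()` pass on a generated survey (rarefied
diversity, permutation statistics, distance decay, lag curves, association
network, occupancy models) and a survey-scale occupancy-law fit — and
writes the results JSON to `--out`.
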