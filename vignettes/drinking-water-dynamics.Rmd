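---
title: "Methods: spatio-temporal dynamics and occupancy-abundance modeling of drinking-water microbiomes"
author: "aquadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drinking-water microbiome dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aquadyn)
```

`aquadyn` analyzes monthly amplicon surveys of drinking-water systems: a
treatment plant (DWTP) plus sampling locations spread over distribution-system
(DWDS) sectors, observed over many months. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not establish. It states no empirical
result that the test suite or the `analysis/` scripts do not themselves
compute.

## Rarefaction and diversity

All diversity quantities are computed after subsampling every sample,
without replacement, to a common depth (a multivariate hypergeometric draw
per sample). The depth default is 834 reads — the shallowest retained sample
of the motivating survey design — and samples below the depth are dropped
and itemized, never silently. Because single rarefactions are noisy, every
metric is averaged over `n_events` independent events; event *e* uses seed
`base_seed + e`, so any event is reproducible in isolation. Defaults: 100
events for the association and occupancy stages, 1,000 for headline
diversity matrices (both configurable; the tests and the workflow scripts
use fewer events and say so — the estimate is unbiased at any event count,
only its Monte-Carlo error changes).

Alpha diversity: richness (observed OTUs), Shannon H = −Σ pᵢ ln pᵢ,
Shannon evenness H/ln(richness), and the Chao–Shen coverage-adjusted
("nonparametric") Shannon estimator: with coverage C = 1 − f₁/n (f₁
singletons, n reads), adjusted proportions p̃ = C·p enter
−Σ p̃ ln p̃ / (1 − (1−p̃)ⁿ). Degenerate guards: evenness at richness 1 is
defined as 0 (ln 1 in the denominator); when every taxon is a singleton,
C = 0 and the estimator is undefined, so f₁ is replaced by n−1 — the
standard fix in the ecosystem the estimator comes from.

Beta diversity: Bray-Curtis (Σ|x−y| / Σ(x+y)) and binary Jaccard
(1 − shared/union) are delegated to vegan. UniFrac is implemented natively
by postorder branch-mass accumulation over the rooted OTU phylogeny:
unweighted UniFrac is unshared branch length over the branch length of the
pair's union; weighted UniFrac is Σ bᵢ|p_{Ai} − p_{Bi}| normalized by
Σ bᵢ(p_{Ai} + p_{Bi}), which bounds it in [0, 1]. This normalization is
mathematically identical to the root-to-tip weighting used by the
field's standard toolchains (each leaf's mass contributes once per branch on
its root path), and the test suite cross-checks both variants against
phyloseq to machine precision. Event-level distance matrices are averaged
element-wise — metric values are averaged over events, not abundances
before the metric.

Principal coordinates use Gower double-centering (`cmdscale`); negative
eigenvalues are reported, never dropped, because Bray-Curtis matrices are
routinely non-Euclidean.

## Permutation statistics

One-way PERMANOVA, ANOSIM and Mantel are implemented natively because the
package needs (i) the exact statistic definitions below and (ii) an
exhaustive-enumeration mode for small n that standard implementations do not
expose; vegan's `adonis2`, `anosim` and `mantel` serve as independent
cross-checks in the tests.

* PERMANOVA: SS_total = Σ d²/n over all pairs, SS_within summed per group
  with the same convention, pseudo-F = (SS_b/(a−1))/(SS_w/(n−a)),
  R² = SS_b/SS_total.
* ANOSIM: R = (mean between-group rank − mean within-group rank)/(M/2) on
  average-tied ranks of the n(n−1)/2 distances.
* Mantel: Pearson correlation of the off-diagonal vectors, permuting
  rows/columns of one matrix.

Random-permutation p-values use the (1+b)/(1+n_perm) estimator under a
caller-supplied seed (default n_perm = 999). In exhaustive mode all n!
relabelings are enumerated (identity included) and p is the proportion with
statistic ≥ observed; this is the convention the brute-force oracles in the
tests reproduce independently. Beta dispersion delegates to
`vegan::betadisper` (distance to group centroid in the PCoA embedding with
imaginary-axis correction) followed by one-way ANOVA and Tukey HSD —
vegan is the canonical implementation here and was the motivating survey's
own tool; groups of size 1 and all-zero dispersions are flagged rather than
fed to ANOVA.

The core-community curve filters OTUs by grand-mean relative abundance or
by detection frequency (thresholds in percent, strict `>` comparisons),
rebuilds Bray-Curtis on the retained subset, and Mantel-correlates it
against the full matrix; points retaining fewer than 3 OTUs are flagged and
their r omitted.

## Pipe network and distance decay

The pipe inventory (section endpoints, length m, diameter m, install year,
material) becomes an undirected graph whose edges carry length, surface
area (π·d·L exactly), and age at a reference date (default the campaign
midpoint). The "shortest water path" minimizes total length; among
equal-length paths the smaller total surface wins, then the
lexicographically smallest node sequence — full determinism so that
manifests hash identically. "Age-weighted length" is Σ(L_e × age_e)
(length-years), and analogously for surface; the source material names but
never defines these quantities, so the definition is stated here and kept
in one place. Distance decay is the Pearson correlation between each path
metric and time-averaged community dissimilarity over all within-sector
location pairs (the location-level matrix averages same-month
between-location distances over months). An alternative anchoring every
pair at the DWTP is possible but not implemented; within-sector all-pairs
matches the way the motivating survey describes its sector comparisons.

## Time lags and plant divergence

The lag curve takes all within-location sample pairs, bins them by month
difference (calendar-month resolution; same-month replicates are one time
point), and reports mean, population variance and pair count per lag. The
sum of pair counts equals the total within-location pair count — an
invariant the tests assert. Divergence from the plant is the distance of
each DWDS sample to the same-month DWTP sample, aggregated per location and
sector; months without a plant sample are skipped with a warning.

## MIC association networks

MIC(x, y) is the maximum over axis-aligned grids (a columns × b rows,
a·b ≤ B(n), a, b ≥ 2) of the grid's mutual information normalized by
log min(a, b). B(n) = max(4, ⌊n^0.6⌋): the exponent 0.6 is the published
default of the MINE family; the floor at 4 exists because for n < 11,
n^0.6 < 4 would admit no grid at all, yet the method is defined from n = 8.
For n ≤ 10 every admissible grid over distinct-value cut points is
enumerated exactly (this is also the tests' independent oracle, reimplemented
in R); for larger n the standard heuristic applies — equipartition one axis,
dynamic programming over clump boundaries on the other (clump factor 15),
both orientations. The DP exploits the column-additivity of
H(P) − H(P,Q), so each segment contributes −(m/n)log(m/n) + Σ_q
(m_q/n)log(m_q/n) independently. The heuristic can only under-estimate the
true maximum; a property test asserts it never exceeds the exhaustive value.

The robustness protocol mirrors the survey design: OTUs must exceed a 30%
detection frequency in **every** rarefaction event; within an event a pair
is tested only if jointly detected in ≥ ceil(0.7·N) samples (and at least
21 — the absolute floor and the fraction are both parameters because the
source material's "minimum of 21 data points" is arithmetically
inconsistent with its own sample count at the 70% gate); an edge requires
MIC > 0.4 with Bonferroni-corrected p < 0.05 in ≥ `min_discoveries` events
(default 10 of 100) and a regression-slope sign that never flips.

p-values deserve a note. A plain permutation p is floored at 1/(n_null+1),
so with thousands of pairs per event no pair could ever clear Bonferroni
correction — the published protocol relied on its tool's large precomputed
null tables. `robust_associations` therefore draws one shared null per
event size (MIC of a random permutation of ranks; ties are thereby
approximated by a tie-free null) and extends its extreme tail with an
exponential peaks-over-threshold fit to the top 50 exceedances, giving
finite, Bonferroni-correctable tail probabilities. The single-pair `mic()`
keeps the literal permutation of the supplied vector. Edge strength is the
median MIC over discovering events (the source does not state its summary).

Cluster extraction: candidate clusters are connected components of the
positive-edge subgraph. A node whose positive edges *bridge* two otherwise
separate candidates makes them one component, so bridges are peeled
iteratively: articulation points whose removal splits their component into
≥ 2 parts of ≥ 2 nodes, lowest degree first (ties lexicographic), become
"unassigned". Nodes with only negative surviving edges are "unassigned";
degree-0 nodes are "isolated". A validation report lists any within-cluster
negative edges rather than hiding them. Network statistics (density over
the connected node set and per cluster, mean local clustering coefficient
with degree < 2 contributing 0) are delegated to igraph and verified
against hand counts. Note the source material's Results and Discussion
disagree about which seasonal cluster has density 0.38 versus 0.1;
`network_stats` simply reports both densities.

## Occupancy–abundance models

For each OTU and month, μ is the mean over events of the month's mean
relative abundance and f the mean over events of the month's detection
fraction; because the sample set is identical across events this equals
regrouping event-averaged matrices, which is what makes the
1,000-permutation envelope affordable. Zero-μ points are dropped (μ > 0
implies f > 0 for extracted points).

The five model forms (Poisson, Nachman, Hanski-Gyllenberg, power, negative
binomial; β fixed at 1) are fitted by maximizing the binomial log-likelihood
Σ [o ln P + (n−o) ln(1−P)] with **fractional** successes o = f·n_sites —
the central modeling decision: f is averaged over subsampling events, so
integer occupancies do not exist. P is clipped to [1e-12, 1−1e-12] with
clip events counted and reported; the power model is additionally clipped
at 1 inside the likelihood since αμ can exceed it. Optimization is Brent's
bounded search over ln α ∈ [ln 1e-6, ln 1e9], tolerance 1e-10; a solution
within 1e-6 of a bound is flagged "boundary". The Poisson form has no free
parameter, so its row reports an evaluation with flag "not_applicable" —
this reconciles the odd "did not converge" phrasing sometimes attached to
it. Goodness of fit is reported as both mean and sum of |f − P|. Points are
binomially weighted by n_sites; the unweighted alternative (each (μ, f)
pair equal) was considered and rejected because months differ in sample
count after depth filtering.

The monthly envelope shuffles month labels among samples *within each
location* (spatial structure preserved), recomputes occupancy points per
pseudo-month and refits the Hanski-Gyllenberg model, reporting observed
monthly α against the permutation min/Q1/Q3/max. The overall fit pools all
months' points, matching a whole-campaign fit rather than any single
month.

`simulate_occupancy` draws (μ, f) directly from a law — binomial occupancy
at P_model(α, μ) — for parameter-recovery testing. Two deliberate choices:
simulated f = 0 points are retained (the generator knows the taxon was
present, keeping the MLE unbiased, unlike extraction from count tables
where an undetected month is indistinguishable from absence), and μ can be
left unnormalized at a fixed scale, because with proportions summing to 1
the total Fisher information for α is bounded (≈ n_sites·α) regardless of
OTU count — so only the fixed-scale mode can exhibit error shrinking with
more OTUs, and the tests use it for exactly that property.

## The synthetic world

`generate()` emulates the survey's processed data: 15 months × (DWTP + 9
locations in 3 sectors; sector 1 a linear chain, sectors 2 and 3 branched),
lognormal baseline abundances (σ_log = 2, a typical amplicon rank-abundance
spread), two disjoint anti-phase seasonal clusters (defaults 25 and 30
members, 12-month sinusoid of log-amplitude 1.5, peaks in mid-winter and
mid-summer, membership interleaved across the abundance range), per-sample
depths lognormal around ~2,800 reads (so a realistic handful of samples
falls below depth 834 and is dropped by rarefaction), an 881-section
46 km pipe inventory with five materials and 1920–2010 install years, a
multiplicative abundance perturbation whose log-sd grows with pipe distance
from the plant (default 3×10⁻⁵ per meter), and location-specific OTU pools
drawn from the most abundant non-cluster OTUs so they are detectable.
Occupancy is imposed by presence thinning: presence probability solves
p·(1 − exp(−d·μ/p)) = P_law(α, μ) by fixed point (capped at 1), so realized
month-level detection targets the law *after* multinomial sequencing loss
at the analysis depth d (`law_depth`, default 834). Counts are multinomial
at each sample's depth. The same spec and seed give byte-identical output;
ground truth (memberships, law, decay rate, unique lists, pipe distances,
depths) is returned alongside.

What the generator does *not* emulate: taxonomic composition, chimeras and
PCR bias, biofilm dynamics, water chemistry covariates (metadata carries
the structural columns only), hydraulics and flow direction, and any
asymmetry between the two seasonal clusters. A green test on generated data
therefore establishes that the estimators recover planted structure of the
stated kind and size — not that real systems have that structure. Two
emergent behaviors are worth noting: seasonal cluster turnover makes winter
months the least dispersed (the direction the motivating survey reported),
and planted seasonality pushes observed monthly α outside the
month-randomization envelope — the envelope stays calibrated (≥ 95% of
months inside) only in the structureless world, which is what the null
acceptance test asserts.

## Numerical conventions

- Distance matrices must be symmetric within 1e-9 and are re-symmetrized
  to (D + Dᵀ)/2 with an exactly zero diagonal; files store full double
  precision (`%.17g`) so round trips are lossless.
- All randomized routines take explicit seeds; rarefaction event *e* uses
  `base_seed + e`; `run_all` derives per-stage seeds from the master seed by
  stage-name hashing so toggling stages never shifts another stage's draw.
- Permutation p-values never report 0: random mode uses (1+b)/(1+n);
  statistic comparisons use a 1e-12 slack to absorb float noise.
- Counts are stored as doubles carrying exact integers (R integer overflow
  starts at 2³¹ total reads).

## Known limitations

- PERMANOVA is one-way only; no strata, covariates or db-RDA.
- The MIC null shared across pairs ignores each pair's tie structure
  (zeros after rarefaction); the peaks-over-threshold tail is an
  extrapolation, honest about being one.
- `extract_clusters` peeling is a heuristic; adversarial graphs with nested
  articulation structure may peel more nodes than a human would.
- The envelope's min/max whiskers are order statistics of `n_reps` draws;
  with few reps the box is narrow and the observed α will sit outside more
  often than the nominal rate.
- UniFrac cost is O(branches × pairs) per event; for surveys much larger
  than ~10³ OTUs × 10² samples the event count is the knob to turn down.
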