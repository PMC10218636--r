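# sretools

Modeling and analysis of **scale-down stimulus–response experiments
(SREs)** in glucose-limited anaerobic chemostats — for bioprocess
engineers and transcriptomics analysts who study how production organisms
react to the substrate-starvation zones of large-scale fermenters.

A scale-down SRE holds a chemostat culture (here: 1.7 L, D ≈ 0.10 h⁻¹,
50 g/L glucose feed) at steady state, then switches the feed off for two
minutes — once (s-LSL), or repeatedly in a 2-min-off/7-min-on cycle whose
cycle-averaged *dynamic steady state* (DS) is compared against the
continuous *reference steady state* (RS). `sretools` implements both
halves of such a study:

**Bioprocess side**

* Monod uptake kinetics q(S) = q_max·S/(K_S+S) in carbon-mole units, and
  the chemostat balances
  dS/dt = D(t)(S_feed−S) − q(S)·X, dX/dt = (Y_X/S·q(S)/c_X − D(t))·X,
  integrated with a stiff adaptive solver under piecewise-constant feed
  programs (`simulate_sre()`, `dilution_profile()`, `steady_state()`)
* Estimation of (q_max, K_S) from feed-off depletion profiles via the
  integrated Monod relation K_S·ln(S₀/S) + (S₀−S) = q_max·X·t
  (`fit_uptake_kinetics()`)
* Biomass-specific rates, C-mol yields, carbon recovery, unknown carbon,
  equilibrium ethanol stripping, Welch comparisons
  (`specific_rate()`, `carbon_recovery()`, `stripping_fraction()`, ...)

**Transcriptome side**

* Negative-binomial GLM likelihood-ratio differential expression with
  median-of-ratios normalization and empirical-Bayes dispersion shrinkage,
  at the study thresholds |log2FC| ≥ 1, BH-FDR < 10⁻³ (`deg_test()`)
* Standardized-trajectory k-means clustering and hypergeometric
  enrichment with display tiers (`kmeans_profiles()`,
  `enrich_hypergeometric()`)
* Set-level Welch t statistics on log2 counts and **exact multi-set
  intersection tests** — the null distribution of the intersection of m
  gene lists by propagated conditional hypergeometrics
  (`set_t_statistic()`, `multiset_intersection_pvalue()`)
* Seeded synthetic-data generators for both measurement types and a
  seven-stage pipeline driver (`gen_count_matrix()`,
  `run_sre_pipeline()`)

## Worked example

```r
library(sretools)

kin <- uptake_kinetics(q_max = 71.50, K_S = 6.19)  # reference-state kinetics
cfg <- reactor_config()                            # 1.7 L, 50 g/L feed

# uptake at the residual glucose level (0.86 mmol/L = 5.16 mmol_C/L)
round(100 * uptake_fraction(5.16, kin))   # 45  (% of q_max)
round(100 * uptake_fraction(1.68, kin))   # 21  (% of q_max at the minimum)
round(monod_rate(1.68, kin) / 6, 1)       # 2.5 (mmol glucose/g/h)

# a two-minute starvation pulse from the steady state
traj <- simulate_sre(cfg, feed_schedule(c(2, 13), c(0, 2.83)), kin,
                     init = list(glucose = 5.16, biomass = 5.06),
                     horizon = 15)
min(traj$glucose) / 6                     # 0.226 mmol/L at the pulse end
recovery_time(traj[traj$time_min >= 2, ], S_ref = 5.16)  # 7.48 min

# differential expression on a synthetic two-condition experiment
fx  <- gen_two_group_counts(n_genes = 2000, spike_fraction = 0.1,
                            lfc = 2, seed = 7)
deg <- deg_test(fx$counts, fx$design)
table(deg$status)
#> down   ns   up
#>   99 1813   88
```

The pulse bottoms out at 0.226 mmol/L glucose (the study observed 0.28,
i.e. uptake throttled to ~21 % of capacity) and recovers to within 5 % of
the steady state about 7.5 minutes after feed resumption. On the
synthetic experiment the DEG stage recovers 187 of the 200 spiked genes
with zero false calls at the study thresholds.

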