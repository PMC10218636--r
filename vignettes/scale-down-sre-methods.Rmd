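---
title: "Modeling scale-down stimulus-response experiments: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling scale-down stimulus-response experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sretools)
```

## The system

Industrial-scale fed-batch fermenters are poorly mixed: cells circulating
through the broth repeatedly traverse zones where the limiting substrate is
locally exhausted. `sretools` models the laboratory scale-down version of
this situation — a glucose-limited anaerobic chemostat (1.7 L working
volume, dilution rate D ~ 0.10 1/h, 50 g/L glucose feed) in which the feed
pump is switched off for 2 minutes to impose a
limitation–starvation–limitation (LSL) cycle, either once (s-LSL, probing
the naive response) or repeatedly in a 2-min-off / 7-min-on program whose
cycle-averaged state defines a *dynamic steady state* (DS) against the
continuous *reference steady state* (RS). The package covers both sides of
such an experiment: the bioprocess quantities (uptake kinetics, rates,
yields, carbon balance, ethanol stripping) and the transcriptome statistics
(differential expression, trajectory clustering, enrichment, gene-set and
intersection tests), plus seeded generators that emulate the study's data
so every stage is testable without external downloads.

## Chemostat model

Glucose uptake follows Monod kinetics, q(S) = q_max S / (K_S + S),
parameterized in carbon units (mmol_C; glucose counts 6 C). All broth
balances are the standard chemostat ODEs with a piecewise-constant
dilution rate D(t) = F(t)/V:

* dS/dt = D(t) (S_feed − S) − q(S) X
* dX/dt = (Y_X/S q(S) / c_X − D(t)) X
* dP_i/dt = Y_i q(S) X − D(t) P_i

with X in g dry biomass/L and c_X the biomass carbon content in mmol_C/g.
During feed-off segments the harvest control is inactive as well, so all
dilution terms vanish and the volume stays constant. CO2 is carried as an
ordinary product stream so that the carbon balance closes exactly when the
yields sum to one; `carbon_balance()` checks this on any simulated
trajectory (closure to < 0.1 % of carbon fed in the tests).

Integration uses `deSolve::lsoda` (stiff-capable, adaptive) restarted at
every segment boundary at relative tolerance 1e-8 / absolute 1e-10, with
output on a 1-second grid for horizons up to 30 min — the 2-minute pulse
needs sub-minute resolution. During a feed-off segment with constant
biomass the model admits the integrated Monod relation

K_S ln(S0/S) + (S0 − S) = q_max X t,

which `integrated_monod()` inverts by bisection. Because that closed form
never touches the ODE solver, the two routes cross-check each other (they
agree to < 0.5 % in the tests, the residual being the slight biomass growth
during the pulse).

Two numerical facts worth knowing: the analytic steady state
(`steady_state()`) reproduces the study's operating point — residual
glucose 0.87 mmol/L and 5.05 g/L biomass from the printed kinetic and
yield parameters — and a simulation switched from that state to the cyclic
feed program settles onto its periodic orbit essentially immediately, with
cycle-averaged dilution equal to the net D to 1e-6.

### Default parameters

| parameter | default | unit | origin |
|---|---|---|---|
| q_max (RS) | 71.50 | mmol_C/g/h | process table, estimated |
| K_S (RS) | 6.19 | mmol_C/L | process table, estimated |
| maintenance | 0.5 | mmol glucose/g/h | literature value used by the study |
| Y_X/S | 0.114 | C-mol/C-mol | process table |
| f_C (biomass carbon) | 0.45 | g_C/g | chosen: reproduces Y_X/S = 0.114 from the other printed values; never stated by the study |
| temperature | 30 | °C | seed-culture temperature; the fermentation temperature is not stated, 30 °C is the conventional choice for this yeast |

The maintenance demand enters only as a diagnostic ratio
(`maintenance_margin()`), not as a term in the uptake law: the study's
claim is that the pulse minimum stays five-fold above maintenance, which is
a ratio check.

## Kinetics estimation

`fit_uptake_kinetics()` fits (q_max, K_S, S0) by least squares of the
integrated Monod equation against observed depletion profiles
(`minpack.lm::nlsLM`, five seeded multi-starts with log-normal jitter from
data-driven starting values: q_max twice the steepest observed uptake,
K_S the median observed concentration). The appendix describing the
study's own estimation procedure is not public, so this choice is the
package's own. Two decisions matter:

* **Weighting.** Concentration assays carry multiplicative
  (constant-CV) noise, so the default minimizes *relative* residuals —
  the maximum-likelihood choice under that noise model and the reason
  K_S, which is informed mostly by the low-concentration tail, is
  recoverable at realistic noise. Absolute least squares is available via
  `weighting = "absolute"`.
* **Identifiability.** A 2-minute pulse samples concentrations only
  between ~5.2 and ~1.4 mmol_C/L, all below K_S; with 5 % CV noise the
  (q_max, K_S) pair is then strongly correlated and individual-parameter
  errors of 20–40 % are expected. The calibration study in the tests
  therefore uses a depletion spanning both sides of K_S (S0 = 30
  mmol_C/L observed over 7 min, 9 time points, 3 replicates), where the
  median error over 100 seeded runs is ~5 % for q_max and ~12 % for K_S.
  Curvature-free data (all S >> K_S, or a straight-line profile) pin K_S
  at its bound and are flagged `non_identifiable`.

## Physiology

`specific_rate()`, `yield_coefficient()`, `carbon_recovery()` and
`percent_change()` are the standard chemostat balances in C-mol units;
`unknown_carbon()` subtracts quantified metabolites and the antifoam
carbon (61 % w/w carbon, assumed not consumed) from the measured total
organic carbon, flagging (not clamping) negative results.
`physiology_table()` assembles the RS-vs-DS comparison with Welch tests,
which the study reports unadjusted.

### Ethanol stripping

Ethanol leaves the reactor with the nitrogen sparge. `stripping_fraction()`
implements a single well-mixed gas phase in vapor-liquid equilibrium with
the broth: ethanol partial pressure = activity coefficient x liquid mole
fraction x Antoine saturation pressure, gas molar flow from the
norm-metered sparge rate, gas mole fraction referred to the 1.3 bar
absolute head pressure. Defaults: activity coefficient 4.68 (the classic
dilute-solution measurement for ethanol in water, Butler et al. 1935,
treated as flat over 25–35 °C), 0.425 vvm, 30 °C. All constants are
explicit arguments.

At the study's operating point this model predicts ~8 % of produced
ethanol lost to the gas, whereas the study reports 4.8 % from a
mass-transfer-based estimate whose appendix is not public. The equilibrium
assumption is an upper bound — it credits the leaving gas with full
saturation — and no defensible choice of the activity coefficient
(published values span roughly 3.6–6.6) closes that gap; reproducing 4.8 %
would require ~2.8. We keep the transparent equilibrium model and the
documented constant rather than fitting an opaque efficiency factor; the
`saturation` argument (default 1) exposes the approach-to-equilibrium
degree for users who have an independent estimate of it.

## Differential expression

The DEG stage is a deliberately compact re-implementation of the
NB-GLM / likelihood-ratio-test workflow:

* `size_factors()` — median-of-ratios normalization.
* `estimate_dispersion()` — per-gene Cox-Reid-adjusted ML dispersion
  under the factor model, a parametric mean-dispersion trend
  (a0 + a1/mean, gamma GLM), and a maximum-a-posteriori estimate that
  combines each gene's CR likelihood with a log-normal prior centered on
  the trend. The prior variance is estimated from the robust spread of
  gene-wise estimates about the trend minus the sampling variance
  trigamma((m − p)/2), floored at 0.25. A proper MAP (rather than a
  weighted average of point estimates) matters for genes whose
  likelihood is flat or maximized at the boundary — under-dispersed
  genes fall back to the trend instead of dragging an arbitrary lower
  bound into the average. This is intentionally not the full machinery of
  the established packages (no outlier refitting, no posterior variance
  bookkeeping); it is validated by simulation rather than by
  bit-equality with them.
* `nb_lrt()` — per-gene NB log-likelihoods maximized under the full
  (one mean per condition) and reduced (single mean) models with fixed
  dispersion and size-factor offsets; 2 delta-log-likelihood referred to a
  chi-squared with (levels − 1) degrees of freedom. For one-hot designs
  the group-mean ML equations are one-dimensional and solved by damped
  Newton, which keeps the whole stage in plain R at ~4 s per 2000-gene
  analysis. A Wald variant is exposed for two-level contrasts (the study
  is not explicit about which was used for the DS-vs-RS comparison; the
  LRT is the default).
* `call_degs()` — status up/down at |log2FC| >= 1 and BH FDR < 1e-3,
  the study's thresholds.

Measured behavior on seeded fixtures (2000 genes, dispersion 0.05, three
replicates per condition): null fraction of p < 0.05 about 0.06 (the
chi-squared reference with the true dispersion is exact at 0.05; the
residue is dispersion-estimation noise), sensitivity ~0.94 with observed
FDR ~0 for |log2FC| = 2 spikes at the study thresholds — closely matching
an established reference implementation run on the same data, which the
test suite includes as an independent cross-check.

## Trajectory patterns and enrichment

Per-timepoint log2 fold changes versus time zero are standardized per gene
(sample sd; the study does not state its scaling, and standardization is
the conventional pre-clustering transform) and clustered with k-means
(Lloyd, Euclidean), run as seeded restarts with centers drawn from the
data and the best within-cluster sum of squares kept; restarts that hit an
empty cluster are redrawn. Defaults k = 7 for the single-pulse series and
k = 2 for the cycle-resolved series mirror the study's choices; 50
restarts stabilize the result against the unstated seeding. Rows are
processed in sorted-name order, making the assignment invariant to input
order and bit-reproducible per seed.

Cluster annotation uses the upper-tail hypergeometric test (identical to
one-sided Fisher, which the tests verify exhaustively for universes up to
30), BH-corrected within cluster (matching per-panel displays; a global
flag exists), and mapped to the display tiers `*` (1e-5 <= q < 5e-2),
`**` (1e-10 <= q < 1e-5), `***` (q < 1e-10).

## Gene-set statistics

`set_t_statistic()` is the two-sample unequal-variance t of set-member
log2 ratios against all non-members — the set-level statistic whose sign
encodes coordinated induction or repression — computed per contrast on
log2(normalized counts + 1). BH runs across sets within a contrast and the
display filter keeps sets significant at FDR < 1e-3 in at least one
contrast, applied at reporting, not computation.

`multiset_intersection_pvalue()` gives the exact null distribution of the
total intersection of m lists drawn uniformly without replacement from a
universe of N genes, by propagating conditional hypergeometrics (the
intersection after adding a set of size n, given current size k, is
hypergeometric(N, k, n)). For m = 2 this is exactly the hypergeometric
upper tail; the tests also verify it against exhaustive enumeration and
seeded Monte Carlo. The universe defaults to the tested genes and is a
parameter, since the study does not state whether genome-wide or expressed
genes were used.

## Synthetic data

`gen_count_matrix()` draws NB counts with mean = baseline x depth factor x
2^(template(t) x amplitude). The defaults encode the study's observed
structure: ~17.6 % responsive genes (1053 of ~6000), impulse templates
peaking at 15 min (inside the reported 10–20 min window) and relaxed to
|log2FC| < 0.1 by 60 min, sustained-shift templates for the DS, a damped
9-min oscillation matching the feed cycle, amplitude 2, dispersion 0.05,
log-normal baselines (meanlog 5, sdlog 1.5) on the count-mean scale, and
±20 % library-size factors around a nominal 2e5-read depth — the study's
2e7-read depth scaled down 100-fold to keep the test suite fast; the
statistical structure, not the absolute depth, is what the downstream
stages consume. What the generator does *not* emulate: gene-gene
correlation, gene-specific dispersion-mean coupling beyond the global
value, GC/length effects, or the yeast genome's real annotation structure
— so green pipeline tests demonstrate correct statistics under the stated
model, not robustness to every artifact of real libraries.

`gen_process_measurements()` overlays multiplicative Gaussian noise
(default CV 5 %, three replicates — the replicate scatter printed in the
study's process table is sd-only, so the distribution is this package's
choice) on a simulated trajectory.

All generators are deterministic per seed (`withr::with_seed`; one seeded
stream per generator call).

## Orchestration

`run_sre_pipeline()` chains the seven stages (synthetic data, kinetics,
physiology, DEG, clustering + enrichment, gene-set statistics,
intersections) on a validated `sre_config()`, writes each stage's tables
as TSV and a JSON manifest with parameters and output checksums, and is
byte-reproducible per seed. The package's interface is its functions and
this pipeline entry point; configurations and feed schedules can be read
from YAML.

## Problem sizes and limitations

The shipped calibration studies use 2000-gene x 6-sample fixtures for the
DEG calibration, a 100-run kinetics recovery study, 1e5-draw Monte Carlo
checks for the intersection test, and a 50-cycle simulation for periodic
convergence — sizes chosen so the whole suite completes in a few minutes
on one core while keeping Monte-Carlo bands tight.

Known limitations: the off-gas CO2 sensor delay noted by the study is not
modeled (CO2 is treated as instantaneously measurable); there are no pH or
temperature control loops and no gas-phase dynamics beyond the equilibrium
stripping estimate; NB fitting supports single-factor designs (condition /
timepoint), not arbitrary design matrices; and the stripping model is an
equilibrium upper bound as discussed above.
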