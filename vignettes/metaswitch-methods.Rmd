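---
title: "Metabolic state-switching: model and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic state-switching: model and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaswitch)
```

## The biological problem

Exponentially growing clonal *Bacillus subtilis* cultures on glucose +
malate split into interacting metabolic subpopulations. A small,
transient subpopulation associated with the genetic-competence program
(marked by high *sucC* expression) secretes acetate; acetate accumulates
to growth-inhibitory levels; high extracellular acetate then induces a
second subpopulation (marked by *alsS*) that reabsorbs acetate and
converts it to acetoin, a pH-neutral storage metabolite. `metaswitch`
provides (i) a generative agent-based model of this interaction and
(ii) the estimators used to quantify such data: snapshot
classification, lineage event statistics, elongation rates, genealogy
trees, and metabolite phase detection.

## The generative model

Each cell carries two independent binary expression states with
memoryless (exponential waiting-time) transitions:

* **sucC+/competent**: entry at rate `k_on_sucC * quorum * f_g`, where
  `f_g = glucose/(K_C + glucose)` — competence requires active growth on
  the preferred sugar and a quorum/conditioned-media signal. Exit at
  `k_off_sucC = 1/252 min^-1`, the reciprocal of the observed mean
  episode length.
* **alsS+/acetoin-producing**: entry at
  `k0 + kmax * A^h / (K^h + A^h)` for ambient acetate `A`
  (Hill induction, defaults `K = 10 mM`, `h = 2`), exit at
  `k_off_alsS = 1/180 min^-1`.

Cells elongate exponentially, `dL/dt = r L`, with

```
r = r_base * rfac * penalty(state) * f_c * f_tox,
f_c   = (glucose + malate) / (K_C + glucose + malate)
f_tox = K_tox / (K_tox + acetate)
```

`rfac` is a per-cell lognormal factor (CV 10%, resampled at birth)
representing growth-rate variability; `penalty(state)` multiplies the
specific rate in the sucC+ (0.750) and alsS+ (0.882) states. The
penalties are the ratios of *log-space* slopes derived from the %/hr
anchors (47.4 vs 67.7 and 63 vs 74 %/hr): because
`%/hr = 100*(exp(60 r) - 1)` is convex, a ratio applied to `r` is not
the same as a ratio of %/hr values, and the model defines penalties on
`r`, the quantity it integrates. Division occurs at threshold length
`L_div = 6 um` with Gaussian division-site noise (CV 5%); both reporter
concentrations partition exactly (concentration-conserving), and a
stable-reporter ODE `dF/dt = beta*f_c - r F` governs fluorescence
(production when carbon is available, dilution by growth, no
degradation). Scaling `beta` by `f_c` encodes that protein synthesis
stops in carbon starvation; it also pins fluorescence distributions
exactly once a closed culture exhausts its substrate.

The environment couples through biomass `B` (OD-equivalents):

```
d(acetate)/dt = (p_A * B_sucC+ + p_A_basal * B) * f_c  -  c_A * B_alsS+
d(acetoin)/dt = y_acetoin * (acetate consumed)
```

with consumption capped at the acetate available (so the cumulative
ledger `produced - consumed = final - initial` closes to floating-point
precision in every closed run). Carbon consumption follows biomass
growth at a fixed yield, split between glucose and malate with glucose
carrying 70-85% of the flux while it lasts: the smaller glucose pool is
exhausted around mid-exponential phase, which closes the competence
window while malate sustains growth through the acetate-reabsorption
phase. This ordering is what makes the sucC+ subpopulation transient
and places the acetate peak strictly inside the run.

### The three experiment modes

* **batch** — closed, well-mixed. A fixed ensemble of `n_sample`
  tracked cells (constant-number Monte Carlo: at division one daughter
  is kept at random) represents the population; a scalar biomass grows
  at the ensemble-mean rate and drives the environment. Defaults: 22 mM
  glucose, 50 mM malate, 16 h, 30-min snapshots, 1000 tracked cells.
* **mother_machine** — chemostatic. Dead-end channels hold a queue of
  at most `channel_capacity` cells; the position-1 "mother" is always
  observed, daughters pushed past capacity are washed out. Acetate and
  quorum are fixed by `media_condition`; carbon is replete. Initial
  states are drawn from the stationary occupancy of each switch, as for
  cells loaded from a pre-adapted culture (this removes burn-in bias
  from occupancy estimates).
* **pad** — microcolony on agarose with 20 mM acetate (the
  mid-exponential concentration) and glucose. The agarose bulk is
  treated as a carbon reservoir (pools held constant — diffusion from
  the pad resupplies the colony), while secreted metabolites form a
  closed local pool whose coupling per cell is `od_per_cell`. The full
  genealogy is retained. Fresh pad medium carries no quorum signal, so
  competence entry is off by default (`media_condition$quorum = 0`).

A division replaces the mother by two new cell ids, so genealogies are
strictly binary and the mother-machine "mother" is identified by
position, not id.

### Integration and determinism

All updates use a fixed explicit step `dt = frame_interval/substeps`
(default 1.2 min for 12-min frames): exact exponential growth and
reporter updates within the step, Bernoulli switching with
`P = 1 - exp(-k dt)`, environment update, then divisions and washout.
Stiffness is mild at default rates. Concentrations are clamped at zero
(clamping events are counted and returned). Each run seeds R's RNG once
from `config$seed`; identical config + seed gives bit-identical tables.

## Estimators

* `classify_positive()` — a cell is positive iff its value is at or
  above `mean + k*sd` (sample SD, `k = 2` by default) of its own
  snapshot. Statistics are never pooled across timepoints, because
  subpopulation fractions are reported at specific culture densities.
  The rule is a *tail* classifier: once a positive subpopulation
  exceeds roughly 20% of cells, the threshold rises past the on-state
  level and the rule loses meaning. This is why the simulator's default
  induction strength keeps batch alsS+ occupancy near 10%, and why
  monotonicity checks against ambient acetate use the simulator's state
  fraction rather than the classified fraction.
* `skewness()` — adjusted Fisher-Pearson `g1*sqrt(n(n-1))/(n-2)`, the
  common statistics-software default; recorded in pipeline output
  metadata since other estimators differ at small n.
* `detect_events()` — an event opens at the first frame at/above
  threshold after a sub-threshold frame and closes at the first frame
  below `hysteresis * threshold`. Events touching a movie boundary are
  censored: they count toward event rates (their onset happened) but
  are excluded from dwell statistics (their length is unknown).
  `dwell_min = n_frames * frame_interval` exactly; when comparing with
  continuous episode lengths a `+frame_interval/2` interval-censoring
  correction applies to the mean. No smoothing by default; an optional
  3-frame median filter is available.
* `elongation_rate()` — least-squares slope `s` of `log(length)` vs
  time within one cell cycle (≥ 3 frames; a > 40% length drop is
  treated as an unnoticed division and rejected), reported as
  `100*(exp(60 s) - 1)` %/hr so that one doubling per hour reads
  100 %/hr. The estimator is invariant to length units.
* `per_state_growth()` — each cell-cycle window is assigned "on" when
  at least 50% of its frames lie inside an activation event (ties count
  as on; censored events still define intervals). Windows that straddle
  a switch dilute the contrast slightly toward the off rate; with
  episodes much longer than a cell cycle the bias is well below the
  standard error at the default scales.
* `detect_phases()` — central finite differences (one-sided at the
  boundaries), moving-average smoothing (window 3), and a dead-band
  `eps` (default 0.005 mM/min, the scale of HPLC noise) that zeroes
  near-flat derivatives. The longest positive and negative runs become
  the production and consumption phases (a `first`-run rule is
  available); endpoints are reported at sample times and snapped to the
  raw-series peak when a run abuts it, so production ends and
  consumption begins at `t_peak`.
* `dose_response()` — bounded Levenberg-Marquardt fit of
  `baseline + amplitude * d^h/(K^h + d^h)` with `amplitude, baseline in
  [0,1]`, `h in [0.5, 6]`, `K` initialised at the dose nearest
  half-maximal response. Flat responses return amplitude 0 flagged
  non-identifiable; designs with < 4 distinct doses get a monotonicity
  report only.

## What the generator does and does not emulate

The synthetic data reproduce: right-skewed unimodal fluorescence
distributions with a high-expressing tail; two-state switching lineages
under chemostatic (mother machine) and cumulative (batch/pad)
environments; a rise-then-fall acetate curve with concomitant acetoin
rise; slower growth of activated cells; a several-fold reduction of
peak acetate in the competence knockout; and acetate-dose-dependent
alsS activation. They do **not** emulate: excitable-circuit competence
dynamics (entry is Poisson, so simulated dwell times are exponential —
CV 1 — whereas observed episode lengths are more regular, 252 ± 89 min);
spatial gradients, cell geometry beyond length, or mechanical
interactions on pads; pH/anion toxicity mechanisms (a single saturating
growth factor stands in); or image-derived segmentation noise beyond a
2% multiplicative length error. Passing tests therefore validate the
estimators and the interaction logic, not the biochemical detail of any
real culture.

## Numerical and design choices

* Default problem sizes were chosen so every check runs in seconds on
  one core while keeping Monte-Carlo error well inside its tolerance:
  batch uses 1000 tracked cells over 16 h; occupancy checks use 145
  single-cell channels over 70 h (≈ 10^4 cell-hours, ≥ 300-500
  episodes); per-state growth uses 8 channels × capacity 4 over 30 h
  (≈ 300-400 windows per class).
* Division-threshold comparison uses a relative tolerance of 1e-9 so
  exact deterministic doublings are not missed to floating-point
  rounding.
* The knockout flags act on parameters, not mechanisms: `comK_null`
  sets `k_on_sucC = 0`, `alsS_null` sets `c_A = 0` (activation itself
  is untouched — the deletion removes the metabolic capacity).
* Open point resolved: the mother-machine frame interval is not
  standardized anywhere; the pad value of 12 min is used for all movie
  modes and is configurable. Conditioned-media activity is modeled as a
  single quorum scalar multiplying `k_on_sucC`; whether secreted
  metabolites also contribute is left outside the model.
* All defaults live in `inst/extdata/default_params.yaml` (versioned),
  never hard-coded; units are fixed package-wide to minutes, um, mM,
  AU.

## A worked batch run

```{r batch, eval = FALSE}
cfg <- scenario_config("batch", duration = 960, frame_interval = 30, seed = 1)
run <- simulate_batch(switch_params(), cfg)
phases <- detect_phases(run$environment[, c("t_min", "acetate_mM")])
phases
fr_sucC <- fraction_timecourse(subset(run$snapshots, reporter == "sucC"))
fr_alsS <- fraction_timecourse(subset(run$snapshots, reporter == "alsS"))
phase_alignment(phases, list(sucC = fr_sucC, alsS = fr_alsS))
```

The sucC+ fraction peaks during acetate production and the alsS+
fraction during consumption; `scripts/acceptance.R` recomputes these
and the other headline quantities from scratch.

## Limitations

The environment model is deliberately phenomenological: secretion and
uptake rates per OD are calibrated, not measured; acetoin is inert
(no late re-consumption); and the constant-number batch ensemble
cannot represent lineage correlations within the batch population (use
pad mode for genealogy questions). The 2-SD classifier inherits the
threshold-rule pathologies discussed above; mixture models were
deliberately excluded from scope.
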