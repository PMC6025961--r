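# metaswitch

Quantification and simulation of **dynamic metabolic subpopulations in
clonal bacterial cultures**.

Growing *Bacillus subtilis* cultures on glucose + malate do not handle
overflow metabolism homogeneously: a small, transient
competence-associated subpopulation (high *sucC* expression) secretes
acetate; when acetate accumulates to inhibitory levels it induces a
second subpopulation (high *alsS*) that reabsorbs acetate and converts
it to the pH-neutral metabolite acetoin. `metaswitch` is for
single-cell microbiologists and modellers who want to (a) generate
realistic synthetic data for this kind of interacting state-switching
system — batch snapshots, mother-machine lineages, agarose-pad
microcolonies — and (b) apply the standard quantification chain to such
data, real or simulated.

## The model and statistics at its core

Cells elongate exponentially (`dL/dt = r L`) and divide at a threshold
length. Two independent binary expression states switch with
exponential waiting times; alsS entry is acetate-induced through a Hill
function `k0 + kmax A^h/(K^h + A^h)`; every cell's growth is slowed by
acetate toxicity `K_tox/(K_tox + A)`; the environment closes the loop:

```
d(acetate)/dt = p_A·B_sucC+ · f_c  +  p_A_basal·B · f_c  −  c_A·B_alsS+
d(acetoin)/dt = y_acetoin · (acetate consumed)
```

Estimators implemented on top of (any) single-cell tables:

* positive-cell classification: `value ≥ mean + k·sd` per snapshot
  (`k = 2`), plus adjusted Fisher–Pearson skewness screening;
* threshold-crossing activation events with censoring, dwell times
  (`n_frames × frame_interval`, `+frame/2` interval-censoring
  correction), events per 100 hr;
* elongation rates as `100·(e^{60s} − 1)` %/hr from the log-length
  slope `s`, and per-state growth comparison (≥ 50% event-overlap rule);
* binary genealogy trees with Newick export (branch lengths =
  cell-cycle durations);
* metabolite production/consumption phases from the sign of the
  smoothed time derivative, aligned with fraction-positive time
  courses;
* bounded Hill fits of acetate dose–response curves.

## Worked example

```r
library(metaswitch)

cfg <- scenario_config("batch", duration = 960, frame_interval = 30, seed = 1)
run <- simulate_batch(switch_params(), cfg)

phases <- detect_phases(run$environment[, c("t_min", "acetate_mM")])
phases
#> <phase_report> production 30-510 min | consumption 510-690 min | peak 24.5 mM at 510 min

fr_sucC <- fraction_timecourse(run$snapshots[run$snapshots$reporter == "sucC", ])
fr_alsS <- fraction_timecourse(run$snapshots[run$snapshots$reporter == "alsS", ])
phase_alignment(phases, list(sucC = fr_sucC, alsS = fr_alsS))
#> # A tibble: 2 × 5
#>   reporter t_argmax phase       coverage_production coverage_consumption
#> 1 sucC          450 production                0.706                    1
#> 2 alsS          540 consumption               0.412                    1
```

The acetate curve rises while the transient sucC+ subpopulation is
active (peaking at 24.5 mM around 8.5 h, when glucose runs out and
competence entry stops) and falls as the acetate-induced alsS+
subpopulation reabsorbs it. The subpopulation fractions, classified per
snapshot by the 2-SD rule, peak inside "their" phases — sucC+ during
production (max fraction 5.4%, distribution skewness 4.15 at the peak
timepoint), alsS+ during consumption (max 7.7%). `coverage_*` is the
share of each phase during which a reporter's fraction exceeds half its
maximum.

Lineage-level analysis of a mother-machine run:

```r
lin <- simulate_mother_machine(switch_params(),
         scenario_config("mother_machine", duration = 4200,
                         n_channels = 60, channel_capacity = 1, seed = 1,
                         media_condition = list(acetate = 0, quorum = 20)))
tr <- mother_traces(lin, "state_sucC")
ev <- dplyr::bind_rows(lapply(seq_along(tr), function(i)
        detect_events(tr[[i]], 0.5, 12, lineage_id = i)))
dwell_summary(ev, correction_min = 6)$mean_min   # ~252 min episodes
```

`run_pipeline(cfg, "out/")` drives simulate → analyse → write for any
mode and records a manifest with the config hash so identical
config + seed reproduce byte-identical summaries.

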