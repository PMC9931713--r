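# longsnn

Spiking neural network modelling of longitudinal clinical cohorts:
interaction analysis and outcome prediction for three-group
ultra-high-risk (UHR) study designs.

Sparse visit data (23 social and cognitive variables measured at months
0, 6, 12, 18, 24, with a month-24 outcome label of HC / Remitter /
Maintained) are turned into dense time series by linear interpolation,
encoded into signed spike trains by a threshold rule on consecutive
changes, and learned by a 3D reservoir of leaky integrate-and-fire
neurons:

    u_i(t) = leak · u_i(t−1) + Σ_j W_ji s_j(t−1) + I_i(t),   fire at u ≥ θ_f

initialised with small-world connectivity (radius 2 on a 10×10×10 grid)
and adapted by additive spike-timing-dependent plasticity
(Δ|w| = ±0.01 for pre-before-post / post-before-pre firing).  A dynamic
evolving SNN (deSNN) readout assigns one output neuron per training
subject with rank-order weights `mod^rank` (mod = 0.8) plus a per-step
drift (0.005), and classifies test subjects by nearest output neuron.
Trained reservoirs are summarised by the mean absolute connection weight
`W_a`, per-variable weight means, and a 23×23 feature interaction
network (FIN) counting spikes exchanged between variable-centred neuron
clusters during STDP learning.

Because the motivating clinical dataset is not public, the package
includes a seeded synthetic-cohort generator (`generate_cohort()`) whose
defaults emulate the study conditions: group sizes 81/58/30, HC
high-stable, Remitters recovering to the HC level by month 24, Maintained
persistently impaired with the strongest cross-variable coupling.  It is
aimed at researchers who want a tested, reproducible reference
implementation of this modelling pipeline.

## Worked example

The numbered scripts under `analysis/` run the full study; the same can
be done interactively:

```r
library(longsnn)

dataset <- generate_cohort(cohort_config(seed = 20240901))
#> cohort_dataset: 169 subjects x 23 variables x 5 visits
#>         HC   Remitter Maintained
#>         81         58         30

# per-group reservoirs and interaction networks
bundle <- run_group_visualization(dataset, experiment_config(master_seed = 20240901))
compare_groups(bundle)$summary
#>       group       W_a fin_total
#>          HC 0.2953028     16320
#>    Remitter 0.2954463     76692
#>  Maintained 0.2968261    206431

# outcome classification, 30 x 2-fold stratified cross-validation
cls <- run_experiment(dataset, experiment_config("classification",
                                                 master_seed = 20240901))
cls
#> evaluation_result (classification): balanced accuracy 0.896 (sd 0.035) over 60 folds
#>         HC   Remitter Maintained
#>      0.950      0.989      0.750
```

The `fin_total` column counts spikes transmitted inside each group's
reservoir during STDP learning: the Maintained group — whose variables
co-move most strongly in the generator — exchanges roughly 13× more
spikes than the healthy controls, reproducing the intended interaction
ordering Maintained > Remitter > HC.  The balanced accuracy is the
macro-averaged per-class recall over all 60 folds; the prediction task
(`task = "prediction"`, test series truncated at month 18) asks how much
of that signal is already present six months before the outcome.

Outputs land in `results/` as plain CSV/JSON: cohort and catalogue
tables, interpolated series, spike trains, model archives, connection
and per-variable weight tables, FIN matrices and edge lists, and
fold-level evaluation tables.  Reruns with the same seeds are
byte-identical.

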