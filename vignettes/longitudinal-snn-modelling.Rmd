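---
title: "Modelling longitudinal social-cognitive trajectories with a spiking reservoir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal social-cognitive trajectories with a spiking reservoir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longsnn)
```

## The modelling problem

Ultra-high-risk (UHR) cohorts for psychosis are followed with batteries of
social and cognitive instruments at a handful of visits — here 23 variables
(BACS, HiSoC, SNK, PC and CPT subscores) at months 0, 6, 12, 18 and 24 —
and each subject carries a month-24 outcome label: healthy control (HC),
*Remitter* (no longer meets UHR criteria) or *Maintained* (still meets
them).  Two questions drive the analysis:

1. **Interaction**: how strongly do the social and cognitive variables
   co-vary over time within each group?
2. **Prediction**: can the month-24 outcome be read from the trajectories,
   and how early — in particular, from the first 18 months only?

Both are answered with one architecture: sparse visit data are linearly
interpolated to a dense series, encoded into spike trains, fed into a 3D
spiking neural network reservoir trained with spike-timing-dependent
plasticity (STDP), and read out by a dynamic evolving SNN (deSNN)
rank-order classifier.  Connection weights and transmitted-spike counts in
the trained reservoir expose the interaction structure; repeated two-fold
cross-validation with balanced accuracy quantifies predictive signal.

## Pipeline stages and their parameters

### Interpolation

Each variable's five measurements become a `total_points = 250` series:
the 5 visits plus 245 artificial points equally spaced within each
inter-visit interval (when the artificial points do not divide evenly,
earlier intervals receive one extra).  Values at visit months are kept
bit-exactly, and interior points are exact linear interpolants — the
interpolation adds resolution without altering the trend.  The 250-point
default matches a roughly-monthly sampling of 24 months while honouring
the stated total of 245 artificial plus 5 original points; it is
configurable, and nothing downstream assumes a particular density.

### Normalization and encoding

Variables are min-max normalized to [0, 1] per variable (z-scoring is
available).  In cross-validation, normalization parameters are fitted on
the training half only and applied to test subjects, so no test
information leaks into the scale.

The encoder marks significant changes: at step *t*, the difference
`d = x(t) − x(t−1)` emits `+1` if `d > θ·σ_v`, `−1` if `d < −θ·σ_v`, else
`0`, with `θ = 0.5`.  The scale `σ_v` is the SD of that variable's
consecutive differences pooled over the training cohort (`sd_of_diff`
mode).  A fixed jump of 0.5 on a [0, 1] scale would essentially never
occur between adjacent points of a smooth monthly-interpolated series, so
anchoring the printed threshold to the difference distribution is what
keeps it meaningful; an `absolute` mode is retained for strict use of the
raw threshold.  Because noise enters at visits and interpolation is
linear, differences are constant within an interval: a variable either
spikes through a whole interval or stays silent, which is exactly the
"significant change" semantics intended.  Negative changes produce
negative spikes that inject negative current — downward trends actively
inhibit rather than merely staying silent.

### The reservoir

A 10 × 10 × 10 grid of leaky integrate-and-fire neurons (1000 total) is
wired with small-world connectivity: every ordered pair within Euclidean
distance 2 connects with probability `min(1, 0.15/d)`, with initial
magnitude `Uniform(0, 0.8)/d` and a 20% chance of being inhibitory.
Dynamics per step:

`u_i(t) = leak · u_i(t−1) + Σ_j W_ji s_j(t−1) + I_i(t)`

with firing at `u ≥ 0.5`, reset to 0.  Defaults: `leak = 0.1`,
`refractory_steps = 0`.  These two deserve explanation.  A time step here
represents about one month of real time, so a biological membrane time
constant has no meaning at this resolution; the design question is only
whether reservoir activity should be self-sustained or input-driven.
With strong retention (leak near 1) the STDP-trained network saturates:
most neurons fire at their maximal rate regardless of the input, and the
readout then mostly measures how *long* a series is rather than what is
in it — which specifically corrupts the prediction task, whose test
series are shorter (18 of 24 months) than the training series.  With low
retention the network re-derives its state from the input each step,
firing tracks the spike trains, and truncating a test series removes
proportionally from every subject.  We therefore ship the input-driven
setting and treat leak as a tunable.

Input placement: 23 well-spread candidate sites are fixed by
deterministic farthest-point sampling, and variables are assigned to
sites by graph matching — maximising Σ S(u,v)/dist(site_u, site_v), where
S is the Pearson correlation of exponentially smoothed training spike
trains — via greedy seeding plus pairwise-swap hill climbing with seeded
random restarts.  Correlated variables thus land on nearby input neurons.

### STDP

Additive, nearest-step: when pre fires one step before post, the
connection magnitude grows by `rate = 0.01`; in the reverse order it
shrinks by the same amount, floored at zero.  Signs and topology never
change; only magnitudes adapt.  Subjects are presented once each, in a
seeded random order.  Every delivery of a spike across a connection is
logged as a *transmission* — these counts are the raw material of the
interaction analysis.

### deSNN readout

After STDP the reservoir is frozen.  Each training subject becomes one
output neuron: reservoir neurons are ranked by first-spike time (ties by
neuron id) and weighted `mod^rank` with `mod = 0.8`; thereafter the
weight drifts by `+0.005` on steps where the neuron fires and `−0.005`
where it does not (floored at 0).  A test subject is encoded the same way
and labelled by its nearest output neuron in Euclidean distance (k = 1;
ties: majority, then smallest distance sum, then lexicographic label).

### Interaction analysis

Neurons are partitioned into 23 clusters by nearest input neuron (ties:
strongest absolute direct connection, then lowest variable id).  The
feature interaction network (FIN) counts, for every transmission during
STDP learning, the (cluster of pre, cluster of post) pair.  The directed
23 × 23 matrix conserves the transmission total exactly, including the
intra-cluster diagonal, which is kept separate; the exported matrix is
the symmetrized sum.  Per-group reservoirs (trained on that group's
subjects only, with shared seeds) are compared by mean absolute
connection weight `W_a`, per-variable weight means, and total FIN mass.

### Evaluation

30 repeats of stratified 50/50 splits; both halves serve once as test
(60 folds).  Each fold refits everything — normalization, encoding scale,
input mapping, reservoir, STDP, readout — from its training half.
Balanced accuracy is macro-averaged recall, which reduces to
(sensitivity + specificity)/2 for two classes; a class absent from a fold
is excluded from the macro mean with a warning.  The prediction task
trains on full series and truncates only the test inputs at month 18.
All seeds derive from one master seed through a fixed stream
(`seed_stream()`), so every experiment is exactly reproducible.

## What the synthetic cohort emulates — and what it does not

The clinical dataset behind this design is not public, so the package
ships a generator whose defaults encode the study's qualitative
structure: group sizes 81/58/30; HC high and stable; Remitters impaired
at baseline and recovered to the HC level by month 24 on every variable
(deeply impaired on the two verbal/working-memory variables, mildly on
the rest); Maintained persistently impaired with no trend.  Within a
subject, variables co-move through one shared latent random-walk factor
scaled by a group coupling strength ordered
Maintained (1.8) > Remitter (0.1) > HC (0.05), with Maintained also
carrying the largest visit-to-visit noise (0.30 z vs 0.12 z).  This is a
minimal mechanism for "strongest cross-variable interaction in the
Maintained group": their variables make large synchronized moves in
either direction, Remitters make small steady gains, controls barely
move.

Values are generated in z-units as
`baseline + (k−1)·delta + coupling·loading·L_k + noise` with `L` a
standard-normal random walk over visits.  The calibration was chosen once
so that (i) the three groups are separable by the full pipeline, (ii) the
interaction ordering above is reproduced in the trained reservoirs across
seeds, and (iii) the prediction task tracks classification closely.  Two
findings from that calibration are worth recording as model behaviour,
not merely tuning: a Remitter profile with *broad* deep impairment
produces persistent synchronized spiking across all 23 variables, which
drives unbounded additive STDP into runaway weight growth and makes the
Remitter model's transmission count explode several-fold across seeds;
and groups that differ only in the *amount* of change (not in *which*
variables change) are much harder for the distance-based readout to
separate.  Both informed the shipped defaults.

What passing tests on this cohort do **not** show: that the method
attains any particular accuracy on real UHR data.  The generator has no
missing data (the study design is complete-case), no measurement floor or
ceiling effects, no site or practice effects, Gaussian noise, a single
latent factor rather than a full covariance structure, and
group-homogeneous trajectories.  Results on it validate the machinery
and its invariants, not the clinical claim.

## Numerical and degenerate-input conventions

- Constant variables: min-max maps to 0.5 with a warning; a zero
  difference-SD yields no spikes for that variable.
- The first time step never spikes (no predecessor).
- Interpolated values use `y1 + w·(y2 − y1)`, exact at knots and for
  constant segments.
- STDP potentiation is applied before depression within a step; a
  connection whose neurons fired in both orders on consecutive steps
  nets zero.
- Weight magnitudes floor at zero and keep their initial sign, so an
  inhibitory connection can recover after being silenced.
- Model archives and all CSV exports print doubles with 17 significant
  digits; round trips are bit-exact and reruns are byte-identical.
- Problem sizes used by the shipped checks: toy networks of ≤ 6 neurons
  for oracle comparisons; 5-variable instances against exhaustive
  enumeration for the input mapping; the full 169-subject cohort at 250
  time points and 1000 neurons for the cross-validated experiments, with
  the permuted-label null run at 10 repeats.

## Known limitations

- The additive STDP rule is unbounded; with strongly synchronized
  persistent input the weights can grow without limit.  The shipped
  initial-weight scale keeps the default cohort below that regime, but
  the package does not impose a hard weight cap.
- The deSNN drift term accumulates over time steps, so comparing series
  of very different lengths biases distances; keep test truncation
  moderate (the month-18 task is fine under the shipped dynamics).
- The graph-matching optimiser is a local search; optimality is verified
  exhaustively only at small size (it attains the global optimum on most
  5-variable instances and is never worse than the median random
  assignment).
- One pass of STDP per training subject is the default; more passes
  amplify both learning and the runaway risk.
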