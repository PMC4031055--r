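---
title: "A gamma-cycle spiking model of remapping in DG and CA3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A gamma-cycle spiking model of remapping in DG and CA3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hippomorph simulates the entorhinal–hippocampal circuit that produces *rate
remapping*: when the walls of a familiar recording box are gradually morphed
from a square (condition 1) to a circle (condition 7), place cells in the
dentate gyrus (DG) and area CA3 keep their firing locations but change their
firing rates. The package asks the question that motivates the model: do the
recurrent collaterals of CA3 act as an attractor network — pulling activity
toward patterns stored for the familiar square and circle — even though no
abrupt transition is ever observed along the morph axis? This vignette
explains the model, its assumptions, the free parameters and how they were
set, and what the simulations do and do not establish.

## The competitive gamma cycle

Both regions are populations of one-compartment integrate-and-fire neurons
with input resistance 33 MΩ, membrane time constant 30 ms, threshold −50 mV
and reset to rest at −65 mV, a −2 nA after-hyperpolarization current decaying
with τ = 7 ms, and a 2 ms absolute refractory period. Spiking is organized in
independent *gamma cycles* of 36.5 ms, one per position sample of the
foraging trajectory. Within a cycle every membrane starts at rest, charges
toward its feedforward drive, and the first cell to reach threshold triggers
global feedback inhibition that arrives 3.3 ± 0.4 ms later (normal,
truncated at zero) and closes the window. Cells whose latency beats the GABA
onset fire; everyone else is silenced. Cycle-to-cycle variability of the
delay turns latency margins into graded firing probabilities, which is the
model's firing rate: a cell that always beats the onset fires at the cycle
rate (~27.4 Hz), a cell at the margin fires in a fraction of cycles.

Two numerical grids are used, following the model's update convention: 1 ms
Euler steps from the cycle start to the first spike, and 0.1 ms steps inside
the window between the first spike and GABA release. For constant input the
explicit-Euler trajectory is a geometric series, so first-spike latencies on
this mixed grid have a closed form; `simulate_session()` exploits this to
run sessions as vectorized latency lookups, while `run_gamma_cycle()` is the
direct step-by-step integrator kept as the reference implementation (a
property test checks that the two agree).

Two timing facts fix the cycle arithmetic. The feedforward gain of 0.68 nA
makes the continuous first-spike latency at the *normalized maximum drive*
(see below) equal to 33.2 ms, and 33.2 + 3.3 ms is exactly the 36.5 ms cycle.
The cycle length therefore bounds where the *first* spike may fall; the GABA
window itself always runs its full sampled course, even when it crosses the
nominal cycle boundary. Truncating follower spikes at 36.5 ms instead would
silence every position whose local drive maximum is slightly below the
population norm — about half the box — and collapse DG activity far below
the sparsity this circuit is known for.

## Entorhinal inputs and their tailoring

Position is encoded by medial entorhinal (MEC) grid cells: the standard
three-cosine interference pattern with spacings drawn from 30–70 cm,
uniformly random orientation and phase. Grid cells ignore morphing. Context
is encoded by lateral entorhinal (LEC) cells: each carries two independent
smooth rate maps (square family / circle family) and a private transition
degree drawn uniformly on (1, 7); at morph condition c it expresses map A if
c is below its threshold, map B otherwise. Because thresholds are uniform,
one sixth of the LEC population switches at every unit step of the morph, so
the summed input changes smoothly even though every cell switches sharply.

Each DG cell receives 1200 MEC and 1500 LEC synapses, each CA3 cell 1400 and
1500, with lognormal synaptic weights (sdlog = 0.78, matching the ~0.9
coefficient of variation of measured dentate spine sizes). The two input
streams are separately normalized by the population mean of the per-cell
spatial maximum and mixed with a factor α (α = 0.5 at the best fit), so that
a typical cell's peak entorhinal drive is 1 in normalized units, or 0.68 nA
of current.

The shapes of the underlying tuning curves are the model's free "tailoring"
knobs (the spatial information of the input maps is constrained by data, not
derived from theory). Two facts about the circuit pin them down. First, with
~2700 synapses per cell the summed drive is extremely smooth, so the spread
of drive across cells at a position is a few percent of its mean; the 3.3 ms
inhibition window corresponds to roughly a 6% drive band below the local
maximum. For the observed regime — a few percent of granule cells active,
place-field peaks near 12 Hz, i.e. firing probabilities well inside (0, 1) —
a substantial fraction of cells must sit *within* that band, which requires
weakly tuned, low-contrast input maps rather than sharp ones. Second, the morph must
move rates appreciably: the population's morph sensitivity is set by the
contrast of the LEC maps, because a switching cell changes the summed input
in proportion to its map's deviation from the population mean. The two
requirements pull in opposite directions: map contrast raises morph
sensitivity but pushes parts of the box below the first-spike horizon,
which shreds place fields and the rhythm. The defaults resolve the tension
in favor of field quality and full spatial coverage: the plain three-cosine
grid profile (`sharpness = 1`) and LEC blobs clipped only at the 5% quantile
of their smooth noise field. They were calibrated once, at the full
desk-scale convergence, against the circuit's published operating points
(gamma-band rhythm, ~12 Hz field peaks, DG morph curves), and are not
revisited; the resulting DG activity (~10% of the granule pool) sits above
the ~3.5% reported for the tissue, the residual cost of that trade-off,
and the morph-driven population decorrelation is correspondingly milder
than recorded. The trade-off is discussed again under Limitations.

Because of the expected sparsity only the top weight decile of the granule
population is instantiated (8,000 simulated cells standing for a pool of
80,000 at desk scale); the lower deciles receive strictly weaker input and
lose every competition. Reported DG sparsity is always a fraction of the
full pool.

## DG → CA3 and the recurrent memory

CA3 cells additionally receive ~50 mossy-fiber inputs drawn from the full
granule pool (so about five land on simulated cells) whose *a-priori mean
rates* drive them: with feedforward-only dynamics and independent cycles,
the spike probability of a DG cell is the tail probability of the truncated
normal delay beyond its latency margin, so the DG rate maps entering CA3 are
computed exactly rather than estimated from a finite session. The summed
mossy input is normalized by the same mean-max convention and scaled by a
gain β (default 1; the original study fitted β but never printed it, so the
package takes the symmetric choice of equal EC and DG scales and exposes it
as a config entry).

The recurrent "memory" is built from recurrence-free sessions in the two
extreme shapes: in each, active cells (session mean rate > 0.1 Hz) are
partitioned by k-medoids on the 1 − correlation distance between their rate
maps (the number of clusters maximizes the mean silhouette over 2..min(50,
n/5); k-medoids is the well-defined analogue of k-means for a correlation
metric), same-cluster cells are connected with weight 1/n(C) — incoming
weights sum to 1, the self-term included in the bookkeeping — and the final
weight of a pair is the maximum over the two conditions. During recall, a
cell whose summed weighted EPSC drive from its partners (self-connection
excluded: no autapse physiology, and a self-EPSC would make every stored
cell burst) exceeds δ times its incoming weight receives the saturating
20 nA feedback current; the recall threshold 1 − δ is 95% at the best fit.
Recruited cells fire within a fraction of a millisecond — pattern completion
inside a single gamma cycle. A recruited or feedforward-driven memory cell
may fire a second spike if a partner's EPSC re-excites it after the 2 ms
refractory period; nothing in the model forbids this, and it simply raises
stored-pattern rates.

Learning updates the matrix after each session by a convex combination with
factor L between the old weights and a temporary cluster matrix built from
the session's active cells; pairs involving inactive cells are untouched and
no renormalization is applied afterwards (the convexity keeps all weights in
[0, 1]).

## Protocols and analyses

`run_morphing()` reproduces the morphing experiment: store the square and
circle patterns, then simulate each condition with recurrence on and off
(sharing trajectory and delays within a condition, so the recurrence effect
is a paired contrast) and DG alongside. `run_hysteresis()` runs 1→7→1 with
learning; `learning_rate_curve()` runs 1-2-3-4-5-6-7-1 across a log grid of
learning rates and `crossing_l_rate()` interpolates where the repeated-visit
correlation (1 vs 1′, six intermediate sessions) meets the smallest-morph
correlation (1 vs 2, none). `run_realignment()` stores the two patterns
under different grid alignments and switches the MEC population mid-morph,
producing the abrupt population-vector drop that distinguishes global from
rate remapping. `parametric_search()` scores a grid of α, β or δ against
reference metric curves by equal-weight least squares (the search resolution
and objective weighting are unspecified upstream; equal weights are the
package's choice).

The analysis battery follows the experimental conventions: 16×16 bins of
5×5 cm; occupancy-normalized rates smoothed with a 5 cm Gaussian kernel over
visited bins only; place fields as 4-connected components above 20% of the
field peak with more than 8 and fewer than 128 bins and a peak of at least
2 Hz; cells active above 0.1 Hz (strictly) in at least one condition;
population vectors per bin over cells whose peak rate exceeds 1 Hz in both
sessions, with Pearson correlation throughout (raw rates, not normalized);
the network rhythm as the reciprocal of the median first-spike latency plus
inhibition delay over spiking cycles (silent cycles have no first spike);
PV autocorrelation over bin pairs 50 ± 2.5 cm apart; rate overlap as the
ratio of the less to the more active session mean. Compared sessions always
use different trajectories, so sampling error is not shared.

## Synthetic trajectories

The virtual rat follows an Ornstein–Uhlenbeck heading process at ~20 cm/s
mean speed with a 60 cm/s cap, sampled once per gamma cycle (36.5 ms) in an
80 cm box — the box size implied by the analysis grid of 16×16 bins of 5 cm.
Wall contacts fold the overshoot back and let the heading slide along the
wall, a mild thigmotaxis that keeps corners visited; every 5×5 cm bin is
occupied within a 600 s session for all tested seeds. The generator
reproduces coverage and speed statistics only — not the detailed kinematics,
head-direction correlations or behavioral states of real foraging — so
passing tests certify the circuit model, not a behavioral one. All
randomness (trajectory, weights, delay draws) is seeded separately so
compared sessions share networks but never trajectories.

## Problem sizes and numerical choices

Desk-scale runs (the package's standard study conditions) use 8,000 MEC +
8,000 LEC cells, 8,000 simulated granule cells, 2,000 CA3 cells, 600 s DG
sessions, 300 s CA3 morph sessions and 120 s sessions in the learning-rate
protocol; the test suite exercises the same code at scale factors of 0.02–
0.25, where population sizes and convergence counts shrink together (note
that smaller convergence widens the relative drive spread, so small-scale
metric values are qualitative). Degenerate inputs are handled explicitly:
empty parameter grids, all-identical rate maps (single-cluster fallback with
a warning), silent cells (overlap undefined, excluded from averages),
constant maps (correlation flagged NA), unvisited bins (masked, never
zero-filled). Tie-breaks: cells crossing threshold within the same 1 ms
Euler step share a spike time; k-medoids is deterministic given the distance
matrix.

## Limitations

The model deliberately omits theta-phase structure, conductance-based
synapses, explicit interneurons, axonal delays beyond the two stated lags,
and any plasticity faster than end-of-session updates. With ~2700 synapses
per cell the summed entorhinal drive is so smooth that one generator family
cannot simultaneously reproduce the tissue's sparsity, its place-field
peaks, and the strong single-step morph decorrelation seen in recordings;
the published model evidently used an input-tailoring procedure (fitting
maps to measured spatial-information scores) whose details are not stated.
The package's defaults favor field quality and coverage; consequently the
feedforward population decorrelates less per morph step than the recorded
one, and the recurrence-driven population-vector gains, though positive,
are smaller than the published best-fit values. The morph axis enters
only through LEC map switching; boundary- and object-vector coding are not
modeled. Quantities that depend on absolute population sizes (extreme-value
statistics of the drive, hence the exact sparsity and rhythm) shift with the
scale factor, which is why headline numbers are quoted at desk scale.
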