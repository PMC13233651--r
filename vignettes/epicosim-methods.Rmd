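---
title: "Methods: two-scale co-simulation of seizure dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-scale co-simulation of seizure dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`epicosim` couples two descriptions of the same piece of hippocampal
tissue that live at different spatial scales:

* a **neural-field simulator**: every vertex of a cortical/hippocampal
  surface mesh carries a six-state Epileptor neural mass, coupled to the
  rest of the mesh through delayed long-range ("global") connections and
  through a Heaviside-gated local kernel over geodesic neighborhoods;
* a **spiking network** of CA1 point neurons (conductance-based bursting
  cells with short-term-plasticity synapses), driven from the field
  through per-vertex devices that convert the field state into
  inhomogeneous Poisson spike trains.

The coupling is one-directional: the field drives the spiking network in
lockstep (identical step `dt = 0.1` ms on both sides), while per-vertex
spike counts are logged as feedback messages but not applied. A feedback
hook exists (`feedback_gain`) and is covered by tests, but it is disabled
by default.

# The field model

Each mesh node integrates six states: the fast discharge pair
(`x1`, `y1`), the slower spike-and-wave (SWE) pair (`x2`, `y2`), the slow
permittivity `z` that governs transitions between interictal and ictal
regimes, and a low-pass integral `g` of past `x1` activity that couples
the two subsystems:

* `dx1/dt = tt * (y1 - f1(x1, x2, z) - z + Iext + glob + lc11)` with the
  cubic/quadratic branch `f1 = a*x1^3 - b*x1^2` for `x1 < 0` and the
  ictal branch `f1 = (x2 - 0.6*(z - 4)^2 - m)*x1` otherwise,
* `dy1/dt = tt * (c - d*x1^2 - y1) / tau1`,
* `dz/dt  = tt * (4*(x1 - x0) - z) / tau0`,
* `dx2/dt = tt * (-y2 + x2 - x2^3 + Iext2 + bb*g - 0.3*(z - 3.5) + lc22)`,
* `dy2/dt = tt * (-y2 + f2(x2)) / tau2` with `f2 = 0` below `x2 = -0.25`
  and `aa*(x2 + 0.25)` above,
* `dg/dt  = tt * (-0.01*(g - 0.1*x1) + lc12)`.

Defaults are the calibrated values of `sem_parameters()`: `Iext = 3.1`,
`Iext2 = 0.45`, `tau0 = 2857`, `tau1 = 1`, `tau2 = 10`, `tt = 0.17`,
`k = 0.636`, `gamma11/12/22 = 0.34/0.064/0.032`,
`theta11/12/22 = -1/-1/-0.5`. The ictal-dynamics parameter `m` defaults
to 0 (the conventional value for this model family); it is exposed in the
configuration. The excitability `x0` selects the regime per node:
epileptogenic-zone nodes use `-1.6`, propagation zones `-1.9`, and
`-2.2` marks tissue with a true stable equilibrium.

**Global coupling** acts on `x1` as a difference coupling
`k * gamma_glob * sum_j w_ij * (x1_j(t - d_ij) - x1_i(t))`, with delays
`d = tract_length / conduction_speed` (default 3 mm/ms, configurable; no
value is canonical for this preparation). The difference form vanishes at
consensus, so a homogeneous rest state is preserved by coupling. Past
`x1` values are served from a ring-buffer history whose depth covers the
maximal delay; the buffer is pre-filled with the initial state.

**Local coupling** uses a Laplace (exponential) kernel
`K_ij = exp(-d_ij / sigma)` on geodesic distances with a hard cutoff
(defaults `sigma = 2` mm, `cutoff = 6` mm; row normalization available
but off by default). Geodesic distances are edge-graph shortest paths
(Dijkstra) on the triangulation - the standard approximation, adequate at
the mesh resolutions used here. The three Heaviside terms
`lc11/lc12/lc22` gate on `x1` (twice) and `x2` and feed the `x1`, `g`
and `x2` equations respectively; the kernel has no self-term (a node does
not locally drive itself).

## Numerics

Integration is deterministic Heun (predictor-corrector) at `dt = 0.1` ms;
no stochastic forcing is used anywhere in the field. Both coupling inputs
are evaluated once per step, from the state at the beginning of the step,
and held fixed across the two Heun stages - the convention of reference
delayed neural-field integrators, and the choice that keeps the sparse
ring-buffer path exactly equivalent to a dense full-history evaluation
(asserted to 1e-10 in the tests). The hot loop is compiled (C++); the
R-level `heun_step()` is retained as the readable reference and the two
paths are asserted to agree step for step. Synaptic and conduction delays
are rounded to integer steps (nearest, ties up; minimum one step on the
spiking side).

## The printed initialization is not an equilibrium

The interictal initialization `(-1.5, -11, 3, -0.9, 0.3, -0.1)` is a
point on the slow interictal branch, not a root of the vector field: the
fast recovery variable `y1` sits ~0.75 off its nullcline
(`1 - 5*x1^2 = -10.25` at `x1 = -1.5`) and relaxes within tens of
milliseconds, and `z` drifts on the `tau0` time scale. Two consequences
shape the tests:

* `find_fixed_point()` locates genuine equilibria (residual < 1e-10);
  for `x0 = -1.9` the root sits at `x1 ~ -1.16`, about 0.34 from the
  printed `-1.5`, and is unstable - only `x0` below about `-2.06` yields
  a true stable rest. We therefore assert proximity to the printed point
  with tolerance 0.4 and treat the rest-state stability check as a
  quasi-stationarity bound (tight on `x1`, `z`, `g`; loose on `y1`).
* a `-1.9` node started at the printed point is quiescent on the study's
  simulated window (~2 s) but transitions on its own at ~2.0-2.1 s as
  `z` drifts below the interictal saddle-node. The excitability tests use
  a 1800 ms window, inside which the dichotomy
  (-2.2 and -1.9 silent, -1.6 seizing at ~1.2 s) holds with double-digit
  percentage margins. Recurrence is counted on `z` cycles, which rise and
  fall exactly once per seizure.

## Seizure detection

The analysis marker is `x2 - x1`. At rest it sits near `+0.6`
(`-0.9 - (-1.5)`); autonomous seizures oscillate between about `-2.8`
and `+2.4`, and nodes recruited by local coupling ramp from `0.6` up to
`~2.7` without any preceding downswing. The default detector therefore
fires on upward crossings of `1.0` (between the rest value and ictal
amplitudes), with hysteresis re-arming `0.5` below threshold; both are
configurable. `seizure_episodes()` merges the per-SWE-cycle events of one
ictal episode.

# The spiking network

Neurons are conductance-based bursting cells in the Hill-Tononi style:
leak Na/K currents with membrane time constant 16 ms, a dynamic threshold
(equilibrium -51 mV, 2 ms relaxation), a spike shape that jumps to
`E_Na = 30` mV and repolarizes toward `E_K` with `tau_spike = 1.75` ms
during the 2 ms refractory period, and four intrinsic currents -
persistent sodium, a spike-triggered sodium-activated potassium
adaptation (`D` variable, 1250 ms decay), low-threshold calcium (dynamic
inactivation) and the anomalous rectifier `I_h`. All constants are
exposed in `ht_parameters()`. This parameterization is silent at rest and
produces recurrent burst firing under sustained step current (several
spikes within tens of milliseconds separated by hundreds of milliseconds
of adaptation silence), the qualitative CA1 signature the network is
meant to carry; the exact spike counts are verified by this package's own
tests rather than taken from any published table. The network is treated
as a single excitatory (pyramidal) population; interneuron classes are a
known omission.

Recurrent synapses follow the Tsodyks-Markram short-term-plasticity
recursion (utilization `U = 0.5`, recovery 800 ms, facilitation off by
default - a depressing excitatory profile), applied event-wise at
presynaptic spikes; the conductance is a normalized dual-exponential
AMPA channel (0.5/2.4 ms). Relay synapses from the per-vertex devices are
static, with default weight 20 - sized so a single relayed spike is
suprathreshold from rest - and 1 ms delay.

Synthetic connectivity emulates a morpho-anatomical wiring strategy at
test scale: connection probability decays exponentially with 3D somatic
distance (`length_scale = 1.5` mm), normalized per source so the expected
out-degree equals `mean_degree`; no self-loops. `downscale()` samples
neurons uniformly without replacement and keeps exactly the induced
subgraph, with order-preserving re-indexing; `integrity_stats()` provides
the density/degree/length distributions used to compare a reduced network
with its parent.

# The bridge

The conversion layer maps each CA1 vertex's state to a per-step Poisson
parameter:

```
p_x1 = max(0, (x1 + 2)    * 0.375 * dt)
p_x2 = max(0, (x2 + 0.5)  * 1.25  * dt)
lambda = p_x1 + p_x2,   spikes ~ Poisson(lambda)
```

with `dt = 0.1` ms. `lambda` is a dimensionless per-step expected count;
dividing by `dt` converts to a rate. At rest the SWE channel is exactly
zero while the fast channel keeps a small constant baseline
(`0.01875` per step) - the rectification boundary sits at `x1 = -2`,
below the resting `-1.5`. Over a full simulated seizure of one
epileptogenic node the maxima are ~0.18 (SWE channel) and ~0.13 (fast
channel), inside the calibrated bounds of 0.31 and 0.16, with the fast
maximum roughly half the SWE maximum by construction of the gains.

Messages are exchanged in lockstep, one vector per step, ordered by
device creation order = ascending CA1 vertex id after relabeling. The
exchange is transport-agnostic: an in-process transport and a serialized
(full-precision text round-trip) transport are provided and asserted to
produce byte-identical logs. One Poisson draw is taken per vertex per
step (counts may exceed 1); each device spike fans out identically to the
whole subpopulation.

# Geometry and co-registration

The synthetic hippocampus is a curved rectangular sheet parameterized
analytically by intrinsic anterior-posterior / proximal-distal (AP-PD)
coordinates (defaults 40 x 10 mm, human scale), rolled along PD with
constant curvature - an isometric embedding, so the stored AP-PD
coordinates are exact ground truth for flat-mapping and no registration
step is computed or emulated. PD bands are labeled
subiculum / CA1 / CA2 (25/50/25%), so the relabeling rule is exercised at
both band boundaries. Somata are sampled uniformly in AP-PD over a
pyramidal-layer band straddling CA1 (PD fraction 0.2-0.8) and displaced
along the outward normal by up to `thickness` (0.5 mm).

Assignment attaches each neuron to its nearest eligible vertex
(CA1/CA2/subiculum) in AP-PD space - a strict partition with lowest-id
tie-breaks, so each device drives a disjoint subpopulation and per-vertex
spike counts are unambiguous. Relabeling then (1) promotes assigned
CA2/subiculum vertices to CA1 and (2) demotes unassigned CA1 vertices to
the label of the nearest non-CA1 vertex; the operation is idempotent and
afterwards CA1 vertices and neuron-bearing vertices coincide.

# Validation analyses

`hilbert_phase()` builds the analytic signal by FFT (mean removed,
negative frequencies zeroed) and returns phases in `[-pi, pi)`.
`phase_locked_histogram()` bins spikes at the phase of their vertex's
signal at the spike time, on 20 half-open, left-inclusive bins, excluding
the first and last 5% of samples against edge artifacts, and averages
per-vertex histograms across CA1 vertices; `vector_strength()` is the
mean-phasor magnitude. Two phase sources are supported and neither is
canonical: the state signal `x2 - x1` and the transmitted spike
probability `lambda`. For locking statistics the probability source is
the informative one: against `x2 - x1`, the fast-discharge and SWE spike
clusters sit at opposite phases and their phasors partially cancel.

The phase-locking validation runs the co-simulation in the configuration
used to validate synchronization - recurrent connectivity disabled, the
full CA1 band ictal - and checks (1) that spike vector strength exceeds
the 95th percentile of 200 time-shuffled nulls (circular shifts, which
preserve the signal's own phase occupancy - the null is deliberately
strict) and (2) that the modal bin of the average histogram is the phase
bin carrying the largest transmitted-probability mass. Relayed network
spikes are allowed a mode shift of up to two bins: synaptic integration,
bursting and adaptation move spike mass slightly within the cycle.

# What the synthetic data do and do not show

The generators reproduce the *structural* properties the method needs:
labeled bands with ground-truth flat-map coordinates, distance-dependent
connectivity with controllable degree, co-registered somata. They do not
emulate subject-specific anatomy, real tractography weights, laminar
microcircuitry, inhibition, or registration error between the two
coordinate systems (the synthetic AP-PD map is exact). Green tests
therefore certify the machinery - coupling algebra, exchange contract,
downscaling, conversion calibration, phase analyses - not the fidelity of
any subject-level prediction.

# Problem sizes

The shipped experiments are chosen for routine desk-scale runs: field
meshes of 72-200 nodes (the full-resolution surface of the original
study, with 4e5 nodes and 5e6 neurons, is supported by the sparse data
structures but not exercised), spiking networks of 100-10,000 neurons,
single-node trajectories of up to 70 s, and co-simulations of 0.2-1.2 s
at `dt = 0.1` ms. The complete test suite runs in a few minutes on one
core.
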