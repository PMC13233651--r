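# epicosim

Two-scale co-simulation of seizure dynamics: a surface Epileptor
neural-field model coupled one-directionally to a spiking network of
hippocampal CA1 point neurons.

## What it is for

Epileptic seizures are whole-brain events with cellular-scale
consequences. Clinically oriented models describe seizure onset,
propagation and termination with neural masses on a patient's cortical
surface; mechanistic models describe how individual CA1 neurons and
synapses respond. `epicosim` is for computational neuroscientists who
want both in one reproducible simulation: a high-resolution field model
drives a biophysical spiking network of the same tissue, in lockstep,
through a calibrated rate-conversion interface, so that macroscale ictal
dynamics and microscale spiking can be analyzed against each other.

## The model

Every mesh vertex carries the six-state Epileptor: fast discharges
(x₁, y₁), spike-and-wave events (x₂, y₂), the slow permittivity z that
switches nodes between interictal and ictal regimes, and an integral
coupling g. Per-node excitability x₀ defines the epileptogenic zone
(x₀ = −1.6) and propagation zones (x₀ = −1.9). Nodes interact through
delayed long-range difference coupling on x₁ (weights/tract lengths in
sparse matrices, delays = length/speed, history ring buffer) and through
Heaviside-gated local coupling over a Laplace kernel on geodesic
neighborhoods (strengths γ₁₁/γ₁₂/γ₂₂ = 0.34/0.064/0.032, thresholds
−1/−1/−0.5). Integration is deterministic Heun at dt = 0.1 ms with a
compiled core.

The bridge converts each CA1 vertex state to a per-step Poisson
parameter through rectified linear transforms,

    p_x1 = max(0, (x1 + 2) · 0.375 · dt)
    p_x2 = max(0, (x2 + 0.5) · 1.25 · dt)
    spikes ~ Poisson(p_x1 + p_x2)

and relays the device spikes to a disjoint per-vertex subpopulation of
conductance-based bursting neurons (Hill–Tononi-style intrinsic currents,
Tsodyks–Markram short-term plasticity). Feedback spike counts are logged
but not applied (one-directional by design; the hook exists). The package
also provides the co-registration pipeline (synthetic hippocampal sheet,
AP–PD flat-mapping, nearest-vertex assignment, anatomical relabeling),
network downscaling with integrity statistics, and the validation
analyses (Hilbert phase, phase-locked spike histograms, vector strength,
onset-latency maps).

## Worked example

```r
library(epicosim)

# synthetic geometry: labeled hippocampal sheet + co-registered neurons
geo <- build_geometry(n_ap = 12, n_pd = 6, n_neurons = 180, seed = 5)
geo$mesh
#> <surface_model> 72 vertices, 110 triangles
#>   labels: CA1=47, CA2=12, subiculum=13

# spiking network with distance-dependent connectivity
net <- build_synthetic_connectivity(geo$cloud, mean_degree = 8, seed = 11)
net
#> <spiking_network> 180 neurons, 1431 connections

# local coupling kernel over geodesic neighborhoods
kern <- local_kernel(geodesic_distances(geo$mesh, cutoff = 6),
                     sigma = 2, cutoff = 6)

# one-directional co-simulation: CA1 epileptogenic, onset in 4 vertices
dev <- geo$assignment$device_order        # 47 CA1 devices
x0 <- rep(-1.9, nrow(geo$mesh$vertices)); x0[dev] <- -1.6
res <- run_cosimulation(sem_parameters(x0 = x0), geo$mesh, kernel = kern,
                        onset_nodes = dev[1:4], net = net,
                        assignment = geo$assignment,
                        duration = 800, seed = 42)
res$spikes
#> <spike_record> 28008 spikes over 800 ms, 47 devices
round(sum(res$rate_log), 1)   # total transmitted expectation (spikes)
#> [1] 30316.8
sum(res$spikes$device_counts) # Poisson spikes drawn by the devices
#> [1] 30532

# phase-locking validation (transmitted-probability phase source)
ph <- phase_from_recording(res$field, dev, source = "probability")
phase_locked_histogram(ph, res$spikes)
#> <phase_lock_histogram> 24802 spikes, 20 bins, vector strength 0.289
```

The transmitted expectation and the realized device spike count agree to
within Poisson noise; the network spikes concentrate around the phases
with the highest transmitted spike-generation probability (vector
strength well above a time-shuffled null — see the acceptance suite).

A command-line wrapper is installed with the package
(`exec/epicosim`): subcommands `generate-fixture`, `simulate-field`,
`simulate-snn`, `downscale`, `cosim` and `analyze`, each writing its
outputs together with the resolved configuration and seed.

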