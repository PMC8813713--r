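---
title: "A cortical-column model of auditory evoked fields: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cortical-column model of auditory evoked fields: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Monaural pure tones evoke a stereotyped source-localised response over
auditory cortex: a small positive deflection near 50 ms (P50m), a prominent
trough near 100 ms (N100m), and a second positive peak near 180-200 ms
(P200m), measured as an equivalent-current-dipole time course in nAm.  Two
robust empirical effects call for a mechanistic account: the N100m is larger
over the right hemisphere than the left, and larger (and slightly earlier)
for contralateral than ipsilateral tone presentation.

`aefsim` implements, as a self-contained R package, a biophysical cortical
column in the lineage of the Human Neocortical Neurosolver (HNN) class of
models, together with the full analysis pipeline needed to simulate these
auditory evoked fields (AEFs), quantify them the way MEG studies do, fit the
exogenous drive parameters by RMSE minimisation, and run the 2 x 2
repeated-measures statistics.

## The column model

The network is a reduced patch of sensory neocortex: per layer, 100
multi-compartment pyramidal neurons (8 sections in layer II/III, 9 in layer
V, with soma, apical trunk/tuft, an oblique branch, and three basal
sections) and 35 single-compartment fast-spiking basket cells.  Dynamics are
Hodgkin-Huxley style: Traub-kinetics Na+ and delayed-rectifier K+ in every
cell, a slow non-inactivating K+ (M-type) conductance, and — in layer V
pyramids only — high-voltage-activated Ca2+, a Ca2+-activated K+ current
fed by a 20-ms calcium pool, a T-type Ca2+ current, and an h-current whose
density grows exponentially along the apical axis.  Synapses are
double-exponential conductances (AMPA 0.5/5 ms, NMDA 1/20 ms with a standard
sigmoidal magnesium block, GABA-A 0.5/5 ms, GABA-B 1/20 ms), and cells are
coupled through the canonical local circuit: within-layer E-E and I-I
connections, translaminar L2/3-to-L5 excitation, somatic basket inhibition
in both layers, and L2/3-basket inhibition of the layer-V apical tuft.
Connection strengths fall off with a per-connection Gaussian distance kernel
on the cell grid (`kernel = FALSE` gives uniform all-to-all coupling).

The recorded quantity is the primary current dipole: for every pyramidal
cell, the intracellular axial current between connected compartments times
the vertical separation of their centres, summed over cells and reported
per layer and in aggregate, positive for current towards the cortical
surface.  Internally the trace is in fAm per network; the pipeline converts
to nAm after multiplying by the scaling factor.  With the default
parameters a simulated N100m corresponds to roughly 0.5 pAm per modelled
pyramidal neuron — the same order as the ~0.2 pAm per cell usually assumed
when converting dipole moments to contributing-cell counts
(`estimateContributingCells()`, `scalingFromSignal()`).

The column is activated by three exogenous spike volleys
(`presetDriveSequence()`): a proximal (feedforward, lemniscal-thalamic)
drive onto basal/oblique pyramidal dendrites and both basket populations, a
distal (feedback) drive onto the apical tufts and layer II/III baskets
(never layer V baskets), and a second proximal drive.  Each target cell
receives one spike per drive per trial, drawn from a per-drive Gaussian
(mean, SD); the 28 drive parameters of a condition are the three means,
three SDs and 22 synaptic weights.  Sampled times are clipped to the
`[0, duration]` window rather than resampled; at the preset parameters
clipping is vanishingly rare.

### Numerical scheme

A fixed-step semi-implicit integrator at `dt = 0.025` ms: gating variables
advance by exponential Euler with rates tabulated on a 0.05 mV voltage
grid, then the cable equation is solved by backward Euler on each cell's
branched tree via Hines elimination, which is unconditionally stable.  The
scheme is first-order; the test suite checks self-convergence under `dt`
halving and agreement with the closed-form RC charging curve on a passive
compartment to better than 1%.  Simulations start from the steady state of
the unstimulated network, obtained once per network by settling the model
for 4 s at a coarse step (the fixed point of the implicit scheme is
independent of the step size) and cached; dipole traces are reported
relative to the resting dipole, and the residual drift of a quiescent
network is below ~1 fAm peak-to-peak over the 250 ms epoch (the evoked
deflections are tens of thousands of fAm).  Drives begin at or after
~47 ms, which doubles as settling margin.

### Fixed parameters and their provenance

Cell geometry, capacitances, axial resistivity, peak conductances of the
local synapses and the drive-targeting rules follow the published
conventions of the canonical HNN-style column (reduced Bush-Sejnowski
pyramidal morphologies; e.g. L2/3-basket-to-L2/3-pyramid GABA-A/GABA-B at
5e-2 uS, pyramidal-to-pyramidal AMPA/NMDA at 5e-4 uS, space constants of 3
grid units for excitation and 20-70 for inhibition).  A subset of
quantities could not be taken from a published table and are package
choices, set so that the column reproduces the documented sequence of
network events — early feedforward firing of layer II/III baskets that
quickly silences most superficial pyramids, a distal-drive-evoked burst of
layer V pyramids supported by apical calcium, and renewed basket firing at
the late proximal drive — and then frozen:

* M-type K+ densities (5e-3 S/cm2 at pyramidal somata, 1e-4 in dendrites,
  2e-3 at the layer-V soma, 8e-3 / 7.5e-3 S/cm2 in layer II/III / V
  baskets).  Dendritic M-current an order of magnitude above the chosen
  value electrically isolates the apical tree and abolishes the N100m
  mechanism, which is why the soma/dendrite split matters.
* KCa density 1e-3 S/cm2: the termination mechanism for the apical calcium
  plateau; much weaker values leave the layer-V dendrites in a standing
  depolarised state that drags the late dipole negative, much stronger
  values abolish layer-V spiking.
* Basket cells: plain Na/K fast-spiking complement (0.10 / 0.08 S/cm2) with
  the M-type adaptation above; without adaptation the ~1 uS NMDA drive
  weights of the fitted conditions make baskets fire tonically at several
  times the reported rates.
* Inhibitory synaptic events reach their targets with a 3 ms base delay
  (excitatory: 1 ms), an effective lumped delay for GABA release and the
  di-synaptic feedforward route; the relative timing of drive excitation and
  basket inhibition decides what fraction of layer II/III pyramids fire and
  is the single most sensitive timing constant in the model.
* The GABA-B decay on layer II/III pyramids is 27 ms (20 ms elsewhere),
  which holds the superficial pyramids in check between the distal and the
  late proximal drive.
* NMDA receptors carry a standard magnesium block
  (1 / (1 + exp(-0.062 V) [Mg]/3.57), [Mg] = 1 mM); the reference column
  software models NMDA as voltage-independent, so this is a deliberate
  physiological refinement, and the concentration is exposed in
  `defaultNetworkParams()$constants`.

Every one of these values lives in the registry returned by
`defaultNetworkParams()` and can be replaced through `networkConfig()`.

### Emergent behaviour under the fitted drive parameters

With the right-hemisphere contralateral drive parameters and scaling 1500,
ten-trial averages show the P50m (positive, ~55 ms), N100m (negative,
~103 ms, ~145 nAm) and P200m (positive, ~163 ms).  Population firing rates
(5 x 10 trials) are ~1.7 / 13.8 / 12.2 / 13.4 spikes/s for layer II/III
pyramids, layer II/III baskets, layer V pyramids and layer V baskets.  Note
that the layer V rate is quantised: late network bursts are all-or-none
events, so this rate moves in steps of roughly 1.5 spikes/s across
parameter or seed changes.  Reducing the distal layer-V AMPA weight from
0.964 to 0.258 uS (the left-hemisphere model) shrinks the N100m by ~25%;
delaying all drives by 5 ms shifts the waveform rigidly (the integrator
starts from a true steady state, so time invariance holds to numerical
precision); reducing the scaling factor from 1500 to 1200 scales amplitude
and slopes by exactly 0.8 (the pipeline is linear).

## The processing pipeline

`conditionWaveform()` applies, in a fixed order recorded in the trace
metadata: trial averaging, scaling (and fAm-to-nAm conversion), smoothing
with a unit-area Hamming window of 30 ms (odd length
`round(window / dt) + 1`, reflect padding at the edges — the choice of
padding only affects the outer half-window of the epoch), and linear-
interpolation resampling onto the 600 Hz acquisition grid, `k/600` s for
`k = 0..150` (151 samples spanning 0-250 ms; both endpoints included).
Every stage is linear, so averaging, scaling and smoothing commute exactly;
the test suite asserts these identities at 1e-12.

Quantification mirrors standard AEF practice: the N100m is the absolute
extremum of the aggregate waveform in the closed 80-120 ms window (reported
as magnitude + latency, ties to the earliest sample), the two slopes are
ordinary least-squares fits over 70-90 ms and 110-130 ms, and model fit is
the RMSE over the full 0-250 ms epoch (window configurable).

## Drive-parameter fitting

`optimizeDriveParameters()` minimises the RMSE between the processed
simulation and a target waveform over a bound-constrained parameter vector
(times, SDs, weights, optionally scaling; frozen flags select the free
subset).  The search is derivative-free and staged — each drive optimised in
temporal order (golden-section on a logistic-transformed coordinate for
single free parameters, Nelder-Mead otherwise), then a joint Nelder-Mead
polish — under a hard evaluation budget (default 200).  Evaluations use
common random numbers: the standard-normal draws behind every per-cell
spike time are fixed once per search, so each candidate's objective is
deterministic and varies smoothly with the drive means and SDs.  Three
trials per evaluation trade fidelity for speed during the search; final
reporting should use ten.  Fresh-seed (noisy-objective) evaluation is
available by resampling the draws per evaluation, but is not the default.
The self-consistency experiment in the test suite recovers the three mean
input times to within 2 ms from +/-8 ms perturbations on a self-generated
target.

## Statistics

`rmAnova2x2()` implements the classical within-subject sums-of-squares
decomposition for the 2 x 2 design (Tone Presentation x Hemisphere): each
effect is tested against its own subject-by-effect interaction term with
df (1, n-1).  Both factors have two levels, so sphericity corrections do
not arise.  Effect size is reported as partial eta squared,
SS_effect / (SS_effect + SS_error) — the natural reading when each effect
has its own error term — with classical eta squared alongside.  The
implementation is cross-checked in the tests against `aov()` error strata
and the F = t2 identity for paired contrasts, and its type-I rate is
calibrated on 2,000 null synthetic datasets.

Applying the same ANOVA to repeated simulation runs (the `reproduce` CLI
subcommand does this with simulation index in the role of subject) treats
trial-sampling variability as the only variance source; the resulting
p-values are qualitative indicators, not comparable to the empirical ones.

## Synthetic data

`generateWaveforms()` emulates a 10-subject, 2-hemisphere, 2-presentation
AEF study without any recorded data: each waveform is the sum of three
signed Gaussian components (defaults +25 nAm / 52 ms / 8 ms for the P50m,
-60 / 98 / 12 for the N100m, +30 / 185 / 28 for the P200m — fixture
constants chosen to resemble source-localised AEFs qualitatively, not
values from any dataset), subject-level parameters drawn once per subject
(amplitude SDs 5/12/8 nAm, latency SD 5 ms, width SD 2 ms), condition
effects applied multiplicatively to amplitudes (contralateral/ipsilateral
ratio 1.25; right/left N100m ratio 1.3) and additively to latencies
(+5 ms ipsilateral), plus white Gaussian noise low-pass filtered at 40 Hz
and rescaled to 2 nAm SD (evoked-average-like smoothness).  Setting all
ratios to 1 and shifts to 0 (`generateNullSet()`) makes the four cells of
each subject exchangeable, which is what the type-I calibration relies on.

At these defaults the measurement + ANOVA pipeline detects the 1.3x
amplitude ratio with power well above 0.8 at n = 10 — a fixture property
the tests verify by simulation, not an empirical claim.  What passing these
tests shows is that the pipeline is correct and sensitive on data with the
assumed structure; real MEG waveforms differ in ways the generator does not
emulate (non-Gaussian component shapes, correlated cross-condition noise,
artifact residue, subject-specific morphology), so they say nothing about
effect sizes in real recordings.

## Problem sizes and reproducibility

The package's own experiments use the study-scale configuration throughout:
the full 270-cell column, `dt = 0.025` ms, 250 ms epochs, 10 trials per
condition, 5 seed replicates for firing rates, 2,000 null datasets for the
ANOVA calibration, and a 200-evaluation optimisation budget.  All
randomness flows through R's RNG via explicit seeds (trial t of a condition
uses `base_seed + t`); the integrator itself is deterministic given a
schedule, so identical configurations and seeds reproduce rasters
bit-identically and dipoles to floating-point reproducibility on a given
platform.

## Known limitations

* One compartment per morphological section (no finer spatial
  discretisation); electrotonic attenuation along the long apicals is
  therefore approximate.
* No axonal propagation, no short-term plasticity, no rhythmic/tonic
  drives.
* The late network activity is burst-quantised (see above); quantities that
  count late spikes inherit ~10-15% jumps between dynamical regimes.
* The magnesium block makes NMDA weights not directly exchangeable with
  those of voltage-independent-NMDA implementations at hyperpolarised
  potentials.
* Fixed parameters not available from a published table are reasoned
  package choices (documented above), not measurements; conclusions that
  hinge on their exact values should treat them as free parameters.
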