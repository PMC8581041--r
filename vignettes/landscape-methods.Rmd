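---
title: "Quantifying decision dynamics: model, landscape, flux and kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying decision dynamics: model, landscape, flux and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decisionscape)
```

## The circuit model

`decisionscape` simulates the classic two-choice cortical decision circuit:
a fully connected network of `N_E = 1600` excitatory and `N_I = 400`
inhibitory leaky integrate-and-fire neurons. Two selective populations S1
and S2 (`f = 0.15` of the excitatory cells each) encode the two choices of
a random-dot motion discrimination task; the remaining excitatory cells are
non-selective (NS), and a common pool of interneurons (I) mediates the
competition between S1 and S2.

Each neuron integrates
`C_m dV/dt = -g_L (V - V_L) - I_syn` below threshold `V_th = -50 mV`, emits
a spike on crossing, and is clamped at `V_reset = -55 mV` for an absolute
refractory period (2 ms excitatory, 1 ms inhibitory). `I_syn` has four
conductance-based components: external AMPA (all background and stimulus
input), recurrent AMPA, recurrent NMDA with the magnesium voltage gate
`1/(1 + [Mg]exp(-0.062 V)/3.57)`, and GABA. Gating variables live on the
presynaptic neuron: AMPA and GABA jump by one per spike and decay with 2 ms
and 5 ms; NMDA saturates through the two-variable rise/decay dynamics
(rise 2 ms, decay 100 ms, coupling `alpha = 0.5/ms`), which provides the
slow reverberation that sustains decisions.

Synaptic structure follows the Hebbian-prestructured weight matrix: weight
`w_plus > 1` within each selective population, the compensating
`w_minus = 1 - f (w_plus - 1)/(1 - f)` between the selective populations
and from NS onto them, and 1 elsewhere, so the spontaneous-state recurrent
drive `f w_plus + (1 - f) w_minus = 1` is independent of `w_plus`
(`derive_w_minus()`). GABA synapses are unweighted; their sign enters
through the driving force `(V - V_I)`.

Every neuron receives independent background Poisson input at 2.4 kHz. A
stimulus of strength `mu` (Hz) and coherence `c` adds independent Poisson
trains at `mu1 = mu(1 + c)` to S1 and `mu2 = mu(1 - c)` to S2 through the
same external-AMPA channel — the equation for the external current names a
single term, so background and stimulus share one gating variable.

### Numerical scheme

The smooth parts of the membrane and gating equations are advanced with a
Heun (second-order Runge-Kutta) step at `dt = 0.02 ms`. Delta inputs are
not Runge-Kutta-integrable, so spike and Poisson increments are applied as
unit jumps between steps; spikes are detected at step boundaries without
sub-step interpolation (at this `dt` the timing error is negligible).
Poisson arrivals are drawn as per-step counts, which is exact in
distribution for the count process given that increments land on step
boundaries. Each neuron owns an RNG stream derived from the master seed, so
rasters are bit-reproducible and independent of iteration order. The
magnesium gate is evaluated through a 0.01 mV interpolation table (relative
error ~5e-8, far below the discretization error). Self-connections are
included: the network is fully connected and the autapse contribution is
O(1/N).

Calibration: an isolated neuron under constant suprathreshold current
reproduces the closed-form interspike interval
`tau_ref + tau_m ln((V_inf - V_reset)/(V_inf - V_th))` to better than 1%
(see the test suite), and the full network reproduces the signature
behaviours of this circuit: spontaneous firing at a few hertz, stimulus-
driven winner-take-all selection, and delay-period persistent activity
after stimulus withdrawal.

### Down-scaling

`network_config(scale = k)` divides all population counts by `k` and
multiplies the recurrent conductances by `k`, preserving the mean synaptic
drive per neuron. Finite-size fluctuations grow as `sqrt(k)`: at `k = 4`
the decision attractors are noticeably shallower than at full size, basin
dwell times shorten from minutes to seconds, and the undecided state
retains substantial occupancy at parameters where the full-size circuit is
cleanly bistable. Desk-scale results therefore probe the estimator
machinery and the qualitative attractor structure; quantitative
reproduction of full-size landscape topographies requires `scale = 1` runs
of several hundred seconds, which the protocols support but the test suite
does not attempt.

## From spikes to the decision space

Population rates are box-window counts: total spikes of a population in a
50 ms window sliding in 5 ms steps, divided by population size and window
length (`compute_population_rates()`). Windows are right-aligned (the
sample at `t` covers `(t - window, t]`) and partial windows are dropped.
The pair `(r1, r2)` of selective-population rates is the decision space.

## Landscape

`estimate_pss()` bins pooled `(r1, r2)` samples on a regular grid; the
potential is `U = -ln P_ss`. Unvisited bins stay `NA` — flooring them would
fabricate potential values, and barrier paths are not allowed to traverse
them. Convergence of `P_ss` is monitored with the relative L2 distance
`sigma = ||P_b - P_a|| / ||P_a||` between distributions estimated from
nested stretches of data.

Two practical choices matter at desk scale:

* **Bin width.** Window counts are integers, so rates are multiples of
  `1/(N_pop * window)`. Bins narrower than this quantum produce a comb of
  artificial minima; the network protocols therefore widen bins to at
  least ~3 quanta.
* **Minima pruning.** Raw finite-sample histograms produce one-bin dimples.
  `find_minima()` smooths `U` with an optional 3x3 boxcar pass and prunes
  minima by topographic persistence (watershed sweep): a minimum absorbed
  by a deeper basin less than `depth = 0.5` (dimensionless potential) above
  its bottom is discarded; a minimum on a disconnected island of visited
  bins is credited with the island's relief.

Minima are labelled by position — SS (both rates low), DS1/DS2 (one high),
DU (both high) — with a configurable cutoff of 15 spikes/s, the
conventional decision threshold for this circuit.

Saddles between minima are minimax levels over 8-connected paths through
visited bins, computed by the sorted-bin union-find sweep (equivalent to
exhaustive path search, and tested against brute-force enumeration).
Barrier heights `BH = U_saddle - U_min` and relative barriers
`RB = BH_from - BH_to` follow directly.

## Probability flux

Broken detailed balance is quantified on a coarse `N1 x N2` box grid
(default 20x20 — coarser than the landscape grid because every face needs
many crossings). Consecutive samples in different boxes are linearly
interpolated so that every crossed face of the straight segment is tallied
with its direction, in parametric order. Net signed rates
`w = (N_forward - N_backward)/t_total` per face are averaged over the two
faces of each box per direction to give the flux vector `J`; rates across
the domain boundary are zero. Per-box standard errors come from splitting
the trajectory into 10 contiguous blocks; circulation tests exclude boxes
with `|J|` below twice the block SE.

Oracles: for gradient (equilibrium) surrogates the estimated `|J|` is
statistically indistinguishable from zero; for the rotational
Ornstein-Uhlenbeck surrogate the flux is `J = omega(-y, x) p_ss` and the
estimator recovers its sense in essentially all above-noise boxes.

## Transition kinetics

Attractor regions are small ellipses (default semi-axis 5 spikes/s) around
landscape minima. First-passage sampling arms a clock when the trajectory
is inside the source region, records a sample at the first subsequent entry
into the destination, and re-arms at the next source visit; windows ending
mid-transition are censored and flagged when they exceed 10% of
observations. The MFPT estimator is validated against the classical 1D
mean-exit-time double integral on the double-well surrogate (quadrature on
a fine grid).

Transition paths run from the last point inside the source region before a
successful excursion to the first point inside the destination; returns to
the source restart the path. Because single transits have diverse
durations, each path is resampled to a fixed number of points by even
interpolation along its sample index (the most literal reading of
"split evenly into equal numbers of points"; arc-length alignment would
weight fast and slow segments differently) and averaged pointwise. Forward
and backward averages differ in the presence of curl flux; on a
time-reversed trajectory the asymmetry flips exactly, which the tests
assert as an identity.

## Surrogates: what they emulate and what they do not

The three Langevin families (`double_well` — optionally tilted,
`triple_well`, `linear_rotational`) share the trajectory container with the
network, offset into positive rate-like units. They provide exact
references: Boltzmann stationary densities for the gradient families, the
Gaussian law with covariance `(D/k) I` and rotational flux for the linear
family, and quadrature escape times for the (1D-reducible) double well.
They emulate the *geometry* of the decision problem — multistability,
barriers, noise-driven switching — but not the network's features:
state-dependent noise, discrete rate quanta, slow NMDA-correlated
fluctuations, or asymmetric basin shapes. Passing the surrogate oracles
therefore validates the estimators, not the neuroscience; the network
checks do the latter at desk scale.

## Protocol parameters and problem sizes

The packaged protocols default to desk-sized problems chosen for
statistical adequacy: landscape runs pool ~5-14 trials of 8-10 s at
`scale = 4` (a few thousand post-transient samples on ~30x40 bins),
discarding the first 2.5 s of each trial as transient; network
transition-path averages pool trials across ~6 seeds so that each
direction collects several tens of switching events (pointwise standard
errors of the average path stabilize around K ~ 50); surrogate oracle
runs use 20-60 s of Langevin time, which yields hundreds of escape events
for first-passage checks. All protocols accept externally supplied
trajectories (`input =`), so the full analysis chain is exercisable on
surrogates alone, and every run embeds a manifest (configuration, seeds,
package version) from which `replay_manifest()` reproduces outputs
bit-for-bit.

The ramp protocol realizes a "continuously varied" stimulus as a staircase
over the levels 5, 16, 40, 76, 90 Hz (the ramp rate is otherwise
unconstrained); hysteresis is reported as the number of levels whose modal
state differs between the up and the down passes. The parameter census
counts minima per `(w_plus, mu)` cell from pooled multi-trial landscapes.

## Known limitations

* The landscape is a 2D projection of the 4-population rate dynamics;
  projection can merge structure that is separated in higher dimensions.
* Finite trajectories under-sample deep basins; barrier values carry
  sampling bias that shrinks only logarithmically with data volume.
* At reduced scale, finite-size noise reshapes the attractor structure
  itself (see Down-scaling above); counts obtained at `scale = 4` need not
  match the full-size circuit in every regime.
* First-passage estimates drop censored windows rather than correcting the
  likelihood; with heavy censoring the MFPT is biased low and flagged.
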