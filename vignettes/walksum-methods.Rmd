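---
title: "Frequency-dependent communication channels of a structural connectome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-dependent communication channels of a structural connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walksum)
```

## The model

A weighted structural connectome `C` (N regions, nonnegative symmetric
weights, zero diagonal) supports signal propagation along its connections
with a characteristic conduction delay `T` per hop (default 10 ms, a
tractography-scale mean, not a fitted parameter).  A walk of `k` hops
contributes the product of its edge weights times a phase factor of
magnitude `k·ω·T`.  Summing over all walks of all lengths gives a geometric
matrix series whose closed form is the resolvent transfer function

    H(f) = (I − e^{s·i·2πfT} C)^{−1},     s = ±1,

valid whenever the spectral radius of `C` is below one.  `connectome()`
guarantees this on construction by dividing by `1.01 ×` the largest
eigenvalue magnitude when necessary (the safety factor is an argument).

`H(f)` splits into the **integrative channel** `I(f) = Re H(f)` — in-phase,
constructive accumulation across walks — and the **routing channel**
`Q(f) = Im H(f)` — the phase-shifted component that supports
frequency-selective, directional communication.  At low frequencies the
phase cost of a hop is small, long hub-mediated walks add up coherently and
the network acts as a broadband integrator; as frequency rises, the phase of
long walks disperses and communication contracts to short, direct routes.
The frequency at which the rank correlation of `Q` with fibre-tract distance
flips sign — the **Q-crossover** — marks that transition.

### The two package-wide conventions

Two conventions determine every number downstream, and both are explicit
arguments recorded in each result object:

1. **Hz versus radians.**  All grids are in Hz; the walk phase is always
   `ωT = 2π·f·T` with `T` in seconds.  The local gain (below) takes Hz
   directly because it depends only on `f/f0` and the damping ratio.
2. **Phase sign** (`phase_sign`).  The default `−1` treats the conduction
   delay as a phase *lag*, `e^{−iωT}` — the transfer function of a pure
   delay under the engineering Fourier convention.  `+1` gives the complex
   conjugate field: identical I, negated Q.  The channel phenomenology this
   package studies (positive `ρ(Q, d)` below a crossover, a negative
   alpha-band Q trough) appears in the lag convention on every
   distance-embedded network we generated, which is why it is the default;
   the conjugate convention is one flag away, and every `resolvent_field`
   records which sign produced it.

### Why a crossover, and why it is resolution-stable

On a network whose long-range traffic is routed through hubs, a distant pair
communicates through a roughly fixed number of hops — periphery → hub →
hub → periphery, about 3–4 — no matter how finely the surface is
parcellated.  The `k`-hop contribution to `Q` flips sign when `k·2πfT`
passes `π`; with `k = 4` and `T = 10` ms this happens at `f = 1/(8T) =
12.5 Hz`, squarely in the alpha band.  Because the routing depth, not the
parcel count, sets the phase budget, the crossover is a topological constant
of the network: this is the mechanism behind its stability under
coarse-graining, and it is why the synthetic generator (below) builds
hub-routed networks by default.

### Local dynamics: the dressed resolvent

Real neural populations are not passive relays.  A damped-harmonic local
gain

    l(f) = f0² / (f0² − f² + 2i·ζ·f0·f)

(two global parameters: natural frequency `f0` in Hz, damping ratio `ζ`)
modulates each node.  `l(0) = 1` and `|l(f0)| = 1/(2ζ)`.  Two readings of
the dressed operator are implemented because the closed form admits both:

* `"literal"` (default): `H = (l·I − l·e^{siωT}C)^{−1}`.  Since both terms
  carry `l`, this equals `(1/l) · H_bare`: a frequency-dependent complex
  rescaling that mixes the channels (its zero-coupling limit is `I/l`).
* `"gain"`: `H = l·(I − l·e^{siωT}C)^{−1}`, the series
  `Σ l^{k+1} e^{s·ikωT} C^k` in which every traversed node contributes one
  gain factor (zero-coupling limit `l·I`).

Neither is asserted as the "true" operator; each is verified against its own
truncated-series oracle, and every fitted or reported result names its
reading.  The group-wise variant replaces the scalar `l` with a diagonal
matrix of per-degree-group gains.

## The synthetic generator

`make_connectome()` is first-class, tested code: its defaults define the
study conditions for every resolution-level claim the package tests.

With `hub_fraction > 0` (default 0.125) it builds a **hub-routed
core–periphery network**: 64 nodes on a ring of radius 80 mm (pairwise
distances up to 160 mm, the fibre-tract range), hubs evenly spread,
peripheral nodes attached to hubs under an exponential distance rule with a
30 mm reach, hub pairs joined by corridors decaying over 100 mm, all weights
carrying lognormal dispersion (sd 0.5) as tractography weights do, then
spectral-radius normalisation.  With `hub_fraction = 0` it instead produces
a dense `exp(−d/λ)` distance-decay lattice (circulant on the ring), which is
the transparent fixture for degree, partition and spectral identities.

What the generator *emulates*: hub-mediated multi-hop routing, realistic
cortical length scales, heavy-tailed weight dispersion, spectral-radius
normalisation.  What it *does not* emulate: direct long-range
periphery–periphery tracts, hemispheric structure, measurement noise,
volume conduction, and — importantly — a local lattice among peripheral
nodes.  A `local_coupling` parameter adds one, but it is 0 by default
because block-merging (`coarse_grain()`) distorts a lattice's short-range
weight mass and destabilises the crossover, whereas hub-routed traffic is
merge-stable.  Passing tests on these networks therefore demonstrate the
*mechanism* (routing-depth-controlled, resolution-stable channel
transitions), not a quantitative prediction for any particular brain
dataset; the crossover frequency itself sits near 25 Hz at these scales
rather than in the alpha band, because the fixture's routing depth is
shallower than a real connectome's.

`make_timeseries()` realises the resolvent as an exact transfer function:
per-node white noise is built in the frequency domain, multiplied bin-wise
by `H(f)` (circular convolution), and inverse-transformed.  One caveat
matters for empirical comparisons: for a *symmetric* network the implied
coherency `G = H·H*` is Hermitian with `Im G = [Im H, Re H]`, a small
commutator.  Linear symmetric filtering therefore produces an almost-real
coherency — its routing channel is structurally tiny and noise-dominated,
so convergence checks are run on `Re` and `|·|` pair profiles, and
imaginary-coherency statistics on generated series should not be
over-interpreted.

## Channel statistics

* **Binning.** `N(N−1)/2` upper-triangle pairs, 20 equal-width bins by
  tract distance (15 is the electrode-data convention), half-open
  `[lo, hi)` bins with the last bin closed; zero or missing distances are
  excluded and counted; empty bins are kept and flagged.
* **Correlations.** Spearman with midranks throughout (`stats::cor`),
  degenerate rank situations return `NA` rather than a fabricated value.
* **Crossover localisation.** Linear interpolation between the bracketing
  grid points of the first positive-to-negative sign change.  A 0.5 Hz grid
  cannot print a crossover such as 12.55 Hz without sub-grid localisation;
  interpolation is the minimal rule consistent with that precision.  An
  exact zero at a grid point is returned as that frequency; absence is a
  value (`NA`), not an error.
* **Divergence.** `D(f) = ρ(Q,d) − ρ(I,d)`; the convergence frequency
  `ω_c` is the grid argmin of `D`, ties to the lowest frequency.
* **Salience.** `S(f)` = pair variance of I plus pair variance of Q.
* **The battery.** C1: mean `ρ(Q,d)` below the crossover is positive, with
  a seeded 1000-draw permutation test shuffling distances (the test is our
  choice; only significance, not a test name, is inherited).  C2: crossover
  present in 8–16 Hz.  C3: band-averaged binned I at the bin containing
  80 mm positive in every band.  C4: the alpha-band binned-Q minimum is
  negative; both the binned minimum and the alpha mean are reported because
  either could serve as "trough magnitude".  C5: "non-trivially structured"
  salience is operationalised as a coefficient of variation of normalised
  `S` above 0.1 — an explicit interpretation, flagged in the report.
  Band averaging always averages per-frequency statistics across the grid
  points inside a band (closed on both ends), never statistics of
  band-averaged matrices.
* Model-side Q statistics are signed; the empirical default is `|Im|`
  (both are exposed everywhere; reports record which was used).

## The eigenmodel

The Laplacian defaults to the symmetric normalised form
`I − D^{−1/2} C D^{−1/2}` (spectrum in `[0, 2]`); mode eigenvalues of the
order 0.07–0.25 for the leading non-constant modes of a parcel-scale graph
are consistent with a normalised spectrum and not with a combinatorial one
on raw tractography sums, hence the default; `"combinatorial"` is a flag.
Projections are quadratic forms `v_m' I(f) v_m` (an expansion-energy variant
exists).  A mode's **peak frequency** maximises its *relative share*
`|p_m(f)| / Σ|p_m'(f)|`: raw projections decay with frequency for every
mode, which would pin all peaks to the grid minimum; the share rule is the
minimal reading that lets higher modes dominate progressively higher bands.
This is flagged as an interpretation.  The constant (λ≈0) mode is included
in indexing but excluded from the eigenvalue–frequency correlation.  The
hub-mode statistic correlates weighted degree with `|v|` of the dominant
eigenvector of `C` (frequency-independent for symmetric weights);
p-values are by seeded permutation for `N ≤ 30`, asymptotic t otherwise.
On simple synthetic hub networks this correlation is strongly *positive*
(the Perron vector loads on hubs) — the opposite of what consensus
connectomes show — which is precisely why the statistic is worth computing:
its sign is a nontrivial fingerprint of real connectome weight structure.

## Spectral estimation

Welch cross-spectra: 2048-sample segments, 50% overlap, Hann window,
constant detrend per segment (the common default; the convention source is
silent on detrending).  Those settings give 0.5 Hz resolution only at
`fs = 1024` Hz; for any other rate the estimator uses its natural FFT grid
and `coherency_on_grid()` maps analysis frequencies to nearest bins,
recording the mapping.  Coherency is `S_ij/√(S_ii S_jj)`; unit diagonal,
`|C| ≤ 1` and conjugate symmetry are tested invariants.  The **dominance
ratio** is `σ1/σ2` of the full complex matrix at a frequency (`Inf` for
rank one).  **Communication dimensionality** is the participation ratio of
the singular values of the stacked 2×P I/Q pair-profile matrix — the term
has no established definition, so this construction is an explicit,
documented interpretation.

## The neural-mass negative control

`simulate_wc()` integrates standard two-population Wilson–Cowan rate units
(logistic sigmoid) by Euler–Maruyama.  The shipped parameter set is the
canonical oscillatory one from the classic rate-model literature
(`c1=16, c2=12, c3=15, c4=3`, gains 1.3/2, thresholds 4/3.7, `P=1.25`) with
10 ms time constants; no parameter values are inherited from elsewhere.
The sweep crosses 8 drive frequencies (2–40 Hz, band-representative) × 6
spatial input configurations (single hub, single peripheral node, all
nodes, seeded random 10%, top-degree 10%, bottom-degree 10% — the set is
our choice, documented here) × 3 couplings (0.2, 0.5, 1.0) = 144
conditions.  Each condition's simulated coherency is compared to the
resolvent at the drive frequency (the natural choice; the comparison
frequency is not otherwise specified): Spearman between the model I/Q pair
profiles and the simulated `Re`/`|Im|` profiles.  Near-zero grand means are
the *negative-control* result: the resolvent describes which channels the
topology affords, not which signals a driven nonlinear system generates.
Rates stay in `[0, 1]` for noise-free integration because each Euler step
is a convex combination when `dt < τ`.

## Fitting the dressing

The objective — unspecified by the framework itself, so declared here — is
the Spearman correlation between model and data *concatenated
distance-binned profiles* (I and `|Q|`, bins × grid frequencies); an
I-only variant and band restrictions are available, and every reported ρ
names its variant.  The homogeneous search is exhaustive on the declared
grid (`f0` 5–16 Hz by 0.5; `ζ` 0.05–1.0 by 0.05; 460 cells), ties to the
lowest `f0` then lowest `ζ`, a degenerate (constant) target returns the
grid origin flagged low-confidence.  Cross-validation is
leave-one-dataset-out with training profiles averaged element-wise.  The
heterogeneous fit runs cyclic coordinate descent over degree groups —
hubs first (descending mean degree), initialised at the homogeneous
optimum, three full cycles by default; each step is an argmax holding the
rest fixed, so the objective trace is nondecreasing and the homogeneous
solution is always in the feasible set.

## Numerical choices

* Resolvents are computed by one linear solve per frequency
  (`solve(A, I)`), never explicit inversion or series truncation; the
  truncated series (`walk_sum_truncated()`) exists purely as an oracle,
  with order chosen from the geometric tail bound `ρ^{K+1}/(1−ρ)` (capped
  at 10 000).
* Degenerate inputs return typed conditions (`walksum_error_*`) or `NA`
  by documented contract — never silent coercion.
* All randomness flows through explicit seeds; generation restores the
  caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is stably expressed: 64-node
study networks (2016 pairs) for channel and eigenmode statistics, 16 nodes
× 10 simulated minutes at 128 Hz for coherency convergence, a 20-node
network × the full 460-cell grid × 20 noisy replicates for parameter
recovery, and the full 144-condition sweep on 10 nodes at 4 s / 0.5 ms per
condition for the negative control.

## Known limitations

Linear, stationary, frequency-domain description; a single global delay
`T` (no distance-dependent delays); symmetric-network coherency carries
almost no imaginary part (see above), so empirical-Q comparisons require
real recordings; the generator's crossover sits above the alpha band at
fixture scale; and quantitative reproduction of published consensus-atlas
values requires those atlases as input — the package computes the same
statistics on any supplied weight/distance matrices via
`load_connectome()`.
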