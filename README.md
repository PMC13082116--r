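# walksum

Frequency-dependent communication architecture of weighted structural
connectomes, derived analytically from the walk-sum resolvent transfer
function.

## The problem

Brain electrophysiology organises into canonical frequency bands, and which
frequencies can carry communication over which anatomical distances is a
structural question: signals traverse white-matter connections with
conduction delays, so every multi-hop route accumulates phase.  Summing all
walks on a connectome `C` (spectral radius < 1) with a per-hop delay `T`
gives the network's transfer function in closed form,

```
H(f) = (I − e^{s·i·2πfT} C)^(−1) = Σ_k e^{s·ikωT} C^k ,   ω = 2πf,
```

which splits into an in-phase **integrative channel** `I(f) = Re H` and a
quadrature **routing channel** `Q(f) = Im H`.  With zero free parameters
this predicts a frequency — the **Q-crossover** — at which the routing
channel's rank correlation with fibre-tract distance flips from positive to
negative, plus a battery of spatial predictions (C1–C5), a Laplacian
eigenmode ladder in which each mode's peak frequency tracks its eigenvalue,
and hub-mediated low-frequency global modes.  A two-parameter dressing
(damped-harmonic local gain `l(f)` with natural frequency `ω0` and damping
`ζ`) adds local dynamics and can be fitted to empirical coherency profiles.

The package is for computational/network neuroscientists who have a weight
matrix and a distance matrix (any parcellation, any tractography pipeline)
and want the full channel analysis: bare/dressed/group-wise resolvents,
distance-binned channel profiles, crossover and channel-divergence
statistics, the prediction battery, eigenmode projections, Welch coherency
estimation for empirical comparison, a Wilson–Cowan negative control, and
grid-search dressing fits with leave-one-dataset-out cross-validation.  A
seeded synthetic generator (hub-routed core–periphery networks embedded in
cortical length scales) makes every stage testable without any data
download.

## Worked example

```r
library(walksum)

conn <- make_connectome(synth_config(seed = 1))   # 64-node hub-routed ring
conn
#> <connectome> 64 nodes, undirected
#>   spectral radius 0.9901 (normalisation factor 5.374)
#>   distances 7.9-160.0 mm

H <- bare_resolvent(conn)                         # 1-45 Hz, T = 10 ms
rep <- evaluate_predictions(H, conn$distances, n_perm = 1000, perm_seed = 2)
rep
#> <channel_report>
#>   Q statistic: signed; 20 distance bins; min distance 0 mm
#>   Q-crossover: 24.77 Hz
#>   convergence frequency omega_c: 31.00 Hz
#>   C1 (Q rises with distance below crossover): PASS (mean rho 0.579, p = 0.000999)
#>   C2 (crossover in 8-16 Hz): fail
#>   C3 (long-range I > 0 in every band): fail
#>   C4 (alpha Q trough < 0): PASS (trough -0.0465)
#>   C5 (salience structured, CV 2.483): PASS

eigenmodel(conn, field = H)
#> <eigenmodel>
#>   64 modes (normalized Laplacian), eigenvalues -0.000-1.773
#>   eigenvalue-peak-frequency Spearman rho = 0.769
#>   top-5 modes explain 66.6% of I variance at 1 Hz, 29.7% at 45 Hz
#>   hub-mode Spearman rho = 0.852 (p = 4.82e-19)
```

Reading the numbers: below 24.77 Hz the routing channel *rises* with
distance (mean Spearman ρ = 0.579, permutation p ≈ 0.001) — long-range
pairs carry relatively more quadrature signal, the signature of multi-hop
phase accumulation; above it the sign flips (C1 and the crossover exist).
The alpha-band binned Q has a negative trough (C4), and channel salience is
strongly frequency-structured (C5).  C2 fails because this small fixture's
routing depth places its crossover near 25 Hz rather than inside the
8–16 Hz window expected of full-scale connectomes, and C3's long-range
integrative positivity likewise depends on network scale — the report says
so rather than papering over it.  Mode peak frequencies track Laplacian
eigenvalues (ρ = 0.769), and on this synthetic network the dominant-mode
participation correlates *positively* with degree — real consensus
connectomes show the opposite sign, which makes the statistic a useful
fingerprint.  Real data enter through `load_connectome()` (delimited weight
and distance matrices) and, for empirical coherency, `welch_csd()` /
`coherency()` on channels × samples series.

A command-line wrapper covering the main stages ships at
`inst/cli/walksum` (subcommands `synth`, `resolvent`, `channels`,
`eigenmodel`, `coherency`, `negctrl`, `fit`).

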