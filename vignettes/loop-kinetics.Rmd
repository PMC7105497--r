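---
title: "Modelling loop-gating kinetics with loopmsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling loop-gating kinetics with loopmsm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopmsm)
```

## The scientific problem

Tetraspanin extracellular loops gate the membrane-facing cavity of the
protein: the large loop (LEL) swings between a closed position, packed
against the short loop (SEL), and an open, lifted position, with a
semi-open state in between. The kinetics of this motion live on
microsecond-and-longer timescales, far beyond what individual short
simulations can show directly. The standard remedy is a Markov state
model: pool many short trajectories, discretize the conformations into
microstates, count transitions at a fixed lag time, and read the slow
kinetics off the spectrum of the estimated transition matrix. `loopmsm`
implements this analysis chain and, in place of an MD engine, ships a
synthetic loop system with exactly known statistics, so every stage of
the chain has a ground-truth recovery test.

## The synthetic loop system

The surrogate reduces the loop motion to a single reaction coordinate:
the gap `g` between the two loops.

**Potential.** The free-energy profile is a log-sum of Gaussian wells,
`U(g) = -kT log Σᵢ exp(Dᵢ − (g−cᵢ)²/2sᵢ²)`. This form was chosen because
its Boltzmann density is a closed-form Gaussian mixture (weights
`∝ exp(Dᵢ)·sᵢ`), which the stationary-law tests compare against directly.
The default system places wells at `c = (4, 8.5, 14)` Å — closed,
semi-open and open — with depths `(2.0, 1.5, 1.8)` kT and widths
`(0.8, 0.8, 0.9)` Å. No experimental barrier heights exist for this
motion, so the defaults were fixed once by two requirements: all three
states carry non-negligible equilibrium weight (0.40/0.24/0.36), and the
inter-well barriers (≈ 2.5–4 kT) put the slowest relaxation near 170 ns —
slow enough to be a genuinely metastable, rare-event system at the 0.1 ns
frame stride, fast enough that a few microseconds of synthetic sampling
resolve it.

**Dynamics.** The gap evolves by overdamped (Brownian) Langevin dynamics,
`g ← g − Δt·U′(g)/γ + √(2kTΔt/γ)·ξ`. The overdamped form was preferred to
underdamped Langevin because only the stationary and kinetic structure
matters downstream and it has one parameter fewer. Units are kT = 1,
γ = 1 ns⁻¹ (diffusion constant 1 Å²/ns), integrator step
Δt = 5·10⁻⁴ ns. With well curvatures near kT/s² ≈ 1.6 Å⁻² the stability
limit is ~1 ns, so the integrator operates three orders of magnitude
below it and discretization bias is negligible against statistical error.
Frames are recorded every 200 steps, i.e. a 0.1 ns frame stride, the
stride the downstream analysis assumes throughout.

**Reference kinetics.** Rather than trusting a single long run, the
package computes the surrogate's exact relaxation spectrum from the
discretized 1-D Smoluchowski generator: nearest-neighbour hopping rates
`D/h²·exp(−ΔU/2kT)` on a fine grid obey detailed balance, the similarity
transform by `√π` is symmetric tridiagonal, and its eigenvalues give the
relaxation times (`gap_relaxation_timescales()`; 170.2 and 23.8 ns for
the default system). The same spectral decomposition, propagated over one
lag and coarse-grained onto the wells, yields the reference 3-state
transition matrix at the 20 ns lag. Tests then check a brute-force
Langevin run against these references with a hand-rolled
transition-frequency estimator.

**Embedding.** Gap series are embedded as 3-D bead frames: a fixed 6-bead
SEL template plus a 10-bead LEL template translated by `g` along the gap
axis, with i.i.d. isotropic Gaussian jitter (0.2 Å by default) on every
coordinate. Jitter is uncorrelated by design — correlated loop flexing
would make the RMSD statistics analytically intractable, and the tests
rely on the rigid-translation geometry (both templates contain an
on-axis bead, so the minimum SEL–LEL distance equals `g` exactly at zero
jitter).

**What the surrogate does not emulate.** It is one-dimensional in its
slow dynamics; real loop motion couples many degrees of freedom, so
featurization choices matter less here than on real data. There is no
solvent, membrane, or internal loop flexibility, and jitter is isotropic
and frame-independent. Passing tests therefore demonstrate that the
estimators recover known kinetics from data with the right statistical
shape (metastability, many short trajectories, frame stride), not that
any particular force field or sampling protocol is adequate.

## Analysis stages and the choices behind them

**Geometry.** Superposition uses the SVD (Kabsch) solution with the
smallest singular value sign-corrected, so a proper rotation is always
returned and reflections can never leak into an RMSD. The minimized RMSD
is recomputed from the transformed residuals rather than from the
singular-value identity, which loses half the significant digits for
near-congruent pairs. Collinear point sets are rejected rather than
resolved arbitrarily. The minimum inter-loop distance is taken over all
inter-group bead pairs (not centroids), and the contact switching
function evaluates the rational form through its partial geometric sums
near the cutoff, so the removable singularity at `d = d₀` yields the
analytic limit `n/m` exactly — for the default `m = 2n` the function
equals `1/(1+(d/d₀)ⁿ)` everywhere, an identity the acceptance checks
verify to 10⁻¹².

**Featurization.** Reference structures are medoids from a PAM-style
k-medoid clustering on the pooled RMSD matrix (k-means++-style seeded,
assignment/medoid alternation to convergence); medoids are actual frames,
so no coordinate averaging happens in RMSD space. Pools larger than a cap
(2000 frames) are stride-subsampled before the O(n²) RMSD matrix. Kernel
features use σ = 0.5 Å. The microstate discretization runs k-means on the
kernel-transformed features — the transformed features, not the raw
RMSDs, are taken as the clustering space, reading the 50-dimensional
feature vector as the object the discretization acts on. PCA components
fix their sign by making the largest-magnitude loading positive, for
backend-independent reproducibility, and requesting components beyond the
matrix rank is an error rather than silent zero-padding.

**k-means.** Implemented in-package (Lloyd from k-means++ seeding,
`tol = 1e-6` on the center shift, `max_iter = 300`) because the
discretization contracts are load-bearing: deterministic output under a
seed, empty clusters repaired by reseeding to the farthest point (the
500/2000 microstate counts are structural and must be preserved), and
nearest-center assignment breaking exact ties toward the lowest center
index. `stats::kmeans` serves as an independent oracle in the tests.

**MSM estimation.** Transitions are counted with a sliding window (every
start offset) by default — strided counting is available — and never
across trajectory boundaries. The count graph is trimmed to the strongly
connected component carrying the most counts. The default estimator is
the reversible maximum-likelihood fixed point on the symmetric flow
matrix, converged when the transition-matrix update falls below 10⁻¹⁰;
plain row normalization is retained as an option and as the oracle
starting point in tests. Reversible models are solved through the
`√π`-symmetrized eigenproblem, so their spectra are exactly real;
non-reversible spectra are sorted by modulus and complex or non-positive
eigenvalues are flagged `NA` in implied timescales, never dropped
silently. Metastable states are counted by the largest relative gap
`(λᵢ−λᵢ₊₁)/λᵢ` among the leading real positive eigenvalues.

**GMRQ.** Folds split at whole-trajectory granularity with a seeded
shuffle, so no frame pair within the lag ever straddles folds. The score
sums the `m` leading eigenvalues of the transition matrix re-estimated
from held-out counts on the train-defined active set (trimmed to its
connected core); `m = 5` by default and recorded in every result, since
no canonical choice exists. A fold whose held-out trajectories miss the
active set entirely is flagged invalid rather than scored.

**Adaptive sampling.** One round clusters the pool in
PCA-reduced superposed-coordinate space (15 dimensions, 2000 clusters at
production scale), samples restart clusters uniformly *without*
replacement — unweighted sampling is the literal reading of "randomly
selected" — and restarts from the actual pool frame nearest each chosen
center. In the overdamped surrogate, re-randomized restart velocities map
to a fresh noise seed. The number of rounds is configuration-exposed with
default 1, matching a single clustering-and-restart pass. Scaled-down
defaults (50 clusters, 10 restarts) ship alongside the production values.

**Reporting.** The contact thresholds mapping values to the named states
(closed ≥ 0.6, open ≤ 0.2) are this package's operationalization: the
named states are structural, no numeric boundary is canonical, and the
thresholds are printed in every report header and stored in the artifact
metadata. Boundary values classify toward the extreme states.

## Configuration, units and indexing

Coordinates are in Å and times in ns throughout; reconstruction spans
accept explicit `ns`/`us`/`ms` suffixes. States and frames are indexed
1-based, the R convention. The run configuration is YAML with unknown
keys rejected and an exact parse/serialize round trip. The production
defaults (σ = 0.5 Å, 50 references, 500 microstates, 20 ns lag, 3 folds,
PCA 15 / 2000 clusters / 100 restarts / 100 ns, d₀ = 8 Å with n = 6 and
m = 12, spans 20 µs / 100 µs / 15 ms) sit in `default_config()`; the
`"test"` scale shrinks only sampling sizes — 12 trajectories of 2000
frames (200 ns each, inside the 100–1000 ns regime the analysis is
designed for), 12 references, 40 microstates — and leaves every physical
parameter untouched. Those are also the problem sizes the test suite and
the acceptance script run at; at this scale the full pipeline takes
roughly 20 s, and the package's own checks confirm the three metastable
states and the slow timescale are recovered reliably there.

## Known limitations

The RMSD-kernel featurization is evaluated on all beads; a bead-subset
selection (the analogue of a Cα-versus-heavy-atom choice) is not
implemented because the surrogate has no such hierarchy. Dihedral
featurization is likewise out of scope — the bead model has no backbone.
Metastable counting uses the spectral gap only; fuzzy membership
assignment (PCCA-like) and hidden Markov refinements are not provided.
Error bars on MSM quantities (Bayesian sampling of transition matrices)
are not implemented; the tests quantify uncertainty empirically over
seeds instead. Periodic-boundary distances are unsupported: the
synthetic system is non-periodic by construction.
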