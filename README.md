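# loopmsm

Markov state model (MSM) analysis of loop-gating conformational kinetics.

Tetraspanins such as CD9 seal their membrane cavity with two extracellular
loops — a short loop (SEL) and a large loop (LEL) — whose opening and
closing motion switches the protein between closed, semi-open and open
conformations. Characterising this motion from molecular simulation takes
a standard but intricate pipeline: many short trajectories are featurized,
discretized into microstates, and compressed into a discrete-lag Markov
chain whose spectrum encodes the slow kinetics. `loopmsm` implements that
pipeline end to end in R, together with a synthetic Langevin loop system
that provides exact ground truth for every stage, so the whole chain is
testable without any molecular-dynamics engine.

It is intended for computational structural biologists who want a small,
fully tested, self-contained MSM stack — for method development, teaching,
or desk-scale reanalysis — rather than a wrapper around an external MD
code.

## The model

**Markov state model.** Microstate trajectories are counted at a lag time
τ (default 20 ns) into a transition count matrix `C`, trimmed to the
largest strongly connected set, and converted to a row-stochastic
transition matrix `T` — by default the maximum-likelihood estimate under
detailed balance π̂ᵢTᵢⱼ = π̂ⱼTⱼᵢ. The eigenvalues λᵢ of `T` give the
implied timescales

    tᵢ = −τ / ln λᵢ(τ),

whose lag-independence diagnoses Markovianity; the number of leading
eigenvalues before the largest relative spectral gap counts the metastable
conformations. Long pseudo-trajectories are reconstructed by sampling the
fitted chain and emitting stored frames of the visited states, so each
step spans one lag time.

**Featurization.** Frames are compared to `k` reference structures
(medoids of a k-medoid clustering on the pairwise minimized RMSD) through
a Gaussian kernel,

    F_ij = exp( − RMSD(x_i, r_j)² / 2σ² ),     σ = 0.5 Å,

and the kernel features are discretized by k-means (k-means++ seeding,
Lloyd iterations). Featurization/discretization choices are compared by
GMRQ cross-validation: the sum of the leading eigenvalues of the held-out
transition matrix under the train-defined states, which by the variational
principle is maximal for kinetics-resolving discretizations.

**Contact observable.** The SEL–LEL association is summarised by the
rational switching function of the minimum inter-loop distance `d`,

    contact(d) = (1 − (d/d₀)ⁿ) / (1 − (d/d₀)ᵐ),   d₀ = 8 Å, n = 6, m = 12,

which is 1 for tight contact, 1/2 at the cutoff (the removable singularity
is evaluated analytically) and → 0 for separated loops.

**Synthetic system.** `default_loop_system()` is a three-well gap
potential (wells at 4, 8.5 and 14 Å for the closed, semi-open and open
states) integrated by overdamped Langevin dynamics and embedded as a
16-bead two-loop model with a 0.1 ns frame stride. Its stationary law is a
closed-form Gaussian mixture and its relaxation spectrum is computed
exactly from the discretized Smoluchowski generator, so estimator-recovery
tests have analytic ground truth.

## Worked example

```r
library(loopmsm)

sys <- default_loop_system()
sys
#> <loop_system> 3 wells at 4, 8.5, 14 A
#>   populations: 0.396 0.24 0.364
#>   slowest timescales (ns): 170.2 23.8

res <- run_pipeline(default_config(seed = 1, scale = "test"), quiet = TRUE)
res
#> <pipeline_result>
#>   trajectories: 12 x 2000 frames
#>   microstates: 40 -> model states: 40
#>   metastable states: 3
#>   state fractions: closed 0.41, semi-open 0.135, open 0.455

summary(res$model)
#> Markov state model summary
#>   states:             40
#>   lag time:           20 ns
#>   estimator:          reversible MLE
#>   transition counts:  21600
#>   metastable states:  3
#>   implied timescales (ns): 176.888,  24.667, n/a, n/a,   6.832,   6.766
```

The surrogate's reference slowest relaxation is 170.2 ns (exact
Smoluchowski value); the MSM fitted on 12 × 200 ns of synthetic
trajectory estimates 176.9 ns and finds the three metastable
conformations, whose populations under the fitted chain appear as the
closed/semi-open/open fractions of the reconstructed 15 ms trajectory.
`plot(res$its)` draws the implied-timescale/lag diagnostic,
`plot(res$reconstructions[["100us"]])` the contact time course, and
`plot(res$report$contact_histogram)` the (multimodal) contact
distribution.

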