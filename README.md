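# msmbind

Markov state model (MSM) analysis of heterogeneous ligand-binding modes on
a protein domain, from molecular-dynamics trajectory ensembles.

Small hydrophobic drugs can bind a protein surface in several distinct,
interconverting poses rather than one well-defined complex. Resolving that
heterogeneity means answering three questions at once: how many metastable
binding modes are there, how probable is each at equilibrium, and how fast
do they interconvert? `msmbind` implements the full analysis chain used to
answer these questions for a ligand bound to a calmodulin-like domain, and
pairs every stage with a synthetic-data generator whose kinetics are known
analytically, so the whole pipeline can be validated end to end.

## The model

Trajectory frames are encoded as protein–ligand contact features: the
minimum distance \(D\) between each residue and each ligand atom is mapped
through a quasi-binary transform, either the indicator \(D < i\) or the
inverse distance \(1/D\) when \(D < i\) (0 beyond the cutoff), with
\(i \in \{5,6,7,8\}\) Å. Candidate encodings are ranked by their
cross-validated VAMP2 score, the variational estimate of captured kinetic
variance. The selected features are projected onto their slowest linear
subspace by time-lagged independent component analysis (tICA), the
generalized eigenproblem \(C_\tau v = \lambda C_0 v\) on the instantaneous
and time-lagged covariances. Projected frames are clustered into
microstates (k-means, k-means++ seeding), and a reversible MSM is estimated
by the detailed-balance maximum-likelihood fixed point on sliding-window
transition counts. The model is validated by implied timescales
\(t_i(\tau) = -\tau/\ln\lambda_i(\tau)\) and a Chapman–Kolmogorov test, and
hyperparameters are selected by the cross-validated generalized matrix
Rayleigh quotient (GMRQ).

The MSM spectrum fixes the number of metastable macrostates (spectral gap);
PCCA+ memberships group microstates into them; frames whose membership
exceeds a core threshold (default 0.8) define core states. Macrostate
populations are \(\pi_A = \sum_i \pi_i \chi_{iA}\), exchange kinetics are
mean first passage times from the first-passage linear system
\((I - T)h = \tau\mathbf{1}\), and equilibrium observables use the frame
weights \(\langle O\rangle = \sum_i \pi_i O_i / \sum_i \pi_i\). Two further
stages mirror the study design: adaptive-sampling seed selection (uniform
tIC-grid targets, and microstate draws inversely proportional to \(\pi\))
and per-residue importance profiles from one-vs-rest random forests (Gini
importance) cross-checked by a Kullback–Leibler divergence baseline, summed
per residue and normalized to [0, 1].

## Worked example

A 12-microstate chain with three metastable blocks, sampled for
5 × 40 000 steps, then recovered by the estimation stack:

```r
library(msmbind)

chain <- build_metastable_chain(
  metastable_chain_spec(n_micro = 12, n_macro = 3,
                        intra_rate = 0.3, inter_rate = 0.01, seed = 7))
truth <- analytic_ground_truth(chain$T, chain$block_assignment, lag = 1)
trajs <- sample_discrete_trajectories(chain$T, n_trajs = 5,
                                      n_steps = 40000, seed = 1)

msm <- estimate_reversible_msm(count_transitions(trajs, lag = 1), lag = 1)
msm
#> <msm_model> 12 active microstates, lag 1 frames (1 ns)
#> slowest implied timescales (ns): 66.36, 57.56, 2.139, 2.126

mm <- macrostate_model(msm, trajs, n_macro = 3, n_boot = 50)
tidy(mm)
#> # A tibble: 3 × 4
#>   macrostate    pi      sd core_frames
#>        <int> <dbl>   <dbl>       <int>
#> 1          1 0.235 0.00824       46932
#> 2          2 0.293 0.0124        58784
#> 3          3 0.472 0.00770       94284

round(mm$mfpt$mfpt, 1)
#>       [,1]  [,2]  [,3]
#> [1,]   0.0 199.7 140.3
#> [2,] 245.9   0.0 142.6
#> [3,] 260.8 216.9   0.0
```

The two slowest implied timescales (66 and 58 ns) sit far above the rest
(~2 ns): three metastable states, as designed. The populations match the
block sums of the true stationary distribution (0.23/0.31/0.46, in the
model's arbitrary macrostate numbering) within the bootstrap uncertainty,
and the MFPT matrix (in ns) reproduces the analytic first-passage times of
the generating chain to within a few percent. For coordinate-level data,
`generate_toy_complex_trajectories()` builds a bead protein–ligand complex
whose ligand hops between designed binding modes, and `run_pipeline()`
executes featurization → tICA → clustering → MSM → macrostates →
importance → characterization in one call.

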