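---
title: "Resolving ligand-binding modes with Markov state models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving ligand-binding modes with Markov state models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmbind)
```

## The problem and the model

A flexible ligand on a shallow protein surface — the motivating case is a
small hydrophobic drug on the C-terminal lobe of calmodulin — does not
occupy a single pose. It samples several metastable binding modes that
interconvert on timescales far longer than the simulation frame spacing.
`msmbind` estimates a discrete-state kinetic model of that process from
trajectory ensembles:

1. **Featurization.** Per frame, the minimum distance between each protein
   residue and each selected ligand atom, passed through a quasi-binary
   contact transform: `binary` gives the indicator $D < i$, `inverse` gives
   $1/D$ for $D < i$ and 0 beyond. Cutoffs $i \in \{5,6,7,8\}$ Å and the two
   transforms define eight candidate encodings.
2. **Feature selection.** Each encoding is scored by cross-validated VAMP2
   (sum of squared singular values of the propagator approximation,
   constant function included, so scores are $\ge 1$); the encoding with
   the highest mean score across lag times wins. The default configuration
   carries the winner of that comparison: inverse distances at 6 Å.
3. **tICA.** The generalized symmetric eigenproblem
   $C_\tau v = \lambda C_0 v$ on mean-free, trajectory-pooled covariances,
   with $C_\tau$ symmetrized — the reversible estimator. Components are
   slow collective coordinates.
4. **MSM.** k-means microstates in tIC space, sliding-window transition
   counts, restriction to the largest bidirectionally connected component,
   and the reversible maximum-likelihood transition matrix via the
   detailed-balance fixed point
   $x_{ij} \leftarrow (c_{ij}+c_{ji}) / (c_i/x_i + c_j/x_j)$ (relative
   tolerance $10^{-10}$, at most $10^4$ iterations). Validation uses
   implied timescales across lags and the Chapman–Kolmogorov test;
   microstate count and tIC dimension are selectable by cross-validated
   GMRQ.
5. **Macrostates.** The number of metastable states is read from the
   spectral gap in the relaxation timescales; PCCA+ memberships coarse-grain
   the microstates; frames above a membership threshold form core states.
   Populations, bootstrap uncertainties, and mean first passage times
   (first-passage linear solve, $\pi$-weighted over source states) follow.
6. **Importance.** Residue-pair inverse distances filtered to pairs that
   cross 6.5 Å are fed to one-vs-rest random forests; per-feature Gini
   importances are summed per residue and min-max normalized per state. A
   symmetrized KL-divergence estimate on the same features is the
   model-free cross-check.
7. **Characterization.** Representative frames (lowest mean ligand RMSD
   after Kabsch alignment on the protein), stationary-weighted contact
   frequencies and their state deltas, weighted distance percentiles, and
   per-residue secondary-structure frequencies from externally supplied
   labels.

## Default parameters

All defaults live in `default_config()` and mirror the study settings the
pipeline reproduces:

| parameter | default | unit | role |
|---|---|---|---|
| `features$cutoff` | 6 | Å | contact cutoff of the selected encoding |
| `features$transform` | `"inverse"` | — | winning quasi-binary transform |
| `tica$lag_ns` | 20 | ns | tICA lag time |
| `tica$n_components` | 10 | — | slow components kept |
| `cluster$k` | 200 | — | microstates |
| `msm$lag_ns` | 15 | ns | Markovian lag (implied-timescale plateau) |
| `macrostates$n_macro` | 7 | — | metastable states (spectral cut) |
| `macrostates$core_threshold` | 0.8 | probability | core-state membership |
| `importance$cutoff_filter` | 6.5 | Å | residue-pair crossing filter |
| folds (VAMP2/GMRQ/RF) | 5 | — | cross-validation folds |

Lags are specified in nanoseconds and validated to be integer multiples of
the frame spacing; every stochastic stage carries an explicit seed, so a
re-run of `run_pipeline()` with the same configuration is bit-identical.

## What the synthetic generator emulates — and what it does not

The generator provides two levels of surrogate data.

**Metastable chains** (`metastable_chain_spec()`,
`build_metastable_chain()`): microstates grouped into blocks, with a
symmetric weighted-graph construction — same-block pairs share a large
weight, cross-block pairs a small one, all scaled by seeded per-state
factors. Row-normalizing a symmetric weight matrix yields a reversible
chain whose stationary distribution is proportional to the incident weight,
so the ground truth ($\pi$, timescales, MFPTs) is available in closed form
via `analytic_ground_truth()`. Reversibility by construction matches the
model class of the downstream reversible MLE. One chain step is identified
with one trajectory frame; lags are frames, converted to ns by the frame
spacing.

**Toy complexes** (`toy_complex_spec()`,
`generate_toy_complex_trajectories()`): one bead per protein residue on a
fixed helix-like arc, a few-bead ligand whose pose centre hops between
designed offsets under a hidden metastable chain, and isotropic Gaussian
jitter on every bead. Each mode's designed contact set (pairs within 6 Å
of the noiseless pose) is recorded, giving coordinate-level data with an
exact contact-pattern ground truth.

The generator deliberately omits: any force field or thermostat, internal
protein conformational change (protein beads jitter about *fixed* sites),
multi-atom residues (one bead each, so minimum distance equals plain
distance — multi-atom minimum distances are exercised separately in the
featurization tests), periodic boundaries, and solvent. Two consequences
matter for interpreting green tests. First, passing on this data shows the
*estimators* are correct, not that real trajectories satisfy their
assumptions — on real data the implied-timescale plateau and CK test must
be checked, not assumed. Second, because the toy protein does not deform,
residue–residue features carry no mode signal there; the importance stage
is therefore validated on emission-based ensembles with designed
discriminative pairs (`emit_feature_trajectories()` and the test fixtures),
while the toy complex validates contact-frequency deltas, which live on
residue–ligand distances.

## Numerical choices

- **tICA regularization** defaults to $\varepsilon = 10^{-6}\,
  \mathrm{tr}(C_0)/d$ added to the diagonal of $C_0$; collinear features
  then stay finite. Eigenvalues above 1 are clipped with a warning.
- **Covariance convention**: symmetrized (reversible) estimators
  throughout, for both tICA and VAMP2 scoring. The non-reversible VAMP
  variant is out of scope; scores are therefore comparable only within
  this package's convention. The constant singular function is included,
  so VAMP2 $\ge 1$ and GMRQ $\ge$ the constant's contribution of 1.
- **Connectivity** requires counts in *both* directions on an edge;
  frames outside the largest connected component get zero weight and are
  excluded from every weighted statistic.
- **Eigenvector signs** are fixed by making each eigenvector's
  largest-magnitude entry positive; PCCA+ argmax ties break toward the
  lower macrostate index. Both choices are purely for determinism.
- **PCCA+** uses the inner-simplex vertex search with clipping of the
  (small) negative memberships and row renormalization, omitting the final
  crispness optimization. On gapped spectra — the regime where macrostate
  analysis is meaningful — the repaired memberships are within $10^{-3}$
  of crisp indicators in our block-chain tests, and the omission makes the
  decomposition deterministic.
- **Weighted percentiles** use the left-continuous weighted empirical CDF
  with midpoint positions and linear interpolation; with uniform weights
  this reproduces the usual midpoint convention (median of 1..100 is 50.5).
- **Free-energy surfaces** use 60 × 60 bins spanning the data extent;
  empty bins are reported as unbounded (`Inf`) rather than smoothed.
- **KL importance** uses 50 shared-range bins with one pseudo-count per
  bin, symmetrized as $(KL(P\Vert Q)+KL(Q\Vert P))/2$; the estimator
  recovers the Gaussian closed form (0.5 nats per direction at unit mean
  shift) within 15% at $n = 10^4$.
- **Random-forest settings**: 100 trees, unlimited depth, $\sqrt{d}$
  features per split, seeded — the library defaults of the toolkit this
  stage mirrors, frozen in the configuration for reproducibility.
- **Uncertainties** are trajectory-level bootstrap standard deviations
  (default 100 resamples) for populations, MFPTs, implied timescales and
  CK curves; the bootstrap keeps microstate definitions fixed and
  re-estimates the MSM per resample.

## Decisions on genuinely open points

- The inverse contact transform maps beyond-cutoff distances to **0**, not
  $1/i$: the encoding is then a contact feature (zero outside contact),
  and together with the binary variant it yields exactly the eight
  candidate encodings scored by VAMP2.
- MFPTs are computed between **crisp argmax PCCA+ sets** of microstates;
  cores remain a frame-level reporting device. Hitting-time systems are
  defined on microstates, and the crisp partition covers the full active
  set, so no stationary mass is dropped.
- Adaptive-sampling draws are **with replacement** and not deduplicated
  across rounds; duplicated draws of a rare microstate are legitimate
  seeds. The grid rule, by contrast, deduplicates frames (next-nearest
  fallback) since identical seeds are useless there.
- The "counts-based" seeding rule is implemented as stated — selection
  probability inversely proportional to stationary probability — with
  inverse visit counts available as an explicit option flag.
- Residue–residue distances use the closest-heavy-atom convention with
  hydrogens excluded, the standard contact definition.

## Validation scale

The test suite and acceptance script run on deliberately small problems
chosen so that sampling error, not compute, is the binding constraint: the
12-microstate/3-block chain at $5 \times 4\times10^4$ steps (stationary
distribution recovered to max error $<0.02$, slowest timescale to $<15\%$,
macrostate MFPTs to $<10\%$ of the dense linear-solve oracle), 100 random
chains for the GMRQ variational bound, $3\times1200$ frames for the
importance stage, and a $3\times4000$-frame, 3-mode toy complex for the
end-to-end run. These sizes complete in well under a minute each; scaling
the same calls to production trajectory ensembles is limited only by the
$O(\text{frames}\times\text{features})$ covariance and distance passes.

## Known limitations

- tICA is linear; slow processes not linearly realizable in the chosen
  features depress eigenvalues and VAMP2 scores (visible in tests where
  random low-dimensional emissions cannot express a 12-state
  eigenfunction). Kernel or deep variants are out of scope.
- The reversible MLE assumes equilibrium sampling within the connected
  set; strongly non-equilibrium data bias $\pi$.
- Bayesian posterior sampling for MSM uncertainties, hidden-Markov
  coarse-graining, and transition-path-theory fluxes are not implemented;
  bootstrap standard deviations stand in for the former.
- The PDB writer emits minimal multi-model files (no connectivity,
  occupancies/B-factors fixed); it round-trips through standard readers but
  is not a general-purpose structure writer.
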