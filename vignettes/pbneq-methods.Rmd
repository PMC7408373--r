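---
title: "Local flexibility of disordered ensembles: protein blocks and the Neq index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local flexibility of disordered ensembles: protein blocks and the Neq index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbneq)
```

## The problem

Intrinsically-disordered proteins (IDPs) do not fold into one tertiary
structure; they exist as conformational ensembles, deposited as multi-model
PDB entries (NMR, SAXS-restrained or MD-derived). Classifying each residue of
such an ensemble as rigid, flexible or disordered requires a *local* measure
of conformational heterogeneity — global descriptors such as RMSF mix local
deformation with rigid-body motion of whole segments.

`pbneq` quantifies local heterogeneity with a structural alphabet. The 16
protein blocks (PBs, labels `a`–`p`) are prototype local conformations, each
defined by eight backbone dihedrals over five consecutive residues, in the
window order $\psi_{i-2}, \phi_{i-1}, \psi_{i-1}, \phi_i, \psi_i, \phi_{i+1},
\psi_{i+1}, \phi_{i+2}$. Every residue of every model is assigned the block
whose window is nearest in RMSDA (root-mean-square deviation over circular
angular differences). Across the $M$ models of an ensemble this yields a
per-position frequency vector $f_a, \dots, f_p$, summarised by the
equivalent number of protein blocks:

$$N_{eq} = \exp\Big(-\sum_{x=1}^{16} f_x \ln f_x\Big), \qquad
N_{eq} \in [1, 16].$$

$N_{eq} = 1$ means one block is ever used (local rigidity); $N_{eq} = 16$
means all sixteen blocks appear with equal probability. Anchor values along
the continuum: below 4 a position is treated as rigid, 4–6 flexible, 6–8
highly flexible, and at or above 8 disordered. The comparison machinery then
confronts these ensemble-derived values with sequence-based disorder
predictor outputs (DISOPRED3, PrDOS, IUPred2A, ANCHOR2 score tracks).

## Pipeline and key parameters

1. **`read_ensemble()`** parses multi-model PDB text: `ATOM` records only,
   one chain (first seen by default), alternate locations resolved by
   highest occupancy then first-seen, models reconciled to the union of
   residues with per-model completeness flags.
2. **`compute_dihedrals()`** derives $\phi/\psi$ by the standard atan2
   torsion construction. A chain break is declared when residue numbering is
   non-consecutive or the C–N peptide bond exceeds **2.5 Å** (`max_cn`);
   dihedrals across breaks are undefined, because missing residues are the
   crystallographic signature of disorder and must not yield spurious
   angles.
3. **`assign_ensemble()`** assigns PBs per model. Positions 1, 2, $L-1$, $L$
   and any window touching an undefined dihedral get the undefined symbol
   `Z`. Ties in RMSDA (measure-zero on real data) go to the alphabetically
   first label, for determinism. All angles are reduced to $(-180, 180]$
   before matching.
4. **`neq_profile()`** computes frequencies over non-`Z` cells only — the
   entropy sums over the 16 blocks, so `Z` is excluded rather than treated
   as a 17th symbol — and requires at least `min_models = 2` defined models
   per position (below that $N_{eq}$ is trivially 1 and uninformative).
   Undefined positions are excluded from all denominators, including the
   distribution summary fractions.
5. **`compare_report()`** computes, per predictor track: the Pearson
   correlation of the continuous pair series (continuous values, never
   binary classes; Pearson because the convention "1.0 = perfect, 0 =
   absent" is that of product-moment correlation); mean scores over the
   strata $N_{eq} < 4$, $4 \le N_{eq} \le 8$, $N_{eq} > 8$; averages over
   twelve classes $[1,2), \dots, [11,12), [12,16]$ with the class
   **lower bound** as the representative for the class-level correlation
   (bound vs midpoint is not canonically fixed; the choice is configurable
   in code and documented here); the two-state agreement decomposition; and
   the prediction-rate sweep over $N_{eq}$ thresholds 1–12, where the
   "true" state at threshold $t$ is disorder iff $N_{eq} > t$. Equality is
   assigned to order so that $t = 1$ makes fully rigid positions
   ($N_{eq} = 1$, the majority in ensemble data) ordered.
6. **Binarization** of score-only tracks uses a 0.5 threshold by default
   (midpoint of the documented $[0,1]$ range); DISOPRED3's native two-state
   marks are preserved unless an override is requested. Track-to-ensemble
   alignment is by 1-based sequential index plus an optional constant
   offset; residue-letter mismatches warn, and at 10% or more they error.

The prototype table ships as plain text
(`inst/extdata/pb_prototypes.tsv`); an alternative alphabet of any size $n$
can be substituted through `pb_prototypes(file =)`, with $N_{eq}$ then
ranging over $[1, n]$.

## The synthetic-data generator

Every stage is testable without external data through `ensemble_spec()` /
`simulate_ensemble()`: each position gets a target PB mixture, labels are
drawn per model, each residue receives the central $(\phi, \psi)$ of its
sampled block plus wrapped Gaussian noise ($\sigma = 5°$ by default, a
realistic within-basin dihedral fluctuation scale), and the chain is built
atom-by-atom with standard backbone geometry (N–CA 1.46 Å, CA–C 1.52 Å,
C–N 1.33 Å, trans peptide). The generator writes standard multi-model PDB
and the predictor-track dialects, so the parsers are exercised too.

Two sampling modes control how labels couple along the chain:

* `"position"` draws each (position, model) label independently. Marginals
  are exact, so PB-matrix-level statistics ($N_{eq}$ convergence, summary
  fractions) are fully testable at any heterogeneity, up to near-uniform
  mixtures.
* `"model"` draws one uniform variate per model and pushes it through every
  position's mixture inverse-CDF (a comonotone coupling). Marginals — and
  therefore the true $N_{eq}$ — are identical to `"position"` mode, but each
  model is a single coherent conformer.

The distinction matters because overlapping five-residue windows constrain
shared dihedrals: imposing only each block's *central* angles makes a run of
one block geometrically self-consistent only for the repetitive blocks `m`
(core helix) and `d` (core extended), whose window angles repeat their
central values. A run of any other block re-reads as `d` or `m` — a real
property of the alphabet, not an implementation artifact — and independent
per-position draws from wide mixtures are not recoverable after the
geometric round trip at all. The package's reference condition for the
full-pipeline identity check, `idp_ensemble_spec()` (60 residues, 200
models, $\sigma = 5°$, a constant `m`/`d` 0.5/0.5 mixture, model-wise
sampling), therefore represents a two-state molten ensemble interconverting
between helical and extended conformers: in that coherent regime sampled
labels are recovered at ≥ 99% of interior positions and recomputed
$N_{eq}$ matches the empirical mixture entropy within 0.05. Graded mixtures
under model-wise sampling produce one helix–extended junction per model;
positions near junctions may mis-assign, which the end-to-end tests treat
as expected behaviour, not error. Terminal positions carry no sampled block
and reuse the nearest interior position's angles (they are `Z` after
assignment regardless).

Score tracks with controlled correlation to a given $N_{eq}$ profile are
generated as $\mathrm{clamp}_{[0,1]}(0.5 + 0.15\,(\rho z +
\sqrt{1-\rho^2}\,\varepsilon))$ with $z$ the standardized $N_{eq}$. The 0.15
slope keeps clamping below ~0.1% of residues, so the attenuation bias is
negligible against the sampling noise of a Pearson correlation at the
problem sizes used ($n = 1000$: 95% Fisher-z band ≈ ±0.06).

## What the synthetic conditions do and do not show

The generator emulates single-chain ensembles of tens-to-hundreds of models
with per-position heterogeneity spanning single-block rigidity to
near-uniform block usage, and score tracks with a prescribed linear
coupling to $N_{eq}$. It does **not** emulate sequence-dependent
conformational preferences, glycine/proline peculiarities (all residues are
emitted as alanine — assignment uses backbone atoms only), excluded volume
(chains may self-intersect; only local dihedrals matter to the pipeline),
or the heavy-tailed, spatially-autocorrelated $N_{eq}$ profiles of real
IDP ensembles. Passing tests therefore demonstrate correctness of the
machinery — assignment, entropy, alignment, statistics — not predictive
claims about any particular protein.

## Numerical choices and degenerate inputs

* Angles are compared on the circle; $-180$ and $180$ are identical, and
  the circular distance is capped at $180°$.
* $0 \ln 0 = 0$ in the entropy; frequency vectors must sum to 1 within
  $10^{-6}$ and be nonnegative.
* Correlations require ≥ 3 pairs and non-constant series; the twelve-class
  correlation requires ≥ 3 populated classes. Both refuse degenerate input
  with explicit errors rather than returning `NA`.
* Degenerate torsion geometry (zero-length or collinear bond vectors)
  yields an undefined angle that propagates to a `Z` label.
* Problem sizes in the test suite — $M = 2000$ models for $N_{eq}$
  convergence, $n = 1000$ for correlation recovery, 60×200 for the
  geometric round trip — were chosen so that sampling tolerances
  (multinomial and Fisher-z) are tight while a full run stays fast on a
  single core.

## Command-line use

`inst/scripts/pbneq.R` wraps the three entry points (`assign`, `compare`,
`simulate`; report writing is part of `compare`) for shell use; the R
functions `run_assign()`, `run_compare()` and `run_simulate()` are the
same interface for scripted analyses. Every run writes a `provenance.txt`
(config echo, seed, prototype-table fingerprint), and identical
configuration reproduces byte-identical outputs.

## Known limitations

* Only PDB input (mmCIF, DCD/XTC trajectories are out of scope); no
  superposition/RMSF computation; no ROC/AUC-style benchmark metrics — the
  evaluation surface is the agreement-rate sweep and the correlation set.
* Multiple predictor tracks are analysed independently; no multiple-testing
  correction is applied.
* PB `d` is reported as a label only; whether a `d`-rich region should be
  read as extended or curved is an interpretation the package does not take
  a position on.
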