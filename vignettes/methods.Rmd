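---
title: "Pharmacophore hypotheses, grid-occupancy QSAR and shape screening: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacophore hypotheses, grid-occupancy QSAR and shape screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

qsarphore implements a ligand-based discovery workflow for enzyme
inhibitors: common-pharmacophore hypothesis generation with survival
scoring, a hypothesis-aligned binary grid-occupancy 3D-QSAR fitted by
partial least squares, a full external-validation suite, Gaussian
shape-plus-feature similarity screening of conformer ensembles, score
fusion with a top-fraction cutoff, and K-means triage of survivors. This
vignette records the models, their assumptions, and every place where the
design was genuinely open and a choice had to be pinned.

## Pharmacophore perception

Sites of six kinds (A acceptor, D donor, H hydrophobe, N negative, P
positive, R aromatic ring) are perceived from the connection table by an
explicit, versioned rule set (`pharmacophore_feature_rules()`, version
1.0). Published pharmacophore dialects differ in detail — in particular in
which oxygens and nitrogens count as acceptors and in what counts as a
hydrophobe — so the definitions are pinned in code rather than inherited
from any external tool, and they are deliberately conservative: acceptors
are uncharged oxygens, pyridine-like ring nitrogens and nitrile nitrogens;
donors are uncharged N/O with at least one hydrogen (implicit hydrogens
derived from standard valences); hydrophobes are terminal carbons on
carbon and halogens on carbon; charges come from formal charges; aromatic
rings are 5/6-rings that are Kekulé-alternating or explicitly aromatic.
Acceptor/donor sites carry a lone-pair/H-axis direction (away from the
mean heavy-neighbour direction), rings carry the plane normal with a
deterministic sign. Output order is deterministic (kind, then position),
so everything downstream is reproducible.

## Common-pharmacophore identification

Candidate pharmacophores are k-site subsets (k = 6 by default, because
six-point hypotheses are the workhorse of this protocol family;
configurable 3–7). Candidates are grouped by their canonical type label
and the binned vector of sorted pairwise intersite distances — eight bins
of 2 Å, distances ≥ 16 Å clipped to the last bin. Binning the sorted
distance vector is equivalent to descending a fixed binary tree of depth
log2(8) per pair; it is a hash, so two geometrically different candidates
can, rarely, collide — the survival-scoring stage re-checks geometry by
explicit alignment, which bounds the damage of a collision to wasted
compute. Groups covering at least half the actives survive; each takes
its sites from the member contributed by the highest-pIC50 active (ties:
lexicographic id, then lower conformer index). The reference-ligand rule
and all tie-breaks are fixed because the upstream literature is silent on
them.

## Survival scoring

A hypothesis is scored as
`S = w_site*S_site + w_vec*S_vec + w_vol*S_vol + w_sel*S_sel + w_rew*m −
w_e*dE + w_act*A`, all weights 1.0 by default. The sub-scores are named
but not normalized in the source protocol, so the following [0, 1] forms
are pinned:

* `S_site` = mean over matched actives of `max(0, 1 − RMSD/tolerance)`;
* `S_vec` = mean cosine between matched A/D/R direction pairs after
  rotation into the hypothesis frame (ring normals compared without sign,
  the mean clamped to [0, 1]; defined as 1 when no direction pairs exist,
  so a vector-free toy still reaches the maximum);
* `S_vol` = mean Gaussian shape Tanimoto between the reference conformer
  and each matched conformer at its aligned pose (heavy atoms only; the
  protonation-state bookkeeping a hydrogen-aware variant would need is
  not available from the generator, and heavy-atom volume is the common
  default); 1 when the hypothesis carries no reference structure;
* `S_sel` = −log2 of the fraction of a decoy conformer pool matching the
  hypothesis (pool = all inactive conformers by default; a zero count is
  floored at half a count; 0 on an empty pool) — an operationalization of
  "rarity of the hypothesis";
* `m` = matched actives − 1; `dE` = reference conformer strain energy
  (ensembles are re-referenced so the minimum is 0); `A` = reference
  pIC50.

The ranking subtracts the inactive-set counterpart (site/vector/volume
means over matched inactives plus their match reward); the
hypothesis-intrinsic terms (selectivity, energy, activity) cancel in a
subtraction and are therefore counted once, on the active side. The
fitness score used during screening is the per-ligand restriction
`w_site*site + w_vec*vec + w_vol*vol`, maximum 3.0 at unit weights.

## Grid-occupancy QSAR

Training molecules are aligned to the hypothesis (best conformer by
matched-pair count, then site RMSD). The grid is the bounding box of all
aligned heavy atoms padded by 2 Å and snapped to integer Å; cubes are
half-open (`[i, i+1)`), spacing 1.0 Å. Bits are laid out class-major: one
block for any-heavy-atom occupancy and one block per feature kind, so
feature-bearing atoms are deliberately counted twice.

Before regression the bit matrix is cleaned by two standard descriptor
treatments whose necessity was established on the synthetic ground truth:

* **Minimum support.** Bits set in ≤ 20% of training rows are dropped.
  Diagnostics showed that a compound whose alignment frame tilts slightly
  (site jitter propagating through the 6-point superposition) occupies a
  private shell of rare cubes; with both actives and inactives in
  training, those rare bits become in-sample activity-class markers with
  large coefficients that do not generalize — held-out actives whose
  frames tilt the same way were systematically branded inactive.
* **Exact-duplicate collapse.** Feature-class bits duplicate the
  heavy-atom bits of the same cube; identical columns split one effect
  across copies and halve every copy's jackknife t-value, pushing true
  signal below the filter cutoff.

PLS (NIPALS, single response) adds factors while leave-one-out Q²
improves by more than 1% relative — the numeric form given to "until
overfitting is detected", since that rule has no published number — up to
10 factors. Coefficients whose jackknife t-value (coefficient over its
leave-one-out standard error, the chosen estimator for "overly sensitive
to small changes in training composition") fall below 2.0 are zeroed and
the model is refitted once on the retained bits. The refit uses as many
factors as the retained set supports (effectively ordinary least squares
on the surviving bits): with the noise bits gone, further shrinkage only
re-compresses the surviving effects and under-disperses predictions,
which the r′₀² acceptance criterion punishes. An optional external
validation set can drive factor selection instead of LOO.

## Validation statistics

`regression_validation_stats()` implements r², the zero-intercept
determination coefficients r₀² and r′₀² (the primed variant has no
published formula; the role-swapped convention is used), the
through-origin slopes k and k′, r_m² = r²(1 − √|r² − r₀²|), RMSE and the
residual SD. The printed form of k in the source literature
(denominator Σpred rather than Σpred²) fails the identity case pred = obs
and contradicts its own 0.85–1.15 acceptance band; the standard
through-origin slope is the default and the printed form is preserved
behind `legacy_k = TRUE` for auditability. The F statistic is
`(r²/m)/((1−r²)/(n−m−1))` with the upper-tail F probability; LOO
stability is the r² between leave-one-out predictions and full-model
predictions (grid, alignment and factor count held fixed across refits —
coefficient stability, not protocol re-selection, is the question).
`accept_model()` is the conjunction q² > 0.5, r² > 0.6,
(r²−r₀²)/r² < 0.1, (r²−r′₀²)/r² < 0.1, 0.85 ≤ k ≤ 1.15, r_m² > 0.5, with
verbatim names of violated inequalities.

## Shape and feature similarity

Heavy atoms are spherical Gaussians with amplitude p = 2.7 and a decay
chosen so each Gaussian integrates to its element's hard-sphere van der
Waals volume — the classic shape-overlay parameterization, fixed here
because the upstream tool's constants are proprietary. Overlap is
evaluated in closed form over first-order atom pairs; higher-order
inclusion–exclusion terms are omitted (a documented approximation that
slightly overcounts dense overlaps but cancels in Tanimoto ratios).
Superposition starts from four deterministic poses (centroid-aligned
principal axes and the three 180° flips — replacing the proprietary
starting-point selection with a seedless equivalent) and refines each by
BFGS over a rotation vector and translation; the single best overlap is
kept. The pair is canonically ordered before optimization, so swapping
the arguments changes nothing. Feature ("color") similarity places one
Gaussian of radius 1 Å per site, accumulates overlap within kinds only
under the shape-optimal transform, and Tanimoto-combines across kinds.
Combined similarity = shape Tanimoto + color Tanimoto, range [0, 2]. The
screening protocol honours two energy windows: 30 kcal/mol for query
ensembles, 10 kcal/mol for library ensembles.

## Fusion and triage

Score columns are z-standardized over records with complete inputs;
fusion is their sum ("Z"), the product of positively shifted z-scores
(`z − min(z) + 1`; the product needs positive operands and no functional
form is published), or the sum of exponentiated z-scores. Exactly
`floor(0.10 n)` records survive the upper-10% cutoff, ties broken by
compound id. Survivors are clustered by K-means (k-means++-style multiple
starts under a fixed seed) on the first 10 principal components of
1024-bit hashed path-based fingerprints; k defaults to 8, matching the
number of candidates conventionally carried forward to assay. The
fingerprint family is pinned to OpenBabel FP2 because the original
fingerprints are proprietary.

## The synthetic-data generator

Every stage is validated against synthetic ligand sets with planted
ground truth, because the original training structures are not
reproducible from the main text. The generator emulates: a multi-scaffold
set of 85 compounds (40 actives, 45 inactives — the printed total; the
class ratio is unstated and chosen to span the 6.0 threshold roughly
evenly), pIC50 spanning the activity threshold of 6.0, several conformers
per compound, a planted six-point ADDRRR template shared by the actives,
and a planted linear activity model.

Design choices that matter, and why:

* **Template geometry.** The default ADDRRR site coordinates keep all 15
  pairwise distances ≥ 0.8 Å away from the 2 Å partition-bin edges and
  ≥ 2.8 Å apart, so the planted common pharmacophore lands in one
  partition group under the default 0.3 Å site jitter rather than being
  split across bin boundaries.
* **Activity model.** Actives: pIC50 = 6.2 + Σ βⱼzⱼ + N(0, 0.3), where
  zⱼ indicates presence of decoration j. The planted coefficients are an
  evenly spaced, randomly permuted ladder from 0.05 to ~0.5: coefficient
  recovery is only a well-posed question if the planted vector has
  spread, and the ladder's sum keeps actives inside the 6–9 band.
  Inactives delete exactly two interior template sites at 1.5 pIC50
  penalty each, landing them in 3.0–5.9 while keeping activity an exact
  linear function of group presence and decorations. Deletions never
  remove the two extremal anchor sites, so every compound stays globally
  superimposable — mirroring real inactive analogs that share scaffold
  termini.
* **Decorations.** Each decoration is a small rigid carbon cage at an
  exact template-frame position (placed by a deterministic max-min search
  that keeps ≥ 3 Å from template sites and other slots); positional noise
  enters through the jittered core sites only. This keeps a decoration's
  occupancy signal concentrated in a stable set of grid cubes — with
  fully independent per-decoration jitter the signal smears across
  neighbouring cubes and the planted coefficients stop being recoverable
  by any linear method, which says something about grid QSAR on sloppy
  alignments but makes the generator useless as a test instrument.
* **Conformers.** Each compound carries the planted pose (low energy)
  plus torsionally bent higher-energy poses, each under a random rigid
  motion, so conformer selection and alignment must do real work.
  Library decoys split between site-deletion decoys and
  geometry-distortion decoys (three sites displaced by 2.5–5 Å).

What the generator does **not** emulate: real chemistry (bond lengths and
valences are only loosely physical; "molecules" are decorated scaffolds),
tautomers/protonation states, conformer strain correlated with geometry,
assay noise structure beyond i.i.d. Gaussians, and activity cliffs.
Passing tests on this generator therefore demonstrates algorithmic
correctness and statistical recoverability under controlled conditions,
not performance on real screening data.

## Problem sizes and numerical choices

Tests and the acceptance analysis run the study conditions at their
natural sizes (85-compound labelled set, 200-compound library with 20
planted actives) and smaller editions of the same generator elsewhere;
unit fixtures are hand-built toys. Alignment tolerance defaults to 2.0 Å
with ≥ 2 matched features; candidate enumeration caps at 20000 subsets
per conformer with label-lexicographic truncation; overlap refinement
runs at most 30 BFGS iterations from each of the four starts (20 during
library screening). Degenerate inputs are contracts, not surprises: empty
libraries, constant activities, zero-information bit matrices and
too-small datasets raise errors naming the offender; a conformer that
matches nothing is a value (`NA`/`NULL`), not an error.

## Known limitations

* Parameter recovery through the full PLS + t-filter chain is noticeably
  below the information ceiling of the occupancy representation: ridge or
  informed least squares on the same bits recovers the planted ladder
  with Pearson ≈ 0.85, while the protocol-faithful estimator typically
  reaches 0.3–0.7 depending on seed, because few-factor PLS under-resolves
  eight small independent effects and the t-filter then prunes
  half-developed coefficients. The acceptance analysis reports what the
  faithful estimator achieves; treating the filter more gently would
  trade fidelity to the published protocol for better-looking recovery.
* The first-order Gaussian overlap overestimates volumes of dense atom
  clusters; Tanimoto normalization absorbs most of it.
* The distance-bin hash can split near-boundary candidate groups (a
  property inherited from the partitioning idea itself); survival scoring
  re-aligns explicitly, so split groups cost compute, not correctness.
* Screening superposition is a local optimizer from four starts; strongly
  non-convex cases can stick in a suboptimal overlay. The self-retrieval
  and enrichment tests bound how often this matters at study sizes.
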