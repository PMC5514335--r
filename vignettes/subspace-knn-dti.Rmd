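---
title: "Feature-subspace kNN ensembles for drug-target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-subspace kNN ensembles for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtiSubspace)
```

## The prediction problem

A drug-target interaction (DTI) is a binding or functional relationship
between a small molecule and a protein. Experimentally confirming one is
slow and expensive, so chemogenomic screening tries to rank candidate pairs
computationally from two ingredients that are always available: the
protein's amino-acid sequence and the molecule's structure-derived
descriptors. `dtiSubspace` implements one such predictor: a grid of
k-nearest-neighbour (kNN) classifiers, each working in a small, chemically
interpretable *feature subspace* of the pair representation, combined by a
conservative unanimity vote.

## The pair representation

**Target proteins.** Thousands of published amino-acid indices (the
AAindex1 collection) assign one number per residue type per physicochemical
property — hydrophobicity scales, helix preferences, transfer free
energies, and so on. These indices are highly redundant, so the package
first z-scores each property across the 20 residues and extracts principal
components of the property matrix (properties as observations, residue
types as variables). Each retained component is a length-20 *loading*: a
synthetic physicochemical scale. On real AAindex1 data seven components
absorb nearly all the variance; the package treats the component count
`n_pca` as a parameter with default 7.

A sequence of length $L$ is cut into `n_frag` (default 10) contiguous
fragments of $\lfloor L/\texttt{n\_frag}\rfloor$ residues from the
N-terminus, the last fragment absorbing the remainder. Within fragment $j$
the 20 residue types are counted, giving $A_j(n)$. The feature for
component $l$, fragment $j$ and residue type $n$ is the count weighted by
that residue's loading,

$$T_{l,j,n} \;=\; w_l(n)\, A_j(n),$$

and the full encoding concatenates the blocks component-major:
$7 \times 10 \times 20 = 1400$ features at the defaults. Two properties of
this encoding matter for testing: it is invariant to shuffling residues
inside a fragment, and a zero loading yields an all-zero block.

**Drugs.** Molecular descriptors (1D/2D: atom counts, topological indices,
electrotopological states, autocorrelations, ...) are consumed as a
precomputed CSV — computing them is the job of dedicated descriptor
software, not of this package. Descriptors that are missing, non-finite or
constant are dropped (never imputed: a kNN distance must be finite, and a
constant coordinate is dead weight). The surviving columns keep their file
order and are cut *in order* into `n_pca` contiguous groups, again with the
last group absorbing the remainder (1444 descriptors split 7 ways gives
206, ..., 206, 208). A pair vector is the drug block followed by the
protein block.

## The classifier grid and the vote

Every combination of one protein component group (200 features at the
defaults) and one descriptor group (~206) defines a subspace of roughly 400
features; with `n_pca = 7` there are 49 of them. The two halves are
deliberately comparable in size so that neither the chemistry nor the
sequence dominates the Euclidean distance. Each subspace trains its own
kNN classifier on the same instances:

* features are min-max scaled with statistics from the training instances
  only (descriptor units span orders of magnitude; a degenerate feature
  gets divisor 1);
* distances are Euclidean, votes inverse-distance weighted ($1/d$) by
  default, with plain uniform voting available;
* a query that coincides with training points is decided by the majority
  label among its zero-distance neighbours (an exact hit should not be
  outvoted by far neighbours with finite weights);
* every tie — a 0.5 vote fraction, or an exact half of the grid under the
  majority rule — resolves to *non-interacting*, the conservative call for
  a screening tool;
* each classifier picks its own neighbour count by leave-one-out over the
  odd values $1, 3, \ldots, 2\lceil\sqrt n\,\rceil + 1$, smallest `k`
  winning ties. Leave-one-out needs no random fold split, so the selection
  is deterministic. A shared fixed `k` can be forced instead.

The ensemble calls a pair interacting under the default **unanimity** rule
only if *all* $n_\mathrm{pca}^2$ classifiers vote positive. A plain
majority rule is also implemented; since a unanimous positive is in
particular a majority positive, switching unanimity to majority can only
add positive calls — a monotonicity the tests exercise. Unanimity trades
recall for precision: each subspace holds a different projection of the
pair, and requiring agreement suppresses false positives that fool only a
few projections.

## Evaluation protocol

Benchmarks of this kind list only *positive* pairs. Presumed negatives are
built by recoupling: the candidate pool is the full cross product of the
observed drugs and targets minus the known positives, and negatives are
drawn from it uniformly without replacement, twice as many as the positives
by default. Evaluation is stratified 10-fold cross-validation: per-class
fold sizes differ by at most one, and for each fold the *entire* ensemble —
scalers, per-classifier neighbour counts, everything that sees labels or
feature scales — is refit on the nine training folds. The property PCA uses
no labels, so it may be fit once globally without leaking test information.
Reported metrics are recall, precision, accuracy, F1 and Matthews
correlation (MCC), the latter being the honest summary under 1:2 class
imbalance. A metric whose denominator vanishes (for instance precision when
the unanimity rule makes no positive call) is reported as `NA` with a
warning — never silently as zero.

## What the synthetic generator emulates

Real benchmark data (curated interaction lists plus descriptor-software
output) cannot ship with the package, so `fixture_spec()` /
`simulate_dti_study()` generate studies with the statistical structure the
method assumes:

* a property matrix of effective rank `property_rank` (mixtures of latent
  residue profiles with geometrically decreasing weights plus noise), so
  the PCA step has a recoverable truth;
* random protein sequences with i.i.d. residues;
* Gaussian drug descriptors;
* an interaction rule planted in exactly one (component $i$, descriptor
  group $j$) subspace: half the drugs and half the proteins carry a latent
  signal class, and a pair interacts exactly when both do. Signal drugs
  have descriptor group $j$ mean-shifted by `effect_size` standard
  deviations; signal proteins have their residue distribution tilted along
  loading $i$. Because the protein features are elementwise products of
  loadings and counts, the composition tilt leaks weakly into every
  component block — so off-signal classifiers are weak but not blind, which
  is exactly the regime where the unanimity/majority contrast is
  informative (a grid of coin-flip classifiers would simply never be
  unanimous).

Default sizes: 60 drugs x 60 proteins, 100 positives + 200 recoupled
negatives, 120 properties of rank 7, and 1400 descriptors — the balanced
drug/protein feature geometry the method is designed around. With
`effect_size = 0` no shift is planted anywhere and labels attach to
uniformly drawn pairs with *no* latent structure at all. The distinction
matters: labels that follow an entity-level rule are learnable from entity
identity alone (repeated drug blocks act as fingerprints across folds),
which is signal, not noise. A faithful null must randomize labels over
pairs, and that is what the generator does.

What the generator does **not** emulate: real descriptor distributions
(heavy tails, discreteness, block correlations), homologous sequences,
hub drugs/targets, or label noise. A pass on these fixtures demonstrates
that the machinery is correct and that the ensemble behaves as designed
when its assumptions hold — not that any particular accuracy carries over
to real screening data.

## Numerical and design choices

* **Pre-PCA normalization** is not dictated by the encoding itself; raw
  AAindex values have wildly different units, so the default z-scores each
  property (per-row). `fit_property_pca(..., standardize = FALSE)` gives
  the raw variant.
* **PCA sign convention**: each loading's largest-magnitude entry is made
  positive; PCA signs are otherwise arbitrary and tests need determinism.
* **Remainders** (sequence length not divisible by `n_frag`; descriptor
  count not divisible by `n_pca`) go to the last fragment/group. Any fixed
  policy works; one policy for both keeps the geometry easy to reason
  about.
* **Counts vs frequencies**: raw fragment counts are the default; a
  frequency option (`frequencies = TRUE`) divides by fragment length.
* **Non-standard residues** (B, Z, X, U, O, gaps) are rejected with a
  clear error by default; `policy = "skip"` drops them before fragmenting.
* **Per-classifier vs shared `k`**: independent selection is the default —
  the 49 subspaces have genuinely different geometry — but a shared `k`
  can be fixed for speed or comparability.
* **Serialization**: PCA models and ensemble bundles are JSON with
  17-significant-digit numbers, which round-trips IEEE doubles exactly;
  a reloaded bundle reproduces every prediction bit for bit.
* The canonical residue order is the AAindex two-row order
  `A R N D C Q E G H I / L K M F P S T W Y V`, fixed everywhere.

## Problem sizes used by the test-suite

The packaged tests run the full protocol at reduced scale, chosen so the
statistical checks are sharp while the whole suite stays fast: planted and
null studies of 300 pairs (the 49-classifier grid, 10-fold), a
~200-instance fixture for exhaustive-oracle comparison of all 49
classifiers under both weightings, and 120-pair studies on a 3x3 grid for
the module-level mechanics. The acceptance script regenerates the encoding
geometry (1400 and 1500 features) from freshly simulated inputs at every
run.

## Known limitations

* Exact neighbour search only; fine up to ~10^4 instances, not beyond.
* The recoupling assumption — that an unobserved pair is negative — is a
  field convention, not a fact; some sampled negatives are undiscovered
  positives in real data.
* The unanimity rule can legitimately return *zero* positive calls (and
  hence undefined precision) when no signal spans all subspaces; this is
  reported honestly rather than patched over.
* Descriptor semantics are whatever the upstream descriptor software
  produced; the package only guarantees the order-preserving partition.
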