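---
title: "Conformational ensembles and their linear motions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational ensembles and their linear motions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confmotion)
```

## The problem

Experimental structural biology rarely observes a protein once. The same
chain, or close homologues of it, is deposited in many crystal forms,
cryo-EM maps and NMR ensembles, each catching the molecule in a different
functional state: open or closed, bound or free, tense or relaxed.
`confmotion` organises such a heterogeneous pile of structure files into
*conformational ensembles* — sets of superimposed conformations of one
protein or protein family — and summarises the variability within each
ensemble as a small number of *linear motions*: principal components of
the C$\alpha$ coordinates.

The pipeline mirrors the practice of ensemble analysis in structural
bioinformatics:

1. **Sequence extraction.** Every polypeptide chain of every input mmCIF
   file is read (first model only). Residues declared in the entity's
   polymer sequence (`_entity_poly_seq`) but lacking coordinates are kept
   as *lowercase* letters; unknown or unmappable modified residues become
   `X`. Chains with fewer than 5 resolved residues or fewer than 5 non-`X`
   letters are discarded.
2. **Clustering.** Sequences are grouped at configurable identity and
   coverage thresholds (both 0.8 by default, coverage bidirectional).
3. **Alignment.** Each cluster is aligned (MAFFT when available, with case
   preserved; a built-in center-star aligner otherwise). Columns containing
   only `X`/gaps are removed and rows are ordered by structure code.
4. **Structure extraction.** Backbone N/CA/C/O coordinates are collected;
   missing carbonyl oxygens are rebuilt from the peptide geometry;
   residues missing any other backbone atom are treated as unresolved.
5. **Ensemble construction.** Each cluster's conformations are
   superimposed on a reference chosen by consensus scoring, redundant
   conformations are removed, and the ensemble is written as a multi-model
   file with its alignment and all-against-all RMSD matrix.
6. **Motion extraction.** PCA of the per-column C$\alpha$ coordinates
   yields modes, eigenvalues, and the intrinsic dimensionality of the
   observed variability.

A generation benchmark (kernel PCA with pre-image reconstruction,
leave-one-cluster-out cross-validation, convex-hull extrapolation scores,
and interpolation trajectories) asks how well the learnt representation
spaces predict conformations that were never seen during fitting.

## Choosing the reference

The reference conformation anchors the superposition. Its sequence should
be the most representative of the alignment, so we first build the
consensus: per column, the modal symbol among the 20 amino acids and the
gap, with `X` counted as a gap. Ties prefer an amino acid over a gap
(favouring longer references) and, among amino acids, the higher BLOSUM62
self-score; a remaining tie falls back to the alphabet. Each row is then
scored against the consensus,

$$\mathrm{score}(s) = \sum_{i=1}^{P} \sigma(s_i, s^{*}_i),$$

with $\sigma$ the BLOSUM62 substitution score and a gap score of
$\min_{a,b}\sigma(a,b) - 1 = -5$ whenever either symbol is a gap or `X`.
The arg-max row wins; equal scores resolve to the lexicographically
smallest identifier, so the choice is deterministic. A configuration flag
(`invert_priority`) flips both tie-breaking rules, reproducing the
robustness experiment of preferring shorter references; on our fixtures
this changes the reference only when the MSA is genuinely ambiguous.
Unresolved (lowercase) residues score as their amino acid: the score
operates on sequence content, and an unresolved residue is still evidence
about the sequence.

## Superposition with uncertainty weights

Alignment columns poorly covered by the ensemble are uncertain: a
deviation there may reflect an alignment error rather than a motion. Each
column therefore carries a confidence weight $w_i$, its fraction of
resolved residues, and each conformation is fitted to the reference by
minimising the weighted least-squares deviation

$$E = \frac{1}{\sum_i w_i}\sum_i w_i\,\lVert r^c_{ij} - r^c_{i0}\rVert^2$$

over the positions resolved in both, after moving both weighted centroids
to the origin. Any exact minimiser of $E$ is acceptable; we use the SVD
form of the weighted Kabsch algorithm with reflection correction, and the
tests verify it against the classical unweighted fit (when $w \equiv 1$),
against an independent implementation, and against a Monte-Carlo sample
of random rotations. Conformations sharing fewer than `min_aligned`
(default 5) resolved positions with the reference are dropped and
reported.

Redundancy is then pruned: a conformation is removed when it deviates by
less than `rms_cut` (default 0.1 Å) from a retained one whose sequence
contains its own ("contains" meaning: at every column the candidate's
symbol is a gap or equal, and its resolved set is a subset). The removal
order is deterministic — resolved length descending, then identifier — and
the reference is always retained, which the order alone cannot guarantee
when the reference is itself a duplicate.

## Missing data and the PCA

Unresolved coordinates are *not* reconstructed. They are filled with the
coordinates of the centering conformation (the per-column mean over
resolved rows by default, or the reference on request, its own gaps
completed by the column means). Filling with the centre adds no spurious
signal and shrinks the variance of poorly covered columns: a column
resolved in $k$ of $n$ rows keeps only $(k-1)/(n-1)$ of its resolved
sample variance, which the tests check symbolically. When weighting is
enabled the filled coordinates are additionally multiplied by $w_i$
before the decomposition, and generated conformations are divided by
$w_i$ on output so they live in Å space; with $w \equiv 1$ the weighted
pipeline reproduces the unweighted one exactly.

The decomposition itself is computed by SVD of the centred $n \times 3m$
coordinate matrix — the $3m \times 3m$ covariance matrix is never formed,
since $3m \gg n$ for typical ensembles and only $n$ components can be
non-trivial. Eigenvalues are reported as fractions of the total positional
variance; the intrinsic dimensionality at a threshold (50/80/85/90/95/99%
by default) is the smallest number of leading modes reaching it. A
correlation-matrix variant normalises each coordinate by its standard
deviation (zero-variance coordinates are excluded with a warning, and the
eigenvalue *fractions* are reported rather than rescaling the spectrum).
The collectivity of a mode uses the per-atom convention: squared
displacements are summed over each atom's three components before the
entropy, so a uniformly displaced mode scores exactly 1 and a single
displaced atom exactly $1/m$. Summing over the $3m$ individual components
instead would give 3 for the uniform mode, violating those boundary
values, which is why the per-atom form is used.

## The generation benchmark

Kernel PCA replaces the linear scores with the spectrum of a
double-centred kernel matrix (RBF, polynomial or sigmoid, the dot-product
kernels scaled by $1/2\sigma^2$; $c = 1$, $d = 3$ by default). Feature
space centering is applied to the training kernel matrix and consistently
to test columns — without it the leading component merely encodes the
feature-space mean. Components are scaled to unit feature-space norm so
that projecting the training data reproduces the eigendecomposition
scores; at large $\sigma$ every kernel linearises and the model reproduces
linear PCA, a limit the tests assert quantitatively. The pre-image map is
kernel ridge regression of the (mean-centred) training coordinates on
their projections, with the same kernel family and width; its ridge
parameter $\alpha$ interpolates between exact interpolation of the
training set ($\alpha \to 0$) and collapse to the training mean
($\alpha \to \infty$).

Cross-validation leaves out one conformation *cluster* at a time, because
deposited conformations cluster heavily around popular states. Clusters
are k-means groups (fixed seed, best of 10 restarts) in the $l$-dimensional
PCA space, $k = l + 2$, with $l$ the dimensionality at 90% variance. The
difficulty of each held-out conformation is its Euclidean distance to the
convex hull of the training projections, computed exactly — without
constructing the hull — by the quadratic program
$\min_\theta \lVert T^\top\theta - p\rVert^2$, $\theta \ge 0$,
$\sum\theta = 1$, solved by a primal active-set method and divided by
$\sqrt{m}$. That normalisation makes hull distances commensurate with
Cartesian RMSDs: in a purely one-dimensional ensemble, two conformations
1 Å RMSD apart sit exactly 1 Å apart in normalised representation-space
distance, an identity the acceptance checks reproduce to $10^{-8}$.
Training folds always contain $l + 1$ clusters, so the hull is a
full-dimensional $l$-polytope; distances are measured in the training-fold
PCA space, since that is the space the training-fold model actually spans.
Interpolation trajectories place 50 regularly spaced points (endpoints
included) on the segment between two cluster centres in the representation
space of a model fitted on those two clusters only, and report each
generated conformation's minimum RMSD to a held-out set.

Hyperparameter choice follows the benchmark's own protocol: a log-grid
over $\sigma$ (median pairwise distance × 0.25…8) and
$\alpha \in \{10^{-10},\dots,10^{-2}\}$, keeping the values with the best
mean cross-validated reconstruction per ensemble. That selection is
optimistic — it peeks at the test clusters — so `kpca_grid_search()` also
implements a nested variant that selects each fold's hyperparameters on
the other folds only.

## What the synthetic generators emulate

All tests run on synthetic ensembles, since no structure download is
assumed:

- `make_linear_motion_ensemble()`: a self-avoiding C$\alpha$ walk (3.8 Å
  steps) deformed along one fixed direction with amplitudes spanning
  ±`amplitude`, plus isotropic noise, emulating the one-dimensional
  opening motions common in deposited ensembles. The direction has unit
  per-atom RMS displacement, so the RMSD between two noise-free
  conformations *equals* their amplitude difference — the property the
  d-norm identity check relies on.
- `make_hinge_ensemble()`: two rigid arms opening symmetrically about a
  pivot, emulating open/closed domain transitions; the inter-domain
  centroid distance is strictly monotone in the angle and the dominant
  mode is collective.
- `make_gapped_cif_fixture()`: toy mmCIF files with declared-but-missing
  residues, a decoy second model and optionally a decoy chain and an
  exact-duplicate entry, exercising parsing, weighting and redundancy
  removal end to end.

Backbone geometry is idealised (canonical bond lengths in a local frame,
carbonyl oxygens from the peptide plane); sequences are uniform over the
20 amino acids. What passing tests therefore show is that the machinery
is numerically correct and recovers planted ground truth; they do not
show robustness to crystallographic artefacts, alternate locations,
genuinely ambiguous alignments, or the sequence diversity of real
families. Problem sizes in the test-suite and acceptance runs are
deliberately small (m = 8–50 positions, n = 5–30 conformations), which a
few seconds of CPU cover while leaving every contract exercised.

## Numerical choices and degenerate inputs

- Rotation fits correct reflections via the determinant sign; collinear
  position sets are flagged (`degenerate_fits`) but still receive the
  minimising rotation.
- The SVD rank cut-off is $10^{-9}$ relative to the largest singular
  value; eigen-null kernel matrices and rank-deficient training folds
  truncate at numerical rank rather than erroring.
- The active-set QP uses a $10^{-10}$ feasibility tolerance and
  pseudo-inverse KKT solves for affinely dependent training points; hull
  distances below $10^{-9}$ are reported as exactly 0.
- k-means is always seeded and restarted 10 times; re-runs with one seed
  are bit-stable, which the pipeline tests assert.
- Ties in the consensus, the reference choice and the redundancy order
  are all resolved lexicographically, so the whole deterministic part of
  the pipeline is reproducible byte for byte.
- Alignment and superposition are independent per cluster, so they may be
  parallelised without changing results; the implementation runs them
  sequentially and the bit-stability test pins the scheduling-independence
  contract.

## Known limitations

- The built-in clusterer and aligner are test-scale tools: greedy
  CD-HIT-style clustering and center-star alignment with BLOSUM62/affine
  gaps. For real family-scale runs, MMseqs2 and MAFFT remain the intended
  backends; the built-in results are flagged as non-canonical.
- `monomer_only` trusts the first listed assembly annotation
  (`oligomeric_count`) and falls back to counting chains in the file.
- Pairwise RMSDs in the output matrix are measured in the common
  superposition frame, not per-pair refitted; per-pair refitting would
  give slightly smaller off-diagonal values.
- Projection and generation are defined for covariance-mode
  decompositions; the correlation variant is analysis-only.
- mmCIF support covers the categories the pipeline consumes
  (`_atom_site`, `_entity_poly_seq`, assembly counts); exotic CIF
  constructs (multi-line text values, multiple data blocks) are out of
  scope.
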