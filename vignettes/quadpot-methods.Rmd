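---
title: "Four-body potentials and tessellation-based computational mutagenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-body potentials and tessellation-based computational mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadpot)
```

## The model

`quadpot` implements a knowledge-based, four-body statistical potential over
protein structures coarse-grained to their C-alpha atoms, and the
computational-mutagenesis machinery built on top of it.

**Tessellation.** The C-alpha coordinates of a chain are the vertices of a 3D
Delaunay tessellation: a tiling of the convex hull by tetrahedra whose
circumspheres contain no other vertex. Each tetrahedron objectively
identifies a quadruplet of nearest-neighbor residues. Tetrahedral edges
longer than 12 &Aring; — usually artifacts that close the convex hull across
surface clefts — are removed, together with every tetrahedron that uses
them. All downstream quantities are computed on this filtered tessellation.
The cutoff is a parameter (`cutoff`, default 12 &Aring;).

**The potential.** Over a training corpus of tessellated chains, for each of
the $\binom{20+3}{4} = 8{,}855$ residue quadruplets $(i,j,k,l)$ (unordered,
repeats allowed, written in ascending alphabetical order) we record the
observed fraction $f_{ijkl}$ of retained tetrahedra carrying that quadruplet,
and compare it with the multinomial chance expectation

$$p_{ijkl} = \frac{4!}{\prod_n t_n!} \prod_n a_n^{t_n},$$

where $a_n$ is the corpus-wide proportion of residue type $n$ (computed over
all residues of the corpus chains, not only tessellation-retained vertices)
and $t_n$ counts repeats of type $n$ in the quadruplet ($\sum_n t_n = 4$).
The inverted-Boltzmann log-likelihood score of the quadruplet is the
log-ratio of the two.

*Sign and base.* The package's default is $s = \log_{10}(f/p)$: an
overrepresented (favorable) quadruplet scores positive, so a substitution
that degrades a residue's environment produces a *negative* residual score.
This matches the empirical behavior of the published structure–function
results (detrimental variants have markedly negative mean residual scores),
although the source literature prints the formula with a leading minus sign.
Both conventions are supported (`sign = "log_ratio"` or `"neg_log_ratio"`)
and the choice is recorded in the potential's metadata and serialized table.

*Unobserved quadruplets.* An additive pseudo-count (default 1, recorded in
metadata) is applied to every count before normalizing, so all 8,855 keys
carry finite scores. The alternative of flooring scores was rejected because
it breaks the additivity identities used throughout (`sum(q) = 4 tp`).

**Computational mutagenesis.** The total potential $tp$ of a chain is the
sum of its tetrahedron scores; the residue environment score $q_i$ sums only
tetrahedra incident to position $i$, so $\sum_i q_i = 4\,tp$. A point
substitution relabels one vertex — the tessellation is *never* recomputed
and no side-chain modeling is attempted — which changes the scores of
exactly the incident tetrahedra. The environmental perturbation
$EP_i = q_{i,\mathrm{mut}} - q_{i,\mathrm{wt}}$ is therefore supported on
the mutated position and its tessellation neighbors only; its value at the
mutated position (the *residual score*) is identically $tp_\mathrm{mut} -
tp_\mathrm{wt}$. `residual_score()` computes both routes and asserts their
agreement to $10^{-9}$ on every call. The comprehensive mutational profile
$CMP_i$ averages the 19 residual scores of all substitutions at $i$.

**Variant features.** Each variant is encoded as 27 attributes: position,
native and replacement residues, residual score; EP scores, identities and
sequence offsets of the six nearest neighbors (ordered by C-alpha distance
along tessellation edges, ties broken by ascending sequence number); mean
volume and mean tetrahedrality
($\sum_{i>j}(l_i - l_j)^2 / (15\,\bar l^2)$ over the 15 edge pairs) of the
incident tetrahedra; secondary structure (H/S/C); tessellation depth
(S/U/B); and the count of edges to surface positions. Depth is defined
combinatorially: a position is surface (S) if it is a vertex of a facet
belonging to exactly one tetrahedron, undersurface (U) if it is
edge-connected to a surface position, buried (B) otherwise — so buried
positions have zero surface edges by construction. Positions with fewer
than six neighbors are padded (EP 0, identity `-`, offset 0) and flagged in
an auxiliary `padded` column outside the 27.

## Numerical choices in the tessellation engine

No 3D Delaunay implementation is available in the package's R dependency
set, and the tessellation is the core primitive of the method, so `quadpot`
ships its own: an incremental Bowyer–Watson construction with a symbolic
vertex at infinity (hull facets are handled by orientation predicates, so no
hull simplex can be lost to a finite "super-tetrahedron" approximation).
Choices that matter:

* **Predicates.** Floating-point in-sphere and orientation determinants with
  tolerances scaled to the configuration (coplanarity band $10^{-10}$
  relative; cosphericality band $10^{-11} \max(D^2, r^2)$ for diameter $D$
  and circumradius $r$). Points falling on a circumsphere within the band
  count as conflicts — a symbolic inflation that gives cospherical clusters
  a deterministic tie-break. A point coplanar with a hull facet is decided
  by the in-circumcircle test within the facet plane.
* **Validity certificate.** Every accepted triangulation is checked
  post-hoc: each facet is shared by at most two tetrahedra, and the summed
  tetrahedron volume equals the volume enclosed by the boundary facets
  (divergence theorem) to $10^{-8}$ relative. An inconsistent result is
  demoted to "degenerate" rather than returned.
* **Joggle.** Degenerate inputs are retried under a deterministic joggle
  (a fixed Lehmer sequence, independent of R's RNG). The schedule starts at
  the nominal $10^{-6}$ &Aring; and escalates to at most
  $5\times 10^{-3}$ &Aring;: highly structured inputs (lattices with
  collinear runs) produce second-order-small determinants that a $10^{-6}$
  perturbation cannot lift out of double-precision noise. Even the largest
  amplitude is negligible against the 3.8 &Aring; backbone spacing and the
  12 &Aring; cutoff. Joggled results are flagged (`joggled`,
  `joggle_amplitude`), and depth classification compensates: a vertex
  pushed off an exactly-boundary plane by the joggle is restored to surface
  when it lies within joggle reach of a boundary facet.
* **Edge filter.** "Longer than 12 &Aring;" is strict: an edge of exactly
  12.0 &Aring; is retained. Isolated vertices (every incident tetrahedron
  filtered away) are labeled surface in depth classification — they sit on
  the structure's exterior — and score zero in all profiles, with a warning.

## Statistics

The structure–function layer reproduces the analysis toolkit around the
residual scores: conservative/non-conservative substitution classes over the
six physicochemical groups [(A,S,T,G,P), (D,E,N,Q), (R,K,H), (F,Y,W),
(V,L,I,M), (C)]; class mean residual scores; a Welch two-sided t-test
(chosen over the pooled-variance test because no variance homogeneity can be
assumed between activity classes); Pearson chi-square without continuity
correction; Fisher's exact test for r&times;c tables (exact network
algorithm up to a total count of 200, then a seeded Monte Carlo
approximation, with the method recorded in the output); residual-score
binning into $(-\infty,-1)$, $[-1,0)$, $[0,1)$, $[1,\infty)$; and ordinary
least squares for the CMP–RES relationship with $R^2$ equal to the squared
Pearson correlation.

Positions are placed in the (environment score, CMP) plane with quadrants
numbered counterclockwise from $(+,+)$ and zero coordinates assigned to the
positive side; the convention is a package choice (the source figures do not
state their axes) and is documented on `assign_quadrant()`.

## Machine learning

Four classifier families are exposed behind one `classifier_spec()`
interface, at the reference hyperparameters: random forest (100 trees),
RBF-kernel SVM (cost 2.0, gamma 0.01, standardized inputs, probability
calibration), bagged decision trees (10 bootstrap iterations), and a neural
network trained for 500 epochs. Two mappings deserve note. The reference NN
is described with two hidden layers of unstated width; `nnet` supports a
single hidden layer, so the package uses one layer of
$(27 + 2)/2 \approx 14$ units (configurable via `hidden`) — with unstated
widths there is no fidelity to lose, and a single wider layer is the
conventional single-hidden-layer surrogate. The decision tree's "pruning
confidence 0.25" is a C4.5-specific parameter; rpart's complexity-based
pruning (`cp = 0.01`) plays the equivalent role. Categorical attributes are
one-hot encoded over closed vocabularies; numeric attributes are
standardized for the SVM and NN only.

Evaluation: LOOCV (deterministic given the model seed) and stratified
10-fold CV averaged over repeats with per-repeat seeds; sensitivity,
specificity, PPV, BAR $= (\text{sens}+\text{spec})/2$, MCC, and AUC by the
rank (Mann–Whitney) formulation, with the unaffected class U as positive.
Label-permutation nulls rerun the full cross-validation per shuffle and
report the null mean ± sd with an empirical p-value; learning curves draw
stratified subsamples without replacement and aggregate 10-fold CV metrics
per size.

## The synthetic generator

Because the published potential was trained on a large curated PDB corpus
that a self-contained package cannot assume, every analysis here is
exercised on synthetic data. `generate_structure()` draws a compact
self-avoiding walk: consecutive C-alpha spacing 3.8 &Aring; (±1%), pairwise
exclusion 3.5 &Aring;, confinement to a sphere of radius
$3.3\,n^{1/3}$ &Aring; so that tessellation edge spectra sit mostly under
the 12 &Aring; cutoff, as in compact globular chains. Residues are drawn
from a configurable composition (uniform by default).
`generate_variant_dataset()` labels variants by a threshold rule — class A
(detrimentally affected) when the residual score falls below $\tau$,
defaulting to the sampled median, which targets the near-balanced class
split of the reference dataset (201 U / 171 A) — and flips labels with
probability $\varepsilon$ to emulate experimental noise.

What this does and does not show: the generator reproduces the *geometry*
the method assumes (protein-like spacing, compactness, tessellatability) and
a *recoverable* structure–function link, so passing tests demonstrate the
correctness of the pipeline's identities and the learnability of a signal
carried by the features. It does not emulate real secondary-structure
content, residue-composition biases, spatial clustering of conserved sites,
or experimental label noise structure, so absolute accuracies on synthetic
data say nothing quantitative about accuracy on real mutagenesis datasets.

A related empirical finding: with noiseless threshold labels, tree ensembles
recover the rule almost perfectly (LOOCV MCC ≈ 0.97 for RF at $n = 200$),
while the SVM and NN — run at the fixed reference hyperparameters with no
tuning — plateau near MCC 0.56–0.70. The signal lives in one of ~66 encoded
dimensions, a geometry that kernel and network methods at a fixed bandwidth
learn slowly. The test suite therefore asserts near-perfect recovery for
RF/DT and far-above-null recovery for SVM/NN.

## Problem sizes

The shipped tests and the acceptance script run at deliberately compact
sizes chosen to exercise every code path while keeping the whole suite
interactive: synthetic chains of 40–120 residues, corpora of 3–6 chains,
variant sets of 24–200, 200 label permutations, and brute-force Delaunay
oracles at up to 25 points (the $O(n^5)$ enumeration is the bottleneck).
The package itself has no such limits; chains of many hundreds of residues
tessellate in well under a second.

## Known limitations

* Coordinates are never re-tessellated after mutation (by design — the
  label-swap model is the method), so conformational relaxation is out of
  scope, as are multi-residue mutants and ΔΔG calibration.
* Secondary structure comes from the PDB's HELIX/SHEET records; an external
  per-residue assignment (e.g. from DSSP) can be supplied via
  `assign_secondary_structure(ss = ...)` but is not computed.
* The published potential table and corpus are not bundled; reproducing the
  published corpus-scale numbers requires downloading the corpus and
  training with `train_potential()`, for which the capability — but not the
  data — is provided.
* mmCIF files, insertion-code-heavy chains and biological-assembly
  generation are not supported; parsing is deliberately minimal C-alpha
  coarse-graining.
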