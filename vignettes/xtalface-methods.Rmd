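---
title: "Classifying biological and crystal-packing interfaces with covariation signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying biological and crystal-packing interfaces with covariation signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`xtalface` decides whether a protein–protein contact observed in a
crystal is part of the biological assembly or an artifact of lattice
packing. This vignette is the package's own account of the method:
the model and its assumptions, every tunable that matters, the
numerical choices, and what the synthetic test bed does and does not
demonstrate.

## The problem and the model

Crystallographic and biological interfaces overlap broadly in buried
area, shape and composition, so purely geometric classifiers plateau.
The observable this package adds is evolutionary: residue pairs that
touch in the functional assembly co-evolve, so the columns of a deep
multiple sequence alignment (MSA) corresponding to a genuine interface
carry detectable statistical couplings, while lattice contacts are
invisible to evolution. The classifier therefore combines

1. classical interface descriptors (65 values), and
2. covariation-signal (CS) counts: for thresholds
   t ∈ {0.2, 0.4, 0.6, 0.8}, the number of residue contact pairs whose
   APC-corrected coupling score exceeds t (4 values),

and feeds them to a random forest or an RBF-kernel SVM. Interchain
couplings are weak compared to intrachain ones — most interface pairs
have no outstanding score at all — which is precisely why *counts
above a threshold*, rather than raw scores or ranks, are used: they
aggregate a handful of subtle signals into a robust statistic.

Assumptions worth stating: the MSA's first sequence matches the
chain(s) of the structure; for homomers both chains map to the same
columns (single-gene mapping); for hetero-oligomers a pre-paired,
concatenated MSA with known chain boundaries is supplied (ortholog
pairing is out of scope); and the alignment is deep enough to estimate
couplings — enforced by the diversity criterion below.

## Geometry: SASA, BSA, and the interface definition

Solvent accessible surface area uses the Shrake–Rupley test-point
method with probe radius 1.4 Å and 3000 points per atom. Test
directions come from a deterministic golden-spiral (Fibonacci)
lattice, so SASA is reproducible bit for bit at a fixed point count;
the discretisation error of an isolated atom is far below 1% at 3000
points and shrinks as the count grows. Van der Waals radii are the
element-based Bondi set shipped as a config file
(`inst/extdata/vdw_bondi.tsv`); unknown elements fall back to 1.8 Å
unless `strict = TRUE`. Hydrogens are dropped on reading (the contact
definition is over non-hydrogen atoms), waters and heteroatoms are
removed, alternate locations resolve to the highest occupancy with an
alphabetical tie-break, and only the first model of multi-model files
is kept.

Buried surface area is the difference of two SASA runs
(alone vs in complex), clipped at zero. An interface exists when some
atom pair across the two sides is closer than 5.5 Å (strict) and both
atoms lose at least 0.1 Å². Residue contact pairs additionally require
complete main chains (N, CA, C, O — "no ambiguous residue") and
relative SASA above 25% of the residue's theoretical maximum
(Tien et al. 2013 table, shipped as config). Relative SASA is computed
on the **unbound** monomer: the alternative (bound) reading would
contradict the core definition, since a core residue (BSA/SASA > 0.95)
is by construction buried in the complex yet must count as a surface
residue. Both thresholds are configurable; classification is known to
be robust to the precise relative-SASA cut.

Crystal partners are rebuilt by applying the space-group operators
(65 Sohncke groups, operator table generated from their
general-position triplets and shipped as
`inst/extdata/spacegroups_sohncke.tsv`) over the 3×3×3 lattice
neighbourhood, keeping copies with any atom within 6.5 Å (the 5.5 Å
interface distance plus a 1 Å margin). Files without cell/symmetry
records work by supplying a pre-generated partner; when several
partners qualify, the one burying the most surface is selected.

## Coupling scores

Sequences are weighted by the reciprocal of their neighbourhood size
at ≥ 62% identity (identity = matches over columns where both
sequences are non-gap; zero comparable columns gives identity 0). The
**diversity criterion** requires at least L non-redundant clusters
(Σ weights ≥ L); failing alignments escalate the clustering threshold
in 1% steps up to 80%. Alignments that still fail are rejected for
coupling estimation rather than silently scored.

Column statistics mix weighted empirical frequencies with a uniform
pseudocount, λ/21 for singles and λ/441 for pairs, over the 21-state
alphabet. For the coupling estimate, the covariance
C<sub>ij</sub>(a,b) = f<sub>ij</sub>(a,b) − f<sub>i</sub>(a)f<sub>j</sub>(b)
is assembled over the **20 amino-acid states only**: the gap state is
dropped as the gauge reference. This matters numerically — with all 21
indicator states the per-column sum-to-one constraint gives the
covariance one exact null vector per column, and its inverse is
dominated by noise. Dropping one state per column (the mean-field DCA
convention) removes the degeneracy, and the default pseudocount is
λ = 0.5, the value this estimator family needs when the effective
number of sequences is comparable to 20·L. We verified on planted
ground truth that recovery is essentially perfect at λ = 0.5 and fails
at λ = 0.2 under the default study conditions (L = 60, n = 1500). The
matrix is shrunk towards its diagonal, ρ growing geometrically from
0.001 until a Cholesky factorisation succeeds, and inverted; a matrix
that is not positive definite even at full shrinkage (e.g. an
alignment of identical sequences at λ = 0) is a hard "degenerate
alignment" error.

Each off-diagonal 20×20 block of the inverse is reduced to one score:
the L2,1 norm (sum of row norms; the default, matching the
inverse-covariance tool convention) or the Frobenius norm. Because the
(i,j) and (j,i) blocks are transposes, the L2,1 reduction is averaged
over both orientations to make the matrix symmetric.

The **Average Product Correction** removes the product-structured
background (column entropy, phylogeny):
corrected(i,j) = raw(i,j) − mean<sub>i</sub>·mean<sub>j</sub>/mean<sub>all</sub>.
Means run over all non-NA entries, and the scorer passes an NA
diagonal so undefined self-scores stay out of the background; this
makes the correction *exactly* annihilate constant and rank-1
matrices. For concatenated hetero-oligomer MSAs the correction is
computed separately per block-pair region (intra-A, intra-B,
inter-AB): a single global correction would subtract the strong
intrachain background from the weak interchain region and erase it.
This per-region form is our documented interpretation of the
modified APC for hetero-oligomeric alignments. A region with zero mean
is left uncorrected and flagged.

Pre-computed scores are accepted in the PSICOV line format (1-based
`i j _ _ score`; unlisted pairs are "no score" and never count) and
the CCMpred dense-matrix format, so the built-in scorer can be swapped
for the original tools at the same boundary.

## Features

* **AA / AAc** — per-residue-type BSA over all (or core-only)
  interface residues of both sides, normalised by the corresponding
  total; an empty core set yields a flagged all-zero vector rather
  than NaNs.
* **AApair** — contact pairs mapped to unordered pairs of the six
  groups small (A,C,G,P,S,T), negative (D,E), positive (H,K,R),
  aromatic (F,W,Y), hydrophobic (I,L,M,V), other (N,Q): 21 bins.
* **LD** — mean number of other interface atoms (both sides, per-atom
  BSA > 0) within 12 Å of each interface atom.
* **RP** — Σ log propensity over interface residues. The propensity
  table is a config artifact (interface vs surface frequency ratio);
  the shipped default is derived from the synthetic fixture set
  (regenerable via `scripts/regen_propensity.R`, and intentionally
  near-neutral since synthetic residues are uniform); real analyses
  should derive one from their training structures with
  `derive_propensity_table()`.
* **GVI** — gap volume / total BSA (Å). Gap volume is a grid estimate:
  voxels (1 Å default) outside every atom whose nearest-atom distance
  to *each* side is ≤ 5 Å, scanned over the interface bounding box
  padded by that same 5 Å so refinement converges. This is a
  documented stand-in for cavity-surface programs; an externally
  computed volume can be passed to override it.
* **Ncore** — the core-residue count.
* **CS_t** — contact pairs with score > t, after two artifact
  filters: mapped columns ≤ 5 positions apart are discarded, as are
  pairs whose intrachain copies have Cβ–Cβ distance ≤ 8 Å (glycine
  gets a virtual Cβ from ideal N/CA/C geometry). Both filters exist
  because such pairs covary through intrachain packing; they apply
  within a chain block only — cross-block (hetero) pairs have no
  intrachain counterpart, so neither filter can apply there.

## Classifier

F-score ranking uses class sample variances (n−1 denominators) and the
convention F = 0 when both variances vanish; ties break
alphabetically. Feature-count selection evaluates RBF-SVM CV accuracy
over candidate counts and takes the smallest count at the maximal
accuracy. SVM features are standardised with training-fold statistics
stored in the model; constant columns get unit scale. Hyper-parameters
are deliberately light (500 trees; C over {0.1, 1, 10, 100} and γ over
{0.25, 1, 4}/p chosen by internal CV) and are recorded in the model
object together with the seed. Cross-validation is stratified,
deterministic given the seed, accepts a pre-assigned fold vector so
several models can share one partitioning, and re-fits selection and
standardisation inside each training fold — the test fold touches
nothing, which the test suite asserts by corrupting test-fold labels
and hashing the refitted models. MCC uses the standard Matthews
formula (zero when any denominator factor vanishes); AUC is the
Mann–Whitney rank statistic with mid-ranks for ties.

The decision threshold on the classifier score defaults to 0.5 and is
configurable; no calibration is attempted.

## MSA polishing

For families whose oligomeric state is not conserved, distant homologs
act as noise. `polish_alignment()` removes sequences below an
identity-to-query floor one at a time, most distant first, stopping
before the diversity criterion would break (and never touching the
query). One-at-a-time greedy removal was chosen over batch removal as
the conservative reading of the procedure; a floor so aggressive that
even the first removal breaks the criterion returns the input with a
warning. Over-polishing trades noise suppression for diversity loss,
so the floor is a user decision, not a default.

## The synthetic test bed

Toy complexes are two identical extended chains (N, CA, C, O, CB per
residue, random non-glycine identities) facing each other with Cβ
atoms pointing inwards; residue i of one chain faces residue i+offset
of the other at exactly `spacing` Å, and the geometry guarantees that
aligned Cβ pairs are the *only* atoms able to satisfy the interface
definition — the contact map is known by construction. Planted-coupling
alignments sample background columns from random 8-residue
distributions and planted column pairs from a two-state co-assignment
scheme (with probability = coupling strength the two columns take a
jointly chosen state pair), followed by a 5% uniform mutation step.
This is a transparent, fast stand-in for Potts Gibbs sampling —
sufficient to drive inverse-covariance recovery, but it produces
star-shaped (independent-draw) sequence relationships.

The default labelled dataset (20 biological + 20 crystallographic,
L = 60, 1500 sequences, 8-ish contacts at strength 0.9, geometry
distributions identical between classes) therefore demonstrates that
the pipeline's CS channel works end to end and that the cross-validation
is leakage-free, with the classes separable *only* through covariation.
It does **not** demonstrate performance on real crystals: real MSAs
have phylogenetic structure, gaps and paralog contamination; real
interfaces bury side chains, have cores (the flat toys have none), and
their classical features carry signal of their own. Conclusions about
real-data accuracy require the curated benchmark sets and deep MSAs
that are outside this package's scope.

Problem sizes in the test suite (toy chains of 4–12 residues, SASA at
1000–2000 points for oracles, alignments of 120–1500 rows) were chosen
as the smallest sizes at which each property is cleanly measurable.

## Known limitations

* The built-in scorer is the shrinkage inverse-covariance estimator,
  not an L1-penalised (graphical-lasso) or pseudo-likelihood one;
  external PSICOV/CCMpred files provide tool-faithful scores when
  needed.
* Gap volume is a voxel estimate, not a surface reconstruction.
* Ligand- or metal-mediated interfaces, nucleic-acid chains and NMR
  multi-model handling are out of scope.
* The synthetic propensity default is near-neutral; RP only becomes
  informative with a user-derived table.
* `symmetry_mates()` covers the 3×3×3 neighbourhood; pathological
  cells thinner than the contact cutoff would need a wider search.
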