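---
title: "Scoring peptide-HLA similarity for T-cell cross-reactivity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring peptide-HLA similarity for T-cell cross-reactivity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A cytotoxic T-cell recognises its target through the interface between its
receptor (TCR) and a peptide-HLA class I complex (pHLA). A single TCR clone
can recognise several distinct pHLAs — T-cell cross-reactivity — which is
useful against viral variants but dangerous in T-cell-based cancer
immunotherapy, where a therapeutic clone directed at a tumour pHLA may also
strike a similar self-pHLA. Cross-reactivity is driven by pHLA similarity,
and sequence similarity alone does not capture it: the TCR reads a
three-dimensional, biochemically textured surface.

`pepsim` scores the pairwise similarity of pHLAs by fusing peptide sequence
similarity with a structural/biochemical comparison of the TCR-facing
surface patch, then clusters and ranks the complexes. pHLAs that co-cluster
(or rank near a designated target) are predicted cross-reactive.

## Sequence components

For equal-length peptides $a$ and $b$ (all supported datasets use
fixed-length 8–11-mers; mixed lengths are a hard error rather than being
silently aligned or padded):

* **BLOSUM62 sum**: $\sum_p B62(a_p, b_p)$, the classic position-wise
  substitution score (matrix taken from Biostrings).
* **Entropy-weighted PMBEC-style score**: $\sum_p w_p\, M(a_p, b_p)$, with
  per-position weights from the Shannon entropy of each peptide column over
  the whole dataset, $w_p = (\log_2 20 - H_p)/\log_2 20 \in [0,1]$:
  conserved positions count fully, maximally diverse positions not at all.
  This is a monotone, bounded reading of the published "entropy weighting"
  idea; weights are deliberately not normalised to sum to one, and they are
  attached only to this component, not to the BLOSUM62 sum. Users may
  override them (`position_weights`) when TCR-contact positions are known.
* **Hamming distance**: the number of differing positions.

**On the substitution matrix.** The PMBEC matrix (derived from
peptide–MHC binding-energy covariance) is not redistributable here, so the
package ships a clearly labelled *synthetic surrogate*,
`pmbec_surrogate()`: the correlation matrix of BLOSUM62 substitution
profiles. It shares PMBEC's structure (symmetric, unit diagonal, values in
$[-1,1]$, correlation-type residue similarity) but not its exact entries;
`read_substitution_matrix()` drops in the published CSV when exact
reproduction is wanted. Scores built on the surrogate behave the same way
qualitatively; absolute values differ.

## Structural and biochemical component

Each complex is processed as follows (all defaults in Å):

1. **Pre-alignment.** Every complex is superposed onto the first by a
   least-squares (Kabsch) fit of HLA Cα atoms matched by author residue
   numbering (≥ 50 shared residues required). Residue numbers are never
   renumbered, mirroring how structure-modelling pipelines preserve HLA
   numbering.
2. **Surface meshing.** A closed triangulated molecular surface at probe
   radius 1.5. The *internal* backend evaluates a Gaussian atom density
   with probe-inflated van der Waals radii on a regular grid (default
   spacing 0.8) and extracts the unit isosurface by marching tetrahedra —
   each grid cube is split into six tetrahedra around its main diagonal,
   which makes the triangulation watertight without a large case table.
   Cavity shells are dropped, keeping the largest edge-connected surface.
   The *external* backend wraps an MSMS binary (density 3.0, probe 1.5)
   when one is available; the probe-rolled internal surface approximates
   the same solvent-excluded surface.
3. **Downsampling** to 1.0 by vertex clustering on a cubic grid anchored
   at absolute coordinates. Cluster centroids stay inside their (convex)
   cells, so the operation is idempotent; connectivity can only merge,
   never split.
4. **Annotation.** Each vertex carries
   (a) the Kyte-Doolittle hydrophobicity of the residue owning its nearest
   heavy atom;
   (b) an electrostatic potential — by default a screened Coulomb sum over
   a fixed formal-charge scheme (Asp/Glu −1, Lys/Arg +1, His +0.1,
   termini ±1, distributed over the charged-group heavy atoms; Debye
   length 8, protein dielectric 4), clipped to ±30 kT/e so that
   near-singular values cannot dominate the 6D distance; an APBS OpenDX
   grid can be supplied instead and is trilinearly interpolated. The
   built-in scheme is a documented stand-in for a full Poisson–Boltzmann
   calculation, not a reproduction of one;
   (c) a hydrogen-bond potential in $[-1, +1]$ (+1 donor-like, −1
   acceptor-like): a Gaussian of heavy-atom distance about 2.9 (σ = 1.0)
   times the cosine of the deviation from the polar group's outward axis,
   zero beyond 3.5, the dominant site winning. This simplified
   orientation-dependent form preserves the sign and range semantics of
   the MaSIF-style potential it abstracts; donor sites are the polar
   heavy atoms themselves, standing in for idealised hydrogens.
5. **Patch extraction.** The TCR-facing region is the circular patch
   around the surface vertex nearest the peptide's centre of mass
   (mass-weighted over heavy atoms; lowest index on ties): every vertex
   within 16 edge hops on the triangle graph (hops, not Euclidean length),
   extracted from the downsampled mesh. The patch becomes an annotated
   point cloud.

### ICP and the D2 score

Patch clouds $S$ (source) and $T$ (target) are registered by iterative
closest point using geometry only:

1. correspondences $C$: each source point's nearest target point, kept if
   within $\epsilon = 2$;
2. the Kabsch transform minimising
   $D = \sum_{(i,j) \in C} \lVert S_i - T_j \rVert^2$;
3. apply, repeat until $|\Delta D| < 10^{-6}$ or 30 iterations.

Two numerical choices matter. First, if no pair lies within $\epsilon$ at
the initial pose, the pair is flagged *non-overlapping* (score sentinel
$\infty$, later replaced by 10× the largest finite cell) instead of
raising — one pathological pair must not abort an $n \times n$ matrix.
Second, when there is initial overlap, registration starts from centroid
alignment with the correspondence gate annealed from the cloud diameter
down to $\epsilon$ (halved per iteration) — the standard coarse-to-fine
remedy that widens the convergence basin for rotations up to ~30° while
leaving the final correspondence set, taken at $\epsilon$ under the final
pose, exactly as defined above. Both behaviours sit behind
`icp_config(coarse_init = )`.

The similarity score extends $D$ to six dimensions — coordinates plus the
three features —

$$D2 = \frac{\sum_{(i,j) \in C} \lVert S_i - T_j \rVert_6^2}{|C|},$$

dividing by $|C|$ so that poorly overlapping registrations (small
corresponding sets) are penalised. Feature columns are z-scored across the
whole dataset before entering the 6D distance (switchable to `"none"`);
without scaling, kT/e-scale electrostatics would dominate Å-scale
geometry. The pairwise matrix symmetrises the directional score as the
mean of $s \to t$ and $t \to s$, since fusion and clustering need a
symmetric matrix.

## Fusion and evaluation

Each component matrix is z-normalised over all $n^2$ cells (diagonal
included, population SD — the literal reading of "the mean of the
matrix"), then summed element-wise with optional per-component weights
(default 1). Similarity-oriented components (BLOSUM62, PMBEC-style) are
negated first so the fused score is consistently *low = similar*; that is
the only orientation under which the published ranking and dendrogram
semantics make sense.

Downstream, the fused matrix feeds:

* **Agglomerative clustering** (`stats::hclust`, Ward or average linkage),
  either cut into 2 clusters (cross-reactive vs not) or kept as a full
  dendrogram exported as Newick with merge heights. hclust and NMDS need
  non-negative dissimilarities, so the z-scored fused matrix is shifted by
  its minimum off-diagonal value (only when negative; diagonal forced to
  0) — a constant shift that preserves the ranking structure.
* **Confusion metrics**: sensitivity $= 100\,TP/(TP+FN)$ and specificity
  $= 100\,TN/(TN+FP)$ to two decimals. A 2-clustering does not label which
  cluster is "cross-reactive", so both assignments are evaluated and the
  one maximising $TP + TN$ is reported.
* **Leave-one-out KNN** for $k = 1..8$: majority vote of the $k$ nearest
  neighbours (self excluded); split votes at even $k$ resolve to the
  nearest neighbour's label (deterministic and standard).
* **Target ranking**: ascending fused score against the target, ties
  broken lexicographically by id.
* **NMDS** (vegan::metaMDS, 2D) for visualisation, deterministic under the
  supplied seed.

All nearest-neighbour searches use a deterministic brute-force kernel
(ties to the lowest index), so the entire pipeline is bit-reproducible for
fixed inputs and seeds.

## What the synthetic generators emulate — and what they do not

`make_synthetic_phla()` builds a toy pHLA: a rigid 160-residue "groove"
scaffold (floor plus two walls, all alanine, byte-identical across
peptides and seeds, mirroring a fixed HLA allele per dataset) with the
peptide laid in extended conformation inside the groove, side-chain
pseudo-atoms named and counted per residue, and seed-controlled jitter on
side-chain placement only. `make_synthetic_dataset()` assembles a
cross-reactivity study in miniature: a family of single conservative
substitutions of one 9-mer (the "recognised by one clone" group) against
random decoys. `make_synthetic_cloud_pair()` produces annotated point
clouds related by a known rigid transform for registration ground truth.

These fixtures validate the machinery — chain-role resolution, meshing
topology, feature assignment, registration, fusion, clustering — but they
are not real structures: the scaffold has no secondary-structure geometry,
side chains are stylised, decoys are random rather than
binding-motif-matched, and protonation/conformational variability is
absent. Passing on them shows the pipeline computes what it claims, not
that real modelled datasets will reach any particular accuracy; for that,
the reproduction kit under `inst/extdata/reproduction/` documents the
exact per-dataset parameters to rerun the published evaluations once
modelled structures are supplied.

## Problem sizes and defaults

The test-suite and acceptance runs use 8–10 synthetic complexes (grid
spacing 0.8–1.0, ≈ 1000–1500-point patches) and 50 registration pairs of
100 points — sizes chosen so a complete check runs in minutes on one core
while still exercising every code path at realistic patch resolution. A
practical upper bound for real studies is a few hundred complexes, with
surface meshing (seconds per complex) dominating.

## Known limitations

* The bundled substitution matrix is a surrogate, not the published PMBEC
  table (see above).
* The Coulomb electrostatics backend is a screened point-charge model with
  a fixed protonation scheme; pKa shifts, β2-microglobulin context and
  solvent structure are out of scope (an APBS grid can be supplied).
* Peptides must be equal length within a dataset.
* Only one HLA chain is assigned per complex; extra chains are tolerated
  but ignored in pre-alignment.
* The method is TCR-independent by design: it predicts similarity-driven
  cross-reactivity likelihood, and a specific clone's actual behaviour can
  differ.
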