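---
title: "Hydrated dinucleotide building blocks: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrated dinucleotide building blocks: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnahydro)
```

## The model

`dnahydro` treats first-shell DNA hydration as a property of the
dinucleotide step, jointly conditioned on conformation and sequence. A step
is two covalently linked nucleotides (O3′–P linkage); its conformation is
summarized by a dinucleotide conformer (NtC) class label and its sequence
by two letters, so the modeling unit is one of 96 × 16 = 1536
conformer/sequence combinations.

The statistical object attached to each combination is an empirical water
distribution: every water O atom observed within d_assoc = 4.0 Å of a step
of that combination, rigidly transferred into the frame of a single
reference dinucleotide. The transfer uses the six step atoms nearest the
water — a deliberately *local* frame, so that a water sitting in, say, the
phosphate cone is mapped by the phosphate geometry rather than by a global
fit that would smear it whenever the two step conformations differ slightly
in an unrelated region. The superposition is a proper-rotation Kabsch fit;
transfers whose six-atom r.m.s.d. exceeds 0.75 Å are discarded, because a
distorted local frame contributes a systematically misplaced water rather
than noise (the corpus gives no quality gate of its own, so this threshold
is this package's choice, exposed as `transfer_max_rmsd`).

Transferred ensembles are converted to continuous probability densities
separately for base-associated and backbone-associated waters (category
membership tested independently at d_calc = 3.4 Å against the base and the
sugar-phosphate atom sets; a water can carry both flags and then
contributes to both densities). The split reflects the empirical fact that
base hydration is much more ordered than phosphate hydration; pooling them
would let the diffuse backbone signal wash out base peaks. The atom
partition is by covalent identity — C1′ and O4′ count as sugar even though
O4′ participates in minor-groove bridges — because a name-based partition
is deterministic and matches the sugar-phosphate/base nomenclature.

Hydration sites are local maxima of the density; the occupancy of a site is
the summed weight of waters within 1 Å (boundary inclusive) divided by the
number of contributing dinucleotides, i.e. the expected number of waters a
single step contributes at that site. Occupancies above 1 can occur when
two dense clusters merge; they are reported with a warning rather than
clamped, since clamping would hide the merge.

## From Fourier averaging to kernel densities

The original formulation of this analysis computed water probability
densities crystallographically: pseudo-structure-factors from the water
ensemble, followed by map synthesis and a peak search. The contract of that
procedure is "a band-limited smooth density whose maxima are the preferred
water positions". This package implements the same contract directly: each
water adds a normalized isotropic Gaussian (σ = 0.4 Å, truncated at 4σ)
on a Cartesian grid (0.2 Å spacing), with σ playing the role of the
pseudo-atom form-factor width. A kernel sum is linear in the input ensemble
and exactly reproducible, and it avoids carrying a crystallographic
toolchain for what is, mathematically, smoothing. Grid margins default to
4.0 Å around the fragment so every associated water's kernel is covered.

Peak detection: strict 26-neighborhood local maxima above a threshold,
refined to sub-voxel positions by per-axis quadratic interpolation, then
greedily merged under a 1.0 Å minimum separation (highest peak wins). The
default threshold is expressed in occupancy-equivalent units — the central
density of a point cluster of total weight `w_min × n_steps`, with
`w_min = 0.05` — so the same setting transfers between a block built from
40 steps and one built from 4000. These defaults were calibrated once on
the synthetic recovery tests (four sites, occupancies 0.9–0.2, 0.25 Å
jitter) and are exposed in `density_params()`.

## Corpus curation

Chains enter the corpus only if they have at least 6 nucleotides,
resolution ≤ 2.6 Å (boundary inclusive) and more than 1.0 observed waters
per nucleotide (boundary exclusive), where the water count includes
symmetry-related copies within 3.4 Å of any chain heavy atom — surface
waters of a packed crystal often "belong" to a neighboring copy. Sequence
redundancy is removed by single-linkage clustering: equal-length sequences
join when their Hamming distance is within the allowance (2 mismatches
below 24 nt; `floor(N_nuc/12)` above, which is continuous with the short
rule at 24 nt — the exact long-sequence formula used originally is not
recoverable, so the continuous extension is this package's choice, and it
is configurable). Unequal lengths are compared by the best ungapped sliding
alignment of the shorter within the longer, with the allowance taken from
the shorter length; this is a deliberately cheap, deterministic
approximation of "same or similar sequence". Reverse complements are *not*
folded together. Within a cluster the best-resolution chain wins, with ties
inside a 0.1 Å window decided by water content and any residue by
lexicographic (structure, chain) order, so curation is order-independent.

## Classification is pluggable

The geometric definition of the 96 NtC classes lives in an external
classifier and is out of scope here. The package consumes either (a) an
assignment table keyed by (structure, chain, first residue) produced by
such a classifier, or (b) a nearest-centroid approximation over the nine
step torsions (δ, ε, ζ of the first nucleotide; α, β, γ, δ of the second;
both glycosidic χ), using per-angle wrapped differences and a 60°
rejection radius beyond which a step is NANT. The approximation is clearly
labeled as such; block building and prediction only need labels, so any
better classifier slots in via the table interface.

## Prediction-time weighting

When blocks are overlaid on a target structure, every transferred water
gets weight 1/n_steps of its block. Two consequences are intended. First,
combinations observed in thousands of corpus steps do not outweigh rare
ones — each *step* of the target contributes total weight equal to its
block's waters-per-step ratio, a bounded quantity (6–10 in practice).
Second, occupancy becomes divisor-free at prediction time (divisor 1), so
block-level and prediction-level occupancies are commensurable. Weight is
conserved exactly: the total weight entering the grids equals the sum of
n_waters/n_steps over the steps actually used, which the test suite checks
to machine precision. Steps classified NANT, and steps whose combination
is missing or below the ~800-water reliability limit, are skipped and
logged (`allow_unreliable = TRUE` overrides the reliability skip).

## The synthetic generator: what it does and does not show

`make_corpus()` emulates exactly the statistical structure the method
relies on: a set of crystallographically independent observations of one
conformer/sequence combination (rigid scatter with optional coordinate
noise), hydrated at fixed sites with Bernoulli presence (planted
occupancy) and isotropic positional jitter (0.25 Å by default, the scale
of coordinate uncertainty in good crystal structures), plus an optional P1
crystal context for the symmetry machinery. Its defaults — 4 sites at
occupancies 0.9/0.6/0.4/0.2, sites anchored 2.8 Å from polar atoms, two
per category — are the study conditions for the recovery tests, sized so
each category grid carries well-separated (> 8 Å) single-category sites.

Passing those tests demonstrates that association, transfer, density,
peak-finding, occupancy and overlay are numerically correct and
self-consistent. It does *not* demonstrate hydration realism: real water
ensembles have anisotropic spreads, correlated occupancies, partial
disorder, and category-ambiguous positions, and real corpora mix
conformers within a chain. Results on real structures therefore depend on
corpus quality in a way these fixtures cannot probe.

## Numerical choices and degenerate inputs

* Superpositions require ≥ 3 non-collinear pairs; reflections are always
  rejected (determinant +1 enforced), and degenerate sets raise an error
  rather than returning a spurious fit.
* Altlocs: the highest-occupancy alternate location wins, ties by altloc
  letter. Hydrogens (H and D) are parsed but excluded from every distance
  computation. Deuterated water (DOD) is water; zero-occupancy waters are
  kept and logged rather than filtered.
* Reference selection: with an external class representative, the step
  with the lowest superposed r.m.s.d. wins (ties within 1e-4 Å by input
  order); without one, the medoid by summed pairwise r.m.s.d. — the
  corpus-internal analogue of "closest to the class representative".
* Six-atom selection ties break by (distance, residue position, atom
  name); missing counterpart atoms drop the water with a log entry rather
  than substituting a different frame.
* Multi-model files expose model 1 by default (selectable); symmetry
  expansion requires cell + operators and otherwise raises an explicit
  no-symmetry condition so the caller decides between ASU-only and abort.
* Peak refinement clamps the quadratic offset to half a voxel; thin grids
  (< 3 voxels on an axis) fall back to the global maximum.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
corpora: 100 structures for the recovery studies, 40 for the unit-level
pipeline, grids of roughly 100³ voxels at 0.2 Å spacing. These sizes were
chosen because the statistical errors they imply (binomial occupancy noise
≈ 0.03–0.05, mean-position noise ≈ 0.06 Å) sit comfortably inside the
recovery tolerances (0.1 occupancy, 0.3 Å); larger corpora only shrink
them.

## Known limitations

* Second-shell water is invisible by construction: the 3.4 Å category
  cutoff means spine-of-hydration second layers cannot be predicted.
* No ions, no anisotropic kernels, no per-water B-factor modeling.
* The nearest-centroid classifier is an admitted approximation of the real
  NtC assignment; for production corpora use external assignment tables.
* The mmCIF reader covers the coordinate subset (atom_site, cell,
  symmetry); it is not a general CIF parser. The PDB writer emits the
  subset needed for corpora, references and hydration-site files.
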