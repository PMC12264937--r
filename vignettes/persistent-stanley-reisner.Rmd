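---
title: "Persistent Stanley-Reisner theory: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent Stanley-Reisner theory: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psrt)
```

This vignette records the model underlying `psrt`, the conventions and
numerical choices it commits to, and the limits of what its synthetic
validation shows. It is the place to look when a default looks arbitrary:
every one of them is argued here.

## The algebraic model

A finite simplicial complex $\Delta$ on vertices $x_1,\dots,x_n$ determines
the Stanley-Reisner ideal $I(\Delta)$, generated by the squarefree
monomials of non-faces, and the face ring $k[\Delta] = S/I(\Delta)$ over
$S = k[x_1,\dots,x_n]$. Three families of invariants of $k[\Delta]$ are
computed:

**Facet ideals.** Each facet $\sigma$ contributes the prime ideal
$P_\sigma = (x_i : x_i \notin \sigma)$, and $I(\Delta)$ is the intersection
of these. `check_primary_decomposition()` verifies the identity by
enumerating all squarefree monomials; it is a theorem, so the check is a
self-test of the face bookkeeping, guarded to 20 vertices because the
enumeration is exponential.

**Graded Betti numbers.** Rather than computing minimal free resolutions,
`psrt` uses Hochster's combinatorial formula: $\beta_{i,i+j}$ is the sum of
$\dim \tilde H_{j-1}(\Delta_W; k)$ over vertex subsets $W$ of size $i+j$,
where $\Delta_W$ is the induced subcomplex. Reduced homology ranks come
from boundary-matrix ranks, with the augmentation map included in degree
zero. Resolutions, Tor modules and Gröbner machinery are deliberately out
of scope: everything the featurization needs is reachable through
Hochster's formula.

**f- and h-vectors.** Face counts $f_i$, the transform
$h_j=\sum_i(-1)^{j-i}\binom{d-i}{j-i}f_{i-1}$ (with $f_{-1}=1$ for the
empty face, which is honored in formulas but never stored), its inverse,
and the Hilbert function of $k[\Delta]$. The Hilbert function is computed
by direct monomial counting — the degree-$t$ dimension is
$\sum_{F}\binom{t-1}{|F|-1}$ over faces $F$ — precisely so it can serve as
an independent oracle for the rational form
$H_\Delta(s) = (h_0+\dots+h_d s^d)/(1-s)^d$ in the tests.

## Persistence

A monotone function $g$ on $\Delta$ ($\tau \subseteq \sigma \Rightarrow
g(\tau)\le g(\sigma)$) induces snapshots
$\Delta^r = \{\sigma : g(\sigma) \le r\}$. Two persistent constructions are
implemented.

**Persistent graded Betti numbers.**
$\beta_{i,i+j}^{r,r'}$ sums, over subsets $W$ of size $i+j$, the rank of
the map $\tilde H_{j-1}(\Delta_W^r) \to \tilde H_{j-1}(\Delta_W^{r'})$
induced by inclusion. The rank is computed as
$\mathrm{rank}[B \mid Z] - \mathrm{rank}\,B$ where $Z$ is the cycle space
at the earlier scale and $B$ the boundary space at the later one, both in
the later chain basis. At $r=r'$ this collapses to Hochster's formula, and
the test suite checks that collapse against an independent implementation
of the static formula on randomized filtrations. Persistent h- and
f-vectors follow by the binomial transform
$h_m^{r,r'}=\sum_j\binom{n-d+m-j-1}{m-j}\sum_i(-1)^i\beta_{i,j}^{r,r'}$
(second Betti index read as total degree, $\beta_{0,0}=1$) and
$f_{m-1}^{r,r'}=\sum_i\binom{d-i}{m-i}h_i^{r,r'}$.

Three conventions deserve note, because the formulas do not fix them:

- $d$ is taken from the snapshot at $r'$ (the later complex). This is
  validated by the coincidence property: at $r=r'$ the persistent f-vector
  must equal the classical f-vector of the snapshot, which the test suite
  asserts on randomized filtrations.
- The binomial convention is $\binom{a}{0}=1$ for every $a$ (including
  $a=-1$, which occurs when $n=d$) and $\binom{a}{b}=0$ for $b>a\ge 0$;
  without it the $h$-transform is ill-defined for cone-like complexes.
- Ranks are computed over $GF(p)$ with $p = 67{,}108{,}859$, a prime small
  enough that modular products stay exact in double precision. The
  generic-field results coincide with rational arithmetic unless the
  complex has $p$-torsion, which cannot occur at the guarded sizes
  (torsion primes of complexes on $\le 12$ vertices are tiny). The known
  homology of standard complexes (spheres, cycles) pins this down in the
  unit tests.

**Facet persistence barcodes.** The facet ideal $P_\sigma$ belongs to the
decomposition of $I(\Delta^r)$ exactly while $\sigma$ is a facet, i.e. from
$b = g(\sigma)$ until $d = \min\{g(\tau): \tau$ a cofacet$\}$. A bar is
emitted only when $d > b$: because snapshot membership uses the closed
threshold $g(\sigma)\le r$, a simplex covered at its own entry value is
never a facet of any snapshot — in an equilateral triangle the edges and
the 2-face share one diameter value, so no edge bar exists. With floating
point inputs, ties of this kind are exact only when the tied distances are
bitwise equal; the tests therefore treat bars shorter than $10^{-9}$ as
ties, while the library itself never rounds. The facet persistence Betti
number $\beta_i^{r,r'}$ counts bars with $b \le r$ and $d > r'$, which the
suite verifies against brute-force intersection of the snapshot facet
sets. Deaths beyond the filtration cap are $+\infty$ (serialized `inf`).

Cofacet visibility drives one precondition: a barcode up to dimension $q$
requires the filtration to be complete through dimension $q+1$, since a
missing cofacet layer would silently inflate deaths. `rips_filtration()`
takes `max_dim` accordingly — 2 for the featurizer (facet statistics for
vertices and edges), 3 for the C60 demonstration so triangle facets are
themselves correctly killed. The Rips value of a simplex is its diameter
(maximum pairwise distance), vertices enter at 0, and simplex inclusion is
closed ($g(\sigma)\le r$).

## From structures to features

`pocket_atoms()` keeps ligand atoms, protein atoms within 12 Å of any
ligand atom, and metal atoms within 15 Å (closed comparisons, atom-atom
minimum distance — the cutoff definition is a package choice; a
centroid-based reading would shrink pockets of elongated ligands).
Proteins are typed on the {C,N,O,S} alphabet (hydrogens and exotic protein
elements are excluded); ligands on {C,N,O,S,P,F,Cl,Br,I,H}; metals on
{Zn,Mg,Mn,Ca,Na,Fe,Ni} — copper is deliberately absent, being too rare in
metalloprotein pockets to support stable statistics. Waters are dropped
entirely, alternate locations keep their first occurrence, and PDB
elements fall back from columns 77-78 to the atom-name initial.

The element-specific scheme crosses the protein and ligand alphabets
(4×10 = 40 pairs; metals add 7×4 = 28 and 7×10 = 70 for 138); the
category-specific scheme retypes only the protein side by residue class
(hydrophobic, uncharged, negatively/positively charged — 9/6/2/3 of the 20
standard residues), leaving ligand and metal sides element-typed so the
counts are preserved. For each pair, two filtered complexes are built on
the two atom groups: the Vietoris-Rips complex of the pooled cloud and the
bipartite complex whose edges only cross between the groups. Emitting both
is a deliberate redundancy: the pooled complex sees within-group structure,
the bipartite complex isolates the interaction, and concatenating them
lets the learner choose. Per grid scale $r$ the features are
$\beta_0^{r,r}, \beta_1^{r,r}, \beta_0^{r,r}/r, \beta_1^{r,r}/r$ — facet
statistics for 0- and 1-simplices only, since higher facets are both rare
and expensive at pocket scale. Protein-ligand pairs use the 23-point
1-12 Å grid; metal-involving pairs the 29-point 1-15 Å grid, mirroring
the collection cutoffs. The resulting vectors have fixed length per scheme
(7,360 without metals; 30,096 with), with absent groups contributing zero
blocks at fixed offsets.

For pocket-scale inputs the featurizer computes facet bars directly from
the distance matrix — a vertex dies at its nearest-neighbor distance, an
edge dies when some third point is within the scale of both endpoints —
instead of materializing all triangles of a 12-15 Å Rips complex. A
dedicated test pins this fast path to the generic
`facet_barcode(rips_filtration(...))` route on random clouds.

## The regression head

The gradient-boosted regressor is fit with `xgboost`, mapped from the
reference configuration as: trees → `nrounds` (20,000 by default; 30,000
is the convention for external sequence-embedding descriptors), learning
rate → `eta` = 0.002, depth 7, subsample 0.8, square-root feature sampling
→ `colsample_bynode` $=\sqrt p/p$, minimum split size 5 →
`min_child_weight` = 5 (for squared-error loss the hessian sum is the leaf
count; this is the closest analogue, though it constrains children where
the reference constrains parents). `base_score` is the training-label mean,
so constant labels reproduce exactly. Twenty repetitions with seeds
`seed + 0..19` are averaged inside `train_predict()`; `consensus()`
averages across models (element-specific, category-specific, external
embeddings) — the two-level averaging is kept separate because they answer
different questions (seed variance vs. descriptor complementarity).
`nthread = 1` everywhere keeps results bit-reproducible.

The `reduced = TRUE` preset (200 trees, 2 repetitions, learning rate 0.05)
exists for examples and tests; 200 trees at the production rate of 0.002
would leave the ensemble deliberately under-trained, so the rate is raised
to keep the preset a meaningful, if coarse, model.

## What the synthetic data shows — and what it does not

`make_c60()` builds the fullerene by truncating a regular icosahedron with
edge $a = 2s + d$ and cut fraction $t = s/a$: pentagon edges then have
length exactly $s$ and hexagon-hexagon segments exactly $d$, so the barcode
assertions test the persistence machinery, not coordinate transcription.
The hexagon second-neighbor distance follows from the law of cosines on
adjacent sides $s, d$ at 120°, $\approx 2.443$ Å at the default bond
lengths, and the pentagon diagonal is $\varphi s \approx 2.351$ Å.

`make_synthetic_pocket()` emulates the geometry of a binding pocket —
ligand atoms in a 5 Å ball (first atom pinned at the origin so every
generated atom respects the collection cutoffs), protein atoms in a
3-11.9 Å shell with roughly physiological element frequencies, residues
uniform over the 20 standard codes, optionally one metal with
frequencies that follow typical metalloprotein abundances (zinc first). It
does **not** emulate covalent geometry, secondary structure, residue-level
atom grouping, or realistic element correlations; passing tests show the
featurization pipeline is correct and stable under permutation and rigid
motion, not that the descriptors are predictive for real proteins. The
benchmark-scale claims on PDBbind-class data are an external-data workflow
(see the README) and are intentionally untested here.

`make_regression_dataset()` labels seeded pockets with a sparse linear
signal: the 12 highest-variance feature columns, unit-variance scaled,
with signed uniform weights, plus Gaussian noise (σ = 0.5 by default; the
σ = 0 variant is used for recovery checks). The recovery tests show that
the noiseless signal is fully recoverable — a lasso fit on the features
exceeds 0.95 held-out correlation — and that permuted labels yield
correlations indistinguishable from noise. The reduced 200-tree boosting
preset itself plateaus below the lasso on this task even though it fits
the training set essentially perfectly: depth-limited piecewise-constant
trees generalize poorly at the pocket-size extremes of smooth count
features with only 150 training samples. That gap is a property of the
model family at desk scale, not of the featurization.

## Degenerate inputs and tie-breaking

Empty point clouds are legal throughout the featurizer (zero or
side-count statistics, fixed offsets); a complex, by contrast, is never
empty (`make_complex_from_facets` rejects empty input, and every vertex is
a face). Simplices are stored as sorted integer vectors with vertices
mapped to sorted-label order at construction; filtrations sort by (value,
dimension, lexicographic vertices), which fixes iteration order wherever
distance ties occur. Distances are never rounded inside the library;
tolerances appear only in tests and in the C60 bond-classification helper
(10⁻³ Å). Brute-force guards (20 vertices for enumeration-based checks, 12
for subset sums in persistent graded Betti numbers) fail loudly rather
than silently truncating: these operations are oracles and demonstrations,
and the guarded sizes are where exhaustive verification is still cheap.

## Known limitations

- Persistent graded Betti numbers enumerate all $\binom{n}{i+j}$ subsets;
  they are exact but exponential, and intended for complexes of at most a
  dozen vertices. The featurizer never calls them.
- The bipartite construction stops at edges by definition, so its
  dimension-1 facet statistics count cross-contacts; it has no analogue of
  triangle covering.
- `read_protein_pdb` parses the fixed-column single-model dialect; it does
  not expand biological assemblies, perceive bonds, or protonate.
- The regression head models a single feature matrix; cross-validation
  scaffolding beyond a deterministic split utility, feature selection and
  hyperparameter search are out of scope.
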