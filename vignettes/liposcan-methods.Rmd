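---
title: "Detecting lipid-binding pockets: models, parameters, and design notes"
author: "liposcan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lipid-binding pockets: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liposcan)
```

`liposcan` turns a protein structure into a ranked list of candidate
lipid-binding pockets, and a proteome of predicted models into a ranked
list of candidate lipid-binding proteins. This vignette is the package's
own account of the science behind each stage: the geometric model, the
descriptor definitions, the classification protocol, the numerical
choices, and what the synthetic fixtures do and do not demonstrate.

## 1. The geometric model: alpha spheres

A pocket is a region of a protein surface that can cradle a ligand. The
package delineates such regions with *alpha spheres*: a sphere tangent
to four heavy atoms with no heavy atom strictly inside. Spheres of small
radius sit wedged in the packed interior; spheres of very large radius
belong to bulk solvent; spheres in an intermediate radius window
(default 3.0–6.0 Å) trace clefts and cavities. Both window edges are
configurable (`computeAlphaSpheres(rMin, rMax)`).

Enumeration works directly from the defining property. For every
quadruple of heavy atoms that are pairwise within `2 * rMax` of each
other (a necessary condition for a circumsphere of radius at most
`rMax`), the circumsphere is solved from the linear system
`2 (p_j - p_1) . c = |p_j|^2 - |p_1|^2`; quadruples with a near-zero
determinant (coplanar) are skipped. A candidate is kept when its radius
lies inside the window and no other heavy atom lies strictly inside. In
general position a four-point circumsphere is empty precisely when the
tetrahedron is Delaunay, so the output coincides with the
Delaunay-tessellation formulation of alpha-sphere finding; the direct
form needs no tessellation library and is re-verified in the tests
against a brute-force scan over *all* atom quadruples.

Three numerical choices matter here:

* **Emptiness tolerance.** An atom is "inside" a sphere only when its
  center distance is `< radius - 1e-6` Å. Without the tolerance,
  co-spherical atom arrangements (five or more atoms on one sphere, as
  occur in symmetric synthetic structures) would reject valid spheres
  on floating-point noise.
* **Degeneracy.** Fewer than four heavy atoms, or an atom set of rank
  < 3 after centering, is a hard error — there is no meaningful
  tessellation of a plane in 3-D.
* **Heavy atoms only, polymer only.** Hydrogens are dropped at parse
  time everywhere; hetero atoms (ligands, cofactors) are excluded from
  the tessellation so a bound ligand does not fill — and thereby hide —
  its own pocket. The test suite re-verifies emptiness against the
  polymer atom set.

**Clustering.** Sphere centers are grouped by single-linkage clustering
(`stats::hclust`) cut at 1.73 Å, followed by a coarse second pass that
merges clusters whose centroids lie within 4.5 Å — an approximation of
the multi-pass grouping used by established alpha-sphere pocket finders.
Clusters with fewer than `minSpheres` (default 30) spheres are
discarded. Pockets are ranked by sphere count, ties broken by centroid
x, then y, then z, so the ranking is reproducible under atom
permutation. A known failure mode of this family of methods — one
continuous cavity split into two reported pockets — is accepted
behaviour, not corrected.

## 2. The seventeen descriptors

Each pocket is summarised by seventeen physicochemical descriptors
(`descriptorNames()`), the feature space of the classifier:

| group | descriptors |
|---|---|
| size/shape | `pock_vol`, `nb_AS`, `as_dens`, `as_max_dst` |
| surface | `surf_vdw`, `surf_pol_vdw`, `surf_apol_vdw`, `mean_as_solv_acc` |
| hydrophobicity | `hydrophobicity_score`, `mean_loc_hyd_dens`, `apol_as_prop`, `prop_polar_atm`, `n_apol_as` |
| residue scales | `volume_score`, `polarity_score`, `charge_score` |
| dynamics | `flex` |

Definitions and conventions:

* `pock_vol` is a Monte-Carlo estimate of the volume of the union of
  member spheres: uniform samples in the bounding box, hit fraction
  times box volume. The default is 20 000 samples per pocket (relative
  error well under 2 % for pocket-sized unions, verified against the
  closed-form two-sphere union in the tests); `pocketVolumeMC` accepts
  any count of at least 10⁴.
* Surface areas sample points on each contact atom's van der Waals
  sphere and discard points covered by another contact atom; polar
  (N, O) and apolar atoms partition the same estimate, so
  `surf_pol_vdw + surf_apol_vdw = surf_vdw` holds exactly.
* A sphere is **apolar** when at least three of its four defining atoms
  are apolar; an atom is apolar when its element is carbon or sulfur
  (config-overridable). `mean_loc_hyd_dens` is, averaged over apolar
  spheres, the number of apolar spheres whose centers lie within the
  overlap neighbourhood (center distance below the sum of radii); the
  sphere itself is included in its own count — the limiting value for a
  pocket with a single apolar sphere is therefore 1, not 0.
* Residue-scale scores average a per-residue scale over the contact
  residues. Defaults: Monera et al. hydrophobicity at pH 7
  (Kyte–Doolittle available by configuration), Zamyatnin residue
  volumes, Grantham polarity, and formal side-chain charge at pH 7
  (Asp/Glu −1, Lys/Arg +1, His 0). No single convention is canonical
  here; these are the defaults of the alpha-sphere tradition and of
  standard references, and every map is replaceable through
  `defaultResidueScales`.
* `flex` divides the contact residues' mean B-factor by the structure's
  mean B-factor, putting experimental B and predicted-model pLDDT on a
  comparable footing (for predicted models the quantity reuses pLDDT,
  which is a confidence, not a mobility — interpret with care).
* The feature list is usually quoted as seventeen descriptors but only
  sixteen have unambiguous standard names; the seventeenth slot here is
  the count of apolar alpha spheres (`n_apol_as`), the one standard
  alpha-sphere output absent from the sixteen. It is a documented
  choice, not a community convention, and `extra = FALSE` gives the
  sixteen-feature mode.

All stochastic estimates (volume, surfaces, solvent accessibility) are
seeded per pocket from a single configuration seed; descriptor vectors
are bit-reproducible, and coordinate scaling by `k` scales volumes by
`k³`, areas by `k²`, distances by `k` and leaves every fraction and
scale score unchanged (property-tested).

## 3. Corpus curation

Pockets from ligand-bound structures are labeled by proximity: a pocket
matches a ligand when at least one sphere center lies within 3.0 Å of a
ligand heavy atom. "Overlap" between a pocket and a ligand has no
universal definition; 3.0 Å sphere-center-to-atom is this package's
convention, is deliberately conservative (a sphere center inside the
first coordination shell of a ligand atom), and is exposed as
`contactCutoff` — it is the single most consequential free parameter of
the curation stage. A pocket matching several ligands takes the nearest,
with exact ties broken lexicographically by component code.

Lipid-class ligands (cholesterol CLR, myristic acid MYR, palmitic acid
PLM, stearic acid STE, oleic acid OLA) label LBP; four common non-lipid
ligands (adenosine ADN, cobalamin B12, β-D-glucose BGC, coenzyme A COA)
label nLBP; heme (HEM) labels HEME; unmatched pockets are pseudo-pockets
(PP). Supporting filters at curation time:

* **Standalone ligands only**: a ligand with any heavy atom within
  1.9 Å of a polymer heavy atom is treated as covalently attached and
  skipped (the bond-length threshold between typical single-bond and
  van der Waals contact distances).
* **Burial**: a ligand is kept only when at least 10 distinct polymer
  residues have an atom within 8 Å of its center of mass, removing
  surface-smeared lipids. The center of mass is the unweighted
  heavy-atom centroid by default (mass weighting by configuration).
* Heme pockets are excluded from default training — including them does
  not fix the known heme/lipid confusion and the class is kept in the
  schema so the experiment remains reproducible.

The assembled corpus supports pseudo-pocket downsampling to a given
PP:LBP ratio (`subsamplePseudo`; ratio 1 is the balanced corpus,
"full" keeps everything) and stratified train/test splitting with
per-class rounding. Both are seeded and bit-stable.

## 4. Classification protocol

The task is binary: LBP against everything else (nLBP and PP jointly
negative). The default engine is a probability random forest (`ranger`)
with the baseline configuration 100 trees, √p features per split,
unlimited depth, bootstrap resampling — the widely-documented default of
mainstream toolkits, recorded in the model manifest so "default" stays
reproducible. Five further engines (SVM, logistic regression, k-nearest
neighbours, naive Bayes, decision tree) run behind the same interface
for comparison; `compareAlgorithms` evaluates each over repeated
stratified 90:10 splits and reports box-plot summaries (quartiles,
whiskers, outliers beyond 1.5 IQR).

The decision threshold is **inclusive** at 0.5: a pocket scoring exactly
0.5 is called positive. Hyperparameter search supports a random stage
(estimator count and depth drawn log-uniformly, the rest uniformly, over
num_trees 100–1000, max_features 2–4, max_depth 10–100, min_split 2–10,
min_leaf 1–4, bootstrap on/off) and a grid stage over num_trees
{100, 200, 400} × max_features {2, 3, 4} × max_depth {50, 70, 90} ×
min_split {2, 5, 10} × min_leaf {1, 2, 4} × bootstrap {on} — 243
candidates — each scored by 3-fold stratified cross-validated F1.
The sklearn-style names map onto ranger as num.trees, mtry, max.depth,
min.node.size, min.bucket and replace.

Evaluation uses the five formula metrics plus AUROC in its rank-sum
(Mann–Whitney) form — identical to the trapezoidal ROC area with ties
contributing one half — and Cohen's kappa. Metrics with zero
denominators are reported as explicit `undefined` flags, never silent
zeros. PCA of descriptor space standardizes columns first: the features
span Å³ to unitless fractions, and an unstandardized decomposition would
simply recover pocket volume. Feature importance comes in both standard
flavours: mean decrease in impurity (normalized to fractions) and
permutation importance (mean ± sd drop in F1 over seeded shuffles).

## 5. Proteome scanning

Predicted models carry per-residue confidence (pLDDT, 0–100) in the
B-factor column; the per-residue value is read from the CA atom (first
atom as fallback — predicted models write identical values to all atoms
of a residue, so residue-mean and atom-mean coincide and the choice only
matters for unusual inputs). The scan pipeline:

1. **Signal-peptide trimming** (cut sites supplied as a two-column TSV;
   prediction itself is out of scope) — applied *before* the length
   filter, since trimming changes the residue count the filter sees.
2. **Filters**: models with fewer than 100 residues, then models with
   mean pLDDT below 70, are removed; both are strict "less than"
   removals, so a 100-residue or exactly-70.0 model survives.
3. **Scoring**: every pocket of a surviving model is described and
   scored; the protein score is the maximum pocket probability, and a
   protein with no pockets is reported as such rather than scored 0.
4. **Ranking**: proteins at or above the threshold (default 0.5,
   inclusive — configurable) are hits; the summary reports
   `n_hits / n_scored` as a percentage rounded to one decimal with
   round-half-even.

Per-protein rows are independent: scanning any subset in any order
yields identical rows, which is what makes the scan trivially
parallelisable.

## 6. The synthetic fixtures: what they show and what they cannot

The package is testable offline through two generators.

`makeCavityStructure` places single-atom pseudo-residues on a jittered
spherical shell (default 60 atoms, 12 Å radius, Fibonacci lattice plus
uniform jitter), optionally planting a small ligand cluster at the
center. Residue identities are drawn from a lining composition, and each
residue's atom element follows its polarity class so that polarity-aware
descriptors see realistic variation. If jitter causes atom collisions
(closer than 1.5 Å) the layout regenerates with reduced jitter, failing
after ten attempts. One geometric consequence is worth spelling out:
because all shell atoms are nearly co-spherical with the shell, every
atom quadruple's circumsphere approximates the shell sphere itself, so
the fixture's alpha spheres concentrate near the shell radius rather
than in a protein-like 3–6 Å window. Fixture-based tests therefore pass
an explicit window bracketing the shell radius
(`cavityDetectionConfig`), and a small `minSpheres`. This exercises
every geometric contract (enumeration, emptiness, clustering, contacts,
descriptors) without claiming the fixture is a protein.

`makeDescriptorTable` draws class-conditional descriptor vectors from
diagonal-covariance normals truncated to the descriptor invariants. The
default corpus is 200 LBP / 300 nLBP / 4000 PP — a 20:1 PP:LBP imbalance
in the regime where the real curation pipeline operates — and the LBP
class is shifted upward on `hydrophobicity_score` by `separation`
standard deviations (default 3) and on `mean_loc_hyd_dens` by half that.
The half-weight on the second feature is deliberate: with equal shifts
the two informative features would be statistically exchangeable and
"which feature ranks first in importance" would be a coin flip, whereas
the lipid-binding problem is dominated by hydrophobicity — the
generator encodes that domain structure so importance-ranking tests are
well-posed.

What passing tests on this corpus *show*: the pipeline's plumbing is
correct end to end; ranking quality is high when a class is separated by
3 sd on one descriptor; imbalance at 20:1 produces the expected
specificity-over-sensitivity asymmetry; balancing the training set
trades precision for sensitivity on a fixed held-out set; and both
importance procedures recover the planted signal. What they *cannot*
show: anything about real proteins — the generator has no covariance
structure between descriptors, no pocket-geometry realism, and its
separation is planted rather than discovered. Real-data performance
claims require real curated corpora, which are deliberately outside the
test suite.

## 7. Problem sizes and reproducibility

All randomness flows through explicit integer seeds (split, training,
Monte-Carlo estimates, permutation shuffles); derived child seeds stay
below 2³¹. The test suite and the acceptance script run the corpus at
its default size (4 500 rows), algorithm comparisons at 5 repeats on a
reduced corpus, and geometry oracles on 40–60-atom fixtures — sizes
chosen so the whole suite completes in about a minute on one CPU while
still exercising every contract at non-trivial scale. The vignette and
README show outputs the code actually printed at those sizes.

## 8. Known limitations

* Multimer interfaces are not handled; pockets spanning chains of an
  assembly are out of scope, as is assembly expansion.
* Heme binders systematically resemble lipid binders in this descriptor
  space; post-filtering with a dedicated heme predictor is recommended
  and out of scope.
* The descriptor set carries no electrostatics, conservation, or
  per-lipid-class features, so the classifier detects "lipid-like
  pocket", not which lipid.
* A continuous cavity may be reported as two pockets (see §1); scores
  are then per-fragment.
* `flex` on predicted models reflects model confidence, not dynamics.
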