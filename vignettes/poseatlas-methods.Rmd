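---
title: "Methods: pose-ensemble analysis for peptide-GPCR docking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose-ensemble analysis for peptide-GPCR docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poseatlas)
```

## The problem

Exhaustive rigid-body docking of a peptide into a G protein-coupled receptor
cavity yields roughly a thousand candidate placements ("poses") per receptor
model, each a rigid copy of the peptide expressed in the receptor's
coordinate frame, each carrying a refinement score where lower is better.
No single pose can be trusted; the signal lives in the structure of the
ensemble. `poseatlas` measures that structure: which poses are physically
admissible, how they cluster geometrically, where the well-scoring clusters
place the peptide in the cavity, and how the peptide is rotated about its
helical axis. The motivating system is the C-terminal fragment of orexin-A
(residues 16–33, an amidated α-helix whose last turn is critical for
activity) docked into orexin-1-receptor models, but every stage is generic
over a receptor + multi-model pose ensemble + score table.

## Coordinate conventions and the membrane frame

All coordinates are in Ångström. Receptor residues are addressed by
Ballesteros–Weinstein (BW) labels — helix.position strings such as `6.48`,
with the most conserved residue of TM helix *N* numbered *N*.50 — resolved
against a user-supplied annotation table, so nothing depends on author
numbering of a particular model.

Geometry is measured in a **membrane frame** built from the receptor:

* The **zero-plane** passes through the Cα atoms of three deep pocket
  residues (defaults 5.46, 6.48, 7.43). Its unit normal is the z-axis; the
  sign is fixed so the centroid of all receptor Cα atoms lies on the
  negative side, i.e. z grows toward the extracellular mouth. The choice
  makes reported binding depths positive for poses above the pocket floor.
  A `zero_mode = "single"` switch instead anchors z = 0 at one residue's Cα
  (default 6.48) for comparison; the plane definition is the primary one.
* **Depth** of a pose is the z-coordinate of an anchor atom, by default the
  Cα of the C-terminal residue (Leu33 in the orexin fragment).
* **Azimuth** is the angle of the Ala28→His26 Cα vector projected into the
  membrane plane, measured counterclockwise (viewed from the extracellular
  side) from an x-axis that points toward a reference residue, default the
  TM4 anchor 4.50. Because no absolute angle convention exists across
  receptor models, everything downstream (mode sectors) is expressed
  relative to named receptor directions, never absolute degrees. The
  projection's in-plane length is reported alongside: a tilted peptide has a
  short projection and a poorly defined rotational state. Azimuth uses the
  Cα-to-Cα vector, not a side-chain tip, so it is defined for reduced-atom
  models too.
* The frame also carries an **axis center** — the centroid of all receptor
  Cα atoms, a point on the bundle axis — used wherever a radial "distance
  from the middle of the bundle" is needed. This is deliberately distinct
  from the zero-plane origin: the centroid of the 5.46/6.48/7.43 Cαs lies
  ~9 Å off the bundle axis in a 7TM bundle, and using it for radial
  distances would skew the cavity test.

Depth and azimuth are invariant under any rigid motion applied jointly to
receptor and poses (the frame co-rotates); this is asserted to 1e-9 in the
tests.

## RMSD without superposition

Pose similarity is the root-mean-square deviation over the peptide Cα trace
with **no superposition**. Rigid-body docking output shares the receptor
frame, and the analysis is about *placement*: least-squares fitting before
RMSD would declare a pose at the cavity mouth identical to the same pose at
the cavity floor. Consequently RMSD here is only jointly motion-invariant —
moving both poses together changes nothing, moving one pose changes the
value — and the matrix code exploits the identity
RMSD(a,b) = ‖a − b‖/√k for k selected atoms to compute the all-pairs matrix
with one Euclidean `dist()` call.

## Clustering and cluster scores

Clustering is the greedy neighbour-count algorithm used throughout the MD
and docking literature: build the neighbour graph at RMSD strictly below
the cutoff (3 Å default), repeatedly take the pose with the most remaining
neighbours as a seed, remove seed plus neighbours as a cluster, and recount
over the remaining pool until it is empty. Two details are deliberate and
documented because the algorithm is sensitive to them:

* neighbour counts are recomputed over the **remaining** pool each round,
  not frozen from the first pass;
* ties in neighbour count break toward the lowest pose index, making the
  partition deterministic.

Every pose is assigned (singletons allowed); members lie strictly within
the cutoff of their seed. Both properties, and exact agreement with an
independently coded exhaustive re-count oracle over hundreds of random
instances, are asserted in the tests.

Clusters are ranked by the **median** member score (even sizes: mean of the
two central values) — medians resist the heavy left tail of refinement
scores. A classical one-way ANOVA over per-pose scores grouped by cluster
(clusters under 2 scored members excluded) tests whether cluster score
differences exceed noise; the degenerate zero-within-variance case reports
F = ∞ with a note rather than failing. Score-based selections implement
"score of t or lower" as ≤ t, and the top fraction f keeps the best
⌈f·N⌉ scored poses with ties broken by pose id.

## Pose landscape embedding

The all-pairs RMSD matrix is embedded in 2D by metric multidimensional
scaling: Kruskal stress-1 minimized by SMACOF majorization (Guttman
transform) from a classical-scaling (Torgerson) start. The majorization
step never increases stress, iteration stops when the relative stress
decrease drops below 1e-7 (default cap 500 iterations), and the only
randomness — a jitter used if the classical start is fully degenerate — is
seed-controlled (default 1337), so embeddings are reproducible. Metric
scaling was chosen over non-metric because RMSD is a genuine metric here
and preserving its scale keeps axis units interpretable as Ångström-like
distances; a non-metric variant would only relax monotone transforms and is
out of scope.

## Filters

Two admissibility rules emulate the screening applied to raw docking
output:

* **Interface rule** — at least one heavy atom of the peptide's C-terminal
  residues (default: last four, 30–33) within 5.0 Å of any receptor heavy
  atom. The 5 Å heavy-atom cutoff is a conventional interface distance;
  both the residue range and the cutoff are configurable, and the rule is a
  geometric proxy for "part of the receptor–ligand interface", which has no
  unique operationalization.
* **Membrane rule** — no peptide heavy atom inside the membrane slab
  (z ∈ [−15, 15] Å around the zero-plane by default, roughly a bilayer) at
  an in-plane radial distance from the bundle axis beyond the cavity radius
  (13 Å default, an approximate 7TM inner radius). Atoms above the slab are
  extracellular and always allowed; the rule only rejects poses threading
  between or beyond the helices into membrane-occupied space.

Filters are pure per-pose predicates, so they commute and combine by
intersection.

## Contacts and binding modes

A receptor residue and a peptide residue are in contact in a pose when any
pair of their atoms lies strictly closer than 4.0 Å — any atom type, no
main-chain/side-chain distinction, hydrogens included when present (a
heavy-atom-only switch exists). Over a pose group, the contact frequency of
a residue pair is the fraction of poses showing the contact; the map of a
singleton group is its binary map.

High-scoring poses concentrate in two alternative rotational states about
100° apart: the bulky residues near the peptide C-terminus face either TM5
or TM7. Classification is by azimuth sector: ±50° around the azimuths of
per-receptor reference residues (5.39 for TM5, 7.35 for TM7, measured from
the bundle axis), requiring an in-plane projection of at least 1 Å.
Everything else — including poses whose azimuth is undefined because the
peptide is nearly parallel to the membrane normal's plane projection — is
an outlier with the reason recorded. Anchoring sectors on structure-derived
directions rather than absolute degrees keeps the classification meaningful
across receptor models with different frames.

## Solvent-accessible surface area

SASA is computed by Shrake–Rupley point sampling: each atom's van der Waals
sphere is expanded by the probe radius (1.4 Å, water) and covered with a
deterministic golden-spiral point set (960 points per atom by default); the
accessible fraction is the share of points outside every neighbour's
expanded sphere. Radii follow a Naccess-like table (C 1.87, N 1.65, O 1.40,
S 1.85, H 1.00, fallback 1.80 Å). The golden spiral makes the estimate
deterministic — no RNG — and the tests pin it against closed forms: an
isolated sphere to 1% at 960 points, the two-sphere spherical-cap solution
to 1% at 4000 points, and convergence |A(4000) − A(16000)|/A(16000) < 0.5%.

## The synthetic study generator

Because docking pipelines are not reproducible at desk scale, the package
ships a generator whose output has the statistical structure the analysis
assumes; it is first-class, tested code, and its defaults are the study
conditions every end-to-end number in this package refers to.

* **Toy receptor** — seven ideal poly-alanine helices (Cα + Cβ) standing on
  a 12 Å circle. Helices alternate direction through the membrane, as TM
  helices do; each is phased about its own axis so its pocket-facing
  residue points at the cavity, and shifted vertically so its zero-plane
  anchor (5.46/6.48/7.43) sits at z = 0. BW label x.yy maps to residue
  yy − 30 of chain LETTERS[x]. The construction axis and center are stored
  as ground truth; the membrane frame recovers the axis to well under 1°.
* **Peptide** — the 18-mer LYELLHGAGNHAAGILTL (residues 16–33), built as a
  straight ideal α-helix (radius 2.3 Å, rise 1.5 Å, twist 100°/residue)
  with Cβ placeholders on non-glycines. Side chains are truncated at Cβ
  deliberately: the pipeline needs Cα geometry and any-atom contacts, not
  rotamers; the documented cost is that absolute contact distances and SASA
  are those of a thinned peptide.
* **Poses** (default 1000) — each pose draws a planted cluster center (five
  on a 4 Å pentagon by default; configurable as explicit
  dx/dy/depth/azimuth/weight rows), adds isotropic positional jitter with
  RMS magnitude `cluster_spread` (1 Å), draws a rotational mode from a
  two-component wrapped-normal mixture (weights 0.6/0.4, sd 15°) whose
  centers default to the receptor's own TM5/TM7 reference azimuths (~103°
  apart, the alternating-helix geometry's realisation of the ~100° mode
  separation), and a depth from N(6, 2²) Å — matching the median ~6 Å
  depths such analyses report. A fixed fraction (10%) of **decoys** is
  planted outside the cavity radius inside the membrane slab; the membrane
  filter must remove exactly these, and does, across seeds.
* **Scores** — Gaussian noise N(−4, 3²) minus a 6-point bonus for
  mode-consistent poses (within 30° of their mode center) at target depth
  (4–9 Å), giving best scores near −17 and making "top-ranking" selections
  enrich for the planted geometry. Lower is better throughout.

Identical configurations generate bit-identical ensembles (one seed drives
everything). What passing tests on this generator shows: the measurement,
clustering, embedding and classification machinery is correct against
planted ground truth and analytic solutions. What it does not show:
anything about real docking energetics, side-chain packing, receptor
flexibility, or whether a particular receptor model's pose distribution is
right — the generator plants exactly the structure the pipeline is designed
to detect.

## Numerical choices and edge cases

* Strict `<` at the clustering cutoff and the 4 Å contact rule (both
  boundary conventions follow the usual wording "closer than"); `≤` at
  score thresholds ("score of −10 or lower").
* Alternate locations in PDB input collapse to the highest-occupancy
  conformer (ties: first); duplicated atom records warn but are kept;
  malformed fixed-width fields fail with the line number.
* Pose ensembles require identical atom count and ordering across models;
  a mismatch names the offending model. A `REMARK 999 POSE_ID` line lets
  string pose ids survive the multi-model PDB round-trip.
* Degenerate inputs fail loudly: collinear zero-plane residues, an azimuth
  reference projecting onto the origin, empty selections, unscored
  ensembles, overlapping mode sectors.
* Problem sizes in the shipped tests and acceptance script (12-pose oracle
  batches, 500-pose recovery runs, a 1000-pose synthetic study) were chosen
  as the smallest sizes at which the statistical assertions are stable
  across seeds.

## Known limitations

* Cβ-truncated synthetic side chains thin the peptide; synthetic contact
  frequencies are lower than an all-atom peptide would give.
* Metric (not non-metric) MDS only; stress on genuinely high-dimensional
  pose landscapes plateaus around 0.15–0.2, which is expected, not a defect.
* The membrane slab and cavity radius are geometric proxies with
  configurable constants, not a membrane model.
* mmCIF input, bond perception, interaction typing (H-bond/salt-bridge
  classes) and cavity-volume estimation are out of scope.
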