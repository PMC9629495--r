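---
title: "Model preparation, fragment phasing and model-free verification on toy crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model preparation, fragment phasing and model-free verification on toy crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragphase)
```

## The problem

Molecular replacement (MR) borrows phases from a placed search model, so
an MR map tends to reproduce the model whether or not the data support
it — the classical model-bias problem. With deep-learning predictions the
search models have become so good that almost every determination starts
from one, which makes it *more* important, not less, to establish what
the diffraction experiment contributes beyond the model. `fragphase`
implements a workflow that addresses this by *omission*: a placed
solution is cut into spherical fragments, each fragment's phases seed an
expansion (density modification and tracing, abstracted behind a backend
interface), the map region of the **whole** original model is masked so
traces can grow only outside it, and the mutually consistent traces are
combined in reciprocal space. Whatever comes out was never part of the
input model; if an area of the model is wrong, the expansions seeded
there collapse and the area fails verification locally.

Everything runs on synthetic toy crystals so that each stage has a
ground truth: amplitudes are computed exactly from a known structure,
the true phases are retained for scoring, and the external tracing
program is replaced by a synthetic backend with the same contract.

## Model preparation

Predicted models carry per-residue confidence (pLDDT, 0–100) or error
estimates (Å) in the B-factor column. `read_structure()` captures that
column verbatim into a `confidence` field and auto-detects the
convention (values in [0, 100] with median above 40 are treated as
pLDDT; sub-30 values with sub-Å spread as error estimates).
Preparation (`prepare_predicted_model()`) then:

* strips hydrogens **by element** (predictor H atoms sit at distances
  meaningless for X-ray scattering, and name-based removal would delete
  a mercury called `HG`);
* sets B to a common 25 Å² for main-chain atoms (N, CA, C, O, OXT) and
  50 Å² for everything else (CB counts as side chain); in polyalanine
  mode side chains are trimmed past CB and all atoms get 25 Å², so the
  fragment library has equivalent scattering;
* removes unstructured regions **geometrically, never by confidence
  score**. Genuinely correct regions can carry poor prediction scores,
  so the measured data — not the predictor's self-estimate — are left to
  judge correctness. Coil is identified from the annotation below; coil
  segments at chain termini (3 residues or longer) are removed, as are
  internal coil segments of at least 7 residues that make no contact
  (CB within 8 Å) with any annotated element. Short connecting loops
  are kept so the topology is never severed.

## Geometric annotation and domains

Annotation uses *characteristic vectors*: for every overlapping
tripeptide, the vector from the centroid of its three CA atoms to the
centroid of its three carbonyl O atoms (n − 2 vectors per contiguous
segment; segments split at numbering gaps and wherever consecutive CA
atoms are further than 4.5 Å apart). Regular secondary structure shows
up as narrow bands in simple CV statistics. The bands were calibrated
once on ideal generated geometries and frozen in `default_config()`:

| feature | ideal helix | ideal strand | random coil |
|---|---|---|---|
| CV modulus (Å) | 2.26 | 1.60 | 1.5 ± 0.3 |
| angle to next CV (°) | 7 | 45 | 40–70 |
| CA(i)–CA(i+3) (Å) | 5.2 | 10.0 | ~8 |
| angle to next-nearest CV (°) | 9 | 4 | 60–70 |

A CV is helix when its modulus lies in [2.0, 2.6] Å and the angle to
its neighbour is at most 25°; strand when the modulus lies in
[1.2, 2.0] Å, the local CA straightness is at least 9 Å **and** the
period-2 angle is at most 30° (the pleat alternates with period two;
modulus and angle alone cannot separate strand from coil). Residues take
the majority label of their covering CVs and runs shorter than 3
residues are demoted to coil. The classification is purely geometric,
hence exactly invariant under rigid motions.

Domains: secondary-structure elements become nodes of a weighted graph
(weight `exp(-d_min / 8 Å)` from the minimum inter-element CA
distance); greedy modularity optimization (`igraph::cluster_fast_greedy`,
deterministic) yields compact folds. Because modularity always splits a
connected graph — even a single compact bundle — the coarser *domain*
level is built by merging folds whose elements approach within 12 Å,
i.e. connected components of the thresholded fold-quotient graph. Two
bundles 40 Å apart stay separate domains; one four-helix bundle stays
one domain.

## Fragment sizing by expected LLG

Sphere size is chosen so a fragment carries a target expected
log-likelihood gain. With scattering fraction $f_m$ and an assumed
coordinate error $r$ (Luzzati-type damping):

$$\sigma_A(s) = \sqrt{f_m}\,e^{-\frac{8\pi^2}{3} r^2 s^2},
\qquad s = \frac{1}{2d}, \qquad
\mathrm{eLLG} = \sum_{\mathbf h} \tfrac{1}{2}\sigma_A^4 .$$

Defaults: eLLG target 60, fragment rmsd estimate 0.8 Å (0.6 Å after
internal rigid-body refinement), general resolution limit 2.5 Å. When a
template is too small to reach the target, the achieved value is
reported and flagged as lowered. The library places one candidate
sphere per (sub-sampled) CA, drawing the nearest residues only from the
centre's domain, and drops candidates that are disjoint (more than one
component in the 5 Å CA graph) or contain large voids. The void
criterion is the occupied-volume fraction of the bounding sphere (atoms
dilated 2.5 Å, 1 Å grid) with threshold 0.045, calibrated on generated
fragments: compact helical fragments score 0.05–0.06 — elongated shapes
fill little of their bounding sphere, so the usable scale is low — while
fragments containing voids of 14 Å or more score at most 0.035.

## Figures of merit

* **CC on normalized intensities** (`cc_normalized`): 100 × Pearson
  correlation of $E^2_{obs}$ against $E^2_{calc}$, invariant under
  positive affine maps of either argument. E-values come from
  equal-count resolution bins with $\langle E^2\rangle = 1$ per bin.
  Input classification uses 20 bins: on small toy cells, 10 bins leave
  the lowest bin so wide that the residual falloff inside it correlates
  *any* compact model with the data (a randomized model scores 25–40%);
  with 20 bins randomized models fall to 10–20% while a true solution
  still scores ~100%.
* **wMPD / wMPE** (`wmpd`): weighted mean absolute circular phase
  difference folded into [0°, 180°], weights
  $f_{obs}\cdot\min(w_p, w_q)$. Two random sets score ~90°; a solution
  is *nonrandom* when its wMPE against the true phases is strictly
  below 80°.
* **mapCC** (`mapcc`): reciprocal-space map correlation
  $\sum f_1 f_2 \cos\Delta\varphi / \sqrt{\sum f_1^2 \sum f_2^2}$.
* **Input recognition** (`classify_input`): a model is a previously
  placed solution iff it carries a cell card matching the data (0.5%
  on lengths, 0.5° on angles, same space group) *and* its CC exceeds
  25%.

Structure factors are computed by direct summation over symmetry
operators with 4-Gaussian Cromer–Mann form factors (C, N, O, S, H) and
isotropic B; tests verify them against an independent P1-expansion
oracle to 1e-8 relative.

## Phase clustering with origin alignment

Phase sets from independent expansions live on arbitrary allowed
origins. `allowed_origin_shifts()` derives, for each supported space
group, the translations $t$ with $(R - I)t$ integral for every operator
(polar axes, along which any shift is allowed, are detected as the
directions fixed by all rotation parts). Alignment minimizes the wMPD
over the discrete shifts, with a 1/48-step grid plus golden-section
refinement along a single polar axis; when two or more axes are polar
the grid coarsens to 1/12 with two passes of per-axis refinement to
stay tractable. Enantiomorph (hand) flips are *not* searched: the
synthetic backend can never produce the inverted hand, and searching it
would double the cost for a case the toy setting cannot exercise.

Clustering is greedy and seeded in caller priority order (e.g. backend
CC rank): members join a cluster when their aligned wMPD to the seed is
at most 60°. The tolerance sits between genuine-solution differences
(~30–50°) and the random level (~90°). Combination is coherent phasor
averaging; the combined weight is the coherence
$|\sum w e^{i\varphi}|/\sum w$, zero (flagged undefined) where members
cancel. Averaging eight 30°-noise copies of a truth beats the median
member in at least 18 of 20 seeds.

## Verification and multicopy search

`run_verification()` shreds the placed model into equal-sized spheres
centred on CA atoms, selected by greedy set cover so every residue is
in at least one sphere (at most `max_spheres`). The mask covers the
full original model, symmetry-expanded, dilated by 2.5 Å on a grid of
$d_{min}/4$; traces are filtered so no retained atom lies in a masked
voxel — this is asserted programmatically on every run, which is the
model-freedom guarantee. Trace-only phases come from structure factors
of the filtered trace alone. The best cluster of trace phase sets is
combined and handed back to the backend for up to 3 further cycles.
Note a structural property of the omission scheme: a *complete and
perfect* model masks everything, leaving nothing to trace. Verification
is informative exactly when the model is partial or partially wrong —
which is the regime the method targets (search models are smaller than
the structures they phase).

`translation_scan()` scores a rotated fragment on a translation grid by
the CC on normalized intensities (fixed copies added to the calculated
set) and standardizes the scores into a z-score over the scan. The top
distinct peaks (duplicates within 2.5 grid steps collapsed; the exact
polar-axis degeneracy collapsed when nothing is fixed) are refined
off-grid by pattern search — grid-level scoring alone loses 6–10 CC
points to discretization at the true position, enough to mis-rank it on
sharp landscapes. `packing_filter()` rejects placements whose CA atoms
come within 3 Å of a fixed copy or any of its symmetry images
(minimum-image convention).

Multicopy prioritization mirrors the retrospective landscape analysis
that motivated it: when first-copy figures of merit do not separate
correct placements from decoys, a fast second-copy translation search
with each probe fixed re-ranks the probes by the best packing-valid
second-copy score, and only the top few are sent on to expansion. With
more than two expected copies the scan-and-fix loop repeats until all
copies are placed per probe.

## What the synthetic generator emulates — and what it does not

`make_toy_crystal()` packs ideal helices at random orientations into a
cell (rejecting symmetry clashes under 3 Å CA–CA), computes exact
amplitudes and keeps true phases. `perturb_to_predicted()` applies
locally *correlated* noise — per-residue displacements smoothed over a
5-residue window, scaled to the target CA rmsd (0.8 Å by default,
matching the expected accuracy regime of predicted fragments) — because
white noise would make domain-level verification trivially easy; it can
append a disordered coil tail, rigidly displace one chain (the
mis-modelled-domain scenario), fills the B column with a pLDDT-like
score `clip(100 − 40·error, 20, 99)` (used only to test that
preparation ignores it), and drops the cell card. The synthetic backend
expands a starting phase set only if its wMPE is below 75°, returns
truth atoms strictly outside the mask with coverage growing as the
start improves, and returns nothing otherwise — the contract that an
incorrect starting hypothesis impedes expansion.

The toys do not emulate measurement noise, anisotropy, twinning,
solvent scattering or coiled-coil intensity modulation, and all
fragments are helical. Passing tests therefore demonstrate the
correctness of the machinery (symmetry, scoring, alignment, masking,
ranking logic), not the statistical performance to be expected on real
diffraction data.

## Numerical choices and problem sizes

Degenerate inputs: empty models and all-zero weights raise errors;
antipodal phase combinations get zero weight and an explicit flag;
empty normalization bins merge into the global mean; a model smaller
than one sphere becomes a single whole-model fragment; an unsupported
space group names the supported set. Ties break deterministically
(lexicographically smallest origin shift, lowest element index, input
order in clustering).

The test-suite and acceptance problem sizes are chosen so each property
is exercised on the smallest crystal that shows it: 2–3 helices of
12–14 residues in P2~1~ cells of 26–42 Å at 2.5–3.0 Å resolution
(1000–2700 unique reflections), 20 seeds for recovery properties, 10
for verdicts and 5 for the multicopy landscape.

## Worked example

```{r example, eval = FALSE}
toy <- make_toy_crystal(toy_crystal_spec(
  spacegroup = "P21", cell = c(40, 34, 42, 90, 105, 90),
  n_helices = 3, helix_len = 14, seed = 1))
rt <- residue_table(toy$truth)
sol <- subset_residues(toy$truth, rt$key[rt$chain %in% c("A", "B")])
classify_input(sol, toy$refl)
report <- run_verification(sol, toy$refl, synthetic_backend(toy$truth),
                           verify_config(n_res = 10, max_spheres = 8))
report
```

## Known limitations

* The eLLG here is a Luzzati-type surrogate, not a full likelihood; the
  `llg_like` scores are CC-based and share only the ranking role with a
  true LLG.
* The plain Pearson form of the intensity CC is used for the 25% rule;
  the threshold is configurable should a different CC variant be
  plugged in.
* No density modification or real autotracing: the backend interface is
  the seam where a real tracing program would attach.
* Hand inversion is not searched during phase clustering.
* Rotations are enumerated from caller-provided lists; there is no
  rotation function.
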