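---
title: "Modelling myonuclear positioning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling myonuclear positioning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological question

In differentiating myotubes the nuclear envelope (NE) becomes the dominant
microtubule-organizing center: centrosomal proteins (Akap450, Pericentrin,
Pcm1) relocate to the nuclear surface, microtubules (MTs) are nucleated
there, and the motors dynein and kinesin-1 (Kif5b) are anchored there via
the Nesprin-1α/LINC complex. `myospread` asks, in silico, what this
organization does for the *positioning* of the many nuclei that share one
myotube: when nuclei nucleate their own MTs and carry motors, do they
disperse evenly along the cell axis, and what happens when nucleation is
relocated to cytoplasmic centrosome-like bodies, with or without NE
kinesin?

The package has three parts: an agent-based Langevin simulator of the
myotube (compiled C++ core), the nuclear spreading-factor (SF) statistic
with rank-sum condition comparisons, and a BioID/TMT proximity-labeling
quantitation pipeline with seeded synthetic-data generators for both data
types.

## The mechanical model

**Geometry.** A myotube is a 2D ellipse of full width 14 um whose length is
19 um per nucleus (95 x 14 um for five nuclei up to 171 x 14 um for nine;
other counts extrapolate the same rule). The choice of 2D matches the
planar geometries the model is defined on; it is also the main reason some
interactions need care (see *Nucleation directions* below).

**Bodies.** Nuclei (radius 4 um) and, in the relocated-nucleation
conditions, centrosome-like bodies (radius 0.5 um) are rigid discs that
translate without rotating. Drag is Stokes-like, gamma = 6 pi eta R, with a
homogeneous cytoplasmic viscosity eta = 1 pN s/um^2. Thermal noise uses
kT = 0.0042 pN um. All objects are confined by a soft linear restoring
force (100 pN/um) toward the nearest boundary point of the (radius-reduced)
ellipse, and bodies repel each other and fibers through a soft linear
excluded-volume force (100 pN/um). Fibers do not interact sterically with
each other; they only interact through connectors.

**Microtubules.** Fibers are vertex chains with harmonic bending (flexural
rigidity 20 pN um^2) and a stiff stretching penalty (100 pN/um per
segment); interior segments carry a rest length of exactly 2 um and the
plus-end segment carries the remainder, so polymer appears and disappears
at the plus end only. Plus ends switch growing -> shrinking with no rescue;
a fiber that shrinks to zero length is removed and its nucleation site
freed. The growth speed is

v = v0 (1 - L_poly / L_max) exp(-f / f_g),

with unloaded speed v0 = 0.2 um/s, a fixed tubulin pool of L_max = 500 um
polymer equivalent per myotube, growth-force sensitivity f_g = 1.5 pN, and
f the force component opposing growth at the tip. The catastrophe rate
depends on the growth speed through a linear interpolation of the mean
catastrophe time between the stalled (30 s) and free-growth (600 s)
limits, so stalled tips are short-lived, as observed in vitro. Shrinkage is
0.4 um/s. Nucleation sites (at most 20 per nucleus, the EB1-comet-derived
cap) sit at fixed points of the body surface; each free site nucleates as
a first-order event and new fibers point along +x or -x with equal
probability.

**Connectors.** Four species, all with first-order binding within a
0.05 um capture radius (k_on = 5/s), zero-rest-length Hookean springs
(100 pN/um), and baseline unbinding k_off = 0.5/s:

* NE dynein (50 per nucleus): minus-end-directed motor, v0 = 1.0 um/s.
* NE Kif5b (50 per nucleus): plus-end-directed motor, v0 = 0.8 um/s.
* MAP4 (200 per myotube): passive crosslinker, two MT-binding heads.
* MAP7-Kif5b (200 per myotube): one passive (MAP7) head, one plus-directed
  Kif5b motor head — the antiparallel-sliding unit.

Motors follow a linear force-velocity law, v = v0 (1 - f/f_stall), clamped
to [0, v0], with stall force 5 pN, and dwell at fiber ends until they
unbind. NE motors are anchored at uniform random points of the nuclear
surface and never leave their anchor; cytoplasmic crosslinkers diffuse
freely while unbound.

**Conditions.** `control` = NE nucleation + NE Kif5b; `no_ne_nucleation` =
nucleation moved to one mobile centrosome-like body per nucleus, placed
uniformly at random, all other features unchanged (NE Kif5b retained);
`no_ne_nucleation_no_kif5b` additionally removes NE Kif5b. NE dynein is
retained in all three (a toggle is provided, since the source experiments
only state the removal of nucleation and Kif5b).

**Initial condition.** Nuclei start as an overlap-free cluster around the
domain center (deterministic steric relaxation of a compressed row), so
that spreading is the observable; there are no fibers at t = 0.

## Design choices made where the design was open

*Nucleation directions.* Strictly horizontal nucleation in 2D produces a
family of parallel lines that can never intersect, so crosslinkers almost
never find two fibers within their 0.05 um capture radius and the
antiparallel organization/sliding machinery is structurally disabled — an
artifact of the dimension, not of the biology, since growing MT ends in
myotubes are observed near-axial with a spread of angles. Fibers therefore
nucleate at ±x plus Gaussian angular noise (`nucleation_angle_sd`, default
0.17 rad ~ 10 deg; 0 restores the strict rule).

*Load-dependent unbinding.* With strictly force-independent detachment the
NE dynein/kinesin tug-of-war deadlocks: equal teams hold each other at
stall indefinitely, nuclei stay where they started in every condition, and
no condition contrast can form. The package therefore defaults to the
standard Kramers form k_off exp(F / f_unbind) with f_unbind = 3 pN per
species (`*_f_unbind = Inf` restores force independence). Load-sensitive
unbinding is the canonical resolution of motor tug-of-wars and is the
standard motor model of the simulation engine this model family uses.

*Crosslinker diffusion.* Free 50-nm crosslinkers would be essentially
immobile under the organelle-scale viscosity (D ~ 0.01 um^2/s) and would
never encounter fibers; small proteins actually experience water-like
microviscosity. Unbound crosslinkers therefore diffuse with their own
coefficient (`crosslinker_diffusion`, default 1 um^2/s), still as
individually tracked particles rather than a mean-field bath.

*Nucleation rate.* The per-site rate (default 0.02/s) is not printed
anywhere; it controls the
steady-state balance between many short fibers and few long ones under the
fixed pool. Rates around 0.02/s keep sites busy while letting fibers reach
the ~10 um lengths at which they span neighbouring nuclei, matching the
longitudinal-array phenotype.

*Centrosome count.* One centrosome-like body per nucleus, mobile, placed
uniformly (the source only says "randomly positioned").

## Numerical scheme

Overdamped Langevin integration at dt = 0.01 s with per-step order: force
accumulation -> motion -> MT plus-end dynamics -> connector kinetics
(walk, unbind, bind) -> nucleation. Three details keep the explicit scheme
robust at this dt:

* per-DOF spring-stiffness tallies are accumulated with the forces; when
  the local stiffness-to-drag ratio exceeds the explicit-Euler stability
  bound the step is subdivided (at most 2 mechanics substeps) and, beyond
  that, the displacement update switches smoothly to an exponential
  (diagonally-implicit) relaxation factor (1 - e^-z)/z, which is
  unconditionally stable for stiff connector clusters;
* thermal noise is applied once per step at full-step variance;
* first-order events are drawn as geometric waiting times in steps,
  exactly equivalent to per-step Bernoulli draws but far cheaper; the
  binding neighbour-search grid is rebuilt every 5 steps with a margin
  that covers the possible inter-rebuild fiber motion.

Blow-ups (a displacement exceeding the domain half-length in one step)
abort with guidance to reduce dt. The ellipse nearest-point problem is
solved by bounded bisection to 1e-9 um. Ensemble replicates use one RNG
stream each (`seed + replicate`), shared across conditions so conditions
are compared on matched initial configurations.

## The spreading factor

For nuclei at axial positions x_1..x_N in a myotube of length L (N >= 3,
the inclusion rule), the SF is the mean over all unordered pairs of
|x_i - x_j| divided by the same mean for N evenly spaced points spanning
[0, L], which is L (N+1) / (3 (N-1)). SF = 1 means perfectly dispersed;
SF -> 0 means fully clustered. "Average internuclear distance" is read as
the all-pairs mean (robust to ordering); a consecutive-neighbour variant is
available via `method = "consecutive"` for sensitivity analysis. The
reference is the even-spacing configuration rather than the literal
maximizer of the mean pair distance (end-stacking), because the statistic
is used so that lower values mean "less spread"; under the literal
maximizer the reading would invert. Experimental centroid tables are
projected onto the myotube's long axis upstream of this package.

Groups are compared with the two-sided Mann-Whitney test (midranks for
ties; exact enumeration when the smaller group has at most 8 observations
and there are no ties, otherwise the normal approximation with tie and
continuity corrections), via `stats::wilcox.test` configured to exactly
that rule; the test suite checks it against an independent enumeration
oracle.

## BioID/TMT quantitation

The pipeline starts from a protein-level reporter-abundance table
(2 cell states x 3 treatments x replicates). Steps:

1. *Identification gate*: proteins identified in >= 2 replicates.
2. *Bait normalization*: every +DOX column is scaled so the bait
   (BirA*-fusion) abundance equals the geometric mean of bait abundances
   across +DOX samples; factors are recorded. Note the invariance this
   buys: rescaling any raw +DOX column moves all normalized ratios by one
   common global factor, so every myotube/myoblast fold change is exactly
   invariant. -DOX columns, where the bait is not expressed, are left
   unscaled.
3. *Ratios*: per protein, cell state and replicate, (+DOX +biotin) over
   the -DOX control (biotin-only when present, untreated otherwise), with
   a logged pseudocount (default: smallest nonzero abundance of the
   denominator column) for zero/missing denominators.
4. *Enrichment filter*: a protein is enriched in a replicate when its
   myotube fold strictly exceeds the threshold (default 1; a 1e-9 relative
   guard keeps floating-point ties at the threshold from counting), and
   passes when enriched in >= 2 of 3 replicates. `enrichment_threshold_sweep()`
   reports the pass-set size over a threshold grid, which brackets any
   published candidate count whose exact cutoff is undocumented.

## What the synthetic generators emulate — and what they do not

`gen_nuclei()` produces clustered (truncated-normal), dispersed
(even + jitter) and uniform-random nucleus tables with the 19 um-per-nucleus
length rule — the statistical skeleton of clustered vs dispersed myotube
phenotypes. It does not emulate segmentation error, curved myotube axes, or
nucleus-size exclusion effects. `gen_tmt()` produces log-normal background
abundances, a planted myotube-enriched set (default 1000 proteins, 50
planted, 4-fold), per-sample bait scales on whole +DOX columns, log-normal
measurement noise at a given CV (default 20%) and optional missingness
(default 0, so the default table is fully observed). It does not emulate
peptide-level effects, isotope-impurity crosstalk, or compositional
distortions. Tests passing on these generators therefore certify the
pipeline's arithmetic and filtering logic, not robustness to everything
real data can do.

## Problem sizes used in the shipped analyses

The ensemble analyses and the acceptance script use 20 replicates per
condition, nucleus counts cycling 5-9, 600 s of simulated time per
replicate at dt = 0.01 s (the SF contrast between conditions is resolved
at this scale; single figures-quality runs use 3600 s), and the
synthetic-table defaults above. The physics checks use 1500 replicates of
5 s for free diffusion, 10^4 steps for conservation audits, and ~10^3
fiber histories for the renewal-process comparison.

## Known limitations

* 2D: fibers cannot pass over nuclei as in 3D; sterics deflect them
  around, which shortens fiber lifetimes near crowded clusters.
* Bodies do not rotate; anchor points are fixed in the body frame.
* The headline biological contrast is only partially reproduced. Removing
  NE Kif5b lowers mean spreading in most parameter screens, but
  relocating nucleation from the NE to cytoplasmic bodies does *not*
  reliably lower it in this implementation: NE kinesin transports nuclei
  along centrosome-nucleated fibers about as effectively as along
  neighbour-nucleus fibers, and the control-specific antiparallel-sliding
  channel is geometry-starved in 2D (bridges only form where fibers
  cross). With the ~10 um fiber lengths enforced by the fixed tubulin
  pool, neighbour-fiber kinesin runs are also short. The condition
  comparison shipped with the package therefore reports whatever the
  mechanistic model actually produces; at 20 replicates per condition the
  control vs relocated-nucleation difference is within replicate noise.
  Longer simulated times (hours, as in real differentiation) and the
  original (unpublished) parameter table may both be required for the
  full experimental contrast.
* Motor parameters are generic (no ATP kinetics, no back-stepping); the
  parameter registry documents every default and all are overridable.
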