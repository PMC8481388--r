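---
title: "Helical-pair motif geometry and PTM-induced solvent-accessibility change: methods"
author: "helixptm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical-pair motif geometry and PTM-induced solvent-accessibility change: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixptm)
```

# The problem

Post-translational modifications (PTMs) — acetylation of lysine,
phosphorylation of serine/threonine/tyrosine, the Gly-Gly remnant that
ubiquitination leaves on lysine after tryptic digestion — change the local
shape and solvent exposure of a protein without changing its sequence.
When a PTM lands inside a compact supersecondary motif built from two
packed helices, the interesting questions are geometric: does the moiety
fit, how much new surface does it expose to solvent, and does the
helix-helix contact survive the ensuing conformational fluctuation?

`helixptm` implements that structural analysis as a pipeline of small,
testable stages: helix detection, least-squares axis fitting, helical-pair
geometry and motif classification, in-silico mounting of the PTM moiety,
solvent-accessible surface area (SASA) deltas for the modified residue and
its *active environment*, and tracking of the pair geometry across
coordinate trajectories. A companion set of curation operations applies
the quality and phenotype-specificity filters used to reduce a cohort's
peptide-spectrum identifications to the group-specific modified peptides
that feed the structural stages.

# Helix detection

Helices are assigned with the Kabsch–Sander hydrogen-bond method. A
backbone hydrogen bond between the N–H of one residue and the C=O of
another is scored with the standard electrostatic model

$$E = 0.084 \times 332 \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}}
  - \frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right) \;
  \mathrm{kcal\,mol^{-1}} ,$$

and recorded when $E < -0.5\ \mathrm{kcal\,mol^{-1}}$. Both constants are
the canonical ones; the method itself fixes neither, so they are stated
here as the package's choice. An *n*-turn at residue $i$ is a bond from
the N–H of residue $i+n$ to the C=O of residue $i$ ($n = 3, 4, 5$); two
consecutive *n*-turns make residues $i \ldots i+n-1$ helical of type 3/10,
$\alpha$ or $\pi$ respectively, with overlap priority
$\alpha > 3/10 > \pi$ and minimal lengths 3/4/5 residues.

Deposited structures usually lack amide hydrogens, so missing H atoms are
placed 1.00 Å from N along the unit vector from the previous residue's
carbonyl O to its C — the common convention. End effects differ between
implementations by about one residue at helix caps; the test suite
compares helix calls on lysozyme against an independent reference
implementation with a ±1-residue tolerance at segment ends, and tolerates
extra minimal 3/10 calls, which are the classic point of
inter-implementation drift. All three helix types enter the pair analysis
by default, configurable through the `types` argument of
`assign_helices()`.

# Axis fitting

Each helix is wound on a cylinder; its axis is found by least squares:
the line minimizing the *variance* of point-to-line radial distances of
the C$\alpha$ trace. The search is seeded with the principal direction of
the C$\alpha$ cloud and refined by Nelder–Mead over four parameters (two
orientation angles, two in-plane offsets). Minimizing the variance rather
than the mean squared distance is what makes the solution a cylinder axis
instead of a total-least-squares line. The fit quality is reported as
`fit_rmsd`, the standard deviation of the radial distances; segments with
`fit_rmsd` above 1 Å (configurable) are excluded from motif selection, and
segments shorter than five residues are flagged as not fittable.

On an ideal helix the fit recovers the construction axis to numerical
precision. At Gaussian coordinate noise of 0.3 Å on a 12-residue helix
the fitted objective is always at least as good as the truth's (asserted
in the tests), so the residual direction error — median well under 3°, at
least 90% of seeds within 3° over 200 seeds — is the statistical limit of
the estimator, not an optimization artifact.

# Pair geometry

Two helix axes in space admit a unique pair of parallel planes, one
through each line; their common normal is the cross product of the axis
directions. The pair is described by six quantities:

* $d$ — the inter-planar distance;
* $r$ — the minimal Euclidean distance between the two finite axis
  *segments* (the axial projections of the first and last C$\alpha$).
  Always $r \ge d$, with equality exactly when the projected segments
  cross;
* $\alpha$ — the unsigned inter-axial angle folded to $[0°, 90°]$,
  measured between the 3-D directions (for axes lying in parallel planes
  this equals the in-plane angle, so the distinction the folding
  convention leaves open is moot);
* $\theta$ — the signed torsion of axis 1 onto axis 2, right-hand rule
  about the plane normal oriented from helix 1's plane to helix 2's
  plane, axes oriented N→C, in $(-180°, 180°]$. Under helix-order swap
  the normal flips and $\theta$ is invariant (asserted); under a
  reflection $\theta$ changes sign;
* $S$, $P$ — area and perimeter of the intersection of the two cylinder
  silhouettes projected onto the mid-plane: each helix projects as a
  rectangle of length equal to its axial segment and width twice its
  fitted radius; the convex intersection polygon is computed by
  Sutherland–Hodgman clipping. Any plane parallel to both axes gives the
  same in-plane geometry; the mid-plane is chosen for symmetry.

The silhouette radius defaults to the mean radial distance of *all heavy
atoms* of the helix when they are supplied (about 5 Å for a real
side-chain-bearing helix, about 2.3 Å for a C$\alpha$ trace). Published
worked examples of $S$ are consistent with an effective cylinder width
near 10 Å, i.e. with the all-heavy-atom radius; since the polygon
construction is not otherwise pinned down, this is a documented package
choice, and absolute $S$, $P$ values should be compared only within one
radius convention.

## Motif classes and selection

Crossing pairs are $\alpha$-$\alpha$ motifs: hairpins when nearly
antiparallel ($|\theta| \ge 120°$ by default), corners otherwise.
Non-crossing pairs ($d < r$, near-null projection overlap) are V-shaped
when the connection is short (≤ 5 residues by default) and L-shaped
otherwise; there is no canonical discrimination rule between L and V, so the
connection-length rule is a documented package choice, and both
thresholds are configurable.

Motif selection for the PTM analysis keeps helix pairs — sequence
adjacency not required, any number of intervening helices — that satisfy:
(1) the modified residue lies on one of the pair's helices, on the chain
between them, or within two residues of a helix end; (2) both axis fits
pass the RMSD criterion; (3) the helices are in tight contact,
$|r - d| \le 0.5$ Å (axis-fit noise tolerance) with $r \le 16$ Å; and
(4) the projection intersection is non-null ($S > 0$, $P > 0$).

# PTM mounting

Moieties are built heavy-atoms-only from idealized internal coordinates
on the side-chain anchor (NZ for lysine; OG/OG1/OH for Ser/Thr/Tyr):
acetyl as a planar sp² amide (N–C 1.33 Å, C=O 1.23 Å, C–CH₃ 1.50 Å),
phosphate tetrahedral (O–P 1.61 Å, P–O 1.52 Å), and the Gly-Gly remnant
with standard peptide-bond geometry. The remnant is built as a reduced
six-heavy-atom set — the proximal glycine complete (C, O, C$\alpha$, N)
plus the distal carbonyl (C, O) — while mass bookkeeping uses the full
chemical formulas (monoisotopic shifts 42.0106, 79.9663 and 114.0429 Da
for acetyl, phospho and Gly-Gly).

The single rotatable anchor dihedral is chosen by a deterministic
30°-grid scan maximizing the minimum distance between moiety atoms and
all non-target heavy atoms. This is a steric objective, not an energy:
no force field is in scope, and neighboring atoms are never relaxed —
post-mount motion is modeled by the trajectory stage instead. Mounting
never moves an existing atom (asserted bit-exactly), and a site where
every rotamer would place the moiety closer than 1.5 Å to the
surroundings is refused with a worst-case report. The idealized-geometry
construction is a stand-in for force-field templates and is labeled as
such in reports.

# Solvent accessibility

SASA is computed with the Shrake–Rupley rolling-probe method: probe
radius 1.4 Å, a deterministic 960-point golden-spiral lattice per atom,
van der Waals radii C 1.76 / N 1.65 / O 1.40 / S 1.85 / P 1.90 Å,
hydrogens ignored. Unknown elements fall back to 1.70 Å with a warning.
The algorithm and radii are the package's documented choice, so
absolute areas from other programs (including the packaged published
table) are matched qualitatively, not numerically.
Determinism of the lattice makes every area exactly reproducible;
doubling the lattice density changes per-atom areas by under 2% (or 1 Ų
absolutely for buried atoms), and total SASA is rotation-invariant to
0.5%.

The *active environment* of a modified residue is the set of residues
with any heavy atom within 6 Å of any heavy atom of that residue,
computed on the intact structure and frozen, so the intact and modified
sums always run over identical residue sets. The environment area
includes the modified residue's own area (the published table's
"active environment" column is read the same way; the count of
decreasing-environment cases is insensitive to this choice as long as it
is applied consistently). Moiety atoms are attributed to the modified
residue.

# Trajectory stability

Trajectories are multi-model coordinate sets (one structure per MODEL
record); the published recording schedule — 0.5 ns sampled every
0.005 ns — corresponds to exactly 100 frames. Per frame, both axes are
re-fitted from that frame's coordinates (never propagated) and the six
descriptors recomputed; frames where a fit fails are flagged and
excluded from the summary, which reports arithmetic means and
*population* standard deviations ($s_d$, $s_r$, $s_\alpha$, $s_\theta$,
$s_S$, $s_P$) over all frames (an equilibration window is configurable but off by default).

The qualitative notion of features staying "within acceptable ranges" is
quantified by three configurable thresholds, reported alongside every
verdict: a run is STABLE when at least 90% of frames keep tight contact
($|r - d| \le 0.5$ Å) and a non-null projection; RUPTURED when the
contact fraction falls below 50% or the mean $r - d$ gap exceeds 2 Å;
FLUCTUATING otherwise. The modified-vs-intact comparison lists
per-feature mean deltas and flags features shifted by more than twice
the intact run's standard deviation. Intact and modified topologies may
number the same helices differently; the caller supplies both spans and
the report records the mapping.

# Curation of identification tables

One record is one peptide-PTM observation in one sample. Quality filters
keep records with ≥ 98% identification confidence, ≥ 80% fragment-spectra
sequence coverage, ≥ 10 units of site-localization D-score, and a proper
flanking b/y ion pair; removals are logged per rule in that order, and
the surviving set is a pure conjunction (order-independent, asserted).
A modified peptide — identity = (sequence, PTM kind, site) — is
*phenotype-specific* for a cancer group when it appears in at least 50%
of that group's samples, in zero control samples, and in at least 20% of
PTM-carrying subjects. "Carriers" are read cohort-wide (any subject with
at least one passed modified peptide); a per-group denominator is
available as a switch, since both readings of the carrier pool are defensible.
The same peptide may be specific to both cancer groups, never to the
control.

Differential abundance replaces null intensities by an instrument floor
of $10^5$ counts, takes the median-ratio $\log_2$ fold change toward the
control group, a two-sided Wilcoxon rank-sum p-value (exact for group
sizes up to 12 without ties, normal approximation with tie correction
otherwise — exactness keeps the planted-truth simulations
deterministic), and the detection frequency; a protein is significant
when $|\log_2 FC| > 1$, $p < 0.05$ and frequency $> 0.8$. No multiplicity
correction is applied at this stage: the thresholds act as a joint
filter, not as a family of independent hypothesis tests.

# Synthetic data: what it emulates, and what it does not

The generators define the study conditions for every test:

* **Ideal helices** — C$\alpha$ traces exactly on a cylinder (radius
  2.3 Å, rise 1.5 Å, twist 100°/residue), or full backbones built at
  constant $\phi/\psi = -57°/-47°$ with standard bond geometry (N–CA
  1.46, CA–C 1.52, C–N 1.33, C=O 1.23 Å). Constant torsions give the
  chain exact screw symmetry, so the generator can return the analytic
  screw axis as ground truth. Side chains are built for Ala, Lys, Ser,
  Thr, Tyr and Gly in extended rotamers — enough to anchor every
  supported PTM.
* **Helical pairs** — helix 2 is laid in a plane at prescribed distance
  $d^\*$ with its direction rotated by the prescribed torsion
  $\theta^\*$, crossing (or not) at prescribed fractional positions. For
  axes in parallel planes the inter-axial angle is implied,
  $\alpha^\* = |\theta^\*|$ folded to $[0°, 90°]$, so it is not an
  independent dial. Crossing constructions satisfy $r = d^\*$ exactly.
  The connecting segment is a straight C$\alpha$-only linker, excluded
  from helix assignment.
* **Trajectories** — i.i.d. Gaussian coordinate jitter plus an optional
  cumulative per-frame translation of a residue span. This emulates the
  *recording schedule and magnitude* of thermal fluctuation, not its
  physics: no bonded constraints, no correlated motions, no force field.
  Passing trajectory tests therefore demonstrates correct bookkeeping
  and geometry under motion, not molecular-dynamics realism.
* **Cohorts** — 53 ovarian-cancer, 24 breast-cancer and 30 control
  subjects by default, mirroring the study demography. Planted peptides
  (by default the packaged 12 + 6 peptide list, with its albumin and
  serotransferrin peptides shared between the cancer groups) appear in
  60% of their group inside an 85% carrier pool with log-normal
  intensities; seven decoys each violate exactly one curation rule, with
  the violated and satisfied rules audited arithmetically at generation
  time (an infeasible design is refused rather than silently generated).
  Decoy peptide sequences are synthetic tokens; no sequence realism is
  attempted.

# Numerical choices and degenerate inputs

* Alt-locs resolve to the highest-occupancy copy (ties: first listed);
  waters are dropped on read; hydrogens are kept when present and
  ignored by SASA and mounting.
* Multi-model files with inconsistent atom counts are rejected naming
  the offending frame; each MODEL block is parsed independently so a
  single model can still be read from such a file.
* Collinear C$\alpha$ points (no cylinder) and sub-5-point traces are
  axis-fit errors; zero-length projected segments are projection errors.
* Near-parallel axes (cross product below $10^{-8}$) fall back to the
  perpendicular inter-anchor component for the plane normal.
* The contact tolerance $\epsilon = 0.5$ Å absorbs axis-fit noise in the
  $r = d$ test; all thresholds are surfaced in `pipeline_config()` and
  echoed into reports.
* An all-constant intensity vector makes the rank-sum test undefined;
  the p-value is reported as 1.

# Problem sizes

The test suite and the acceptance script run at desk scale: helices of
12–20 residues, pairs of 2 × 16 residues, 100-frame trajectories,
10³–10⁴ random axis pairs for the geometry oracles (dense-sampling and
Monte-Carlo references), 200 seeds for noisy axis recovery, one synthetic
cohort of 107 subjects, and 200 replicates of the abundance simulation —
sizes chosen so every number is recomputed from scratch in seconds while
keeping the Monte-Carlo standard errors well inside the asserted
tolerances.

# Known limitations

* No force field anywhere: mounting is steric, trajectories are
  synthetic or externally supplied, and free-energy statements are out
  of scope.
* SASA radii and algorithm are a documented choice; absolute published
  areas are reproduced only qualitatively (the packaged area table is
  used verbatim for count-based results).
* β-containing motifs, mmCIF input, and structure-database-wide motif
  mining are out of scope.
* The L/V discrimination rule and the carrier-denominator reading are
  package choices exposed as configuration, as discussed above.
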