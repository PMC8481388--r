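# helixptm

Structural analysis of PTM-induced conformational fluctuation in
helical-pair motifs.

Post-translational modifications (PTMs) — lysine acetylation,
Ser/Thr/Tyr phosphorylation, the Gly-Gly ubiquitination remnant — often
land inside compact supersecondary motifs built from two packed
α-helices (α-α-corners, hairpins, L- and V-structures). `helixptm` is an
R package, with an accompanying analysis workflow under `analysis/`, for
asking the geometric questions that follow: does the modified residue
sit on a tight helix-helix contact, how much solvent-accessible surface
does the mounted moiety expose, and does the contact survive
conformational fluctuation? A second arm of the package applies the
proteomic curation rules that reduce cohort identification tables to the
group-specific modified peptides feeding the structural analysis.

## The method in brief

* **Helix detection** — Kabsch–Sander hydrogen bonds,
  E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with a
  −0.5 kcal/mol cutoff, distinguishing α, 3/10 and π helices.
* **Axis fitting** — each helix is wound on a cylinder; the axis is the
  line minimizing the variance of point-to-line radial distances of the
  Cα trace (least squares), with the standard deviation of those
  distances as the fit-quality measure.
* **Pair geometry** — through two skew axes one draws two parallel
  planes; the pair is described by the inter-planar distance d, the
  minimal segment distance r (r = d exactly when the projected segments
  cross), the inter-axial angle α ∈ [0°, 90°], the signed torsion θ
  about the inter-plane normal, and the area S and perimeter P of the
  intersection of the two cylinder silhouettes projected on the
  mid-plane.
* **Motif selection** — pairs in tight contact (r = d within 0.5 Å,
  r ≤ 16 Å, S, P > 0, well-fitted axes) that carry the PTM site on or
  near one of their helices.
* **PTM mounting** — idealized heavy-atom moieties (acetyl, phosphate,
  Gly-Gly remnant) on the side-chain anchor, rotamer chosen by a
  deterministic clash-minimizing grid scan; mass shifts 42.0106 /
  79.9663 / 114.0429 Da.
* **Solvent accessibility** — Shrake–Rupley SASA (probe 1.4 Å, 960-point
  deterministic lattice), with before/after deltas for the modified
  residue and its active environment (all residues with heavy atoms
  within 6 Å, frozen on the intact structure).
* **Trajectory stability** — the six descriptors re-measured per frame
  over multi-MODEL trajectories (0.5 ns at 0.005 ns = 100 frames), means
  and standard deviations (s_d, s_r, s_α, s_θ, s_S, s_P), and a
  STABLE / FLUCTUATING / RUPTURED verdict.
* **Curation** — PSM filters (98% confidence, 80% coverage, D-score ≥ 10,
  proper b/y pairs), phenotype specificity (≥ 50% of the cancer group,
  absent from controls, ≥ 20% of PTM carriers), and median-ratio log2
  fold change with an exact Wilcoxon rank-sum test and a 10^5-count
  intensity floor.

Synthetic-data generators (ideal and noisy helices, pairs with
prescribed d*/θ*, jittered and drifting trajectories, cohort tables with
planted PTMs and rule-violating decoys) provide exact ground truth for
every stage and are first-class, tested code.

## Worked example

Build a crossing helical pair at inter-planar distance 11.7 Å and
torsion −57° with a lysine mid-helix, then run the full structural
pipeline on the acetylation site:

```r
library(helixptm)
seq1 <- rep("ALA", 16); seq1[8] <- "LYS"
pair <- make_helix_pair(d = 11.7, theta = -57, backbone = "FULL_BACKBONE",
                        lengths = c(16, 16), sequence1 = seq1)
res <- run_structural_pipeline(pair$structure,
                               site = list(chain = "A", resno = 8),
                               ptm = "ACETYL_K")
res$motifs[, c("d", "r", "alpha", "theta", "S", "P", "motif_class")]
#>          d        r    alpha     theta        S        P motif_class
#> 1 11.70021 11.70021 57.00029 -57.00029 24.24926 21.53531   AA_CORNER
res$sasa_report
#> <sasa_report> residue 8: 160.49 -> 224.19 A^2 (delta +63.70); environment
#> (11 members + center): 789.57 -> 853.27 A^2 (delta +63.70)
```

The fitted pair recovers the construction exactly — the minimal and
inter-planar distances are equal (the tight-contact signature of
crossing helices) and the signed torsion matches the prescription — and
the acetyl moiety adds about 64 Å² of solvent-accessible surface to the
exposed lysine. On the curation side, running the packaged
modified-peptide table through the pipeline:

```r
tab <- table1_as_records()
run_curation_pipeline(tab$records, tab$cohort)$counts
#> OC: 12 modified peptides from 8 proteins
#> BC: 6 modified peptides from 3 proteins
```

The numbered scripts under `analysis/` walk the same pipeline as a
narrative: `01_simulate.R` builds the structures and trajectories,
`02_motif_geometry.R` detects and selects the motif, `03_mount_sasa.R`
mounts the moiety and reports the SASA deltas, `04_trajectory_stability.R`
renders the stability verdicts (the quiet run is STABLE with all six SDs
zero; the constructed drift run is RUPTURED), and `05_curation.R`
reproduces the per-group counts and the planted-truth recovery. Each
writes its tables under `results/`.

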