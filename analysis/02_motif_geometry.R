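#!/usr/bin/env Rscript
# Helix detection and helical-pair geometry on the simulated pair:
# Kabsch-Sander helix assignment, least-squares axis fits, the
# six-descriptor pair characterization, and the tight-contact motif
# selection around the lysine site. Writes results/motif_table.tsv.
# Run after 01_simulate.R.

suppressMessages(library(helixptm))
dir.create("results", showWarnings = FALSE)

st <- read_structure("results/structures/pair_corner.pdb")
helices <- assign_helices(st)
cat("Helix calls:\n"); print(helices)

site <- find_residue(st, "A", 8)
motifs <- select_motifs(st, helices, site)
cat("\nTight-contact motifs covering the PTM site:\n")
print(motifs)

write.table(motifs, "results/motif_table.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

if (nrow(motifs) == 1) {
  cat(sprintf(
    "\nThe pair is recovered as an alpha-alpha corner in tight contact: d = %.2f A, r = %.2f A (r = d as the projections cross), theta = %.1f deg, S = %.1f A^2.\n",
    motifs$d, motifs$r, motifs$theta, motifs$S))
}
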