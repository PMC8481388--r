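#!/usr/bin/env Rscript
# Mount an N-epsilon-acetyl moiety on the pair's lysine and quantify the
# solvent-accessibility change of the residue and its active
# environment; also count, from the packaged published area table, how
# many peptides lose active-environment area on modification. Writes
# results/sasa_report.json. Run after 01_simulate.R.

suppressMessages(library(helixptm))
dir.create("results", showWarnings = FALSE)

st <- read_structure("results/structures/pair_corner.pdb")
mr <- mount_ptm(st, ptm_spec("ACETYL_K", "A", 8))
cat("Mounted:", format(mr$spec$kind), "- dihedral", mr$chosen_dihedral,
    "deg, min clash distance", round(mr$min_clash_distance, 2), "A\n")
write_structure(mr$structure, "results/structures/pair_corner_acK.pdb")

ridx <- find_residue(st, "A", 8)
env <- active_environment(st, ridx, cutoff = 6.0)
rep <- sasa_delta_report(st, mr$structure, ridx, env)
print(rep)

dec <- environment_decrease_count()
cat(sprintf(
  "\nPackaged area table: %d distinct peptides show a decreased active-environment area after modification.\n",
  dec$n_decreasing))
print(dec$peptides)

jsonlite::write_json(list(
  site = list(chain = "A", resno = 8, kind = "ACETYL_K"),
  residue_intact = rep$residue_intact,
  residue_modified = rep$residue_modified,
  environment_intact = rep$environment_intact,
  environment_modified = rep$environment_modified,
  delta_residue = rep$delta_residue,
  delta_environment = rep$delta_environment,
  environment_members = rep$members,
  parameters = list(probe_radius = rep$probe_radius,
                    n_points = rep$n_points, cutoff = rep$cutoff),
  table_decrease_cases = dec$n_decreasing
), "results/sasa_report.json", auto_unbox = TRUE, digits = NA,
pretty = TRUE)
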