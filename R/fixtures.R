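# Packaged fixtures: transcriptions of the published modified-peptide
# list (18 rows: 12 ovarian-cancer + 6 breast-cancer) and of the
# published solvent-accessibility table (per-peptide areas of the
# modified amino acid and its active environment, intact vs modified),
# plus reference synthetic structures written by the generators.
#
# The tables are stored verbatim as printed (decimal commas normalized
# to points), including apparent typographical oddities in the source
# (an environment area of 163 without decimals, a truncated peptide, an
# amino-acid area pair 21.53/7.29); analyses that depend only on the
# sign of the environment delta are insensitive to these.

FIXTURE_NAMES <- c("TABLE1", "TABLE2", "IDEAL_HELIX_20", "PAIR_CORNER")

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "helixptm")
  if (p == "") {
    # during in-source development
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) stop("fixture file missing: ", file)
  p
}

#' Load a packaged fixture
#'
#' `TABLE1`: the modified-peptide list (group, gene, protein name,
#' peptide, PTM site and kind). `TABLE2`: the per-peptide
#' solvent-accessibility quadruples (modified amino acid and active
#' environment, intact vs modified, in square Angstrom) with motif
#' localization labels. `IDEAL_HELIX_20`: a 20-residue poly-alanine
#' ideal helix (full backbone, 5 heavy atoms per residue).
#' `PAIR_CORNER`: a crossing helical pair built at inter-planar distance
#' 11.7 Angstrom and torsion -57 degrees, with a lysine mid-helix-1.
#'
#' @param name one of `"TABLE1"`, `"TABLE2"`, `"IDEAL_HELIX_20"`,
#'   `"PAIR_CORNER"`.
#' @return A data.frame (tables) or `ptm_structure` (structures).
#' @export
load_fixture <- function(name) {
  name <- match.arg(toupper(name), FIXTURE_NAMES)
  switch(name,
         TABLE1 = utils::read.delim(fixture_path("table1_ptm_peptides.tsv"),
                                    stringsAsFactors = FALSE),
         TABLE2 = utils::read.delim(fixture_path("table2_sasa.tsv"),
                                    stringsAsFactors = FALSE,
                                    na.strings = c("NA", "")),
         IDEAL_HELIX_20 = read_structure(fixture_path("ideal_helix_20.pdb")),
         PAIR_CORNER = read_structure(fixture_path("pair_corner.pdb")))
}

#' Count peptides whose active-environment area decreases on modification
#'
#' From the packaged solvent-accessibility table: the number of distinct
#' modified peptides — identified by (sequence, PTM kind, site) — whose
#' active-environment solvent-accessible area is smaller after the PTM
#' is mounted than before.
#'
#' @param table2 the `TABLE2` fixture (loaded when omitted).
#' @return list(`n_decreasing`, `peptides` = their identities).
#' @export
environment_decrease_count <- function(table2 = load_fixture("TABLE2")) {
  key <- paste(table2$peptide, table2$ptm_kind, table2$site)
  dec <- table2$env_ptm < table2$env_intact
  dk <- unique(key[dec])
  list(n_decreasing = length(dk),
       peptides = table2[match(dk, key),
                         c("gene", "peptide", "ptm_kind", "site")])
}
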