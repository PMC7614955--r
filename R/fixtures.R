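#' Apicomplexan and chromerid lineages
#'
#' The nine lineages whose NTH gene complements the package ships as
#' fixtures, in conventional order with the chromerid outgroup first.
#'
#' @return Character vector of lineage names.
#' @export
apicomplexan_lineages <- function() {
  c("Chromerida", "Gregarinia", "Marosporida", "Cryptosporidia",
    "Nephromycida", "Sarcocystidae", "Eimeriidae", "Haemosporida",
    "Piroplasmida")
}

#' Packaged lineage gene complements
#'
#' Reported NTH gene complements of the apicomplexan and chromerid
#' lineages, one record per gene with its isoform and beta-alpha paralogue
#' group. Piroplasmida contribute no records (no NTH gene is known there);
#' tandem duplicates (the gregarine *Porospora* copies) are kept as
#' separate records, although copy number within a character does not
#' affect the presence/absence matrix.
#'
#' @return Tibble with `lineage`, `gene_id`, `isoform`, `paralog_group`.
#' @export
lineage_complements <- function() {
  df <- utils::read.delim(nth_extdata("lineage_complements.tsv"),
                          stringsAsFactors = FALSE, na.strings = "NA")
  as_tibble(df)
}

#' Packaged lineage-by-isoform presence/absence matrix
#'
#' The nine-lineage, three-character matrix of NTH isoform/paralogue
#' presence across apicomplexans and chromerids: Chromerida retain all
#' three characters, Piroplasmida none. Identical to
#' `build_presence_matrix(lineage_complements(), apicomplexan_lineages())`.
#'
#' @return A `presence_matrix` tibble.
#' @export
lineage_presence_matrix <- function() {
  read_presence_matrix(nth_extdata("lineage_matrix.tsv"))
}

#' Candidate apicomplexan topologies
#'
#' Three rooted candidate trees over the nine fixture lineages, encoding
#' the competing published groupings of the four core apicomplexan clades:
#' `mathur` (Cryptosporidia with Coccidia and Hematozoa), `janouskovec`
#' (Gregarinia with Cryptosporidia) and `salomaki` (Gregarinia with
#' Coccidia and Hematozoa). Chromerida is the outgroup in each. Branching
#' order beyond those constraints is a documented free choice (see the
#' methods vignette).
#'
#' @return Named list of rooted `phylo` trees.
#' @export
candidate_topologies <- function() {
  names <- c("mathur", "janouskovec", "salomaki")
  setNames(lapply(names, function(n) {
    read_newick(nth_extdata(paste0(n, ".nwk")))
  }), names)
}

#' Packaged synthetic paralogue-group reference sequences
#'
#' Synthetic reference sequence sets for beta-alpha paralogue groups I and
#' II, generated with [make_reference_families()] (seed 42) and frozen as
#' FASTA fixtures. They stand in for curated clade representatives, which
#' users can substitute with their own reference FASTA files.
#'
#' @return List of tibbles `group_I` and `group_II` (`id`, `sequence`).
#' @export
paralog_reference_sets <- function() {
  list(
    group_I = read_protein_fasta(nth_extdata("synthetic_refs_group_I.fasta")) |>
      select("id", "sequence"),
    group_II = read_protein_fasta(nth_extdata("synthetic_refs_group_II.fasta")) |>
      select("id", "sequence")
  )
}
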