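# Loaders for the small published-data fixtures shipped with the package:
# a screening panel of 27 collagen-derived candidate peptides (classifier
# votes plus CDOCKER energies against ACE, with the lisinopril positive
# control), and the eight printed top-10 hub-gene columns of the matching
# network-pharmacology analysis.

#' Bundled candidate screening panel
#'
#' 27 collagen-derived candidate peptides with their three classifier votes
#' (logistic regression, SVM, MLP; raw server labels) and docking energies
#' (-CE, -CIE in kcal/mol) against ACE.
#'
#' @return Data frame: `sequence`, `lr`, `svm`, `mlp`, `cdocker_energy`,
#'   `cdocker_interaction`.
#' @export
default_candidate_panel <- function() {
  utils::read.delim(system.file("extdata", "candidate_panel.tsv",
                                package = "pepprospect"),
                    stringsAsFactors = FALSE)
}

#' Bundled reference docking ligand (lisinopril)
#'
#' @return A [reference_ligand()] for the lisinopril positive control
#'   (-CE 93.7579, -CIE 103.348 kcal/mol).
#' @export
default_reference_ligand <- function() {
  tab <- utils::read.delim(system.file("extdata", "reference_ligand.tsv",
                                       package = "pepprospect"),
                           stringsAsFactors = FALSE)
  reference_ligand(tab$name[1], tab$cdocker_energy[1],
                   tab$cdocker_interaction[1])
}

#' Read ranked hub columns from a TSV
#'
#' The TSV has columns `method`, `rank`, `gene`; each method's genes are
#' returned in rank order, ready for [consensus_hubs()].
#'
#' @param path TSV path; default: the bundled eight top-10 hub columns.
#' @return Named list of character vectors, one per method.
#' @export
load_rank_columns <- function(path = system.file("extdata",
                                                 "hub_rankings.tsv",
                                                 package = "pepprospect")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("method", "rank", "gene")
  if (!all(need %in% names(tab))) {
    stop("rank table needs columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[order(tab$method, tab$rank), , drop = FALSE]
  split(tab$gene, tab$method)
}
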