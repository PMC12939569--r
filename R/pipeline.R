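# End-to-end workflow: digest -> profile -> screen -> property panel, with a
# combined machine-readable report. TSV is the interchange format at every
# stage boundary so real tool exports (toxicity/allergenicity predictors,
# activity classifiers, docking runs, interaction databases) can be spliced
# in for any synthetic table.

#' Run the full prospecting pipeline
#'
#' Loads chains, trims signal peptides, digests with the selected enzyme
#' cocktail, profiles the hydrolysate against the reference database, screens
#' the released peptides through the filter cascade, and computes the
#' physicochemical panel for the survivors.
#'
#' @param chains_fa FASTA of protein chains.
#' @param signals_tsv Optional signal-annotation TSV (`chain_id`,
#'   `signal_end`).
#' @param refdb_tsv Reference peptide TSV (default: bundled snapshot).
#' @param enzymes Character vector of enzyme names from the rule table.
#' @param rules_yaml Enzyme rule YAML (default: bundled table).
#' @param stoichiometry Optional named copy-number vector by chain id.
#' @param activity Activity label to screen for.
#' @param annotations Named list of annotation tables/paths for the cascade
#'   (see [run_cascade()]).
#' @param reference A [reference_ligand()] for docking selection (required
#'   when `annotations$docking` is given).
#' @param strict Safety policy for unannotated candidates.
#' @param out_dir Optional directory; when given, writes `digest.tsv`,
#'   `profile.tsv`, `cascade_log.tsv`, `panel.tsv` and `report.json`.
#' @return A list report: `chains` (summary), `digest` (per-chain d, D, DH_T,
#'   fragment counts, length distribution), `dh_weighted`, `release_A`
#'   (per chain and weighted), `cascade` (stage counts, survivors),
#'   `panel` (property data frame).
#' @export
run_pipeline <- function(chains_fa, signals_tsv = NULL, refdb_tsv = NULL,
                         enzymes, rules_yaml = NULL,
                         stoichiometry = NULL, activity = "ACE inhibitor",
                         annotations = list(), reference = NULL,
                         strict = TRUE, out_dir = NULL) {
  chains <- load_fasta(chains_fa)
  if (!is.null(signals_tsv)) chains <- apply_signal_annotations(chains, signals_tsv)
  if (!is.null(stoichiometry)) chains <- set_stoichiometry(chains, stoichiometry)
  db <- if (is.null(refdb_tsv)) default_refdb() else load_refdb(refdb_tsv)
  rules <- if (is.null(rules_yaml)) default_enzymes() else compile_rules(rules_yaml)
  missing_enz <- setdiff(enzymes, names(rules))
  if (length(missing_enz)) {
    stop("unknown enzyme(s): ", paste(missing_enz, collapse = ", "),
         "; rule table has: ", paste(names(rules), collapse = ", "))
  }

  results <- lapply(chains, digest, rules = rules[enzymes])
  copies <- vapply(chains, `[[`, integer(1), "copy_number")
  rel <- lapply(results, release_frequency, db = db, activity = activity)
  digest_summary <- data.frame(
    chain_id = names(chains),
    d = vapply(results, `[[`, integer(1), "d"),
    D = vapply(results, `[[`, integer(1), "D"),
    DH_T = vapply(results, function(r) r$d / r$D * 100, numeric(1)),
    n_fragments = vapply(results, function(r) nrow(r$fragments), integer(1)),
    n_distinct = vapply(results, function(r) length(distinct_fragments(r)),
                        integer(1)),
    A = vapply(rel, `[[`, numeric(1), "A"),
    stringsAsFactors = FALSE, row.names = NULL)

  candidates <- unique(unlist(lapply(results, distinct_fragments,
                                     min_length = 2L)))
  cascade <- run_cascade(candidate_set(candidates), db, activity,
                         annotations = annotations, reference = reference,
                         strict = strict)
  panel <- if (nrow(cascade$survivors) > 0L) {
    property_panel(cascade$survivors$sequence)
  } else {
    property_panel(character(0))
  }

  report <- list(
    chains = chain_summary(chains),
    digest = digest_summary,
    length_distribution = lapply(stats::setNames(results, names(chains)),
                                 length_distribution),
    dh_weighted = degree_of_hydrolysis(unname(results), copies),
    release_A_weighted = weighted_profile(rel, copies),
    cascade = list(counts = cascade$counts,
                   survivors = cascade$survivors),
    panel = panel
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_digest_tsv(unname(results), file.path(out_dir, "digest.tsv"))
    utils::write.table(digest_summary, file.path(out_dir, "profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cascade$log, file.path(out_dir, "cascade_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(panel, file.path(out_dir, "panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}
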