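# Candidate filter cascade: novelty -> toxicity/allergenicity -> activity
# votes -> docking energy versus a reference ligand. Every record keeps a
# full per-stage audit trail; rejected records are retained (not dropped) so
# each input sequence ends in exactly one terminal state.

.TOX_LEVELS <- c("toxic", "non-toxic", "unannotated")
.ALG_LEVELS <- c("allergenic", "non-allergenic", "unannotated")
.VOTE_LEVELS <- c("high", "low_non")

#' Default controlled-vocabulary mapping for external tool labels
#'
#' Maps the labels printed by common annotation servers onto the package's
#' controlled vocabulary. Users splice in their own mapping when their tool
#' export uses different strings.
#'
#' @return Named character vector (external label -> internal label).
#' @export
default_vocab <- function() {
  c("toxic" = "toxic", "non-toxic" = "non-toxic", "non toxic" = "non-toxic",
    "allergenic" = "allergenic", "non-allergenic" = "non-allergenic",
    "no evidence" = "non-allergenic",
    "high" = "high", "high activity" = "high",
    "low_non" = "low_non", "low & non-activity" = "low_non",
    "low and non-activity" = "low_non")
}

#' Create a candidate set
#'
#' @param sequences Character vector of candidate peptides (length >= 2
#'   residues; free amino acids are excluded from screening). Duplicates are
#'   collapsed.
#' @param origins Optional data frame `sequence`, `chain_id`, `start`, `end`,
#'   `enzymes` recording where each peptide was released.
#' @return An object of class `candidate_set` holding the record table and an
#'   empty stage log.
#' @export
candidate_set <- function(sequences, origins = NULL) {
  sequences <- toupper(unique(as.character(sequences)))
  if (length(sequences) == 0L) {
    records <- data.frame(sequence = character(0), stringsAsFactors = FALSE)
  } else {
    short <- sequences[nchar(sequences) < 2L]
    if (length(short)) {
      stop("candidate(s) shorter than 2 residues: ",
           paste(short, collapse = ", "))
    }
    for (s in sequences) {
      bad <- .bad_residue_at(s, allow_x = TRUE)
      if (bad > 0L) stop("invalid residue in candidate '", s, "'")
    }
    records <- data.frame(sequence = sequences, stringsAsFactors = FALSE)
  }
  n <- nrow(records)
  records$is_novel <- rep(NA, n)
  records$toxicity <- rep("unannotated", n)
  records$allergenicity <- rep("unannotated", n)
  records$vote_lr <- rep(NA_character_, n)
  records$vote_svm <- rep(NA_character_, n)
  records$vote_mlp <- rep(NA_character_, n)
  records$cdocker_energy <- rep(NA_real_, n)
  records$cdocker_interaction <- rep(NA_real_, n)
  records$status <- rep("active", n)
  structure(list(records = records, log = .empty_log(), origins = origins),
            class = "candidate_set")
}

.empty_log <- function() {
  data.frame(sequence = character(0), stage = character(0),
             decision = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set>", nrow(x$records), "record(s);",
      sum(x$records$status == "active"), "active\n")
  invisible(x)
}

#' Active (not yet rejected) candidate sequences
#'
#' @param candidates A `candidate_set`.
#' @return Character vector.
#' @export
passing <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_set"))
  candidates$records$sequence[candidates$records$status == "active"]
}

.append_log <- function(candidates, sequence, stage, decision, reason) {
  if (length(sequence) == 0L) return(candidates)
  candidates$log <- rbind(candidates$log, data.frame(
    sequence = sequence, stage = stage, decision = decision, reason = reason,
    stringsAsFactors = FALSE))
  candidates
}

.map_vocab <- function(values, vocab, allowed, what) {
  v <- tolower(trimws(values))
  mapped <- unname(vocab[v])
  mapped[is.na(mapped) & v %in% allowed] <- v[is.na(mapped) & v %in% allowed]
  bad <- which(is.na(mapped) | !mapped %in% allowed)
  if (length(bad)) {
    stop(what, ": unknown label '", values[bad[1]], "' at row ", bad[1],
         " (allowed after mapping: ", paste(allowed, collapse = ", "), ")")
  }
  mapped
}

#' Ingest an external annotation table
#'
#' Annotation tables are tool exports keyed by peptide sequence:
#' \describe{
#'   \item{toxicity}{columns `sequence`, `label` in \{toxic, non-toxic\}.}
#'   \item{allergenicity}{columns `sequence`, `label` in \{allergenic,
#'     non-allergenic\}.}
#'   \item{activity}{columns `sequence`, `lr`, `svm`, `mlp`, each a
#'     classifier vote in \{high, low_non\}.}
#'   \item{docking}{columns `sequence`, `cdocker_energy`,
#'     `cdocker_interaction` (negated CDOCKER energies, kcal/mol; larger
#'     means stronger predicted binding).}
#' }
#' Labels pass through the controlled-vocabulary mapping first, so raw server
#' strings like `"high activity"` are accepted. Table rows whose sequence
#' matches no candidate are reported via the `"unmatched"` attribute of the
#' return value; candidates absent from the table stay unannotated.
#'
#' @param candidates A `candidate_set`.
#' @param table Data frame or path to a TSV.
#' @param kind One of `"toxicity"`, `"allergenicity"`, `"activity"`,
#'   `"docking"`.
#' @param vocab Label mapping, see [default_vocab()].
#' @return The updated `candidate_set`.
#' @export
ingest_annotations <- function(candidates, table,
                               kind = c("toxicity", "allergenicity",
                                        "activity", "docking"),
                               vocab = default_vocab()) {
  stopifnot(inherits(candidates, "candidate_set"))
  kind <- match.arg(kind)
  if (is.character(table)) {
    table <- utils::read.delim(table, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) {
    attr(candidates, "unmatched") <- character(0)
    return(candidates)
  }
  if (!"sequence" %in% names(table)) stop("annotation table needs a 'sequence' column")
  table$sequence <- toupper(table$sequence)
  rec <- candidates$records
  idx <- match(table$sequence, rec$sequence)
  unmatched <- table$sequence[is.na(idx)]
  keep <- !is.na(idx)
  table <- table[keep, , drop = FALSE]
  idx <- idx[keep]
  if (kind == "toxicity") {
    if (!"label" %in% names(table)) stop("toxicity table needs a 'label' column")
    rec$toxicity[idx] <- .map_vocab(table$label, vocab,
                                    setdiff(.TOX_LEVELS, "unannotated"),
                                    "toxicity")
  } else if (kind == "allergenicity") {
    if (!"label" %in% names(table)) stop("allergenicity table needs a 'label' column")
    rec$allergenicity[idx] <- .map_vocab(table$label, vocab,
                                         setdiff(.ALG_LEVELS, "unannotated"),
                                         "allergenicity")
  } else if (kind == "activity") {
    need <- c("lr", "svm", "mlp")
    if (!all(need %in% names(table))) {
      stop("activity table needs columns: sequence, lr, svm, mlp")
    }
    rec$vote_lr[idx] <- .map_vocab(table$lr, vocab, .VOTE_LEVELS, "activity/lr")
    rec$vote_svm[idx] <- .map_vocab(table$svm, vocab, .VOTE_LEVELS, "activity/svm")
    rec$vote_mlp[idx] <- .map_vocab(table$mlp, vocab, .VOTE_LEVELS, "activity/mlp")
  } else {
    need <- c("cdocker_energy", "cdocker_interaction")
    if (!all(need %in% names(table))) {
      stop("docking table needs columns: sequence, cdocker_energy, cdocker_interaction")
    }
    rec$cdocker_energy[idx] <- as.numeric(table$cdocker_energy)
    rec$cdocker_interaction[idx] <- as.numeric(table$cdocker_interaction)
  }
  candidates$records <- rec
  attr(candidates, "unmatched") <- unique(unmatched)
  candidates
}

#' Reference docking ligand
#'
#' @param name Ligand name (e.g. a positive-control drug).
#' @param cdocker_energy Negated CDOCKER energy (-CE, kcal/mol).
#' @param cdocker_interaction Negated CDOCKER interaction energy (-CIE,
#'   kcal/mol).
#' @return An object of class `reference_ligand`.
#' @export
reference_ligand <- function(name, cdocker_energy, cdocker_interaction) {
  stopifnot(is.numeric(cdocker_energy), is.numeric(cdocker_interaction),
            is.finite(cdocker_energy), is.finite(cdocker_interaction))
  structure(list(name = name, cdocker_energy = cdocker_energy,
                 cdocker_interaction = cdocker_interaction),
            class = "reference_ligand")
}

#' Novelty filter
#'
#' Rejects candidates whose full sequence is already a reference peptide of
#' the given activity (known peptides need no rediscovery).
#'
#' @param candidates A `candidate_set`.
#' @param db A `reference_db`.
#' @param activity Activity label.
#' @return The updated `candidate_set`.
#' @export
novelty_filter <- function(candidates, db, activity) {
  stopifnot(inherits(candidates, "candidate_set"))
  rec <- candidates$records
  act <- rec$status == "active"
  part <- classify_known_novel(rec$sequence, db, activity)
  rec$is_novel <- !rec$sequence %in% part$known
  reject <- act & !rec$is_novel
  rec$status[reject] <- "rejected:novelty"
  candidates$records <- rec
  .append_log(candidates, rec$sequence[act], "novelty",
              ifelse(reject[act], "rejected", "kept"),
              ifelse(reject[act], "known peptide", "novel"))
}

#' Safety filter (toxicity and allergenicity)
#'
#' Keeps candidates annotated non-toxic AND non-allergenic. Unannotated
#' records are rejected under the default strict policy and kept under the
#' permissive one.
#'
#' @param candidates A `candidate_set`.
#' @param strict Reject unannotated records (default TRUE).
#' @return The updated `candidate_set`.
#' @export
safety_filter <- function(candidates, strict = TRUE) {
  stopifnot(inherits(candidates, "candidate_set"))
  rec <- candidates$records
  act <- rec$status == "active"
  reason <- rep(NA_character_, nrow(rec))
  reason[rec$toxicity == "toxic"] <- "toxicity"
  reason[is.na(reason) & rec$allergenicity == "allergenic"] <- "allergenicity"
  if (strict) {
    reason[is.na(reason) & (rec$toxicity == "unannotated" |
                            rec$allergenicity == "unannotated")] <-
      "unannotated under strict policy"
  }
  reject <- act & !is.na(reason)
  rec$status[reject] <- "rejected:safety"
  candidates$records <- rec
  .append_log(candidates, rec$sequence[act], "safety",
              ifelse(reject[act], "rejected", "kept"),
              ifelse(reject[act], reason[act], "non-toxic, non-allergenic"))
}

#' Activity-vote selection
#'
#' Keeps candidates for which at least one of the three classifier votes is
#' `"high"` (any-of-three rule). Records with no votes at all are rejected
#' with reason `"unscored"`.
#'
#' @param candidates A `candidate_set`.
#' @return The updated `candidate_set`.
#' @export
activity_select <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_set"))
  rec <- candidates$records
  act <- rec$status == "active"
  votes <- cbind(rec$vote_lr, rec$vote_svm, rec$vote_mlp)
  any_high <- apply(votes, 1, function(v) any(v == "high", na.rm = TRUE))
  unscored <- apply(votes, 1, function(v) all(is.na(v)))
  reject <- act & (!any_high | unscored)
  rec$status[reject] <- "rejected:activity"
  candidates$records <- rec
  reason <- ifelse(unscored, "unscored",
                   ifelse(any_high, "at least one high-activity vote",
                          "no high-activity vote"))
  .append_log(candidates, rec$sequence[act], "activity",
              ifelse(reject[act], "rejected", "kept"), reason[act])
}

#' Docking-energy selection against a reference ligand
#'
#' Keeps candidates whose -CE and -CIE are both strictly above the reference
#' ligand's values (larger negated CDOCKER energies mean stronger predicted
#' binding). Every active candidate must carry both energies.
#'
#' @param candidates A `candidate_set`.
#' @param reference A [reference_ligand()].
#' @return The updated `candidate_set`; survivors are readable via
#'   [docking_ranking()] sorted by -CIE descending.
#' @export
docking_select <- function(candidates, reference) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (missing(reference) || !inherits(reference, "reference_ligand")) {
    stop("a reference_ligand is required for docking selection")
  }
  rec <- candidates$records
  act <- rec$status == "active"
  if (any(act & (is.na(rec$cdocker_energy) | is.na(rec$cdocker_interaction)))) {
    miss <- rec$sequence[act & (is.na(rec$cdocker_energy) |
                                is.na(rec$cdocker_interaction))]
    stop("active candidate(s) lack docking energies: ",
         paste(miss, collapse = ", "))
  }
  pass <- rec$cdocker_energy > reference$cdocker_energy &
    rec$cdocker_interaction > reference$cdocker_interaction
  reject <- act & !pass
  rec$status[reject] <- "rejected:docking"
  candidates$records <- rec
  .append_log(candidates, rec$sequence[act], "docking",
              ifelse(reject[act], "rejected", "kept"),
              ifelse(reject[act],
                     paste0("not above ", reference$name,
                            " on both energies"),
                     paste0("-CE and -CIE above ", reference$name)))
}

#' Docking survivors ranked by interaction energy
#'
#' @param candidates A `candidate_set` after [docking_select()].
#' @return Data frame `sequence`, `cdocker_energy`, `cdocker_interaction`
#'   sorted by `cdocker_interaction` descending.
#' @export
docking_ranking <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_set"))
  rec <- candidates$records
  out <- rec[rec$status == "active",
             c("sequence", "cdocker_energy", "cdocker_interaction")]
  out <- out[order(-out$cdocker_interaction, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full screening cascade
#'
#' Stages execute in fixed order: novelty, safety, activity, docking. Stages
#' whose annotation table is `NULL` are skipped (with a note in the report),
#' so partial cascades on partially annotated data are possible.
#'
#' @param candidates A `candidate_set` (or character vector of sequences).
#' @param db A `reference_db` for the novelty stage.
#' @param activity Activity label for the novelty stage.
#' @param annotations Named list with any of `toxicity`, `allergenicity`,
#'   `activity`, `docking`: each a data frame or TSV path (see
#'   [ingest_annotations()]).
#' @param reference A [reference_ligand()]; required when a docking table is
#'   given.
#' @param strict Safety policy for unannotated records.
#' @param vocab Controlled-vocabulary mapping.
#' @return A `cascade_report`: list with `candidates` (final
#'   `candidate_set`), `counts` (data frame stage, n_in, n_out), `survivors`
#'   (ranked docking survivors or active sequences), and `log`.
#' @export
run_cascade <- function(candidates, db, activity = "ACE inhibitor",
                        annotations = list(), reference = NULL,
                        strict = TRUE, vocab = default_vocab()) {
  if (!inherits(candidates, "candidate_set")) {
    candidates <- candidate_set(candidates)
  }
  for (kind in c("toxicity", "allergenicity", "activity", "docking")) {
    if (!is.null(annotations[[kind]])) {
      candidates <- ingest_annotations(candidates, annotations[[kind]], kind,
                                       vocab = vocab)
    }
  }
  counts <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), stringsAsFactors = FALSE)
  tick <- function(stage, n_in, cs) {
    rbind(counts, data.frame(stage = stage, n_in = n_in,
                             n_out = length(passing(cs)),
                             stringsAsFactors = FALSE))
  }
  n_in <- length(passing(candidates))
  candidates <- novelty_filter(candidates, db, activity)
  counts <- tick("novelty", n_in, candidates)

  n_in <- length(passing(candidates))
  candidates <- safety_filter(candidates, strict = strict)
  counts <- tick("safety", n_in, candidates)

  n_in <- length(passing(candidates))
  candidates <- activity_select(candidates)
  counts <- tick("activity", n_in, candidates)

  if (!is.null(annotations$docking)) {
    n_in <- length(passing(candidates))
    candidates <- docking_select(candidates, reference)
    counts <- tick("docking", n_in, candidates)
    survivors <- docking_ranking(candidates)
  } else {
    survivors <- data.frame(sequence = passing(candidates),
                            stringsAsFactors = FALSE)
  }
  structure(list(candidates = candidates, counts = counts,
                 survivors = survivors, log = candidates$log),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  print(x$counts, row.names = FALSE)
  cat("survivors:", paste(x$survivors$sequence, collapse = ", "), "\n")
  invisible(x)
}
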