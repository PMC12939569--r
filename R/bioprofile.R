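# Reference-peptide database and bioactive-fragment frequency profiling.
#
# The occurrence frequency A = a / N (a: bioactive fragments found in, or
# released from, a protein; N: its residue count) is the standard
# BIOPEP-style statistic for judging a protein as a bioactive-peptide
# precursor and for scoring simulated hydrolysates.

#' Build a reference peptide database
#'
#' @param peptides Data frame with columns `sequence`, `activity`, and
#'   optionally `ic50_um` (positive, micromolar) and `source`. Sequences are
#'   uppercased and validated (length >= 2, no `'X'`); duplicate
#'   (sequence, activity) pairs are dropped with a warning.
#' @return An object of class `reference_db`.
#' @export
reference_db <- function(peptides) {
  stopifnot(is.data.frame(peptides))
  need <- c("sequence", "activity")
  if (!all(need %in% names(peptides))) {
    stop("reference table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(peptides) == 0L) stop("reference table is empty")
  if (is.null(peptides$ic50_um)) peptides$ic50_um <- NA_real_
  if (is.null(peptides$source)) peptides$source <- ""
  peptides$sequence <- toupper(peptides$sequence)
  peptides$ic50_um <- suppressWarnings(as.numeric(peptides$ic50_um))
  for (i in seq_len(nrow(peptides))) {
    s <- peptides$sequence[i]
    if (nchar(s) < 2L) {
      stop("row ", i, ": reference peptide '", s, "' is shorter than 2 residues")
    }
    bad <- .bad_residue_at(s, allow_x = FALSE)
    if (bad > 0L) {
      stop("row ", i, ": invalid residue '", substr(s, bad, bad),
           "' in reference peptide '", s, "'")
    }
    if (!is.na(peptides$ic50_um[i]) && peptides$ic50_um[i] <= 0) {
      stop("row ", i, ": ic50_um must be positive")
    }
  }
  key <- paste(peptides$sequence, peptides$activity, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(peptides$sequence[duplicated(key)])
    warning("dropping duplicate (sequence, activity) pair(s): ",
            paste(dups, collapse = ", "))
    peptides <- peptides[!duplicated(key), , drop = FALSE]
  }
  rownames(peptides) <- NULL
  structure(list(peptides = peptides), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db>", nrow(x$peptides), "peptide(s),",
      length(unique(x$peptides$activity)), "activity class(es)\n")
  invisible(x)
}

#' Load a reference peptide database from TSV
#'
#' Expected columns: `sequence`, `activity`, `ic50_um` (may be empty),
#' `source`. The bundled ACE-inhibitor snapshot is at
#' `system.file("extdata", "ace_refdb.tsv", package = "pepprospect")`.
#'
#' @param path Path to the TSV.
#' @return A `reference_db`.
#' @export
load_refdb <- function(path) {
  if (!file.exists(path)) stop("reference DB file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (nrow(tab) == 0L) stop("reference DB is empty: ", path)
  reference_db(tab)
}

#' The bundled ACE-inhibitor reference snapshot
#'
#' @return A `reference_db` of known ACE-inhibitory peptides found in
#'   collagen hydrolysates (database-verified di-/tripeptides plus
#'   literature-reported sequences with IC50 where published).
#' @export
default_refdb <- function() {
  load_refdb(system.file("extdata", "ace_refdb.tsv", package = "pepprospect"))
}

.db_activities <- function(db) sort(unique(db$peptides$activity))

.db_sequences <- function(db, activity) {
  if (!activity %in% db$peptides$activity) {
    stop("unknown activity label '", activity, "'; available: ",
         paste(.db_activities(db), collapse = ", "))
  }
  unique(db$peptides$sequence[db$peptides$activity == activity])
}

#' Occurrence-frequency profile of a precursor chain
#'
#' Counts occurrences of every reference peptide of the given activity as a
#' substring of the chain and reports `A = a / N` with `N` the chain length.
#' By default every positional occurrence is counted and overlapping matches
#' are allowed (`overlapping = FALSE` counts non-overlapping occurrences per
#' peptide, greedily left to right). `'X'` residues in the chain match
#' nothing.
#'
#' @param chain A mature `protein_chain`.
#' @param db A `reference_db`.
#' @param activity Activity label to profile.
#' @param overlapping Count overlapping positional occurrences (default TRUE).
#' @return An `activity_profile`: list with `activity`, `chain_id`, `a`, `N`,
#'   `A` (exactly `a / N`).
#' @export
occurrence_profile <- function(chain, db, activity, overlapping = TRUE) {
  stopifnot(inherits(chain, "protein_chain"), inherits(db, "reference_db"))
  pats <- .db_sequences(db, activity)
  subject <- Biostrings::BString(chain$residues)
  a <- 0L
  for (p in pats) {
    if (nchar(p) > nchar(chain$residues)) next
    m <- Biostrings::matchPattern(p, subject)  # reports overlapping matches
    if (overlapping) {
      a <- a + length(m)
    } else {
      # greedy left-to-right non-overlapping count
      ends <- 0L
      st <- Biostrings::start(m)
      for (s in st) {
        if (s > ends) { a <- a + 1L; ends <- s + nchar(p) - 1L }
      }
    }
  }
  structure(list(activity = activity, chain_id = chain$id, a = as.integer(a),
                 N = nchar(chain$residues), A = a / nchar(chain$residues)),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat("<activity_profile> ", x$chain_id, " [", x$activity, "]: a=", x$a,
      ", N=", x$N, ", A=", format(x$A, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Release-frequency profile of a hydrolysate
#'
#' Counts released fragments whose full sequence is a reference peptide of
#' the given activity; a fragment released twice counts twice. `A = a / N`
#' with `N` the mature chain length.
#'
#' @param result A `digest_result`.
#' @param db A `reference_db`.
#' @param activity Activity label.
#' @return An `activity_profile`.
#' @export
release_frequency <- function(result, db, activity) {
  stopifnot(inherits(result, "digest_result"), inherits(db, "reference_db"))
  pats <- .db_sequences(db, activity)
  a <- sum(result$fragments$sequence %in% pats)
  structure(list(activity = activity, chain_id = result$chain_id,
                 a = as.integer(a), N = result$chain_length,
                 A = a / result$chain_length),
            class = "activity_profile")
}

#' Copy-number-weighted pooled A value
#'
#' Type I collagen carries two alpha-1 chains per alpha-2 chain, so pooled
#' frequencies weight the per-chain values 2:1.
#'
#' @param profiles List of `activity_profile`, one per chain.
#' @param copies Numeric copy numbers, either unnamed in profile order or
#'   named by chain id.
#' @return Weighted mean of the per-chain `A` values.
#' @export
weighted_profile <- function(profiles, copies) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  ok <- vapply(profiles, inherits, logical(1), "activity_profile")
  if (!all(ok)) stop("profiles must be activity_profile objects")
  ids <- vapply(profiles, `[[`, character(1), "chain_id")
  if (anyDuplicated(ids)) stop("multiple profiles for one chain")
  if (!is.null(names(copies)) && all(nzchar(names(copies)))) {
    if (!all(ids %in% names(copies))) {
      stop("copies must cover every profiled chain id")
    }
    copies <- copies[ids]
  } else if (length(copies) != length(profiles)) {
    stop("copies must match the number of profiles")
  }
  A <- vapply(profiles, `[[`, numeric(1), "A")
  sum(A * as.numeric(copies)) / sum(as.numeric(copies))
}

#' Partition fragments into known and novel peptides
#'
#' Known means an exact full-sequence match to a reference peptide of the
#' given activity; everything else is novel. The partition is exhaustive and
#' disjoint.
#'
#' @param fragments Character vector of peptide sequences.
#' @param db A `reference_db`.
#' @param activity Activity label.
#' @return List with character vectors `known` and `novel`.
#' @export
classify_known_novel <- function(fragments, db, activity) {
  stopifnot(inherits(db, "reference_db"))
  if (length(fragments) == 0L) return(list(known = character(0),
                                           novel = character(0)))
  pats <- .db_sequences(db, activity)
  hit <- fragments %in% pats
  list(known = fragments[hit], novel = fragments[!hit])
}

#' Profile report over chains and activities
#'
#' @param chains A mature `chain_set`.
#' @param db A `reference_db`.
#' @param activities Activity labels (default: all in the DB).
#' @return Data frame: activity, chain_id, a, N, A, weighted_A (repeated per
#'   activity across its chains).
#' @export
profile_report <- function(chains, db, activities = NULL) {
  stopifnot(inherits(chains, "chain_set"))
  if (is.null(activities)) activities <- .db_activities(db)
  copies <- vapply(chains, `[[`, integer(1), "copy_number")
  rows <- lapply(activities, function(act) {
    profs <- lapply(chains, occurrence_profile, db = db, activity = act)
    wA <- weighted_profile(profs, copies)
    data.frame(activity = act, chain_id = names(chains),
               a = vapply(profs, `[[`, integer(1), "a"),
               N = vapply(profs, `[[`, integer(1), "N"),
               A = vapply(profs, `[[`, numeric(1), "A"),
               weighted_A = wA, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
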