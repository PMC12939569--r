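# Protein-chain model: loading, validation, signal-peptide trimming and
# chain-stoichiometry bookkeeping. Coordinates facing the user are 1-based
# inclusive; digestion-internal bond indices are 0-based (see digestion.R).

#' Construct a protein chain
#'
#' A `protein_chain` holds one collagen alpha-chain (or any protein): its id,
#' residue string, an optional signal-peptide annotation and a stoichiometric
#' copy number. Type I collagen assembles as two alpha-1 chains and one
#' alpha-2 chain, so pooled statistics weight the alpha-1 chain with
#' `copy_number = 2`.
#'
#' @param id Chain identifier (e.g. a UniProt accession). Non-empty string.
#' @param residues Residue string over the 20 amino-acid one-letter codes
#'   plus `"X"` (unknown). Lowercase input is uppercased.
#' @param signal_end Optional 1-based position of the last signal-peptide
#'   residue; must satisfy `0 < signal_end < nchar(residues)`.
#' @param copy_number Positive integer stoichiometric multiplicity.
#' @return An object of class `protein_chain`.
#' @export
protein_chain <- function(id, residues, signal_end = NULL, copy_number = 1L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) {
    stop("chain '", id, "': residue string is empty")
  }
  bad <- .bad_residue_at(residues)
  if (bad > 0L) {
    stop("chain '", id, "': invalid residue '",
         substr(residues, bad, bad), "' at position ", bad)
  }
  if (!is.null(signal_end)) {
    signal_end <- as.integer(signal_end)
    if (is.na(signal_end) || signal_end <= 0L || signal_end >= nchar(residues)) {
      stop("chain '", id, "': signal_end must satisfy 0 < signal_end < length (",
           nchar(residues), "), got ", signal_end)
    }
  }
  copy_number <- as.integer(copy_number)
  if (is.na(copy_number) || copy_number < 1L) {
    stop("chain '", id, "': copy_number must be a positive integer")
  }
  structure(
    list(id = id, residues = residues, signal_end = signal_end,
         copy_number = copy_number),
    class = "protein_chain"
  )
}

#' @export
print.protein_chain <- function(x, ...) {
  cat("<protein_chain> ", x$id, ": ", nchar(x$residues), " aa",
      if (!is.null(x$signal_end)) paste0(", signal 1-", x$signal_end),
      ", copies ", x$copy_number, "\n", sep = "")
  invisible(x)
}

#' Construct a chain set
#'
#' An ordered collection of [protein_chain()] objects with unique ids.
#'
#' @param chains List of `protein_chain` objects.
#' @return An object of class `chain_set` (a named list of chains).
#' @export
chain_set <- function(chains) {
  stopifnot(is.list(chains), length(chains) > 0L)
  ok <- vapply(chains, inherits, logical(1), "protein_chain")
  if (!all(ok)) stop("all elements must be protein_chain objects")
  ids <- vapply(chains, `[[`, character(1), "id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate chain id(s): ", paste(unique(dup), collapse = ", "))
  }
  names(chains) <- ids
  structure(chains, class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat("<chain_set> of", length(x), "chain(s)\n")
  for (ch in x) print(ch)
  invisible(x)
}

#' Load protein chains from a FASTA file
#'
#' Reads every record of a FASTA file into a [chain_set()]. Ids are taken
#' from the header up to the first whitespace; residues are uppercased and
#' validated against [AA_ALPHABET]. All copy numbers default to 1 and can be
#' reassigned afterwards (see [set_stoichiometry()]).
#'
#' @param path Path to a FASTA file.
#' @return A `chain_set`.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  chains <- lapply(seq_along(seqs), function(i) {
    protein_chain(ids[i], as.character(seqs[[i]]))
  })
  chain_set(chains)
}

#' Write a chain set to FASTA
#'
#' @param chains A `chain_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chains, path) {
  stopifnot(inherits(chains, "chain_set"))
  res <- vapply(chains, `[[`, character(1), "residues")
  x <- Biostrings::BStringSet(res)
  names(x) <- names(chains)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Remove an annotated signal peptide from a chain
#'
#' Collagen alpha-chains carry an N-terminal export signal that is absent
#' from the secreted protein; analyses run on the mature chain. The cleavage
#' position comes from an external predictor's annotation (e.g. a
#' SignalP-style export), not from this package.
#'
#' @param chain A `protein_chain`.
#' @param signal_end 1-based position of the last signal-peptide residue. If
#'   omitted, the chain's own `signal_end` annotation is used.
#' @return The mature `protein_chain`: residues `signal_end+1 .. length`,
#'   same id and copy number, `signal_end` cleared.
#' @export
trim_signal <- function(chain, signal_end = NULL) {
  stopifnot(inherits(chain, "protein_chain"))
  if (is.null(signal_end)) signal_end <- chain$signal_end
  if (is.null(signal_end)) {
    stop("chain '", chain$id, "': no signal_end supplied or annotated")
  }
  signal_end <- as.integer(signal_end)
  n <- nchar(chain$residues)
  if (is.na(signal_end) || signal_end < 1L || signal_end >= n) {
    stop("chain '", chain$id, "': signal_end must satisfy 1 <= signal_end < ",
         n, ", got ", signal_end)
  }
  protein_chain(chain$id, substr(chain$residues, signal_end + 1L, n),
                signal_end = NULL, copy_number = chain$copy_number)
}

#' Read a signal-peptide annotation table and trim a chain set
#'
#' The table is a two-column TSV (`chain_id`, `signal_end`) matching what a
#' signal-peptide predictor exports. Chains absent from the table are left
#' untouched; `signal_end = 0` means "no signal peptide".
#'
#' @param chains A `chain_set`.
#' @param path Path to the TSV.
#' @return The trimmed `chain_set`.
#' @export
apply_signal_annotations <- function(chains, path) {
  stopifnot(inherits(chains, "chain_set"))
  if (!file.exists(path)) stop("signal annotation file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chain_id", "signal_end")
  if (!all(need %in% names(tab))) {
    stop("signal annotation TSV must have columns: ",
         paste(need, collapse = ", "))
  }
  unknown <- setdiff(tab$chain_id, names(chains))
  if (length(unknown)) {
    stop("signal annotations for unknown chain(s): ",
         paste(unknown, collapse = ", "))
  }
  out <- unclass(chains)
  for (i in seq_len(nrow(tab))) {
    id <- tab$chain_id[i]
    s <- as.integer(tab$signal_end[i])
    if (is.na(s)) stop("row ", i, ": signal_end is not an integer")
    if (s > 0L) out[[id]] <- trim_signal(out[[id]], s)
  }
  chain_set(out)
}

#' Assign stoichiometric copy numbers
#'
#' @param chains A `chain_set`.
#' @param copies Named integer vector, names are chain ids. E.g.
#'   `c(alpha1 = 2, alpha2 = 1)` for type I collagen.
#' @return The updated `chain_set`.
#' @export
set_stoichiometry <- function(chains, copies) {
  stopifnot(inherits(chains, "chain_set"))
  unknown <- setdiff(names(copies), names(chains))
  if (length(unknown)) {
    stop("copy numbers for unknown chain(s): ", paste(unknown, collapse = ", "))
  }
  out <- unclass(chains)
  for (id in names(copies)) {
    ch <- out[[id]]
    out[[id]] <- protein_chain(ch$id, ch$residues, ch$signal_end,
                               as.integer(copies[[id]]))
  }
  chain_set(out)
}

#' Summarise a chain set
#'
#' @param chains A `chain_set`.
#' @return Data frame with one row per chain: id, length, signal_end (NA when
#'   absent), copy_number, n_unknown ('X' count).
#' @export
chain_summary <- function(chains) {
  stopifnot(inherits(chains, "chain_set"))
  data.frame(
    id = names(chains),
    length = vapply(chains, function(c) nchar(c$residues), integer(1)),
    signal_end = vapply(chains, function(c)
      if (is.null(c$signal_end)) NA_integer_ else c$signal_end, integer(1)),
    copy_number = vapply(chains, `[[`, integer(1), "copy_number"),
    n_unknown = vapply(chains, function(c)
      sum(strsplit(c$residues, "")[[1]] == "X"), integer(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
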