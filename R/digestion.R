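# Simulated proteolysis under a cleavage-specificity rule grammar.
#
# A bond is indexed 0-based: bond i sits between residues i and i+1 (0-based
# residue indices), so a chain of length n has D = n - 1 bonds. A cleavage
# spec constrains up to four context positions around bond i:
#   P2 = residue i-1, P1 = residue i, P1' = residue i+1, P2' = residue i+2.
# A spec matches when every constrained position exists and carries a residue
# from the constrained set; a bond is cleaved when some spec matches and no
# exception spec matches. Bonds whose P1 or P1' residue is 'X' are never
# cleaved.

.SPEC_POSITIONS <- c("p2", "p1", "p1prime", "p2prime")

.validate_spec <- function(spec, where) {
  if (!is.list(spec)) stop(where, ": cleavage spec must be a mapping")
  extra <- setdiff(names(spec), .SPEC_POSITIONS)
  if (length(extra)) {
    stop(where, ": unknown spec position(s): ", paste(extra, collapse = ", "),
         " (allowed: ", paste(.SPEC_POSITIONS, collapse = ", "), ")")
  }
  spec <- spec[intersect(.SPEC_POSITIONS, names(spec))]
  sets <- Filter(Negate(is.null), spec)
  if (length(sets) == 0L || all(lengths(sets) == 0L)) {
    stop(where, ": spec constrains no position")
  }
  for (pos in names(sets)) {
    set <- toupper(as.character(sets[[pos]]))
    bad <- setdiff(set, setdiff(AA_ALPHABET, "X"))
    if (length(bad)) {
      stop(where, ", position ", pos, ": invalid residue(s) ",
           paste(bad, collapse = ", "))
    }
    spec[[pos]] <- set
  }
  spec
}

#' Construct an enzyme cleavage rule
#'
#' @param name Enzyme name, unique within a rule table.
#' @param ec EC number string (may be `""` for unofficial rules).
#' @param specs List of cleavage specs. Each spec is a list with any of the
#'   elements `p2`, `p1`, `p1prime`, `p2prime`, each a character vector of
#'   allowed residues at that context position.
#' @param exceptions List of specs; a bond matching any exception is not
#'   cleaved even if a spec matches (e.g. trypsin's "not before proline").
#' @param source Free-text provenance note for the encoding.
#' @return An object of class `enzyme_rule`.
#' @export
enzyme_rule <- function(name, ec = "", specs, exceptions = list(), source = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.list(specs) || length(specs) == 0L) {
    stop("enzyme '", name, "': at least one cleavage spec is required")
  }
  specs <- lapply(seq_along(specs), function(i)
    .validate_spec(specs[[i]], paste0("enzyme '", name, "', spec ", i)))
  exceptions <- lapply(seq_along(exceptions), function(i)
    .validate_spec(exceptions[[i]], paste0("enzyme '", name, "', exception ", i)))
  structure(list(name = name, ec = ec, specs = specs,
                 exceptions = exceptions, source = source),
            class = "enzyme_rule")
}

#' @export
print.enzyme_rule <- function(x, ...) {
  cat("<enzyme_rule>", x$name,
      if (nzchar(x$ec)) paste0("(EC ", x$ec, ")"),
      "-", length(x$specs), "spec(s),",
      length(x$exceptions), "exception(s)\n")
  invisible(x)
}

#' Compile an enzyme rule table from YAML
#'
#' The YAML has a single top-level key `enzymes`, a list of entries with
#' `name`, optional `ec` and `source`, a list `specs` and an optional list
#' `exceptions`; each spec maps context positions (`p2`, `p1`, `p1prime`,
#' `p2prime`) to residue lists. The bundled table is at
#' `system.file("extdata", "enzymes.yaml", package = "pepprospect")` and is
#' deliberately user-editable: published cleavage-rule encodings differ
#' between databases, and fragment-level results are sensitive to them.
#'
#' @param path Path to the YAML rule file.
#' @return Named list of [enzyme_rule()] objects, class `enzyme_table`.
#' @export
compile_rules <- function(path) {
  if (!file.exists(path)) stop("rule file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$enzymes) || length(doc$enzymes) == 0L) {
    stop("rule file has no 'enzymes' entries: ", path)
  }
  rules <- lapply(doc$enzymes, function(e) {
    if (is.null(e$name)) stop("rule file entry without a name")
    enzyme_rule(e$name, ec = e$ec %||% "",
                specs = .as_spec_list(e$specs, e$name),
                exceptions = .as_spec_list(e$exceptions %||% list(), e$name),
                source = e$source %||% "")
  })
  nm <- vapply(rules, `[[`, character(1), "name")
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) stop("duplicate enzyme name(s): ", paste(dup, collapse = ", "))
  names(rules) <- nm
  structure(rules, class = "enzyme_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_spec_list <- function(x, enzyme) {
  if (is.null(x)) return(list())
  if (!is.list(x)) stop("enzyme '", enzyme, "': specs must be a list")
  # a bare mapping (single spec) is tolerated
  if (length(x) && !is.null(names(x)) && any(names(x) %in% .SPEC_POSITIONS)) {
    x <- list(x)
  }
  x
}

#' The bundled enzyme rule table
#'
#' Convenience wrapper compiling the rule table shipped with the package
#' (papain, ficin, stem bromelain, calpain 2, pancreatic elastase, trypsin,
#' chymotrypsin A). The encodings are approximations from the protease
#' specificity literature; see the YAML file's comments.
#'
#' @return An `enzyme_table`.
#' @export
default_enzymes <- function() {
  compile_rules(system.file("extdata", "enzymes.yaml", package = "pepprospect"))
}

# internal: does `spec` match bond `i` (0-based) of residue vector `chars`?
# Vectorised over a bond index vector.
.spec_matches <- function(spec, chars, bonds) {
  n <- length(chars)
  ok <- rep(TRUE, length(bonds))
  offs <- c(p2 = -1L, p1 = 0L, p1prime = 1L, p2prime = 2L)
  for (pos in names(offs)) {
    set <- spec[[pos]]
    if (is.null(set) || length(set) == 0L) next
    ridx <- bonds + offs[[pos]] + 1L  # to 1-based residue index
    inrange <- ridx >= 1L & ridx <= n
    hit <- inrange
    hit[inrange] <- chars[ridx[inrange]] %in% set
    ok <- ok & hit
  }
  ok
}

#' Cleavage sites of one enzyme on a mature chain
#'
#' @param chain A mature `protein_chain` (signal peptide already removed;
#'   a chain still carrying a `signal_end` annotation is an error).
#' @param rule An `enzyme_rule`.
#' @return Sorted integer vector of 0-based bond indices.
#' @export
cleavage_sites <- function(chain, rule) {
  stopifnot(inherits(chain, "protein_chain"), inherits(rule, "enzyme_rule"))
  if (!is.null(chain$signal_end)) {
    stop("chain '", chain$id,
         "' still carries a signal-peptide annotation; trim_signal() first")
  }
  chars <- strsplit(chain$residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  bonds <- 0:(n - 2L)
  hit <- rep(FALSE, length(bonds))
  for (spec in rule$specs) hit <- hit | .spec_matches(spec, chars, bonds)
  for (exc in rule$exceptions) hit <- hit & !.spec_matches(exc, chars, bonds)
  # unknown residues block cleavage of their bonds
  hit <- hit & chars[bonds + 1L] != "X" & chars[bonds + 2L] != "X"
  bonds[hit]
}

#' Digest a chain with one or more enzymes acting simultaneously
#'
#' Multi-enzyme digestion takes the union of the per-enzyme cleavage-site
#' sets (all enzymes present in the same reaction), then cuts the chain into
#' maximal fragments between consecutive sites.
#'
#' @param chain A mature `protein_chain`.
#' @param rules A single `enzyme_rule`, a list of them, or an `enzyme_table`.
#' @return An object of class `digest_result`: `chain_id`, sorted 0-based
#'   `sites`, `d` (number of cleaved bonds), `D` (total bonds = length - 1),
#'   `fragments` (data frame `sequence`, `start`, `end`; 1-based inclusive),
#'   `enzymes`, `chain_length`, `copy_number`.
#' @export
digest <- function(chain, rules) {
  stopifnot(inherits(chain, "protein_chain"))
  if (inherits(rules, "enzyme_rule")) rules <- list(rules)
  rules <- unclass(rules)
  if (!is.list(rules) || length(rules) == 0L) {
    stop("at least one enzyme rule is required")
  }
  sites <- sort(unique(unlist(lapply(rules, cleavage_sites, chain = chain))))
  sites <- as.integer(sites)
  n <- nchar(chain$residues)
  starts <- c(1L, sites + 2L)          # bond i cuts between 1-based i+1 | i+2
  ends <- c(sites + 1L, n)
  frags <- data.frame(
    sequence = substring(chain$residues, starts, ends),
    start = starts, end = ends, stringsAsFactors = FALSE
  )
  structure(
    list(chain_id = chain$id, sites = sites, d = length(sites), D = n - 1L,
         fragments = frags,
         enzymes = sort(vapply(rules, `[[`, character(1), "name")),
         chain_length = n, copy_number = chain$copy_number),
    class = "digest_result"
  )
}

#' @export
print.digest_result <- function(x, ...) {
  cat("<digest_result> ", x$chain_id, ": d=", x$d, " of D=", x$D,
      " bonds cleaved by {", paste(x$enzymes, collapse = ", "), "}; ",
      nrow(x$fragments), " fragments\n", sep = "")
  invisible(x)
}

#' Theoretical degree of hydrolysis
#'
#' Per chain, `DH_T = d / D * 100` where `d` is the number of cleaved bonds
#' and `D` the total number of peptide bonds. For a multi-chain protein the
#' pooled value is the copy-number-weighted mean of the per-chain values
#' (type I collagen: alpha-1 weighted 2, alpha-2 weighted 1).
#'
#' @param results A `digest_result` or list of them (one per chain).
#' @param copies Optional named numeric vector of copy numbers keyed by
#'   chain id; defaults to the copy numbers carried on the results.
#' @return Weighted DH_T percentage in `[0, 100]`.
#' @export
degree_of_hydrolysis <- function(results, copies = NULL) {
  if (inherits(results, "digest_result")) results <- list(results)
  stopifnot(length(results) > 0L)
  ids <- vapply(results, `[[`, character(1), "chain_id")
  if (anyDuplicated(ids)) stop("multiple digest results for one chain")
  dh <- vapply(results, function(r) {
    if (r$D == 0L) stop("chain '", r$chain_id,
                        "' has a single residue (D = 0); DH_T undefined")
    r$d / r$D * 100
  }, numeric(1))
  w <- if (is.null(copies)) {
    vapply(results, `[[`, integer(1), "copy_number")
  } else {
    if (!all(ids %in% names(copies))) {
      stop("copies must be named with every chain id")
    }
    as.numeric(copies[ids])
  }
  sum(dh * w) / sum(w)
}

#' Distinct fragment sequences of a digest
#'
#' Duplicate releases of the same sequence are collapsed; positional records
#' stay available in `result$fragments`.
#'
#' @param result A `digest_result`.
#' @param min_length Drop sequences shorter than this (default 1 keeps all;
#'   peptide-level screening uses 2 to exclude free amino acids).
#' @return Character vector of unique sequences in order of first release.
#' @export
distinct_fragments <- function(result, min_length = 1L) {
  stopifnot(inherits(result, "digest_result"))
  seqs <- unique(result$fragments$sequence)
  seqs[nchar(seqs) >= min_length]
}

#' Length distribution of distinct fragments
#'
#' @param result A `digest_result`.
#' @return Named integer vector over the classes `"1"`, `"2"`, `"3"`, `"4"`,
#'   `"5"`, `">=6"`; the counts partition the distinct fragment sequences.
#' @export
length_distribution <- function(result) {
  stopifnot(inherits(result, "digest_result"))
  len <- nchar(distinct_fragments(result))
  cls <- ifelse(len >= 6L, ">=6", as.character(len))
  out <- stats::setNames(integer(6), c("1", "2", "3", "4", "5", ">=6"))
  tab <- table(cls)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Rank multi-enzyme combinations by ACE-inhibitory release frequency
#'
#' Enumerates all subsets of the selected enzymes of the given sizes, digests
#' every chain with each subset acting simultaneously, and scores the subset
#' by the copy-number-weighted release frequency `A` of the chosen activity
#' (primary key, descending), breaking ties by higher weighted DH_T and then
#' by the lexicographic enzyme-name combination.
#'
#' @param chains A mature `chain_set`.
#' @param rules An `enzyme_table` (or named list of `enzyme_rule`).
#' @param db A `reference_db` (see [load_refdb()]).
#' @param activity Activity label to score, e.g. `"ACE inhibitor"`.
#' @param enzymes Character vector of enzyme names to combine; defaults to
#'   all names in `rules`.
#' @param sizes Combination sizes to enumerate (default binary and ternary).
#' @return Data frame: `enzymes` (comma-joined names), `A`, `DH_T`, sorted
#'   best first.
#' @export
rank_enzyme_combinations <- function(chains, rules, db, activity,
                                     enzymes = names(rules), sizes = c(2L, 3L)) {
  stopifnot(inherits(chains, "chain_set"))
  missing <- setdiff(enzymes, names(rules))
  if (length(missing)) {
    stop("unknown enzyme(s): ", paste(missing, collapse = ", "))
  }
  enzymes <- sort(enzymes)
  combos <- unlist(lapply(sizes[sizes <= length(enzymes)], function(k)
    utils::combn(enzymes, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(combos, function(cmb) {
    results <- lapply(chains, digest, rules = rules[cmb])
    profs <- lapply(results, release_frequency, db = db, activity = activity)
    data.frame(
      enzymes = paste(cmb, collapse = ","),
      A = weighted_profile(profs,
                           vapply(chains, `[[`, integer(1), "copy_number")),
      DH_T = degree_of_hydrolysis(unname(results)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$A, -out$DH_T, out$enzymes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write digest fragments to TSV
#'
#' @param results A `digest_result` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_digest_tsv <- function(results, path) {
  if (inherits(results, "digest_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(chain_id = r$chain_id, start = r$fragments$start,
               end = r$fragments$end, sequence = r$fragments$sequence,
               length = nchar(r$fragments$sequence),
               enzymes = paste(r$enzymes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
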