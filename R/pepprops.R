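# Physicochemical property panel for candidate peptides: average molecular
# weight, side-chain net charge at neutral pH, Henderson-Hasselbalch
# isoelectric point (bisection), and hydropathy under a registered scale.

.pep_chars <- function(sequence, what, allow_x = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop(what, ": empty sequence")
  bad <- .bad_residue_at(sequence, allow_x = allow_x)
  if (bad > 0L) {
    stop(what, ": invalid residue '", substr(sequence, bad, bad),
         "' at position ", bad, " in '", sequence, "'")
  }
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

#' Peptide molecular weight
#'
#' Sum of residue masses plus one water. Average masses by default, which is
#' the convention that matches the values reported by peptide-property web
#' servers; monoisotopic masses behind a flag.
#'
#' @param sequence Peptide string (no `'X'`).
#' @param monoisotopic Use monoisotopic masses (default FALSE = average).
#' @return Mass in Da.
#' @export
molecular_weight <- function(sequence, monoisotopic = FALSE) {
  chars <- .pep_chars(sequence, "molecular_weight")
  if (monoisotopic) {
    sum(AA_MONO_MASS[chars]) + AA_WATER_MONO
  } else {
    sum(AA_AVG_MASS[chars]) + AA_WATER
  }
}

#' Side-chain net charge at neutral pH
#'
#' `(#K + #R) - (#D + #E)`; histidine is treated as neutral at pH 7 and the
#' termini are ignored (side chains only).
#'
#' @param sequence Peptide string.
#' @return Integer net charge.
#' @export
net_charge <- function(sequence) {
  chars <- .pep_chars(sequence, "net_charge", allow_x = TRUE)
  as.integer(sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E")))
}

# internal: Henderson-Hasselbalch net charge of a peptide at a given pH
.hh_charge <- function(counts_pos, counts_neg, pka, ph) {
  pos <- sum(counts_pos / (1 + 10^(ph - pka$positive[names(counts_pos)])))
  neg <- sum(counts_neg / (1 + 10^(pka$negative[names(counts_neg)] - ph)))
  pos - neg
}

#' Isoelectric point by bisection
#'
#' Finds the pH in `[0, 14]` at which the Henderson-Hasselbalch net charge
#' over the N-terminus, C-terminus and ionizable side chains (D, E, C, Y, H,
#' K, R) is zero, by bisection to a pH tolerance of 1e-4. The pKa set is
#' configurable; the default is a standard textbook set (see [PKA_DEFAULT]).
#'
#' @param sequence Peptide string.
#' @param pka pKa set: list with named numeric vectors `positive` (must
#'   include `nterm`) and `negative` (must include `cterm`).
#' @param include_termini Include the backbone termini (default TRUE).
#' @return pI in pH units, or `NA_real_` when the peptide has no ionizable
#'   group under the chosen settings (charge identically zero).
#' @export
isoelectric_point <- function(sequence, pka = PKA_DEFAULT,
                              include_termini = TRUE) {
  chars <- .pep_chars(sequence, "isoelectric_point", allow_x = TRUE)
  counts_pos <- table(factor(chars[chars %in% setdiff(names(pka$positive), "nterm")],
                             levels = setdiff(names(pka$positive), "nterm")))
  counts_neg <- table(factor(chars[chars %in% setdiff(names(pka$negative), "cterm")],
                             levels = setdiff(names(pka$negative), "cterm")))
  counts_pos <- c(stats::setNames(as.numeric(counts_pos), names(counts_pos)),
                  nterm = if (include_termini) 1 else 0)
  counts_neg <- c(stats::setNames(as.numeric(counts_neg), names(counts_neg)),
                  cterm = if (include_termini) 1 else 0)
  counts_pos <- counts_pos[counts_pos > 0]
  counts_neg <- counts_neg[counts_neg > 0]
  if (length(counts_pos) == 0L && length(counts_neg) == 0L) return(NA_real_)
  f <- function(ph) .hh_charge(counts_pos, counts_neg, pka, ph)
  lo <- 0; hi <- 14
  qlo <- f(lo); qhi <- f(hi)
  # all-positive or all-negative peptides never cross zero inside [0, 14]
  if (qlo <= 0) return(if (abs(qlo) < 1e-9) NA_real_ else 0)
  if (qhi >= 0) return(if (abs(qhi) < 1e-9) NA_real_ else 14)
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Peptide hydropathy under a registered scale
#'
#' Ships the Kyte-Doolittle scale with `sum` and `mean` aggregation. Web
#' servers report hydrophobicity under assorted proprietary scales, so panel
#' output always labels the scale used; custom per-residue scales can be
#' supplied.
#'
#' @param sequence Peptide string.
#' @param scale `"kyte_doolittle"` or a named numeric vector giving a value
#'   per residue.
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return Scale-dependent hydropathy value.
#' @export
hydrophobicity <- function(sequence, scale = "kyte_doolittle",
                           aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (is.character(scale)) {
    scale <- switch(scale,
      kyte_doolittle = KYTE_DOOLITTLE,
      stop("unknown hydropathy scale '", scale,
           "'; registered: kyte_doolittle, or pass a named numeric vector")
    )
  }
  chars <- .pep_chars(sequence, "hydrophobicity")
  missing <- setdiff(unique(chars), names(scale))
  if (length(missing)) {
    stop("scale lacks value(s) for residue(s): ", paste(missing, collapse = ", "))
  }
  v <- scale[chars]
  if (aggregate == "sum") sum(v) else mean(v)
}

#' Physicochemical property panel
#'
#' @param sequences Character vector of peptides.
#' @param pka pKa set for the pI solver.
#' @param scale Hydropathy scale name or named numeric vector.
#' @param aggregate Hydropathy aggregation, `"mean"` or `"sum"`.
#' @return Data frame: sequence, length, molecular_weight (Da, 2 decimals),
#'   net_charge, isoelectric_point (2 decimals), hydrophobicity,
#'   hydrophobicity_scale.
#' @export
property_panel <- function(sequences, pka = PKA_DEFAULT,
                           scale = "kyte_doolittle",
                           aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  scale_label <- if (is.character(scale)) scale else "custom"
  data.frame(
    sequence = sequences,
    length = nchar(sequences),
    molecular_weight = round(vapply(sequences, molecular_weight, numeric(1)), 2),
    net_charge = vapply(sequences, net_charge, integer(1)),
    isoelectric_point = round(vapply(sequences, isoelectric_point, numeric(1),
                                     pka = pka), 2),
    hydrophobicity = vapply(sequences, hydrophobicity, numeric(1),
                            scale = scale, aggregate = aggregate),
    hydrophobicity_scale = paste0(scale_label, "_", aggregate),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
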