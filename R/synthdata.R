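# Synthetic-data generator: collagen-like chains with planted reference
# peptides, annotation tables with planted pass/fail outcomes, target sets
# with a planted disease overlap, and interaction graphs with planted hubs -
# each with ground truth, so every pipeline stage is testable offline.
#
# One pseudo-random stream per artifact: each generator derives its own
# sub-seed from the master seed and a stable label, so adding a generator
# never perturbs the draws of another.

.derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629 + 1)
}

#' Synthetic study specification
#'
#' Bundles every knob of the generator. The defaults emulate the type I
#' collagen screening study the pipeline is built around: two alpha-chains in
#' 2:1 stoichiometry of roughly collagen length with an N-terminal signal
#' peptide, a candidate pool of 107 novel peptides of which one is toxic and
#' one allergenic, 27 carrying a high-activity classifier vote and 4 passing
#' docking, and a 112-node interaction network with 4 planted hubs.
#'
#' @param seed Master seed (mandatory).
#' @param n_chains Number of chains.
#' @param chain_length Total chain length including the signal peptide.
#' @param signal_length Signal-peptide length (0 = none).
#' @param gxy_fraction Fraction of body triplets following the collagen
#'   Gly-X-Y repeat.
#' @param copy_numbers Stoichiometric copy numbers, one per chain.
#' @param planted_peptides Data frame `sequence`, `activity`, `count`:
#'   reference peptides inserted into the chains at recorded coordinates.
#' @param n_candidates Number of novel candidate peptides for the cascade.
#' @param n_known Known (reference-database) peptides mixed into the
#'   candidate pool; they must fall at the novelty stage.
#' @param n_toxic,n_allergenic Planted safety failures (disjoint).
#' @param n_high_activity Candidates given at least one "high" vote.
#' @param n_docking_pass Candidates given both docking energies above the
#'   reference ligand.
#' @param graph List `n_nodes`, `n_hubs`, `attachment`, `hub_fraction` for
#'   the interaction-network generator.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(seed,
                       n_chains = 2L,
                       chain_length = 1450L,
                       signal_length = 22L,
                       gxy_fraction = 0.95,
                       copy_numbers = c(2L, 1L),
                       planted_peptides = data.frame(
                         sequence = c("VY", "PK", "AY"),
                         activity = "ACE inhibitor",
                         count = c(2L, 2L, 2L),
                         stringsAsFactors = FALSE),
                       n_candidates = 107L,
                       n_known = 5L,
                       n_toxic = 1L,
                       n_allergenic = 1L,
                       n_high_activity = 27L,
                       n_docking_pass = 4L,
                       graph = list(n_nodes = 112L, n_hubs = 4L,
                                    attachment = 1L, hub_fraction = 0.5)) {
  if (missing(seed)) stop("a master seed is mandatory")
  stopifnot(n_chains >= 1L, chain_length > signal_length,
            signal_length >= 0L, gxy_fraction >= 0, gxy_fraction <= 1,
            length(copy_numbers) == n_chains,
            n_toxic >= 0L, n_allergenic >= 0L,
            n_toxic + n_allergenic + n_high_activity <= n_candidates,
            n_docking_pass <= n_high_activity,
            graph$n_hubs < graph$n_nodes)
  structure(as.list(environment()), class = "synth_spec")
}

.AA20 <- setdiff(AA_ALPHABET, "X")
# residues common at collagen X/Y positions (proline-rich)
.GXY_XY <- c("P", "P", "P", "A", "R", "S", "K", "E", "Q", "L", "V", "G")
.SIGNAL_AA <- c("L", "L", "A", "V", "F", "I", "W", "C", "S", "T", "G", "M")

#' Generate collagen-like chains with planted reference peptides
#'
#' Each chain is an N-terminal signal peptide followed by a Gly-X-Y-dominated
#' body. Planted peptides are written over non-overlapping windows of the
#' mature (post-signal) body at recorded coordinates; ground-truth
#' coordinates are 1-based on the mature chain. Optionally the plants are
#' re-drawn until no cleavage site of the given enzyme rules falls strictly
#' inside a planted peptide, so digestion releases them intact.
#'
#' @param spec A [synth_spec()].
#' @param avoid_rules Optional list of `enzyme_rule`: re-draw plant positions
#'   (up to 50 attempts) until no rule cleaves inside a planted window.
#' @return List: `chains` (untrimmed `chain_set`), `signals` (data frame
#'   `chain_id`, `signal_end`), `ground_truth` (list with `plants` data frame
#'   `chain_id`, `sequence`, `start`, `end` on the mature chain, and
#'   `signal_length`).
#' @export
gen_chains <- function(spec, avoid_rules = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  plants <- spec$planted_peptides
  if (any(nchar(plants$sequence) + 2 > spec$chain_length - spec$signal_length)) {
    stop("planted peptide(s) longer than the mature chain body")
  }
  .with_seed(.derive_seed(spec$seed, "chains"), {
    ids <- sprintf("SYN%02d", seq_len(spec$n_chains))
    n_mature <- spec$chain_length - spec$signal_length
    bodies <- lapply(seq_len(spec$n_chains), function(i) {
      n_tri <- ceiling(n_mature / 3)
      tri <- vapply(seq_len(n_tri), function(j) {
        if (stats::runif(1) < spec$gxy_fraction) {
          paste0("G", paste(sample(.GXY_XY, 2, replace = TRUE), collapse = ""))
        } else {
          paste(sample(.AA20, 3, replace = TRUE), collapse = "")
        }
      }, character(1))
      substr(paste(tri, collapse = ""), 1, n_mature)
    })
    # one plant instance per row repetition, assigned round-robin to chains
    inst <- plants[rep(seq_len(nrow(plants)), plants$count), , drop = FALSE]
    inst$chain <- rep_len(seq_len(spec$n_chains), nrow(inst))
    place <- function() {
      rows <- vector("list", nrow(inst))
      occupied <- lapply(seq_len(spec$n_chains), function(i) integer(0))
      for (r in seq_len(nrow(inst))) {
        ci <- inst$chain[r]
        w <- nchar(inst$sequence[r])
        ok_start <- NULL
        for (attempt in seq_len(200L)) {
          s <- sample.int(n_mature - w + 1L, 1L)
          win <- s:(s + w - 1L)
          if (!any(win %in% occupied[[ci]])) { ok_start <- s; break }
        }
        if (is.null(ok_start)) stop("overcrowded plants: no room left on chain ", ci)
        occupied[[ci]] <- c(occupied[[ci]], win)
        rows[[r]] <- data.frame(chain_id = ids[ci],
                                sequence = inst$sequence[r],
                                start = ok_start, end = ok_start + w - 1L,
                                stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }
    for (attempt in seq_len(50L)) {
      plant_df <- place()
      mod <- bodies
      for (r in seq_len(nrow(plant_df))) {
        ci <- match(plant_df$chain_id[r], ids)
        substr(mod[[ci]], plant_df$start[r], plant_df$end[r]) <-
          plant_df$sequence[r]
      }
      if (is.null(avoid_rules)) break
      clean <- TRUE
      for (ci in seq_len(spec$n_chains)) {
        ch <- protein_chain(ids[ci], mod[[ci]])
        sites <- sort(unique(unlist(lapply(avoid_rules, cleavage_sites,
                                           chain = ch))))
        pl <- plant_df[plant_df$chain_id == ids[ci], , drop = FALSE]
        for (r in seq_len(nrow(pl))) {
          # bond b (0-based) separates 1-based residues b+1 and b+2; it is
          # internal to the plant when both fall inside [start, end]
          inside <- sites >= pl$start[r] - 1L & sites <= pl$end[r] - 2L
          if (any(inside)) { clean <- FALSE; break }
        }
        if (!clean) break
      }
      if (clean) break
      if (attempt == 50L) stop("could not place plants clear of cleavage sites")
    }
    signals <- vapply(seq_len(spec$n_chains), function(i) {
      if (spec$signal_length == 0L) return("")
      paste0("M", paste(sample(.SIGNAL_AA, spec$signal_length - 1L,
                               replace = TRUE), collapse = ""))
    }, character(1))
    chains <- chain_set(lapply(seq_len(spec$n_chains), function(i) {
      protein_chain(ids[i], paste0(signals[i], mod[[i]]),
                    copy_number = spec$copy_numbers[i])
    }))
    list(
      chains = chains,
      signals = data.frame(chain_id = ids, signal_end = spec$signal_length,
                           stringsAsFactors = FALSE),
      ground_truth = list(plants = plant_df,
                          signal_length = spec$signal_length)
    )
  })
}

.random_peptides <- function(n, len_range = c(2L, 9L), forbidden = character(0)) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 50L * n + 1000L) stop("could not draw enough unique peptides")
    w <- sample(seq(len_range[1], len_range[2]), 1L)
    p <- paste(sample(.AA20, w, replace = TRUE), collapse = "")
    if (!p %in% out && !p %in% forbidden) out <- c(out, p)
  }
  out
}

#' Generate a candidate pool for the cascade
#'
#' Draws `n_candidates` unique random peptides absent from the reference
#' database (the novel pool) and mixes in `n_known` reference peptides, which
#' the novelty stage must reject.
#'
#' @param spec A [synth_spec()].
#' @param db A `reference_db`.
#' @param activity Activity label whose reference sequences count as known.
#' @return List: `candidates` (shuffled character vector), `novel`, `known`.
#' @export
gen_candidates <- function(spec, db, activity = "ACE inhibitor") {
  stopifnot(inherits(spec, "synth_spec"), inherits(db, "reference_db"))
  known_pool <- .db_sequences(db, activity)
  if (spec$n_known > length(known_pool)) {
    stop("n_known exceeds the reference database for '", activity, "'")
  }
  .with_seed(.derive_seed(spec$seed, "candidates"), {
    novel <- .random_peptides(spec$n_candidates, forbidden = known_pool)
    known <- sample(known_pool, spec$n_known)
    list(candidates = sample(c(novel, known)), novel = novel, known = known)
  })
}

#' Generate annotation tables with planted outcomes
#'
#' Produces toxicity, allergenicity, activity-vote and docking tables over
#' the novel candidates such that the cascade's stage counts are known by
#' construction: the toxic and allergenic sets are disjoint, high-activity
#' votes go to safe candidates, and docking passers (both energies above the
#' reference ligand) are a subset of the high-activity set. Known candidates
#' are annotated too (benign labels), since real tool exports cover whatever
#' was submitted.
#'
#' @param spec A [synth_spec()].
#' @param candidates Output of [gen_candidates()] (list with `novel`,
#'   `known`).
#' @param reference A [reference_ligand()] the docking energies are drawn
#'   around.
#' @return List: `tables` (named list of data frames: toxicity,
#'   allergenicity, activity, docking), `reference`, `ground_truth` (list
#'   `counts` with the expected per-stage output sizes and the planted sets).
#' @export
gen_annotations <- function(spec, candidates,
                            reference = reference_ligand("control", 90, 100)) {
  stopifnot(inherits(spec, "synth_spec"))
  novel <- candidates$novel
  all_seq <- c(candidates$novel, candidates$known)
  n <- length(novel)
  if (spec$n_toxic + spec$n_allergenic + spec$n_high_activity > n) {
    stop("planted counts exceed the novel candidate pool")
  }
  .with_seed(.derive_seed(spec$seed, "annotations"), {
    shuffled <- sample(novel)
    toxic <- utils::head(shuffled, spec$n_toxic)
    allergenic <- utils::head(setdiff(shuffled, toxic), spec$n_allergenic)
    safe <- setdiff(shuffled, c(toxic, allergenic))
    high <- utils::head(safe, spec$n_high_activity)
    dock_pass <- utils::head(high, spec$n_docking_pass)

    toxicity <- data.frame(
      sequence = all_seq,
      label = ifelse(all_seq %in% toxic, "toxic", "non-toxic"),
      stringsAsFactors = FALSE)
    allergenicity <- data.frame(
      sequence = all_seq,
      label = ifelse(all_seq %in% allergenic, "allergenic", "non-allergenic"),
      stringsAsFactors = FALSE)
    vote <- function(seqs) {
      t(vapply(seqs, function(s) {
        if (s %in% high) {
          v <- rep("low_non", 3)
          v[sample.int(3, sample.int(3, 1))] <- "high"
          v
        } else rep("low_non", 3)
      }, character(3)))
    }
    votes <- vote(all_seq)
    activity <- data.frame(sequence = all_seq, lr = votes[, 1],
                           svm = votes[, 2], mlp = votes[, 3],
                           stringsAsFactors = FALSE)
    # docking energies: passers strictly above the reference on both axes,
    # everyone else strictly below on the interaction energy
    ce <- reference$cdocker_energy +
      ifelse(all_seq %in% dock_pass, stats::runif(length(all_seq), 2, 25),
             stats::runif(length(all_seq), -40, 20))
    cie <- reference$cdocker_interaction +
      ifelse(all_seq %in% dock_pass, stats::runif(length(all_seq), 2, 20),
             -stats::runif(length(all_seq), 2, 40))
    docking <- data.frame(sequence = all_seq,
                          cdocker_energy = round(ce, 4),
                          cdocker_interaction = round(cie, 4),
                          stringsAsFactors = FALSE)
    list(
      tables = list(toxicity = toxicity, allergenicity = allergenicity,
                    activity = activity, docking = docking),
      reference = reference,
      ground_truth = list(
        counts = c(novelty = n,
                   safety = n - spec$n_toxic - spec$n_allergenic,
                   activity = spec$n_high_activity,
                   docking = spec$n_docking_pass),
        toxic = toxic, allergenic = allergenic, high = high,
        docking_pass = dock_pass)
    )
  })
}

#' Generate an interaction graph with planted hubs
#'
#' A sparse preferential-attachment background of `n_nodes - n_hubs` genes
#' plus `n_hubs` hub genes: the hubs form a clique and each is wired to a
#' large random subset (`hub_fraction` of the background). The sparse
#' background and the mutually connected, massively wired hubs make the
#' planted hubs dominate every topological centrality, including the
#' percolation-based one. Edge confidences are drawn above 0.9 so the
#' default loader keeps every edge.
#'
#' @param spec A [synth_spec()].
#' @return List: `edges` (data frame `geneA`, `geneB`, `combined_score`),
#'   `ground_truth` (list `hubs`, `n_nodes`, `n_edges`).
#' @export
gen_graph <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  g <- spec$graph
  .with_seed(.derive_seed(spec$seed, "graph"), {
    n_base <- g$n_nodes - g$n_hubs
    base <- igraph::sample_pa(n_base, power = 1, m = g$attachment,
                              directed = FALSE)
    base_names <- sprintf("G%03d", seq_len(n_base))
    el <- igraph::as_edgelist(base, names = FALSE)
    edges <- data.frame(geneA = base_names[el[, 1]],
                        geneB = base_names[el[, 2]],
                        stringsAsFactors = FALSE)
    hubs <- sprintf("HUB%d", seq_len(g$n_hubs))
    n_wire <- ceiling(g$hub_fraction * n_base)
    for (h in hubs) {
      nb <- sample(base_names, n_wire)
      edges <- rbind(edges, data.frame(geneA = h, geneB = nb,
                                       stringsAsFactors = FALSE))
    }
    if (length(hubs) >= 2L) {
      pairs <- utils::combn(hubs, 2L)
      edges <- rbind(edges, data.frame(geneA = pairs[1, ], geneB = pairs[2, ],
                                       stringsAsFactors = FALSE))
    }
    a <- pmin(edges$geneA, edges$geneB)
    b <- pmax(edges$geneA, edges$geneB)
    keep <- !duplicated(paste(a, b)) & a != b
    edges <- data.frame(geneA = a[keep], geneB = b[keep],
                        combined_score = round(stats::runif(sum(keep),
                                                            0.905, 0.999), 3),
                        stringsAsFactors = FALSE)
    list(edges = edges,
         ground_truth = list(hubs = hubs,
                             n_nodes = length(unique(c(edges$geneA,
                                                       edges$geneB))),
                             n_edges = nrow(edges)))
  })
}

#' Generate predicted target sets with a planted disease overlap
#'
#' Emulates per-peptide target prediction plus a disease gene list: the
#' union of the peptide target sets intersects the disease set in exactly
#' `planted_overlap` genes.
#'
#' @param spec A [synth_spec()].
#' @param n_sets Number of peptide target sets.
#' @param set_size Targets per peptide.
#' @param planted_overlap Exact size of (union of sets) intersect disease.
#' @param disease_extra Disease genes outside the union.
#' @return List: `peptide_sets` (list of character vectors), `disease`
#'   (character vector), `ground_truth` (list `overlap` genes).
#' @export
gen_target_sets <- function(spec, n_sets = 4L, set_size = 100L,
                            planted_overlap = 201L, disease_extra = 500L) {
  stopifnot(inherits(spec, "synth_spec"))
  .with_seed(.derive_seed(spec$seed, "targets"), {
    # union drawn first, then dealt into sets with replacement-style sharing
    union_size <- max(planted_overlap,
                      ceiling(n_sets * set_size * 0.8))
    if (union_size > n_sets * set_size) union_size <- n_sets * set_size
    universe <- sprintf("T%05d", seq_len(union_size + disease_extra + 2000L))
    union_genes <- sample(universe, union_size)
    slots <- c(seq_len(union_size),               # every union gene once
               sample.int(union_size, n_sets * set_size - union_size,
                          replace = TRUE))        # the rest shared
    slots <- sample(slots)
    sets <- split(union_genes[slots], rep(seq_len(n_sets), each = set_size))
    # de-duplicate within a set by swapping in unused union genes
    sets <- lapply(sets, function(s) {
      while (anyDuplicated(s)) {
        dup <- which(duplicated(s))
        pool <- setdiff(union_genes, s)
        s[dup] <- sample(pool, length(dup))
      }
      s
    })
    overlap_genes <- sample(union_genes, planted_overlap)
    disease <- sample(c(overlap_genes,
                        sample(setdiff(universe, union_genes), disease_extra)))
    list(peptide_sets = unname(sets), disease = disease,
         ground_truth = list(overlap = sort(overlap_genes)))
  })
}

#' Write a full synthetic study to a directory
#'
#' Emits `chains.fa`, `signals.tsv`, `refdb.tsv`, `annotations/*.tsv`,
#' `graph.tsv` and `ground_truth.json`, each loadable by its consuming
#' module.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if missing).
#' @param db Reference database used for candidates/novelty (default the
#'   bundled snapshot).
#' @param activity Activity label.
#' @return Invisibly, the list of generated objects.
#' @export
synth_bundle <- function(spec, dir, db = default_refdb(),
                         activity = "ACE inhibitor") {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(file.path(dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)
  chains <- gen_chains(spec)
  cand <- gen_candidates(spec, db, activity)
  ann <- gen_annotations(spec, cand)
  grph <- gen_graph(spec)
  targ <- gen_target_sets(spec)

  write_fasta(chains$chains, file.path(dir, "chains.fa"))
  utils::write.table(chains$signals, file.path(dir, "signals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(db$peptides, file.path(dir, "refdb.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sequence = cand$candidates),
                     file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (kind in names(ann$tables)) {
    utils::write.table(ann$tables[[kind]],
                       file.path(dir, "annotations", paste0(kind, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(grph$edges, file.path(dir, "graph.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- list(chains = chains$ground_truth,
             cascade = ann$ground_truth,
             known_candidates = cand$known,
             graph = grph$ground_truth,
             targets = targ$ground_truth,
             reference_ligand = unclass(ann$reference))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(chains = chains, candidates = cand, annotations = ann,
                 graph = grph, targets = targ, ground_truth = gt))
}
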