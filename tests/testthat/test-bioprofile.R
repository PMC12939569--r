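ace_db <- function(seqs) {
  reference_db(data.frame(sequence = seqs, activity = "ACE inhibitor",
                          stringsAsFactors = FALSE))
}

test_that("the bundled reference snapshot loads with its literature IC50s", {
  db <- default_refdb()
  vy <- db$peptides[db$peptides$sequence == "VY" &
                    db$peptides$activity == "ACE inhibitor", ]
  expect_equal(nrow(vy), 1L)
  expect_equal(vy$ic50_um, 5.2)
  expect_true(all(c("PPG", "APG", "PK", "CDF", "AK", "DL") %in%
                  db$peptides$sequence))
  # the printed alpha-2 list repeats DL; the snapshot holds it once
  expect_equal(sum(db$peptides$sequence == "DL"), 1L)
})

test_that("reference DB validation catches bad rows and duplicates", {
  expect_error(load_refdb(withr::local_tempfile(fileext = ".tsv")), "not found")
  expect_error(reference_db(data.frame(sequence = "A", activity = "x")),
               "shorter than 2")
  expect_error(reference_db(data.frame(sequence = "AB1", activity = "x")),
               "row 1")
  expect_warning(db <- reference_db(data.frame(sequence = c("VY", "VY"),
                                               activity = "x")),
                 "duplicate")
  expect_equal(nrow(db$peptides), 1L)
})

test_that("occurrence profile counts overlapping positional matches", {
  ch <- protein_chain("c", "GAVGAV")
  p <- occurrence_profile(ch, ace_db("AV"), "ACE inhibitor")
  expect_equal(p$a, 2L)
  expect_equal(p$N, 6L)
  expect_equal(p$A, 2 / 6)
  # overlapping self-matches: AA in AAA occurs at 2 positions
  p2 <- occurrence_profile(protein_chain("c", "AAA"), ace_db("AA"),
                           "ACE inhibitor")
  expect_equal(p2$a, 2L)
  p3 <- occurrence_profile(protein_chain("c", "AAA"), ace_db("AA"),
                           "ACE inhibitor", overlapping = FALSE)
  expect_equal(p3$a, 1L)
  expect_error(occurrence_profile(ch, ace_db("AV"), "no-such-activity"),
               "available")
})

test_that("matcher equals naive scanning on random chains and databases", {
  set.seed(11)
  aa <- setdiff(AA_ALPHABET, "X")
  for (i in 1:200) {
    chain <- random_chain_string(max_len = 60)
    pats <- unique(replicate(sample(1:6, 1), paste(
      sample(aa, sample(2:4, 1), replace = TRUE), collapse = "")))
    p <- occurrence_profile(protein_chain("c", chain), ace_db(pats),
                            "ACE inhibitor")
    expect_equal(p$a, oracle_count_occurrences(chain, pats),
                 info = paste(chain, paste(pats, collapse = "/")))
  }
})

test_that("A is invariant under chain duplication (scales as 1/N)", {
  set.seed(3)
  for (i in 1:20) {
    s <- random_chain_string(max_len = 40, x_prob = 0)
    db <- ace_db(c("AV", "GK", "PL"))
    a1 <- occurrence_profile(protein_chain("c", s), db, "ACE inhibitor")
    a2 <- occurrence_profile(protein_chain("c", strrep(s, 2)), db,
                             "ACE inhibitor")
    # doubling the sequence at least doubles matches; junction may add more
    expect_gte(a2$A, a1$A - 1e-12)
  }
  # exact invariance when the junction creates no new match
  db <- ace_db("VY")
  a1 <- occurrence_profile(protein_chain("c", "GVYG"), db, "ACE inhibitor")
  a2 <- occurrence_profile(protein_chain("c", "GVYGGVYG"), db, "ACE inhibitor")
  expect_equal(a1$A, a2$A)
})

test_that("release frequency counts matched fragments with multiplicity", {
  tryp <- enzyme_rule("t", specs = list(list(p1 = c("K", "R"))),
                      exceptions = list(list(p1prime = "P")))
  d <- digest(protein_chain("c", "AKRGFPK"), tryp)
  p <- release_frequency(d, ace_db("AK"), "ACE inhibitor")
  expect_equal(p$a, 1L)
  expect_equal(p$A, 1 / 7)
  expect_equal(release_frequency(d, ace_db("WW"), "ACE inhibitor")$A, 0)
  # multiplicity: AK released twice counts twice
  d2 <- digest(protein_chain("c", "AKAKG"), enzyme_rule("k", specs = list(list(p1 = "K"))))
  expect_equal(d2$fragments$sequence, c("AK", "AK", "G"))
  expect_equal(release_frequency(d2, ace_db("AK"), "ACE inhibitor")$a, 2L)
})

test_that("weighted profile pools per-chain A by copy number", {
  mk <- function(id, A) structure(list(activity = "x", chain_id = id,
                                       a = 0L, N = 1L, A = A),
                                  class = "activity_profile")
  expect_equal(weighted_profile(list(mk("a1", 0.8947), mk("a2", 0.9261)),
                                c(a1 = 2, a2 = 1)),
               (2 * 0.8947 + 0.9261) / 3)
  expect_equal(weighted_profile(list(mk("a", 0.5), mk("b", 0.5)), c(3, 1)), 0.5)
  expect_equal(weighted_profile(list(mk("a", 0.42)), 5), 0.42)
  expect_error(weighted_profile(list(mk("a", 1), mk("b", 1)), c(a = 1, zz = 1)),
               "every profiled chain")
})

test_that("known/novel partition is exhaustive, disjoint, exact-match only", {
  db <- default_refdb()
  part <- classify_known_novel(c("VY", "QICVCDS"), db, "ACE inhibitor")
  expect_equal(part$known, "VY")
  expect_equal(part$novel, "QICVCDS")
  expect_equal(classify_known_novel(character(0), db, "ACE inhibitor"),
               list(known = character(0), novel = character(0)))
  part2 <- classify_known_novel(c("VY", "AK"), db, "ACE inhibitor")
  expect_equal(part2$novel, character(0))
  # substring is not a match: VYG is novel even though VY is known
  expect_equal(classify_known_novel("VYG", db, "ACE inhibitor")$novel, "VYG")
})

test_that("planted peptides are recovered by the occurrence profile", {
  db <- default_refdb()
  for (seed in c(5, 6)) {
    sp <- synth_spec(seed = seed)
    g <- gen_chains(sp)
    chains <- g$chains
    for (i in seq_along(chains)) {
      mature <- trim_signal(chains[[i]], g$ground_truth$signal_length)
      plants <- g$ground_truth$plants
      plants <- plants[plants$chain_id == mature$id, , drop = FALSE]
      # every planted coordinate really carries its peptide
      for (r in seq_len(nrow(plants))) {
        expect_equal(substr(mature$residues, plants$start[r], plants$end[r]),
                     plants$sequence[r])
      }
      p <- occurrence_profile(mature, db, "ACE inhibitor")
      expect_gte(p$a, nrow(plants))
    }
  }
})
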