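panel <- default_candidate_panel()
lisinopril <- default_reference_ligand()

test_that("annotation ingestion maps tool labels and reports unmatched rows", {
  cs <- candidate_set(c("ECCPICPDS", "DVWK", "AVIL"))
  cs <- ingest_annotations(cs, data.frame(sequence = c("ECCPICPDS", "ZZ"),
                                          label = c("toxic", "non-toxic")),
                           "toxicity")
  expect_equal(attr(cs, "unmatched"), "ZZ")
  rec <- cs$records
  expect_equal(rec$toxicity[rec$sequence == "ECCPICPDS"], "toxic")
  expect_equal(rec$toxicity[rec$sequence == "DVWK"], "unannotated")

  cs <- ingest_annotations(cs, data.frame(
    sequence = c("DVWK", "AVIL"),
    lr = c("high activity", "low & non-activity"),
    svm = c("low & non-activity", "high activity"),
    mlp = c("low & non-activity", "low & non-activity")), "activity")
  rec <- cs$records
  expect_equal(rec$vote_lr[rec$sequence == "DVWK"], "high")
  expect_equal(rec$vote_svm[rec$sequence == "AVIL"], "high")

  expect_error(
    ingest_annotations(cs, data.frame(sequence = "DVWK", label = "meh"),
                       "toxicity"),
    "unknown label 'meh' at row 1")
  # empty table leaves everything unannotated
  cs2 <- ingest_annotations(candidate_set("DVWK"),
                            data.frame(sequence = character(0),
                                       label = character(0)), "toxicity")
  expect_equal(cs2$records$toxicity, "unannotated")
})

test_that("safety filter keeps only non-toxic, non-allergenic records", {
  cs <- candidate_set(c("AAQ", "CCQ", "DDQ"))
  cs <- ingest_annotations(cs, data.frame(
    sequence = c("AAQ", "CCQ", "DDQ"),
    label = c("non-toxic", "toxic", "non-toxic")), "toxicity")
  cs <- ingest_annotations(cs, data.frame(
    sequence = c("AAQ", "CCQ", "DDQ"),
    label = c("non-allergenic", "non-allergenic", "allergenic")),
    "allergenicity")
  out <- safety_filter(cs)
  expect_equal(passing(out), "AAQ")
  lg <- out$log
  expect_equal(lg$reason[lg$sequence == "CCQ"], "toxicity")
  expect_equal(lg$reason[lg$sequence == "DDQ"], "allergenicity")
  # strict vs permissive on unannotated records
  un <- candidate_set("EEQ")
  expect_equal(length(passing(safety_filter(un, strict = TRUE))), 0L)
  expect_equal(passing(safety_filter(un, strict = FALSE)), "EEQ")
})

test_that("activity selection keeps any-of-three high votes", {
  cs <- candidate_set(panel$sequence)
  cs <- ingest_annotations(cs, panel, "activity")
  out <- activity_select(cs)
  # every panel row carries at least one high vote
  expect_setequal(passing(out), panel$sequence)
  # DVWK (high/low/low) and AVIL (low/high/low) both kept
  expect_true(all(c("DVWK", "AVIL") %in% passing(out)))
  # all-low and unscored records fall
  cs2 <- candidate_set(c("GGQ", "GGW"))
  cs2 <- ingest_annotations(cs2, data.frame(sequence = "GGQ", lr = "low_non",
                                            svm = "low_non", mlp = "low_non"),
                            "activity")
  out2 <- activity_select(cs2)
  expect_equal(length(passing(out2)), 0L)
  expect_equal(out2$log$reason[out2$log$sequence == "GGW"], "unscored")
})

test_that("docking selection reproduces the published four-peptide outcome", {
  cs <- candidate_set(panel$sequence)
  cs <- ingest_annotations(cs, panel, "docking")
  out <- docking_select(cs, lisinopril)
  rk <- docking_ranking(out)
  expect_equal(rk$sequence, c("QICVCDS", "DVWK", "IIEY", "APMDVG"))
  expect_true(all(rk$cdocker_energy > lisinopril$cdocker_energy))
  expect_true(all(rk$cdocker_interaction > lisinopril$cdocker_interaction))
  # VIEY beats the control on -CE but not -CIE: rejected
  expect_true("VIEY" %in%
                out$records$sequence[out$records$status == "rejected:docking"])
  expect_error(docking_select(cs, NULL), "reference_ligand")
  # empty candidate list passes through
  empty <- docking_select(candidate_set(character(0)), lisinopril)
  expect_equal(nrow(docking_ranking(empty)), 0L)
})

test_that("cascade stages run in order with a complete audit trail", {
  db <- default_refdb()
  seqs <- c(panel$sequence, "VY")  # VY is known -> falls at novelty
  tox <- data.frame(sequence = seqs, label = "non-toxic")
  alg <- data.frame(sequence = seqs, label = "non-allergenic")
  rep <- run_cascade(candidate_set(seqs), db, "ACE inhibitor",
                     annotations = list(toxicity = tox, allergenicity = alg,
                                        activity = panel, docking = panel),
                     reference = lisinopril)
  expect_equal(rep$counts$stage, c("novelty", "safety", "activity", "docking"))
  expect_true(all(rep$counts$n_out <= rep$counts$n_in))
  # CDF and WY are in the reference snapshot, so they fall at novelty too
  expect_equal(rep$counts$n_out[1], length(setdiff(
    seqs, db$peptides$sequence[db$peptides$activity == "ACE inhibitor"])))
  expect_equal(rep$survivors$sequence, c("QICVCDS", "DVWK", "IIEY", "APMDVG"))
  # audit completeness: every input in exactly one terminal state
  expect_setequal(rep$candidates$records$sequence, seqs)
  expect_equal(anyDuplicated(rep$candidates$records$sequence), 0L)
  # rejected records carry no later-stage log entries
  lg <- rep$log
  expect_equal(nrow(lg[lg$sequence == "VY" & lg$stage != "novelty", ]), 0L)
  # determinism: identical inputs give identical reports
  rep2 <- run_cascade(candidate_set(seqs), db, "ACE inhibitor",
                      annotations = list(toxicity = tox, allergenicity = alg,
                                         activity = panel, docking = panel),
                      reference = lisinopril)
  expect_identical(rep$counts, rep2$counts)
  expect_identical(rep$log, rep2$log)
})

test_that("an empty cascade yields all-zero counts", {
  rep <- run_cascade(candidate_set(character(0)), default_refdb(),
                     "ACE inhibitor")
  expect_true(all(rep$counts$n_in == 0L))
  expect_true(all(rep$counts$n_out == 0L))
})
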