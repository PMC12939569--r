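test_that("generation is deterministic under the master seed", {
  sp <- synth_spec(seed = 41)
  a <- gen_chains(sp)
  b <- gen_chains(sp)
  expect_identical(vapply(a$chains, `[[`, character(1), "residues"),
                   vapply(b$chains, `[[`, character(1), "residues"))
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(gen_graph(sp)$edges, gen_graph(sp)$edges)
  db <- default_refdb()
  expect_identical(gen_candidates(sp, db), gen_candidates(sp, db))
})

test_that("chains carry the requested signal, length, and stoichiometry", {
  sp <- synth_spec(seed = 13)
  g <- gen_chains(sp)
  expect_equal(length(g$chains), 2L)
  for (ch in g$chains) expect_equal(nchar(ch$residues), 1450L)
  expect_equal(vapply(g$chains, `[[`, integer(1), "copy_number"),
               c(SYN01 = 2L, SYN02 = 1L))
  expect_equal(g$signals$signal_end, c(22L, 22L))
  # the mature body is glycine-rich, as a collagen body should be
  mature <- trim_signal(g$chains[[1]], 22L)
  gly <- mean(strsplit(mature$residues, "")[[1]] == "G")
  expect_gt(gly, 0.25)
})

test_that("plants can avoid internal cleavage sites of chosen enzymes", {
  rules <- default_enzymes()[c("papain", "ficin")]
  sp <- synth_spec(seed = 19, chain_length = 400L)
  g <- gen_chains(sp, avoid_rules = rules)
  for (i in seq_along(g$chains)) {
    mature <- trim_signal(g$chains[[i]], g$ground_truth$signal_length)
    sites <- sort(unique(unlist(lapply(rules, cleavage_sites, chain = mature))))
    pl <- g$ground_truth$plants
    pl <- pl[pl$chain_id == mature$id, , drop = FALSE]
    for (r in seq_len(nrow(pl))) {
      expect_false(any(sites >= pl$start[r] - 1L & sites <= pl$end[r] - 2L))
    }
  }
})

test_that("overcrowded plants raise an error", {
  sp <- synth_spec(seed = 2, chain_length = 30L, signal_length = 5L,
                   planted_peptides = data.frame(
                     sequence = strrep("VY", 6), activity = "ACE inhibitor",
                     count = 40L))
  expect_error(gen_chains(sp), "overcrowded|room")
})

test_that("annotation tables plant the exact cascade outcomes", {
  db <- default_refdb()
  sp <- synth_spec(seed = 31)
  cand <- gen_candidates(sp, db)
  expect_equal(length(cand$novel), 107L)
  expect_equal(length(cand$known), 5L)
  expect_true(all(cand$known %in% db$peptides$sequence))
  expect_false(any(cand$novel %in% db$peptides$sequence))
  ann <- gen_annotations(sp, cand)
  expect_equal(sum(ann$tables$toxicity$label == "toxic"), 1L)
  expect_equal(sum(ann$tables$allergenicity$label == "allergenic"), 1L)
  # toxic and allergenic plants are disjoint
  expect_false(ann$tables$toxicity$sequence[
    ann$tables$toxicity$label == "toxic"] %in% ann$ground_truth$allergenic)
  # docking passers all beat the reference on both energies
  d <- ann$tables$docking
  pass <- d[d$sequence %in% ann$ground_truth$docking_pass, ]
  expect_true(all(pass$cdocker_energy > ann$reference$cdocker_energy))
  expect_true(all(pass$cdocker_interaction > ann$reference$cdocker_interaction))
  # counts exceeding the (smaller) novel pool actually passed are rejected
  sp_big <- synth_spec(seed = 1, n_candidates = 20L, n_toxic = 6L,
                       n_allergenic = 5L, n_high_activity = 9L,
                       n_docking_pass = 0L)
  expect_error(gen_annotations(sp_big,
                               list(novel = sprintf("A%sQ", LETTERS[1:10]),
                                    known = character(0))),
               "exceed")
})

test_that("the cascade reproduces planted ground-truth counts over 20 seeds", {
  db <- default_refdb()
  for (seed in 1:20) {
    sp <- synth_spec(seed = seed)
    cand <- gen_candidates(sp, db)
    ann <- gen_annotations(sp, cand)
    rep <- run_cascade(candidate_set(cand$candidates), db, "ACE inhibitor",
                       annotations = ann$tables, reference = ann$reference)
    got <- stats::setNames(rep$counts$n_out, rep$counts$stage)
    expect_equal(got, ann$ground_truth$counts, info = paste("seed", seed))
  }
})

test_that("planted hubs are recovered by every centrality's top-(h+2)", {
  for (seed in c(3, 17)) {
    sp <- synth_spec(seed = seed)
    gg <- gen_graph(sp)
    g <- load_graph(gg$edges)
    expect_equal(igraph::vcount(g), gg$ground_truth$n_nodes)
    expect_equal(igraph::ecount(g), gg$ground_truth$n_edges)
    h <- length(gg$ground_truth$hubs)
    pan <- centrality_panel(g, k = h + 2L, epc_seed = seed)
    for (m in names(pan)) {
      expect_true(all(gg$ground_truth$hubs %in% pan[[m]]$top_k),
                  info = paste("seed", seed, m))
    }
    expect_true(all(gg$ground_truth$hubs %in% consensus_hubs(pan)))
  }
  # no hubs: consensus may be empty, but nothing crashes
  sp0 <- synth_spec(seed = 4, graph = list(n_nodes = 30L, n_hubs = 0L,
                                           attachment = 1L,
                                           hub_fraction = 0.5))
  g0 <- load_graph(gen_graph(sp0)$edges)
  expect_silent(centrality_panel(g0, k = 5, epc_seed = 1))
})

test_that("planted target overlap is exact", {
  sp <- synth_spec(seed = 8)
  ts <- gen_target_sets(sp)
  expect_equal(length(ts$peptide_sets), 4L)
  expect_true(all(lengths(ts$peptide_sets) == 100L))
  ov <- overlap_targets(ts$peptide_sets, ts$disease)
  expect_equal(ov, ts$ground_truth$overlap)
  expect_equal(length(ov), 201L)
})

test_that("every emitted bundle file loads in its consuming module", {
  dir <- withr::local_tempdir()
  sp <- synth_spec(seed = 55, chain_length = 300L)
  b <- synth_bundle(sp, dir)
  chains <- load_fasta(file.path(dir, "chains.fa"))
  chains <- apply_signal_annotations(chains, file.path(dir, "signals.tsv"))
  expect_equal(nchar(chains[[1]]$residues), 300L - 22L)
  db <- load_refdb(file.path(dir, "refdb.tsv"))
  expect_s3_class(db, "reference_db")
  g <- load_graph(file.path(dir, "graph.tsv"))
  expect_gt(igraph::vcount(g), 0L)
  cand <- utils::read.delim(file.path(dir, "candidates.tsv"))
  rep <- run_cascade(candidate_set(cand$sequence), db, "ACE inhibitor",
                     annotations = list(
                       toxicity = file.path(dir, "annotations", "toxicity.tsv"),
                       allergenicity = file.path(dir, "annotations",
                                                 "allergenicity.tsv"),
                       activity = file.path(dir, "annotations", "activity.tsv"),
                       docking = file.path(dir, "annotations", "docking.tsv")),
                     reference = do.call(reference_ligand,
                                         b$ground_truth$reference_ligand))
  expect_equal(stats::setNames(rep$counts$n_out, rep$counts$stage),
               b$annotations$ground_truth$counts)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(unlist(gt$graph$hubs), b$ground_truth$graph$hubs)
})
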