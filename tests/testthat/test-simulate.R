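test_that("background simulation hits the requested GC and reproduces", {
  spec <- sim_spec(genome_length = 100000L, gc_content = 0.5, seed = 71L,
                   autonomous = NULL, ht_pairs = NULL,
                   empty_site_pairs = 0L)
  g <- simulate_background(spec)
  gc <- mean(strsplit(g$seq, "")[[1L]] %in% c("G", "C"))
  expect_true(gc > 0.49 && gc < 0.51)  # binomial CI at n = 1e5
  g2 <- simulate_background(spec)
  expect_identical(g$seq, g2$seq)

  at_only <- simulate_background(sim_spec(genome_length = 5000L,
                                          gc_content = 0,
                                          autonomous = NULL,
                                          ht_pairs = NULL,
                                          empty_site_pairs = 0L,
                                          seed = 1L),
                                 length = 5000L)
  expect_false(grepl("[GC]", at_only$seq))
})

test_that("planting duplicates the target site and conserves length", {
  spec <- sim_spec(genome_length = 30000L, seed = 72L, autonomous = NULL,
                   ht_pairs = NULL, empty_site_pairs = 0L)
  g0 <- simulate_background(spec)
  fs <- family_spec(250L, 12L, 8L, 6L, 0, 0)
  res <- plant_family(g0, fs, "famX", seed = 72L)
  tr <- res$truth
  expect_equal(nrow(tr), 6L)
  # length conservation
  expect_equal(nchar(res$genome$seq),
               nchar(g0$seq) + sum(nchar(tr$seq) + tr$tsd_len))
  for (r in seq_len(nrow(tr))) {
    # TSD duplicated on both sides of the copy
    left <- substr(res$genome$seq, tr$start[r] - tr$tsd_len[r] + 1L,
                   tr$start[r])
    right <- substr(res$genome$seq, tr$end[r] + 1L,
                    tr$end[r] + tr$tsd_len[r])
    expect_equal(left, tr$tsd_seq[r])
    expect_equal(right, tr$tsd_seq[r])
    # divergence 0: every copy equals the consensus
    expect_equal(substr(res$genome$seq, tr$start[r] + 1L, tr$end[r]),
                 res$consensus)
  }
})

test_that("every truth interval reproduces its recorded inserted sequence", {
  ts <- small_fixture(seed = 73L, genome_length = 30000L)
  tr <- ts$truth
  for (r in seq_len(nrow(tr))) {
    g <- ts$genomes[[tr$genome[r]]]
    expect_equal(substr(g$seq, tr$start[r] + 1L, tr$end[r]), tr$seq[r])
  }
})

test_that("the autonomous partner carries the requested ORF and termini", {
  set.seed(74)
  fs <- family_spec(300L, 14L, 8L, 5L, 0, 0)
  cons <- mitescan:::make_family_consensus(fs)
  host <- genome_record("h", rand_dna(30000L), role = "host")
  res <- plant_autonomous_and_derivative(host, cons, length = 3000L,
                                         orf_aa = 500L, seed = 74L)
  aut <- res$autonomous
  orfs <- find_orfs(aut$seq, min_aa = 450L)
  expect_true(any(vapply(orfs, function(o)
    o$protein_length_aa == 500L, TRUE)))
  # derivative termini equal the autonomous termini
  fam <- new_mite_family(members = list(), consensus = cons)
  expect_equal(terminal_similarity(fam, aut$seq), 15L)
  # the retained blocks align at full identity beyond the TIRs
  al <- align_pair(cons, aut$seq, mode = "local")
  expect_gte(al$identity_pct, 70)
})

test_that("HT scenarios drive presence calls and monophyly as designed", {
  sc_lo <- simulate_ht_scenario(cross_divergence = 0.05, mode = "single",
                                seed = 75L)
  fam <- new_mite_family(
    members = list(structure(list(
      interval = interval("ht_virus", 0L, 10L), family = "ht_fam",
      completeness = "full", divergence = 0, tsd = NULL),
      class = "mite_copy")),
    name = "ht_fam", consensus = sc_lo$consensus)
  expect_true(ht_presence_call(fam, sc_lo$genomes$ht_host)$present)
  expect_true(ht_presence_call(fam, sc_lo$genomes$ht_virus)$present)

  sc_hi <- simulate_ht_scenario(cross_divergence = 0.5, mode = "single",
                                seed = 76L)
  fam_hi <- new_mite_family(members = fam$members, name = "ht_fam",
                            consensus = sc_hi$consensus)
  # the recipient copies are ~50% diverged from the donor consensus
  expect_false(ht_presence_call(fam_hi, sc_hi$genomes$ht_virus)$present)

  # single ancestral transfer: recipient copies form a clade
  tree_of <- function(sc) {
    tr <- sc$truth
    seqs <- tr$seq
    names(seqs) <- sprintf("%s_%d", tr$genome, seq_len(nrow(tr)))
    aln <- align_multi(seqs)
    nj_tree(mitescan:::pdist_matrix(mitescan:::aln_matrix(aln)))
  }
  sc1 <- simulate_ht_scenario(cross_divergence = 0.15, mode = "single",
                              seed = 77L)
  t1 <- tree_of(sc1)
  virus_tips <- grep("^ht_virus", t1$tip.label, value = TRUE)
  expect_true(is_monophyletic(t1, virus_tips))

  sc2 <- simulate_ht_scenario(cross_divergence = 0.15, mode = "multi",
                              seed = 78L)
  t2 <- tree_of(sc2)
  virus_tips2 <- grep("^ht_virus", t2$tip.label, value = TRUE)
  expect_false(is_monophyletic(t2, virus_tips2))
})

test_that("recovery scoring is exact on perfect and empty detections", {
  ts <- small_fixture(seed = 79L, genome_length = 30000L)
  tr <- ts$truth
  # construct 'perfect' detections straight from the truth
  fams <- lapply(split(seq_len(nrow(tr)), tr$family), function(rows) {
    members <- lapply(rows, function(r) {
      g <- ts$genomes[[tr$genome[r]]]
      iv <- interval(tr$genome[r], tr$start[r], tr$end[r])
      list(interval = iv, seq = tr$seq[r], strand = "+",
           tsd = tryCatch(call_tsd(iv, g), error = function(e) NULL))
    })
    new_mite_family(members = members, name = tr$family[rows[1L]],
                    consensus = tr$seq[rows[1L]])
  })
  copies <- lapply(seq_len(nrow(tr)), function(r) structure(list(
    interval = interval(tr$genome[r], tr$start[r], tr$end[r]),
    family = tr$family[r], completeness = "full", divergence = 0,
    tsd = NULL), class = "mite_copy"))
  rep <- evaluate_recovery(ts, fams, list(sim_virus = copies))
  expect_equal(rep$family$f1, 1)
  expect_equal(rep$copies$f1, 1)
  expect_equal(rep$copies$count_error, 0)
  expect_gte(rep$tsd_exact_frac, 0.9)
  expect_equal(rep$boundary$max_offset, 0)

  # detector disabled: zero recall
  rep0 <- evaluate_recovery(ts, list(), list(sim_virus = list()))
  expect_equal(rep0$family$recall, 0)
  expect_equal(rep0$copies$recall, 0)

  expect_error(evaluate_recovery(ts, fams, list(wrong_id = copies)),
               "mismatch")
})
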