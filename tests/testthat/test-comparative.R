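test_that("a planted paralogous empty site is found and occupied loci are not", {
  set.seed(41)
  elem <- rand_dna(200L)
  L <- rand_dna(100L); R <- rand_dna(100L)
  bg <- rand_dna(20000L)
  # occupied source locus at 5000, empty duplicate of the junction at 12000
  seq <- splice_in(bg, paste0(L, elem, R), 5000L)
  seq <- splice_in(seq, paste0(L, R), 12000L)
  g <- genome_record("g", seq)
  src <- mk_copy("g", 5100L, 5300L)
  es <- find_empty_paralogs(src, g)
  expect_length(es, 1L)
  expect_lte(es[[1L]]$gap_len, 15L)
  expect_gte(es[[1L]]$left_identity_pct, 85)
  expect_true(es[[1L]]$locus$start >= 11900L &&
              es[[1L]]$locus$end <= 12350L)

  # no duplicated flanks -> no empty site
  g2 <- genome_record("g", splice_in(bg, paste0(L, elem, R), 5000L))
  expect_length(find_empty_paralogs(mk_copy("g", 5100L, 5300L), g2), 0L)

  # flanks duplicated around a second full copy -> excluded
  seq3 <- splice_in(bg, paste0(L, elem, R), 5000L)
  seq3 <- splice_in(seq3, paste0(L, elem, R), 12000L)
  g3 <- genome_record("g", seq3)
  other <- mk_copy("g", 12100L, 12300L)
  es3 <- find_empty_paralogs(mk_copy("g", 5100L, 5300L), g3,
                             family_copies = list(other))
  expect_length(es3, 0L)
})

test_that("empty sites never overlap an annotated same-family copy", {
  set.seed(42)
  elem <- rand_dna(200L)
  L <- rand_dna(100L); R <- rand_dna(100L)
  seq <- rand_dna(30000L)
  seq <- splice_in(seq, paste0(L, elem, R), 4000L)
  seq <- splice_in(seq, paste0(L, R), 11000L)
  seq <- splice_in(seq, paste0(L, elem, R), 18000L)
  g <- genome_record("g", seq)
  fam_copies <- list(mk_copy("g", 4100L, 4300L),
                     mk_copy("g", 18300L, 18500L))
  es <- find_empty_paralogs(fam_copies[[1L]], g, family_copies = fam_copies)
  for (s in es) for (fc in fam_copies)
    expect_equal(reciprocal_overlap(s$locus, fc$interval), 0)
})

test_that("HT presence calls follow the identity and coverage rule", {
  set.seed(43)
  cons <- rand_dna(300L)
  fam <- new_mite_family(members = list(mk_copy("src", 100L, 400L)),
                         name = "f1", consensus = cons)
  # low-divergence full-length copy -> present
  tgt1 <- genome_record("t1", splice_in(rand_dna(20000L),
                                        mutate_dna(cons, 0.05), 9000L),
                        taxon = "host1", role = "host")
  call1 <- ht_presence_call(fam, tgt1)
  expect_true(call1$present)
  expect_gte(call1$best_identity_pct, 85)

  # nothing resembling the consensus -> absent
  tgt2 <- genome_record("t2", rand_dna(20000L), taxon = "host2",
                        role = "host")
  expect_false(ht_presence_call(fam, tgt2)$present)

  # high identity over only half the consensus -> absent by coverage
  tgt3 <- genome_record("t3", splice_in(rand_dna(20000L),
                                        substr(cons, 1L, 150L), 9000L),
                        taxon = "host3", role = "host")
  call3 <- ht_presence_call(fam, tgt3)
  expect_false(call3$present)
  expect_lt(call3$coverage, 0.6)
})

test_that("raising the identity threshold can only revoke presence", {
  set.seed(44)
  cons <- rand_dna(300L)
  fam <- new_mite_family(members = list(mk_copy("src", 100L, 400L)),
                         name = "f1", consensus = cons)
  tgt <- genome_record("t", splice_in(rand_dna(15000L),
                                      mutate_dna(cons, 0.2), 7000L),
                       taxon = "h", role = "host")
  prev <- TRUE
  for (thr in c(40, 60, 75, 90, 99)) {
    cur <- ht_presence_call(fam, tgt,
                            ht_screen_params(min_identity_pct = thr))$present
    expect_false(!prev && cur)  # no absent -> present flip
    prev <- cur
  }
})

test_that("presence calls bracket the 60% rule on a divergence gradient", {
  set.seed(45)
  cons <- rand_dna(300L)
  fam <- new_mite_family(members = list(mk_copy("src", 100L, 400L)),
                         name = "f1", consensus = cons)
  plant <- function(d) genome_record("t", splice_in(
    rand_dna(15000L), mutate_dna(cons, d), 7000L), taxon = "h",
    role = "host")
  expect_true(ht_presence_call(fam, plant(0.05))$present)
  expect_true(ht_presence_call(fam, plant(0.25))$present)
  expect_false(ht_presence_call(fam, plant(0.45))$present)
  expect_false(ht_presence_call(fam, plant(0.6))$present)
})

test_that("identity matrices are orientation-aware and symmetric", {
  set.seed(46)
  a <- rand_dna(200L)
  m <- pairwise_identity_matrix(c(x = a, y = a))
  expect_equal(m$identity["x", "y"], 100)
  m2 <- pairwise_identity_matrix(c(x = a, y = revcomp(a)))
  expect_equal(m2$identity["x", "y"], 100)
  expect_equal(m2$orientation["x", "y"], "-")
  b <- mutate_dna(a, 0.1)
  m3 <- pairwise_identity_matrix(c(x = a, y = b, z = revcomp(b)))
  expect_true(isSymmetric(m3$identity))
})

test_that("pair identity at substitution rate 0.2 matches the JC expectation", {
  # two lineages each at rate 0.1 from a common ancestor: expected
  # identity ~ 81% once chance agreement of differing sites is counted
  set.seed(47)
  ids <- replicate(40, {
    anc <- rand_dna(300L)
    pairwise_identity_matrix(c(a = mutate_dna(anc, 0.1),
                               b = mutate_dna(anc, 0.1)))$identity[1, 2]
  })
  expect_lt(abs(mean(ids) - 81), 3)
})

test_that("orthologous sites are scored present, empty or unalignable", {
  set.seed(48)
  elem <- rand_dna(200L)
  ctxL <- rand_dna(400L); ctxR <- rand_dna(400L)
  pre <- rand_dna(3000L); post <- rand_dna(3000L)
  gA <- genome_record("gA", paste0(pre, ctxL, elem, ctxR, post))
  gB <- genome_record("gB", paste0(rand_dna(2500L), ctxL, elem, ctxR,
                                   rand_dna(3500L)))
  gC <- genome_record("gC", paste0(rand_dna(3500L), ctxL, ctxR,
                                   rand_dna(2500L)))
  genomes <- list(gA = gA, gB = gB, gC = gC)
  fam <- new_mite_family(members = list(mk_copy("gA", 3400L, 3600L)),
                         name = "f1", consensus = elem)
  copies <- list(gA = list(mk_copy("gA", 3400L, 3600L, "f1")),
                 gB = list(mk_copy("gB", 2900L, 3100L, "f1")),
                 gC = list())
  osm <- orthologous_site_matrix(list(fam), genomes, copies)
  expect_gte(length(osm$sites), 1L)
  st <- osm$sites[[1L]]$status
  expect_equal(unname(st[c("gA", "gB", "gC")]),
               c("present", "present", "empty"))

  # divergent context in gC -> unalignable there
  gC2 <- genome_record("gC", rand_dna(6800L))
  osm2 <- orthologous_site_matrix(list(fam),
                                  list(gA = gA, gB = gB, gC = gC2),
                                  copies)
  expect_equal(unname(osm2$sites[[1L]]$status["gC"]), "unalignable")

  # element present in all three
  gC3 <- genome_record("gC", paste0(rand_dna(3500L), ctxL, elem, ctxR,
                                    rand_dna(2500L)))
  copies3 <- copies
  copies3$gC <- list(mk_copy("gC", 3900L, 4100L, "f1"))
  osm3 <- orthologous_site_matrix(list(fam),
                                  list(gA = gA, gB = gB, gC = gC3),
                                  copies3)
  expect_equal(unname(osm3$sites[[1L]]$status[c("gA", "gB", "gC")]),
               rep("present", 3L))
})
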