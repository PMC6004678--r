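make_family_from <- function(genome, intervals, genomes_list) {
  members <- lapply(intervals, function(iv)
    list(interval = iv, seq = substr(genome$seq, iv$start + 1L, iv$end),
         strand = "+"))
  new_mite_family(members = members)
}

test_that("boundary refinement recovers exact core edges from noisy calls", {
  set.seed(21)
  core <- tir_element(200L, 12L)
  bg <- rand_dna(20000L)
  ats <- c(2000L, 6000L, 10000L, 14000L)
  gwc <- genome_with_copies(bg, core, ats)
  g <- gwc$genome
  # candidate calls 5 bp short at the 5' end
  short <- lapply(gwc$intervals, function(iv)
    interval(iv$genome_id, iv$start + 5L, iv$end))
  fam <- make_family_from(g, short, list(gtest = g))
  ref <- refine_boundaries(fam, list(gtest = g))
  for (k in seq_along(ref$members))
    expect_equal(c(ref$members[[k]]$interval$start,
                   ref$members[[k]]$interval$end),
                 c(gwc$intervals[[k]]$start, gwc$intervals[[k]]$end))
})

test_that("identical members including flanks are flagged indeterminate", {
  set.seed(22)
  block <- rand_dna(400L)  # element + identical context, duplicated
  bg <- paste0(rand_dna(3000L), block, rand_dna(3000L), block,
               rand_dna(3000L))
  g <- genome_record("g", bg)
  ivs <- list(interval("g", 3100L, 3300L),
              interval("g", 6500L, 6700L))
  fam <- make_family_from(g, ivs, list(g = g))
  ref <- refine_boundaries(fam, list(g = g))
  expect_true("boundary_indeterminate" %in% ref$flags)
  expect_equal(ref$members[[1L]]$interval$start, 3100L)
  expect_equal(ref$members[[1L]]$interval$end, 3300L)
})

test_that("TSD calling finds planted duplications and honors absence", {
  set.seed(23)
  elem <- rand_dna(150L)
  tsd8 <- "ACGTTGCA"
  bg <- rand_dna(2000L)
  g8 <- genome_record("g", paste0(substr(bg, 1, 900), tsd8, elem, tsd8,
                                  substr(bg, 901, 2000)))
  call <- call_tsd(interval("g", 908L, 1058L), g8)
  expect_equal(call$seq, tsd8)
  expect_equal(call$length, 8L)

  g2 <- genome_record("g", paste0(substr(bg, 1, 900), "TA", elem, "TA",
                                  substr(bg, 901, 2000)))
  call2 <- call_tsd(interval("g", 902L, 1052L), g2)
  expect_equal(call2$length, 2L)
  expect_equal(call2$seq, "TA")

  # flanks engineered to share no terminal k-mer
  gno <- genome_record("g", paste0(strrep("AC", 300), elem,
                                   strrep("GT", 300)))
  expect_null(call_tsd(interval("g", 600L, 750L), gno))
  expect_error(call_tsd(interval("g", 3L, 153L), gno), "flank")
})

test_that("false-positive filters fire for the right reasons", {
  set.seed(24)
  # oversized consensus
  fam_long <- new_mite_family(members = list(), consensus = rand_dna(850L))
  v <- apply_candidate_filters(fam_long)
  expect_false(v$keep); expect_equal(v$reason, "too_long")

  # clean planted family: TIR + TSDs on >= 2 members
  arm <- rand_dna(12L)
  elem <- paste0(arm, rand_dna(276L), revcomp(arm))
  bg <- rand_dna(20000L)
  tsd <- "ACGTTGCA"
  ats <- c(3000L, 9000L, 15000L)
  for (at in rev(ats)) bg <- splice_in(bg, paste0(tsd, elem, tsd), at)
  g <- genome_record("g", bg)
  ivs <- lapply(seq_along(ats), function(k) {
    s <- sort(ats)[k] + (k - 1L) * (nchar(elem) + 16L) + 8L
    interval("g", s, s + nchar(elem))
  })
  members <- lapply(ivs, function(iv) {
    m <- list(interval = iv, seq = substr(g$seq, iv$start + 1L, iv$end),
              strand = "+")
    m$tsd <- call_tsd(iv, g)
    m
  })
  fam_ok <- new_mite_family(members = members, consensus = elem)
  v_ok <- apply_candidate_filters(fam_ok)
  expect_true(v_ok$keep); expect_equal(v_ok$reason, "ok")

  # same family with TSD calls removed -> no_tsd
  fam_no_tsd <- fam_ok
  fam_no_tsd$members <- lapply(fam_no_tsd$members, function(m) {
    m$tsd <- NULL; m
  })
  v_nt <- apply_candidate_filters(fam_no_tsd)
  expect_false(v_nt$keep); expect_equal(v_nt$reason, "no_tsd")

  # no inverted termini -> no_tir
  fam_no_tir <- fam_ok
  fam_no_tir$consensus <- rand_dna(300L)
  fam_no_tir$tir <- NULL
  v_ni <- apply_candidate_filters(fam_no_tir)
  expect_false(v_ni$keep); expect_equal(v_ni$reason, "no_tir")

  # compound: consensus embedding another family's consensus
  other <- new_mite_family(members = members, consensus = elem)
  comp_cons <- paste0(arm, rand_dna(100L), elem, rand_dna(100L),
                      revcomp(arm))
  fam_comp <- new_mite_family(members = members, consensus = comp_cons)
  fam_comp$members <- members
  v_c <- apply_candidate_filters(fam_comp, list(other))
  expect_false(v_c$keep); expect_equal(v_c$reason, "compound")

  # idempotence: the verdict does not depend on repetition or the order
  # of the comparison set
  expect_identical(apply_candidate_filters(fam_ok), v_ok)
  expect_identical(apply_candidate_filters(fam_comp, list(other, fam_long)),
                   apply_candidate_filters(fam_comp, list(fam_long, other)))
})

fake_family <- function(consensus, tsd_lens, tsd_seqs = NULL) {
  members <- lapply(seq_along(tsd_lens), function(i) {
    list(interval = interval("g", 100L, 100L + nchar(consensus)),
         seq = consensus, strand = "+",
         tsd = structure(list(
           seq = if (is.null(tsd_seqs)) strrep("A", tsd_lens[i])
                 else tsd_seqs[i],
           length = tsd_lens[i],
           left_interval = interval("g", 90L, 100L),
           right_interval = interval("g", 400L, 410L)),
           class = "tsd_call"))
  })
  new_mite_family(members = members, consensus = consensus)
}

test_that("superfamily classification follows TIR/TSD signatures", {
  set.seed(25)
  mid <- rand_dna(200L)
  hatm <- fake_family(paste0("TAGGGTG", mid, "CACCCTA"), c(8L, 8L, 9L))
  expect_equal(classify_superfamily(hatm), "hATm")

  cmc <- fake_family(paste0("CAC", mid, "GTG"), c(2L, 2L))
  expect_equal(classify_superfamily(cmc), "CMC")

  tc1 <- fake_family(paste0("CAGT", mid, "ACTG"), c(2L, 2L),
                     tsd_seqs = c("TA", "TA"))
  expect_equal(classify_superfamily(tc1), "Tc1/mariner")

  unk <- fake_family(paste0("GGGG", mid, "CCCC"), c(5L, 5L))
  expect_equal(classify_superfamily(unk), "Unknown")
})

test_that("terminal motif matching is sharp at the mismatch budget", {
  set.seed(26)
  mid <- rand_dna(200L)
  # hATm allows <= 1 mismatch per terminus
  one_mm <- fake_family(paste0("TAGCGTG", mid, "CACCCTA"), c(8L, 8L))
  expect_equal(classify_superfamily(one_mm), "hATm")
  two_mm <- fake_family(paste0("TAGCCTG", mid, "CACCCTA"), c(8L, 8L))
  expect_false(classify_superfamily(two_mm) == "hATm")
})

test_that("hairpin scores separate constructed stems from noise", {
  set.seed(27)
  S <- rand_dna(50L)
  hp <- paste0(S, rand_dna(10L), revcomp(S))
  expect_gte(hairpin_pairing_score(hp), 0.9)
  expect_equal(hairpin_pairing_score(strrep("A", 100L)), 0)
  expect_error(hairpin_pairing_score("ACGTACGT"), "short")
})

test_that("hairpin scores of random sequence match the simulated baseline", {
  # frozen Monte-Carlo baseline for i.i.d. 200-mers (1000 draws under
  # the package scoring gave mean 0.462, sd 0.028)
  set.seed(28)
  scores <- replicate(120, hairpin_pairing_score(rand_dna(200L)))
  expect_lt(abs(mean(scores) - 0.462), 0.05)
})
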