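test_that("a planted element with a perfect 10-bp TIR is recovered exactly", {
  set.seed(101)
  elem <- tir_element(300L, 10L)
  g <- genome_record("g1", splice_in(rand_dna(10000L), elem, 5000L))
  cands <- find_tir_candidates(g)
  hit <- Filter(function(cd) cd$interval$start == 5000L &&
                  cd$interval$end == 5300L, cands)
  expect_length(hit, 1L)
  expect_equal(hit[[1L]]$tir_mismatches, 0L)
  expect_gte(hit[[1L]]$tir_len, 10L)
  expect_equal(hit[[1L]]$seq, elem)
})

test_that("a homopolymer genome yields no candidates", {
  g <- genome_record("h", strrep("A", 5000L))
  expect_length(find_tir_candidates(g), 0L)
})

test_that("the TIR mismatch budget is a sharp detection threshold", {
  set.seed(202)
  arm <- rand_dna(12L)
  armc <- strsplit(arm, "")[[1L]]
  armc[10L] <- setdiff(BASES, armc[10L])[1L]  # one internal substitution
  elem <- paste0(paste(armc, collapse = ""), rand_dna(276L), revcomp(arm))
  g <- genome_record("g", splice_in(rand_dna(3000L), elem, 1500L))
  p1 <- discovery_params(tir_min_len = 12L, tir_max_mismatch = 1L)
  p0 <- discovery_params(tir_min_len = 12L, tir_max_mismatch = 0L)
  found <- function(cands) any(vapply(cands, function(cd)
    reciprocal_overlap(cd$interval, interval("g", 1500L, 1800L)) >= 0.9,
    TRUE))
  expect_true(found(find_tir_candidates(g, p1)))
  expect_false(found(find_tir_candidates(g, p0)))
})

test_that("no candidate ever exceeds the element length ceiling", {
  set.seed(303)
  for (i in 1:3) {
    g <- genome_record("r", rand_dna(15000L))
    cands <- find_tir_candidates(g)
    if (length(cands))
      expect_true(all(vapply(cands, function(cd)
        cd$full_end - cd$interval$start <= 800L, TRUE)))
  }
})

test_that("circular genomes are scanned across the origin", {
  set.seed(111)
  arm <- rand_dna(12L)
  elem <- paste0(arm, rand_dna(276L), revcomp(arm))
  bg <- rand_dna(5000L)
  # element split across the origin: its tail opens the sequence, its
  # head closes it
  lin <- paste0(substr(elem, 151L, 300L), substr(bg, 151L, 4850L),
                substr(elem, 1L, 150L))
  g <- genome_record("c", lin, circular = TRUE)
  hits <- Filter(function(cd) isTRUE(cd$wraps), find_tir_candidates(g))
  expect_length(hits, 1L)
  expect_equal(hits[[1L]]$interval$start, nchar(lin) - 150L)
  expect_equal(hits[[1L]]$full_end, nchar(lin) + 150L)
  # the same genome treated as linear finds no origin-spanning element
  gl <- genome_record("l", lin, circular = FALSE)
  expect_length(Filter(function(cd) isTRUE(cd$wraps),
                       find_tir_candidates(gl)), 0L)
})

test_that("clustering respects the copy-number floor", {
  set.seed(404)
  elem <- tir_element(200L, 12L)
  mk <- function(n) {
    ats <- seq(2000L, by = 3000L, length.out = n)
    genome_with_copies(rand_dna(3000L * (n + 1L)), elem, ats)
  }
  g5 <- mk(5L)
  c5 <- find_tir_candidates(g5$genome)
  f5 <- cluster_into_families(c5, list(gtest = g5$genome))
  expect_length(f5, 1L)
  expect_length(f5[[1L]]$members, 5L)

  g2 <- mk(2L)
  c2 <- find_tir_candidates(g2$genome)
  f2 <- cluster_into_families(c2, list(gtest = g2$genome))
  expect_length(f2, 0L)
})

test_that("well-separated families are not merged", {
  set.seed(505)
  e1 <- tir_element(240L, 12L)
  e2 <- tir_element(240L, 12L)  # independent random: ~25% identity
  bg <- rand_dna(30000L)
  for (k in 0:2) bg <- splice_in(bg, e1, 2000L + k * 9000L)
  for (k in 0:2) bg <- splice_in(bg, e2, 5000L + k * 9000L)
  g <- genome_record("g", bg)
  fams <- cluster_into_families(find_tir_candidates(g), list(g = g))
  expect_length(fams, 2L)
  expect_setequal(vapply(fams, function(f) length(f$members), 0L),
                  c(3L, 3L))
})

test_that("family recovery is invariant to genome record order", {
  set.seed(606)
  elem <- tir_element(220L, 12L)
  mkg <- function(id) {
    ats <- c(2000L, 6000L, 10000L)
    genome_with_copies(rand_dna(14000L), elem, ats, id = id)$genome
  }
  ga <- mkg("ga"); gb <- mkg("gb")
  cand_a <- find_tir_candidates(ga); cand_b <- find_tir_candidates(gb)
  key <- function(fams) sort(vapply(
    unlist(lapply(fams, `[[`, "members"), recursive = FALSE),
    function(m) sprintf("%s:%d-%d", m$interval$genome_id,
                        m$interval$start, m$interval$end), ""))
  f1 <- cluster_into_families(c(cand_a, cand_b), list(ga = ga, gb = gb))
  f2 <- cluster_into_families(c(cand_b, cand_a), list(gb = gb, ga = ga))
  expect_equal(key(f1), key(f2))
})

test_that("recovery on the divergent planted fixture meets the floor", {
  # family-level recall and precision on copies planted at 5% divergence
  ts <- small_fixture(seed = 12L, genome_length = 40000L)
  g <- ts$genomes$sim_virus
  cands <- find_tir_candidates(g)
  fams <- cluster_into_families(cands, ts$genomes)
  # every cluster should map to one planted family and at least 2 of the
  # 3 planted families should be found at this scale
  hit_fams <- unique(unlist(lapply(fams, function(f) {
    labs <- vapply(f$members, function(m) {
      tr <- ts$truth
      ov <- vapply(seq_len(nrow(tr)), function(r) {
        if (tr$genome[r] != m$interval$genome_id) return(0)
        o <- max(0L, min(tr$end[r], m$interval$end) -
                   max(tr$start[r], m$interval$start))
        min(o / (m$interval$end - m$interval$start),
            o / (tr$end[r] - tr$start[r]))
      }, 0)
      if (max(ov) >= 0.5) tr$family[which.max(ov)] else NA_character_
    }, "")
    labs[!is.na(labs)]
  })))
  expect_gte(length(hit_fams), 2L)
})
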