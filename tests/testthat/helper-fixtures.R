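# Shared fixture builders. All randomness is seeded at the call site so
# individual tests are reproducible in isolation.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                              collapse = "")

mutate_dna <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

# insert `elem` into `bg` after 0-based position `at`
splice_in <- function(bg, elem, at)
  paste0(substr(bg, 1L, at), elem, substr(bg, at + 1L, nchar(bg)))

# an element with perfect TIR arms
tir_element <- function(len, arm_len) {
  arm <- rand_dna(arm_len)
  paste0(arm, rand_dna(len - 2L * arm_len), revcomp(arm))
}

# genome with copies of `elem` (optionally mutated) at given 0-based
# insertion points (applied right-to-left so positions stay valid);
# returns the genome record plus the final element intervals
genome_with_copies <- function(bg, elem, ats, rate = 0, tsd = "",
                               id = "gtest") {
  ats <- sort(ats, decreasing = TRUE)
  ivs <- list()
  for (at in ats) {
    cp <- if (rate > 0) mutate_dna(elem, rate) else elem
    ins <- paste0(cp, tsd)
    bg <- splice_in(bg, ins, at)
  }
  g <- genome_record(id, bg)
  # recompute intervals left-to-right
  ats2 <- sort(ats)
  shift <- 0L
  for (k in seq_along(ats2)) {
    s <- ats2[k] + shift
    ivs[[k]] <- interval(id, s, s + nchar(elem))
    shift <- shift + nchar(elem) + nchar(tsd)
  }
  list(genome = g, intervals = ivs)
}

write_temp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", ids, "\n", unname(seqs)), path)
  path
}

mk_copy <- function(gid, s, e, family = "f", completeness = "full") {
  structure(list(interval = interval(gid, s, e), family = family,
                 completeness = completeness, divergence = 0, tsd = NULL),
            class = "mite_copy")
}

NONSTOP <- setdiff(as.vector(outer(as.vector(outer(BASES, BASES, paste0)),
                                   BASES, paste0)),
                   c("TAA", "TAG", "TGA"))

# sequence whose maximal ORF occupies exactly [start, end] (1-based,
# stop codon included), embedded in random sequence
orf_at <- function(start, end, total) {
  aa <- (end - start + 1L) / 3L - 1L
  orf <- paste0("ATG", paste(sample(NONSTOP, aa - 1L, replace = TRUE),
                             collapse = ""), "TAA")
  pre <- rand_dna(start - 4L)            # leaves room for a stop before
  paste0(pre, "TAA", orf, rand_dna(total - end))
}

# tiny simulated fixture shared by several tests (kept small: three
# families, no truncation, single virus genome)
small_fixture <- function(seed = 7L, genome_length = 50000L) {
  simulate_genomes(sim_spec(
    genome_length = genome_length,
    families = list(family_spec(300L, 14L, 8L, 8L, 0.05, 0),
                    family_spec(180L, 12L, 2L, 6L, 0.05, 0),
                    family_spec(420L, 10L, 8L, 5L, 0.05, 0)),
    autonomous = NULL, ht_pairs = NULL, empty_site_pairs = 0L,
    seed = seed))
}
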