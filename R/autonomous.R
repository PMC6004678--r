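# Putative autonomous partners: long elements sharing termini with a MITE
# and carrying a transposase-scale ORF; terminus logo matrices.

.STOPS <- c("TAA", "TAG", "TGA")

#' Find open reading frames
#'
#' All maximal ATG-to-stop frames on both strands with protein length
#' (excluding the stop) of at least `min_aa`. The terminal stop codon is
#' included in the reported span, so `protein_length_aa = span/3 - 1`.
#'
#' @param seq DNA string.
#' @param min_aa Minimum protein length in amino acids.
#' @return List of `"orf_record"`s: `start`, `end` (1-based inclusive
#'   nucleotide positions on the forward sequence), `strand`,
#'   `protein_length_aa`. Sorted by decreasing length.
#' @export
find_orfs <- function(seq, min_aa = 100L) {
  n <- nchar(seq)
  orfs <- list()
  for (std in c("+", "-")) {
    s <- if (std == "-") revcomp(seq) else seq
    for (frame in 0:2) {
      cstarts <- seq(frame + 1L, n - 2L, by = 3L)
      if (!length(cstarts)) next
      codons <- substring(s, cstarts, cstarts + 2L)
      is_stop <- codons %in% .STOPS
      is_atg <- codons == "ATG"
      prev_stop <- 0L
      for (k in which(is_stop)) {
        atg <- which(is_atg & seq_along(codons) > prev_stop &
                     seq_along(codons) < k)
        prev_stop <- k
        if (!length(atg)) next
        a <- atg[1L]
        aa <- k - a  # codons from ATG to stop, excluding the stop
        if (aa < min_aa) next
        s1 <- cstarts[a]; s2 <- cstarts[k] + 2L
        if (std == "-") { tmp <- s1; s1 <- n - s2 + 1L; s2 <- n - tmp + 1L }
        orfs[[length(orfs) + 1L]] <- structure(list(
          start = s1, end = s2, strand = std,
          protein_length_aa = aa), class = "orf_record")
      }
    }
  }
  orfs[order(-vapply(orfs, `[[`, 0L, "protein_length_aa"))]
}

#' Terminal similarity between a family and a candidate element
#'
#' Ungapped comparison of the first `window` bases of the family consensus
#' with the candidate's first `window`, and of the last `window` with the
#' candidate's last `window` (reverse-complement consistent when both are
#' in the same orientation). Returns the smaller of the two end counts:
#' both termini must resemble the family for the transposase to act.
#'
#' @param family A `"mite_family"` with consensus.
#' @param candidate_seq Candidate DNA string.
#' @param window Terminus window (default 15).
#' @return Integer number of matches (0..`window`).
#' @export
terminal_similarity <- function(family, candidate_seq, window = 15L) {
  cons <- family$consensus
  if (is.null(cons)) stop("family consensus must be built")
  if (nchar(cons) < window || nchar(candidate_seq) < window)
    stop("sequences shorter than the terminus window")
  m5 <- window - count_mismatches(substr(cons, 1L, window),
                                  substr(candidate_seq, 1L, window))
  nc <- nchar(cons); ncand <- nchar(candidate_seq)
  m3 <- window - count_mismatches(substr(cons, nc - window + 1L, nc),
                                  substr(candidate_seq,
                                         ncand - window + 1L, ncand))
  min(m5, m3)
}

#' Link a family to putative autonomous partner elements
#'
#' Scans genomes for 1-10 kb regions similar to the family consensus,
#' delimits a candidate element by the best-matching pair of terminus
#' windows, and keeps candidates whose termini reach `min_matches` out of
#' `window` and which carry an ORF of at least `min_orf_aa` amino acids
#' (transposase scale). Candidates whose internal sequence (beyond the
#' termini) still aligns to the MITE consensus at >= 70% identity are
#' flagged as the family's deletion-derivative source.
#'
#' @param family A `"mite_family"` with consensus.
#' @param genomes Named list of [genome_record()]s to scan.
#' @param min_matches Terminus match floor (default 8 of 15).
#' @param window Terminus window (default 15).
#' @param min_orf_aa Transposase-scale ORF floor (default 300 aa).
#' @return List of `"autonomous_candidate"`s sorted by decreasing
#'   `terminus_matches`: `interval`, `length`, `orfs`,
#'   `terminus_matches`, `matched_family`, `deletion_derivative`,
#'   `evidence_tier` (`"confident"` >= 13/15, else `"loose"`).
#' @export
link_autonomous_partner <- function(family, genomes, min_matches = 8L,
                                    window = 15L, min_orf_aa = 300L) {
  cons <- family$consensus
  if (is.null(cons)) stop("family consensus must be built")
  term5 <- substr(cons, 1L, window)
  term3 <- substr(cons, nchar(cons) - window + 1L, nchar(cons))
  out <- list()
  for (gid in names(genomes)) {
    g <- genomes[[gid]]
    hits <- scan_hits(cons, g, min_identity_pct = 60, min_coverage = 0)
    if (!nrow(hits)) next
    # merge hits into candidate regions (anything within 10 kb)
    o <- order(hits$start)
    hits <- hits[o, , drop = FALSE]
    grp <- cumsum(c(1L, diff(hits$start) > 10000L))
    for (gg in unique(grp)) {
      h <- hits[grp == gg, , drop = FALSE]
      rs <- max(0L, min(h$start) - 10000L)
      re <- min(nchar(g$seq), max(h$end) + 10000L)
      region <- substr(g$seq, rs + 1L, re)
      mm_budget <- window - min_matches
      p5 <- Biostrings::matchPattern(term5, Biostrings::DNAString(region),
                                     max.mismatch = mm_budget)
      p3 <- Biostrings::matchPattern(term3, Biostrings::DNAString(region),
                                     max.mismatch = mm_budget)
      # matchPattern with a mismatch budget can report matches hanging
      # over the sequence ends; keep in-bounds ones only
      p5s <- start(p5)[start(p5) >= 1L &
                       start(p5) + window - 1L <= nchar(region)]
      p3e <- end(p3)[end(p3) <= nchar(region) &
                     end(p3) - window + 1L >= 1L]
      if (!length(p5s) || !length(p3e)) next
      best <- NULL
      for (a in p5s) for (b in p3e) {
        len <- b - a + 1L
        if (len < 1000L || len > 10000L) next
        m5 <- window - count_mismatches(substr(region, a, a + window - 1L),
                                        term5)
        m3 <- window - count_mismatches(substr(region, b - window + 1L, b),
                                        term3)
        sc <- min(m5, m3)
        if (sc < min_matches) next
        if (is.null(best) || sc > best$sc ||
            (sc == best$sc && len > best$len)) {
          best <- list(a = a, b = b, len = len, sc = sc)
        }
      }
      if (is.null(best)) next
      cand_seq <- substr(region, best$a, best$b)
      orfs <- find_orfs(cand_seq, min_aa = min_orf_aa)
      if (!length(orfs)) next
      internal <- substr(cand_seq, window + 1L, best$len - window)
      deriv <- FALSE
      if (nchar(internal) >= 30L) {
        al <- align_pair(cons, internal, mode = "local")
        aligned_len <- al$a_range[2L] - al$a_range[1L] + 1L
        deriv <- al$identity_pct >= 70 && aligned_len >= 30L
      }
      out[[length(out) + 1L]] <- structure(list(
        interval = interval(gid, rs + best$a - 1L, rs + best$b, "+"),
        length = best$len,
        orfs = orfs,
        terminus_matches = best$sc,
        terminus_window = window,
        matched_family = family$name,
        deletion_derivative = deriv,
        evidence_tier = if (best$sc >= 13L) "confident" else "loose"),
        class = "autonomous_candidate")
    }
  }
  out[order(-vapply(out, `[[`, 0L, "terminus_matches"))]
}

#' Base-frequency (logo) matrix across an element boundary
#'
#' Per-column base frequencies over the 30-nt window centred on the
#' element boundary (15 nt of flank and 15 nt of element, TSD included on
#' the flank side), plus the per-column information content
#' `2 - H` in bits.
#'
#' @param copies List of `"mite_copy"`s (>= 2) with sufficient flanks;
#'   copies without 15 bp of flank are skipped with a warning.
#' @param genomes Named list of [genome_record()]s.
#' @param boundary `"5p"` (default) or `"3p"`. Windows are read in element
#'   orientation: for `"5p"` columns 1-15 are flank (TSD included) and
#'   16-30 element; for `"3p"` columns 1-15 are element and 16-30 flank.
#' @return List of class `"logo_matrix"`: `freq` (4 x 30 matrix, columns
#'   sum to 1) and `bits` (length-30 information content in `[0, 2]`).
#' @export
terminus_logo_matrix <- function(copies, genomes,
                                 boundary = c("5p", "3p")) {
  boundary <- match.arg(boundary)
  half <- 15L
  wins <- character()
  for (cp in copies) {
    iv <- cp$interval
    g <- genomes[[iv$genome_id]]
    L <- nchar(g$seq)
    # the element end sitting at the genome-left boundary depends on strand
    at_start <- (boundary == "5p") == (iv$strand == "+")
    if (at_start) {
      if (iv$start < half || iv$start + half > L) {
        warning("copy at ", iv$start, " skipped: insufficient flank")
        next
      }
      w <- substr(g$seq, iv$start - half + 1L, iv$start + half)
    } else {
      if (iv$end + half > L || iv$end < half) {
        warning("copy at ", iv$start, " skipped: insufficient flank")
        next
      }
      w <- substr(g$seq, iv$end - half + 1L, iv$end + half)
    }
    if (iv$strand == "-") w <- revcomp(w)
    wins <- c(wins, w)
  }
  if (length(wins) < 2L) stop("fewer than 2 copies with sufficient flank")
  M <- do.call(rbind, strsplit(wins, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  freq <- vapply(seq_len(ncol(M)), function(j) {
    cnt <- vapply(bases, function(b) sum(M[, j] == b), 0L)
    tot <- sum(cnt)
    if (tot == 0L) rep(0.25, 4L) else cnt / tot
  }, numeric(4L))
  rownames(freq) <- bases
  bits <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  structure(list(freq = freq, bits = bits, n = nrow(M)),
            class = "logo_matrix")
}
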