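# Seed-and-extend local similarity search of a query against a genome.
# Backs library-based copy annotation, horizontal-transfer screening,
# empty-site flank search and autonomous-partner anchoring. Exactness over
# speed: genomes here are at most a few Mb.

# Exact k-mer seed positions of `query` (plus-strand orientation) in a
# DNAString genome. Returns data.frame(qpos, gpos) of 1-based starts.
kmer_seeds <- function(query, gseq_dna, k, max_hits_per_kmer = 500L) {
  nq <- nchar(query)
  if (nq < k) return(data.frame(qpos = integer(), gpos = integer()))
  starts <- seq_len(nq - k + 1L)
  kmers <- substring(query, starts, starts + k - 1L)
  ok <- grepl("^[ACGT]+$", kmers)
  starts <- starts[ok]; kmers <- kmers[ok]
  if (!length(kmers)) return(data.frame(qpos = integer(), gpos = integer()))
  uq <- unique(kmers)
  pd <- Biostrings::PDict(uq)
  mi <- Biostrings::matchPDict(pd, gseq_dna)
  glist <- Biostrings::startIndex(mi)
  idx <- match(kmers, uq)
  out_q <- vector("list", length(starts))
  out_g <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    gp <- glist[[idx[i]]]
    if (is.null(gp) || length(gp) == 0L ||
        length(gp) > max_hits_per_kmer) next
    out_q[[i]] <- rep.int(starts[i], length(gp))
    out_g[[i]] <- gp
  }
  data.frame(qpos = unlist(out_q) %||% integer(),
             gpos = unlist(out_g) %||% integer())
}

#' Scan a genome for local matches of a query sequence
#'
#' Seed-and-extend search: exact k-mer seeds are clustered by implied start
#' position, and each cluster window is locally aligned to the query with
#' the package's fixed scoring. Both strands are searched; minus-strand
#' hits are reported in forward-genome coordinates.
#'
#' @param query DNA string (the element/consensus/flank to look for).
#' @param genome A [genome_record()] (or plain DNA string).
#' @param min_identity_pct Minimum percent identity over aligned columns.
#' @param min_coverage Minimum aligned fraction of the query.
#' @param seed_k Exact seed length (default 11).
#' @param both_strands Search the minus strand too?
#' @return `data.frame` with 0-based half-open `start`, `end`, `strand`,
#'   `identity_pct`, `coverage`, `score`, `q_start`, `q_end` (1-based on
#'   the query in its searched orientation), and `subst_frac` (mismatch
#'   fraction over gap-free aligned columns). Sorted by `start`.
#' @export
scan_hits <- function(query, genome, min_identity_pct = 70,
                      min_coverage = 0, seed_k = 11L, both_strands = TRUE) {
  gseq <- if (inherits(genome, "genome_record")) genome$seq else genome
  L <- nchar(gseq)
  nq <- nchar(query)
  gdna <- Biostrings::DNAString(gseq)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), identity_pct = numeric(),
                      coverage = numeric(), score = numeric(),
                      q_start = integer(), q_end = integer(),
                      subst_frac = numeric())
  if (nq < seed_k || L < seed_k) return(empty)
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (std in strands) {
    qs <- if (std == "-") revcomp(query) else query
    seeds <- kmer_seeds(qs, gdna, seed_k)
    if (!nrow(seeds)) next
    implied <- seeds$gpos - seeds$qpos + 1L
    o <- order(implied)
    implied <- implied[o]
    grp <- cumsum(c(1L, diff(implied) > max(30L, round(0.6 * nq))))
    pad <- max(20L, round(0.2 * nq))
    for (g in split(implied, grp)) {
      ws <- max(1L, min(g) - pad)
      we <- min(L, max(g) + nq - 1L + pad)
      if (we - ws + 1L < seed_k) next
      wseq <- substr(gseq, ws, we)
      al <- align_pair(qs, wseq, mode = "local")
      hit_start <- ws - 1L + al$b_range[1L] - 1L  # 0-based
      hit_end <- ws - 1L + al$b_range[2L]         # exclusive
      np <- al$n_matches + al$n_mismatches
      rows[[length(rows) + 1L]] <- data.frame(
        start = hit_start, end = hit_end, strand = std,
        identity_pct = al$identity_pct, coverage = al$coverage_of_a,
        score = al$score, q_start = al$a_range[1L], q_end = al$a_range[2L],
        subst_frac = if (np) al$n_mismatches / np else 0)
    }
  }
  if (!length(rows)) return(empty)
  hits <- do.call(rbind, rows)
  hits <- hits[hits$identity_pct >= min_identity_pct &
               hits$coverage >= min_coverage, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  hits <- hits[order(hits$start, -hits$score), , drop = FALSE]
  # drop hits mostly contained in a better-scoring hit
  keep <- rep(TRUE, nrow(hits))
  acc <- list()
  ord <- order(-hits$score)
  for (i in ord) {
    ok <- TRUE
    for (j in seq_along(acc)) {
      a <- acc[[j]]
      ov <- max(0L, min(a[2L], hits$end[i]) - max(a[1L], hits$start[i]))
      if (ov > 0.5 * min(a[2L] - a[1L], hits$end[i] - hits$start[i])) {
        ok <- FALSE; break
      }
    }
    if (ok) acc[[length(acc) + 1L]] <- c(hits$start[i], hits$end[i])
    keep[i] <- ok
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
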