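# Paralogous empty sites, orthologous presence/absence across related
# genomes, and horizontal-transfer screening.

#' Empty-site search parameters
#'
#' @param flank_len Flank length used as query (50 or 100).
#' @param min_flank_identity_pct Identity each flank must reach.
#' @param max_gap Maximum spacing (bp) between the two flank hits for a
#'   locus to count as "adjacent" (tolerates small indels).
#' @return Validated list of class `"empty_site_params"`.
#' @export
empty_site_params <- function(flank_len = 100L,
                              min_flank_identity_pct = 85,
                              max_gap = 15L) {
  if (flank_len <= 0L) stop("flank_len must be positive")
  structure(list(flank_len = as.integer(flank_len),
                 min_flank_identity_pct = min_flank_identity_pct,
                 max_gap = as.integer(max_gap)),
            class = "empty_site_params")
}

#' Horizontal-transfer screening parameters
#'
#' The presence rule is identity/coverage based (>= 60% identity over
#' >= 60% of the consensus length). The BLAST score/e-value pair used
#' historically for this screen is retained as provenance metadata only;
#' e-values depend on engine and database size and do not reproduce.
#'
#' @param min_identity_pct Identity threshold (percent).
#' @param min_length_fraction Consensus coverage threshold.
#' @return Validated list of class `"ht_screen_params"` (with
#'   `legacy_hit_score = 123`, `legacy_evalue = 3e-11` as metadata).
#' @export
ht_screen_params <- function(min_identity_pct = 60,
                             min_length_fraction = 0.6) {
  if (min_length_fraction <= 0 || min_length_fraction > 1)
    stop("min_length_fraction must be in (0, 1]")
  structure(list(min_identity_pct = min_identity_pct,
                 min_length_fraction = min_length_fraction,
                 legacy_hit_score = 123, legacy_evalue = 3e-11),
            class = "ht_screen_params")
}

# Best consistent (ordered, same-strand, small-gap) pairing of left/right
# flank hits in a genome. Returns data.frame of candidate loci.
pair_flank_hits <- function(lh, rh, max_gap) {
  out <- list()
  if (!nrow(lh) || !nrow(rh)) return(NULL)
  for (i in seq_len(nrow(lh))) for (j in seq_len(nrow(rh))) {
    if (lh$strand[i] != rh$strand[j]) next
    if (lh$strand[i] == "+") {
      gap <- rh$start[j] - lh$end[i]
      locus <- c(lh$start[i], rh$end[j])
    } else {
      gap <- lh$start[i] - rh$end[j]
      locus <- c(rh$start[j], lh$end[i])
    }
    if (gap < 0L) next
    out[[length(out) + 1L]] <- data.frame(
      locus_start = locus[1L], locus_end = locus[2L],
      gap_len = gap, strand = lh$strand[i],
      left_identity_pct = lh$identity_pct[i],
      right_identity_pct = rh$identity_pct[j],
      inner_start = if (lh$strand[i] == "+") lh$end[i] else rh$end[j],
      inner_end = if (lh$strand[i] == "+") rh$start[j] else lh$start[i])
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Find paralogous empty sites for one element copy
#'
#' The two flanks of a full-length copy are used as queries against the
#' genome; loci where both align (same order and orientation, separated by
#' at most `max_gap` bp) without an intervening copy of the family are
#' empty paralogous sites: evidence of transposition.
#'
#' @param copy A `"mite_copy"` (full-length, with >= `flank_len` flanks).
#' @param genome The [genome_record()] to search.
#' @param params An [empty_site_params()] list.
#' @param family_copies All annotated copies of the same family on this
#'   genome (used for the exclusion rule).
#' @return List of `"empty_site"` records (`locus`, flank identities,
#'   `gap_len`); empty list if none.
#' @export
find_empty_paralogs <- function(copy, genome,
                                params = empty_site_params(),
                                family_copies = list()) {
  iv <- copy$interval
  L <- nchar(genome$seq)
  fl <- params$flank_len
  if (iv$start < fl || iv$end > L - fl)
    stop("insufficient flank for empty-site search")
  left <- substr(genome$seq, iv$start - fl + 1L, iv$start)
  right <- substr(genome$seq, iv$end + 1L, iv$end + fl)
  lh <- scan_hits(left, genome,
                  min_identity_pct = params$min_flank_identity_pct,
                  min_coverage = 0.8)
  rh <- scan_hits(right, genome,
                  min_identity_pct = params$min_flank_identity_pct,
                  min_coverage = 0.8)
  loci <- pair_flank_hits(lh, rh, params$max_gap)
  if (is.null(loci)) return(list())
  out <- list()
  for (i in seq_len(nrow(loci))) {
    if (loci$gap_len[i] > params$max_gap) next
    # exclude the source locus itself
    if (loci$locus_start[i] < iv$end && loci$locus_end[i] > iv$start) next
    # exclude loci containing a same-family copy
    occupied <- any(vapply(family_copies, function(fc) {
      fiv <- fc$interval
      fiv$start < loci$locus_end[i] && fiv$end > loci$locus_start[i]
    }, TRUE))
    if (occupied) next
    out[[length(out) + 1L]] <- structure(list(
      source_copy = copy,
      locus = interval(genome$id, loci$locus_start[i], loci$locus_end[i],
                       loci$strand[i]),
      left_identity_pct = loci$left_identity_pct[i],
      right_identity_pct = loci$right_identity_pct[i],
      gap_len = loci$gap_len[i]), class = "empty_site")
  }
  out
}

#' Presence/absence matrix at orthologous sites across genomes
#'
#' For each full-length copy, its flanks are searched in every other
#' genome. A genome is `present` at the site when the flanks bracket a
#' same-family copy, `empty` when they sit adjacent (gap <= `max_gap`)
#' with no copy between them, and `unalignable` otherwise. Reciprocal
#' detections of the same locus are merged into one site.
#'
#' @param families List of `"mite_family"` objects (members carry
#'   intervals on their source genomes).
#' @param genomes Named list of >= 2 [genome_record()]s.
#' @param copies_by_genome Named list (by genome id) of annotated copy
#'   lists, used both for anchoring and the bracketing test.
#' @param params An [empty_site_params()] list.
#' @return Object of class `"ortho_site_matrix"`: a list of sites, each
#'   with `family`, `anchor` (genome id + interval) and `status` (named
#'   character vector over genomes).
#' @export
orthologous_site_matrix <- function(families, genomes, copies_by_genome,
                                    params = empty_site_params()) {
  if (length(genomes) < 2L) stop("need >= 2 genomes")
  gids <- names(genomes)
  sites <- list()
  for (fam in families) {
    fam_copies <- lapply(gids, function(g)
      Filter(function(x) x$family == fam$name && x$completeness == "full",
             copies_by_genome[[g]] %||% list()))
    names(fam_copies) <- gids
    all_fam <- lapply(gids, function(g)
      Filter(function(x) x$family == fam$name,
             copies_by_genome[[g]] %||% list()))
    names(all_fam) <- gids
    for (g in gids) {
      for (cp in fam_copies[[g]]) {
        iv <- cp$interval
        gn <- genomes[[g]]
        fl <- params$flank_len
        if (iv$start < fl || iv$end > nchar(gn$seq) - fl) next
        left <- substr(gn$seq, iv$start - fl + 1L, iv$start)
        right <- substr(gn$seq, iv$end + 1L, iv$end + fl)
        status <- stats::setNames(rep("unalignable", length(gids)), gids)
        status[g] <- "present"
        loci <- stats::setNames(vector("list", length(gids)), gids)
        loci[[g]] <- iv
        for (h in setdiff(gids, g)) {
          gh <- genomes[[h]]
          lh <- scan_hits(left, gh,
                          min_identity_pct = params$min_flank_identity_pct,
                          min_coverage = 0.8)
          rh <- scan_hits(right, gh,
                          min_identity_pct = params$min_flank_identity_pct,
                          min_coverage = 0.8)
          pl <- pair_flank_hits(lh, rh, params$max_gap)
          if (is.null(pl)) next
          pl <- pl[order(pl$gap_len), , drop = FALSE]
          best <- pl[1L, ]
          bracketed <- any(vapply(all_fam[[h]], function(fc) {
            fiv <- fc$interval
            fiv$start >= best$inner_start - params$max_gap &&
              fiv$end <= best$inner_end + params$max_gap
          }, TRUE))
          if (bracketed && best$gap_len > params$max_gap) {
            status[h] <- "present"
            loci[[h]] <- interval(h, best$locus_start, best$locus_end)
          } else if (best$gap_len <= params$max_gap) {
            status[h] <- "empty"
            loci[[h]] <- interval(h, best$locus_start, best$locus_end)
          }
        }
        sites[[length(sites) + 1L]] <- list(
          family = fam$name, anchor_genome = g, anchor = iv,
          status = status, loci = loci)
      }
    }
  }
  # merge reciprocal sites: same family, overlapping loci in every genome
  # where both are defined
  merged <- list()
  for (s in sites) {
    dup <- FALSE
    for (m in merged) {
      if (m$family != s$family) next
      shared <- FALSE; conflict <- FALSE
      for (g in gids) {
        a <- m$loci[[g]]; b <- s$loci[[g]]
        if (is.null(a) || is.null(b)) next
        if (a$start < b$end && b$start < a$end) shared <- TRUE
        else conflict <- TRUE
      }
      if (shared && !conflict) { dup <- TRUE; break }
    }
    if (!dup) merged[[length(merged) + 1L]] <- s
  }
  structure(list(sites = merged, genomes = gids),
            class = "ortho_site_matrix")
}

#' @export
print.ortho_site_matrix <- function(x, ...) {
  cat(sprintf("ortho_site_matrix: %d sites x %d genomes\n",
              length(x$sites), length(x$genomes)))
  invisible(x)
}

#' Horizontal-transfer presence call for one family in one genome
#'
#' Best local alignment of the family consensus against the target;
#' `present` when identity and aligned consensus coverage both reach the
#' thresholds (>= 60% / >= 60% by default).
#'
#' @param family A `"mite_family"` with consensus.
#' @param target A [genome_record()].
#' @param params An [ht_screen_params()] list.
#' @return List of class `"ht_call"`: `family`, `query_taxon`,
#'   `target_taxon`, `best_identity_pct`, `coverage`, `present`.
#' @export
ht_presence_call <- function(family, target, params = ht_screen_params()) {
  if (is.null(family$consensus)) stop("family consensus must be built")
  hits <- scan_hits(family$consensus, target, min_identity_pct = 0,
                    min_coverage = 0)
  if (nrow(hits)) {
    best <- hits[which.max(hits$score), ]
    ident <- best$identity_pct
    cov <- best$coverage
  } else {
    ident <- 0; cov <- 0
  }
  structure(list(
    family = family$name,
    query_taxon = family$members[[1L]]$interval$genome_id %||% NA,
    target_taxon = target$taxon,
    best_identity_pct = ident, coverage = cov,
    present = ident >= params$min_identity_pct &&
      cov >= params$min_length_fraction), class = "ht_call")
}

#' Orientation-aware pairwise identity matrix
#'
#' Global-alignment identities for every pair of sequences; each pair is
#' also evaluated against the reverse complement and the larger identity
#' kept, with the orientation recorded. Backs dotplot-style comparisons of
#' putative horizontal-transfer partners.
#'
#' @param seqs Named character vector of >= 2 DNA sequences.
#' @return List with `identity` (symmetric percent matrix, 100 on the
#'   diagonal) and `orientation` (`"+"`/`"-"` matrix).
#' @export
pairwise_identity_matrix <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) stop("need >= 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_len(n))
  idm <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  orm <- matrix("+", n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    fwd <- align_pair(seqs[[i]], seqs[[j]], mode = "global")$identity_pct
    rev <- align_pair(seqs[[i]], revcomp(seqs[[j]]),
                      mode = "global")$identity_pct
    if (rev > fwd) {
      idm[i, j] <- idm[j, i] <- rev
      orm[i, j] <- orm[j, i] <- "-"
    } else {
      idm[i, j] <- idm[j, i] <- fwd
    }
  }
  list(identity = idm, orientation = orm)
}
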