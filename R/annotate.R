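# Boundary refinement from copy+flank alignments, TSD calling,
# false-positive filters, superfamily classification and a hairpin score.

#' Refine family boundaries from a copy+flank multiple alignment
#'
#' Members are extended by `flank_len` on both sides (in member
#' orientation) and aligned. Per-column conservation is the modal-base
#' frequency; boundaries move outward from the family core through
#' conserved columns (>= 0.8 conservation), which recovers element ends
#' that the initial TIR calls clipped, and are then polished to the
#' offset best supported by member TSD calls. If the flanks themselves
#' stay conserved for more than 20 columns the context is ambiguous
#' (tandem/segmental duplication): boundaries are left unchanged and the
#' family is flagged `"boundary_indeterminate"`.
#'
#' @param family A `"mite_family"` with at least 2 members.
#' @param genomes Named list of [genome_record()]s.
#' @param flank_len Flank length added to each member before alignment.
#' @param cons_min Conservation threshold (default 0.8).
#' @return The family with adjusted member intervals (and updated member
#'   sequences), or flagged unchanged.
#' @export
refine_boundaries <- function(family, genomes, flank_len = 100L,
                              cons_min = 0.8, polish = TRUE) {
  members <- family$members
  if (length(members) < 2L) stop("need >= 2 members to refine boundaries")
  exts <- lapply(members, function(m) {
    g <- genomes[[m$interval$genome_id]]
    s <- max(0L, m$interval$start - flank_len)
    e <- min(nchar(g$seq), m$interval$end + flank_len)
    list(seq = extract_seq(g, s, e, m$strand), s = s, e = e,
         lfl = if (m$strand == "+") m$interval$start - s
               else e - m$interval$end,
         core_len = iv_len(m$interval))
  })
  aln <- align_multi(vapply(exts, `[[`, "", "seq"))
  M <- aln_matrix(aln)
  nc <- ncol(M); nm <- nrow(M)
  cons <- vapply(seq_len(nc), function(j) {
    tb <- table(M[, j][M[, j] != "-"])
    if (!length(tb)) 0 else max(tb) / nm
  }, 0)
  # core columns: majority of members inside their current element region
  inside <- matrix(FALSE, nm, nc)
  for (i in seq_len(nm)) {
    pos <- cumsum(M[i, ] != "-")  # residue index per column
    inside[i, ] <- M[i, ] != "-" & pos > exts[[i]]$lfl &
      pos <= exts[[i]]$lfl + exts[[i]]$core_len
  }
  core_frac <- colMeans(inside)
  core_cols <- which(core_frac >= 0.5)
  if (!length(core_cols)) {
    family$flags <- union(family$flags, "boundary_indeterminate")
    return(family)
  }
  cL <- min(core_cols); cR <- max(core_cols)
  conserved <- cons >= cons_min
  # boundaries only move outward from the core edge, greedily through
  # conserved columns (clipped element columns are conserved; flank
  # columns almost never are); the core edge itself is a per-column
  # majority vote over member calls, so per-copy overshoot is already
  # absorbed there
  nL <- cL
  while (nL > 1L && conserved[nL - 1L]) nL <- nL - 1L
  nR <- cR
  while (nR < nc && conserved[nR + 1L]) nR <- nR + 1L
  if ((cL - nL) > 20L || (nR - cR) > 20L) {
    family$flags <- union(family$flags, "boundary_indeterminate")
    return(family)
  }
  # map refined columns back to member coordinates
  res_ls <- rep(NA_integer_, nm); res_rs <- rep(NA_integer_, nm)
  for (i in seq_len(nm)) {
    row <- M[i, ]
    pos <- cumsum(row != "-")
    # first residue at or after nL; last residue at or before nR
    res_l <- if (row[nL] != "-") pos[nL] else {
      nxt <- which(row != "-" & seq_len(nc) >= nL)
      if (!length(nxt)) next else pos[nxt[1L]]
    }
    res_r <- if (row[nR] != "-") pos[nR] else {
      prv <- which(row != "-" & seq_len(nc) <= nR)
      if (!length(prv)) next else pos[prv[length(prv)]]
    }
    if (res_r < res_l) next
    res_ls[i] <- res_l; res_rs[i] <- res_r
    ex <- exts[[i]]
    m <- members[[i]]
    if (m$strand == "+") {
      new_s <- ex$s + res_l - 1L
      new_e <- ex$s + res_r
    } else {
      new_e <- ex$e - (res_l - 1L)
      new_s <- ex$e - res_r
    }
    g <- genomes[[m$interval$genome_id]]
    m$interval <- interval(m$interval$genome_id, new_s, new_e, m$strand)
    m$seq <- extract_seq(g, new_s, new_e, m$strand)
    members[[i]] <- m
  }
  family$members <- members
  if (!polish) return(family)
  # TSD polish: the duplication test (left flank suffix == right flank
  # prefix at each site) is the only signal that separates the element
  # boundary from TIR-like sequence such as a palindromic TSD, which
  # pairs with itself and masquerades as extra TIR columns. Each member
  # is micro-adjusted (+/- 6 bp per end, in element orientation)
  # individually - per-member alignment wobble makes a single shared
  # offset unreliable - but the family must agree on one TSD length:
  # the length supported by the most members wins (ties: the longer).
  # Inward moves may only excise residues from unconserved columns, so a
  # conserved element terminus can never be re-labelled as TSD.
  delta_max <- 6L
  tsd_max_len <- 10L
  adjust <- function(m, d5, d3) {
    iv <- m$interval
    if (iv$strand == "+") {
      s <- iv$start + d5; e <- iv$end + d3
    } else {
      s <- iv$start - d3; e <- iv$end - d5  # 5' end sits at the genome end
    }
    if (e - s < 20L) return(NULL)
    tryCatch(interval(iv$genome_id, s, e, iv$strand),
             error = function(err) NULL)
  }
  unconserved_streak <- function(cols) {
    k <- 0L
    for (cl in cols) {
      if (is.na(cl) || cl < 1L || cl > nc || conserved[cl]) break
      k <- k + 1L
    }
    k
  }
  cands <- vector("list", nm)
  for (i in seq_len(nm)) {
    if (is.na(res_ls[i])) next
    colof <- which(M[i, ] != "-")
    nres <- length(colof)
    take <- function(res) if (any(res < 1L | res > nres)) rep(NA_integer_,
      length(res)) else colof[res]
    in5 <- unconserved_streak(take(res_ls[i] + 0:5))
    in3 <- unconserved_streak(take(res_rs[i] - 0:5))
    rows <- list()
    for (d5 in seq(-delta_max, min(in5, delta_max)))
      for (d3 in seq(-min(in3, delta_max), delta_max)) {
        iv <- adjust(members[[i]], d5, d3)
        if (is.null(iv)) next
        tc <- tryCatch(call_tsd(iv, genomes[[iv$genome_id]],
                                max_len = tsd_max_len),
                       error = function(e) NULL)
        if (!is.null(tc))
          rows[[length(rows) + 1L]] <- c(d5 = d5, d3 = d3,
                                         len = tc$length)
      }
    if (length(rows)) cands[[i]] <- do.call(rbind, rows)
  }
  lens_seen <- sort(unique(unlist(lapply(cands, function(x)
    if (is.null(x)) NULL else x[, "len"]))))
  if (length(lens_seen)) {
    support <- vapply(lens_seen, function(L) sum(vapply(cands, function(x)
      !is.null(x) && any(x[, "len"] == L), TRUE)), 0L)
    # chance repeats scatter across the offset box; the true duplication
    # sits at small, consistent offsets - rank lengths by support, then
    # by the mean minimal offset of their supporters, then by length
    mean_off <- vapply(lens_seen, function(L) {
      offs <- vapply(cands, function(x) {
        if (is.null(x)) return(NA_real_)
        sel <- x[, "len"] == L
        if (!any(sel)) return(NA_real_)
        min(abs(x[sel, "d5"]) + abs(x[sel, "d3"]))
      }, 0)
      mean(offs, na.rm = TRUE)
    }, 0)
    Lstar <- lens_seen[order(-support, mean_off, -lens_seen)][1L]
    i_star <- which(lens_seen == Lstar)
    # gate: chance repeats of length <= 3 are common enough that support
    # alone cannot distinguish a real short TSD from none; a real one is
    # betrayed by offsets concentrated at the refined boundaries
    if (Lstar <= 3L && mean_off[i_star] > 1.5) return(family)
    for (i in seq_len(nm)) {
      x <- cands[[i]]
      if (is.null(x)) next
      # a member whose true duplication chance-extended beyond L* still
      # counts (len >= L*), but an off-by-one boundary with a chance
      # L*+1 repeat must not outrank the family length at a 1-bp
      # offset: non-modal lengths carry a 1.5-bp offset penalty
      x <- x[x[, "len"] >= Lstar, , drop = FALSE]
      if (!nrow(x)) next
      pick <- order(abs(x[, "d5"]) + abs(x[, "d3"]) +
                      1.5 * (x[, "len"] != Lstar),
                    -x[, "len"], x[, "d5"], x[, "d3"])[1L]
      iv <- adjust(members[[i]], x[pick, "d5"], x[pick, "d3"])
      if (is.null(iv)) next
      g <- genomes[[iv$genome_id]]
      if (iv$start < 0L || iv$end > nchar(g$seq)) next
      members[[i]]$interval <- iv
      members[[i]]$seq <- extract_seq(g, iv$start, iv$end, iv$strand)
    }
  }
  family$members <- members
  family
}

#' Call the target site duplication of one copy
#'
#' Longest exact direct repeat of length `2..max_len` whose left copy ends
#' exactly at the element start and whose right copy begins exactly at the
#' element end. Exact match is required: the TSD is a literal duplication
#' of the target motif created at insertion.
#'
#' @param copy An [interval()] (0-based half-open element coordinates).
#' @param genome The [genome_record()] it lives on.
#' @param max_len Longest TSD searched (default 10).
#' @return A `"tsd_call"` list (`seq`, `length`, `left_interval`,
#'   `right_interval`) or `NULL` when no repeat of length >= 2 exists.
#' @export
call_tsd <- function(copy, genome, max_len = 10L) {
  L <- nchar(genome$seq)
  if (copy$start < max_len || copy$end > L - max_len)
    stop("insufficient flank for TSD search (need ", max_len,
         " bp on both sides)")
  left <- substr(genome$seq, copy$start - max_len + 1L, copy$start)
  right <- substr(genome$seq, copy$end + 1L, copy$end + max_len)
  for (m in max_len:2L) {
    lw <- substr(left, max_len - m + 1L, max_len)
    rw <- substr(right, 1L, m)
    if (lw == rw && !grepl("N", lw, fixed = TRUE)) {
      return(structure(list(
        seq = lw, length = m,
        left_interval = interval(copy$genome_id, copy$start - m,
                                 copy$start),
        right_interval = interval(copy$genome_id, copy$end,
                                  copy$end + m)),
        class = "tsd_call"))
    }
  }
  NULL
}

# Detect the TIR of a consensus by pairing its two ends (anchor at the
# sequence midpoint). Returns list(left, right, arm, mismatches) or NULL.
consensus_tir <- function(consensus, params = discovery_params()) {
  n <- nchar(consensus)
  if (n < 2L * params$tir_min_len) return(NULL)
  sc <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  cc <- unname(.COMP[sc]); cc[is.na(cc)] <- "N"
  maxarm <- min(params$tir_max_len, floor(n / 2))
  mv <- sc[seq_len(maxarm)] == cc[n + 1L - seq_len(maxarm)] &
    sc[seq_len(maxarm)] != "N"
  if (!mv[1L]) return(NULL)  # arm must start at the very terminus
  cs <- cumsum(!mv)
  ok <- which(mv & cs <= params$tir_max_mismatch)
  if (!length(ok)) return(NULL)
  arm <- max(ok)
  if (arm < params$tir_min_len) return(NULL)
  list(left = substr(consensus, 1L, arm),
       right = substr(consensus, n - arm + 1L, n),
       arm = arm, mismatches = cs[arm])
}

#' Apply the false-positive filters to a candidate family
#'
#' A family is rejected when (in this order) its consensus exceeds 800 bp
#' (`too_long`); it has no TIR within the mismatch budget (`no_tir`);
#' fewer than two members yield an identical-length TSD call (`no_tsd`,
#' waived for families with a perfect >= 10 bp TIR when the signature
#' table carries a TSD-less superfamily such as IS200/IS605); or its
#' consensus contains a >= 80% identity match covering >= 50% of another
#' family's consensus (`compound`).
#'
#' @param family A `"mite_family"` with consensus and member TSD calls.
#' @param other_families Other families, for the compound check.
#' @param params A [discovery_params()] list.
#' @param signatures Signature table (see [default_signatures()]), used
#'   only for the TSD-less exemption.
#' @return List of class `"filter_verdict"`: `keep` (logical) and
#'   `reason` in `{"ok","too_long","no_tir","no_tsd","compound"}`.
#' @export
apply_candidate_filters <- function(family, other_families = list(),
                                    params = discovery_params(),
                                    signatures = default_signatures()) {
  verdict <- function(keep, reason)
    structure(list(keep = keep, reason = reason), class = "filter_verdict")
  cons <- family$consensus
  if (is.null(cons)) stop("family consensus must be built before filtering")
  if (nchar(cons) > params$elem_max_len) return(verdict(FALSE, "too_long"))
  tir <- family$tir %||% consensus_tir(cons, params)
  if (is.null(tir)) return(verdict(FALSE, "no_tir"))
  tsd_lens <- member_tsd_lengths(family)
  has_tsd <- length(tsd_lens) >= 2L && max(table(tsd_lens)) >= 2L
  if (!has_tsd) {
    exempt <- any(vapply(signatures, function(s)
      identical(s$tsd_lengths, 0L), TRUE)) &&
      tir$mismatches == 0L && tir$arm >= 10L
    if (!exempt) return(verdict(FALSE, "no_tsd"))
  }
  for (of in other_families) {
    if (is.null(of$consensus)) next
    if (identical(of$consensus, cons)) next
    al <- align_pair(of$consensus, cons, mode = "local")
    if (al$identity_pct >= 80 && al$coverage_of_a >= 0.5 &&
        nchar(cons) > nchar(of$consensus))
      return(verdict(FALSE, "compound"))
  }
  verdict(TRUE, "ok")
}

member_tsd_lengths <- function(family) {
  unlist(lapply(family$members, function(m) {
    t <- m$tsd
    if (is.null(t)) NULL else t$length
  }))
}

member_tsd_seqs <- function(family) {
  unlist(lapply(family$members, function(m) {
    t <- m$tsd
    if (is.null(t)) NULL else t$seq
  }))
}

#' Default superfamily signature table
#'
#' TIR/TSD signatures of the DNA-transposon superfamilies relevant to
#' MITEs in small genomes: hAT (8-bp TSD, no terminus motif), hATm
#' (8-9 bp TSD, TAGGGTG/CACCCTA termini, <= 1 mismatch), CMC/CACTA
#' (2-3 bp TSD, invariable CAC/GTG termini), Tc1/mariner (2-bp TSD that
#' must itself be "TA"), and IS200/IS605-like (no TSD; requires a perfect
#' >= 10 bp TIR). Shipped as an editable TSV in `inst/extdata`.
#'
#' @param path Optional path to a signature TSV (columns `name`,
#'   `tsd_lengths` (comma-separated), `terminus_5p`, `max_mismatch`,
#'   `tsd_motif`).
#' @return List of signature records.
#' @export
default_signatures <- function(path = system.file(
    "extdata", "superfamily_signatures.tsv", package = "mitescan")) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE, fill = TRUE,
                          colClasses = "character", na.strings = NULL)
  tb[is.na(tb)] <- ""
  lapply(seq_len(nrow(tb)), function(i) {
    list(name = tb$name[i],
         tsd_lengths = as.integer(strsplit(tb$tsd_lengths[i], ",")[[1L]]),
         terminus_5p = if (nzchar(tb$terminus_5p[i])) tb$terminus_5p[i]
                       else NA_character_,
         terminus_3p = if (nzchar(tb$terminus_5p[i]))
                       revcomp(tb$terminus_5p[i]) else NA_character_,
         max_terminus_mismatch = as.integer(tb$max_mismatch[i]),
         tsd_motif = if (nzchar(tb$tsd_motif[i])) tb$tsd_motif[i]
                     else NA_character_)
  })
}

count_mismatches <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(ca != cb)
}

#' Classify a family into a superfamily by TIR/TSD signature
#'
#' The best signature whose TSD-length set contains the family's modal
#' TSD length and whose terminal motifs match the consensus ends within
#' the allowed mismatches wins; ties are broken by longer terminus motif.
#' A signature with a TSD motif (Tc1/mariner "TA") additionally requires
#' the modal TSD sequence to equal that motif.
#'
#' @param family A `"mite_family"` with consensus and TSD calls.
#' @param signatures Signature table from [default_signatures()].
#' @return Superfamily name, or `"Unknown"`.
#' @export
classify_superfamily <- function(family, signatures = default_signatures()) {
  cons <- family$consensus
  if (is.null(cons)) stop("family consensus must be built first")
  tsd_lens <- member_tsd_lengths(family)
  modal_len <- if (length(tsd_lens)) modal_value(tsd_lens) else 0L
  tsd_seqs <- member_tsd_seqs(family)
  modal_seq <- if (length(tsd_seqs))
    names(sort(table(tsd_seqs), decreasing = TRUE))[1L] else NA_character_
  best <- NULL; best_motif_len <- -1L
  for (sg in signatures) {
    if (!(modal_len %in% sg$tsd_lengths)) next
    if (!is.na(sg$tsd_motif) &&
        (is.na(modal_seq) || modal_seq != sg$tsd_motif)) next
    mlen <- 0L
    if (!is.na(sg$terminus_5p)) {
      mlen <- nchar(sg$terminus_5p)
      if (nchar(cons) < 2L * mlen) next
      mm5 <- count_mismatches(substr(cons, 1L, mlen), sg$terminus_5p)
      mm3 <- count_mismatches(
        substr(cons, nchar(cons) - mlen + 1L, nchar(cons)),
        sg$terminus_3p)
      if (mm5 > sg$max_terminus_mismatch ||
          mm3 > sg$max_terminus_mismatch) next
    } else if (identical(sg$tsd_lengths, 0L)) {
      tir <- family$tir %||% consensus_tir(cons)
      if (is.null(tir) || tir$mismatches > 0L || tir$arm < 10L) next
    }
    if (mlen > best_motif_len) {
      best <- sg$name; best_motif_len <- mlen
    }
  }
  best %||% "Unknown"
}

#' Hairpin pairing score of a sequence
#'
#' Global alignment of the 5' half against the reverse complement of the
#' 3' half; the score is the fraction of aligned columns that match. A
#' stand-in for thermodynamic folding: MITEs with paired TIR-containing
#' arms score high, unstructured sequence scores near the random baseline.
#'
#' @param seq DNA string of length >= 20.
#' @return Score in `[0, 1]`.
#' @export
hairpin_pairing_score <- function(seq) {
  n <- nchar(seq)
  if (n < 20L) stop("sequence too short for a hairpin score (need >= 20)")
  half <- floor(n / 2)
  a <- substr(seq, 1L, half)
  b <- revcomp(substr(seq, n - half + 1L, n))
  al <- align_pair(a, b, mode = "global")
  al$n_matches / al$n_columns
}
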