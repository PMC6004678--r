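# De novo detection of TIR-flanked candidate elements and clustering into
# multi-copy families.

#' Discovery parameters
#'
#' @param tir_min_len Minimum TIR arm length (>= 4).
#' @param tir_max_len Maximum TIR arm length.
#' @param tir_max_mismatch Mismatch budget between the two arms.
#' @param elem_min_len,elem_max_len Element length window. Elements longer
#'   than 800 bp are outside the MITE size class and are never reported.
#' @param min_copies Minimum cluster size for a family (>= 2).
#' @param cluster_min_identity_pct Single-linkage identity threshold.
#' @param max_n_frac Candidate windows with more than this fraction of `N`
#'   are dropped (ambiguity-dominated assembly regions).
#' @return A validated parameter list of class `"discovery_params"`.
#' @export
discovery_params <- function(tir_min_len = 8L, tir_max_len = 60L,
                             tir_max_mismatch = 2L, elem_min_len = 50L,
                             elem_max_len = 800L, min_copies = 3L,
                             cluster_min_identity_pct = 80,
                             max_n_frac = 0.2) {
  p <- list(tir_min_len = as.integer(tir_min_len),
            tir_max_len = as.integer(tir_max_len),
            tir_max_mismatch = as.integer(tir_max_mismatch),
            elem_min_len = as.integer(elem_min_len),
            elem_max_len = as.integer(elem_max_len),
            min_copies = as.integer(min_copies),
            cluster_min_identity_pct = cluster_min_identity_pct,
            max_n_frac = max_n_frac)
  if (p$tir_min_len < 4L) stop("tir_min_len must be >= 4")
  if (p$elem_min_len >= p$elem_max_len)
    stop("elem_min_len must be < elem_max_len")
  if (p$min_copies < 2L) stop("min_copies must be >= 2")
  structure(p, class = "discovery_params")
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Verify/extend one seed pair into a TIR arm. `sc` is the genome as a char
# vector, `cc` its per-position complement. Seed: left k-mer at i pairs
# with (the reverse complement) k-mer at j; anchor C = i + j + k - 1 so a
# left-arm position p pairs with right position C - p. Returns the best
# (longest arm, then fewest mismatches, then outermost) TIR consistent
# with the parameters, or NULL.
tir_verify <- function(sc, cc, i, j, k, params) {
  L <- length(sc)
  Canchor <- i + j + k - 1L
  tlo <- max(-(params$tir_max_len - 1L), 1L - i, Canchor - L - i)
  thi <- min(params$tir_max_len - 1L,
             floor((j - i + k - 2L) / 2))  # arms must not cross
  if (thi < k - 1L) return(NULL)
  tt <- tlo:thi
  lp <- i + tt
  rp <- Canchor - lp
  mv <- sc[lp] == cc[rp] & sc[lp] != "N"
  off <- 1L - tlo  # index of t = 0
  t0s <- tt[tt <= 0L & mv]
  t1s <- tt[tt >= (k - 1L) & mv]
  if (!length(t0s) || !length(t1s)) return(NULL)
  cs <- cumsum(!mv)
  # evaluate all (outer, inner) arm delimitations; prefer fewest
  # mismatches, then the longer arm, then the outermost boundary -
  # minimizing mismatches first keeps boundaries from drifting outward
  # on chance-paired flanking bases
  grid_t0 <- rep(t0s, times = length(t1s))
  grid_t1 <- rep(t1s, each = length(t0s))
  arm <- grid_t1 - grid_t0 + 1L
  elen <- Canchor - 2L * (i + grid_t0)
  mism <- cs[grid_t1 + off] - cs[grid_t0 + off] +
    as.integer(!mv[grid_t0 + off])
  ok <- arm >= params$tir_min_len & arm <= params$tir_max_len &
    arm <= floor(elen / 2) & mism <= params$tir_max_mismatch &
    elen >= params$elem_min_len & elen <= params$elem_max_len
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  b_i <- cand[order(mism[cand], -arm[cand], grid_t0[cand])][1L]
  a <- i + grid_t0[b_i]
  b <- Canchor - a
  list(a = a, b = b, arm = arm[b_i], mism = mism[b_i])
}

#' Find TIR-flanked candidate elements in a genome
#'
#' Seed-and-verify search for inverted-repeat pairs delimiting elements in
#' the configured length window: exact k-mer seeds matching their reverse
#' complement downstream are extended outward/inward under the arm
#' mismatch budget. Overlapping candidates sharing more than half their
#' span are reduced to the one with fewer TIR mismatches (tie: longer TIR,
#' then leftmost). Circular genomes are scanned on a linearized copy
#' extended by `elem_max_len - 1` wrap-around bases.
#'
#' @param genome A [genome_record()].
#' @param params A [discovery_params()] list.
#' @return List of candidate elements, each with `interval`, `tir_left`,
#'   `tir_right`, `tir_mismatches` and `seq`; sorted by start.
#' @export
find_tir_candidates <- function(genome, params = discovery_params()) {
  seq0 <- genome$seq
  L0 <- nchar(seq0)
  if (L0 < params$elem_min_len)
    stop("genome shorter than elem_min_len")
  seq <- if (genome$circular && L0 > params$elem_max_len)
    paste0(seq0, substr(seq0, 1L, params$elem_max_len - 1L)) else seq0
  L <- nchar(seq)
  # seeds shorter than the minimum arm tolerate internal arm mismatches
  k <- max(4L, min(6L, params$tir_min_len))
  sc <- strsplit(seq, "", fixed = TRUE)[[1L]]
  cc <- unname(.COMP[sc])
  cc[is.na(cc)] <- "N"
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  rc_at <- function(i) paste(rev(cc[i:(i + k - 1L)]), collapse = "")
  # hash k-mer -> positions
  env <- list2env(split(starts, kmers), hash = TRUE)
  rseq <- paste(rev(cc), collapse = "")
  rc_kmers <- substring(rseq, L - starts - k + 2L, L - starts + 1L)
  lo_off <- params$elem_min_len - k
  hi_off <- params$elem_max_len - k
  pairs_i <- vector("list", 2000L); pairs_j <- vector("list", 2000L)
  np <- 0L
  for (ii in seq_along(starts)) {
    js <- get0(rc_kmers[ii], envir = env, inherits = FALSE)
    if (is.null(js)) next
    js <- js[js >= ii + lo_off & js <= ii + hi_off & js > ii + k]
    if (!length(js)) next
    np <- np + 1L
    if (np > length(pairs_i)) {
      length(pairs_i) <- 2L * np; length(pairs_j) <- 2L * np
    }
    pairs_i[[np]] <- rep.int(ii, length(js))
    pairs_j[[np]] <- js
  }
  if (np == 0L) return(list())
  pi_ <- unlist(pairs_i[seq_len(np)]); pj_ <- unlist(pairs_j[seq_len(np)])
  o <- order(pi_ + pj_, pi_)
  pi_ <- pi_[o]; pj_ <- pj_[o]
  cands <- list()
  seen <- character()
  for (idx in seq_along(pi_)) {
    v <- tir_verify(sc, cc, pi_[idx], pj_[idx], k, params)
    if (is.null(v)) next
    key <- paste0(v$a, ":", v$b)
    if (key %in% seen) next
    seen <- c(seen, key)
    eseq <- substr(seq, v$a, v$b)
    nfrac <- mean(strsplit(eseq, "", fixed = TRUE)[[1L]] == "N")
    if (nfrac > params$max_n_frac) {
      message("dropping N-dominated candidate at ", v$a - 1L, "-", v$b)
      next
    }
    a0 <- v$a - 1L  # 0-based
    if (a0 >= L0) next  # duplicate image of an origin-spanning candidate
    cands[[length(cands) + 1L]] <- list(
      interval = interval(genome$id, a0,
                          if (v$b <= L0) v$b else L0, "+"),
      wraps = v$b > L0,
      full_end = v$b,
      tir_left = substr(seq, v$a, v$a + v$arm - 1L),
      tir_right = substr(seq, v$b - v$arm + 1L, v$b),
      tir_mismatches = v$mism,
      tir_len = v$arm,
      seq = eseq)
  }
  if (!length(cands)) return(list())
  # overlap reduction: >50% shared span -> fewer mismatches, longer TIR,
  # leftmost
  mism <- vapply(cands, `[[`, 0L, "tir_mismatches")
  arm <- vapply(cands, `[[`, 0L, "tir_len")
  st <- vapply(cands, function(x) x$interval$start, 0L)
  en <- vapply(cands, function(x) x$full_end, 0L)
  pref <- order(mism, -arm, st)
  keep <- logical(length(cands))
  for (i in pref) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- max(0L, min(en[i], en[j]) - max(st[i], st[j]))
      if (ov > 0.5 * min(en[i] - st[i], en[j] - st[j])) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  cands <- cands[keep]
  cands[order(vapply(cands, function(x) x$interval$start, 0L))]
}

#' Cluster candidate elements into provisional families
#'
#' Single-linkage clustering on pairwise identity over mutually covered
#' sequence: two candidates are linked when a local alignment (in either
#' relative orientation) reaches the identity threshold with at least 80%
#' coverage of both. Clusters smaller than `min_copies` are discarded.
#' Members are oriented consistently against the cluster's longest member;
#' the family plus strand is later fixed by the lexicographic rule on the
#' consensus (see [build_family()]).
#'
#' @param candidates List of candidates from [find_tir_candidates()]
#'   (possibly pooled across genomes).
#' @param genomes Named list of [genome_record()]s the candidates came from.
#' @param params A [discovery_params()] list.
#' @return List of provisional families of class `"mite_family"` (no
#'   consensus/classification yet), ordered by decreasing size then
#'   first-member position.
#' @export
cluster_into_families <- function(candidates, genomes,
                                  params = discovery_params()) {
  n <- length(candidates)
  if (n == 0L) return(list())
  seqs <- vapply(candidates, `[[`, "", "seq")
  lens <- nchar(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1L) {
    # shared-k-mer prefilter (both orientations): only pairs with several
    # exact 11-mers in common can reach the identity/coverage thresholds
    k <- 11L
    km_list <- lapply(seq_len(n), function(i) {
      if (lens[i] < k) return(character())
      st <- seq_len(lens[i] - k + 1L)
      unique(c(substring(seqs[i], st, st + k - 1L),
               substring(revcomp(seqs[i]), st, st + k - 1L)))
    })
    by_km <- split(rep.int(seq_len(n), lengths(km_list)),
                   unlist(km_list))
    by_km <- by_km[lengths(by_km) >= 2L & lengths(by_km) <= 100L]
    pair_keys <- unlist(lapply(by_km, function(ids) {
      cmb <- utils::combn(sort(ids), 2L)
      paste(cmb[1L, ], cmb[2L, ], sep = ":")
    }))
    if (length(pair_keys)) {
      tall <- table(pair_keys)
      keys <- names(tall)[tall >= 5L]
      if (length(keys)) {
        km <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
        pi_ <- as.integer(km[, 1L]); pj_ <- as.integer(km[, 2L])
        keep <- pmin(lens[pi_], lens[pj_]) /
          pmax(lens[pi_], lens[pj_]) >= 0.7
        pi_ <- pi_[keep]; pj_ <- pj_[keep]
        # batch the candidate alignments per shared subject (the
        # higher-frequency partner, so batches are as large as
        # possible): one vectorized call per subject per orientation
        freq <- tabulate(c(pi_, pj_), nbins = n)
        swap <- freq[pi_] > freq[pj_]
        subj <- ifelse(swap, pi_, pj_)
        quer <- ifelse(swap, pj_, pi_)
        ss_all <- Biostrings::DNAStringSet(seqs)
        rc_all <- Biostrings::reverseComplement(ss_all)
        # after a few failed link attempts against members of one
        # component, further attempts against that component are
        # hopeless (members are >= 80% alike) and are skipped
        fails <- new.env(hash = TRUE)
        failed_out <- function(q, root) {
          (get0(paste0(q, ":", root), envir = fails,
                inherits = FALSE) %||% 0L) >= 3L
        }
        grp_sizes <- table(subj)
        for (j in as.integer(names(sort(grp_sizes,
                                        decreasing = TRUE)))) {
          is <- sort(unique(quer[subj == j]))
          is <- is[vapply(is, function(q) {
            find(q) != find(j) && !failed_out(q, find(j)) &&
              !failed_out(j, find(q))
          }, TRUE)]
          if (!length(is)) next
          pat_f <- ss_all[is]
          pat_r <- rc_all[is]
          sub <- ss_all[[j]]
          paf <- Biostrings::pairwiseAlignment(
            pat_f, sub, type = "local", substitutionMatrix = .submat(),
            gapOpening = 5, gapExtension = 2)
          par_ <- Biostrings::pairwiseAlignment(
            pat_r, sub, type = "local", substitutionMatrix = .submat(),
            gapOpening = 5, gapExtension = 2)
          metrics <- function(pa) {
            # alignment columns = aligned pattern residues + gaps opened
            # in the pattern view (avoids materializing gapped strings)
            rp <- end(Biostrings::pattern(pa)) -
              start(Biostrings::pattern(pa)) + 1L
            gaps <- vapply(BiocGenerics::width(
              Biostrings::indel(Biostrings::pattern(pa))), sum, 0L)
            ncols <- rp + gaps
            list(ident = 100 * Biostrings::nmatch(pa) / ncols,
                 cov_i = (end(Biostrings::pattern(pa)) -
                          start(Biostrings::pattern(pa)) + 1L) / lens[is],
                 cov_j = (end(Biostrings::subject(pa)) -
                          start(Biostrings::subject(pa)) + 1L) / lens[j])
          }
          mf <- metrics(paf); mr <- metrics(par_)
          use_r <- BiocGenerics::score(par_) > BiocGenerics::score(paf)
          for (idx in seq_along(is)) {
            m <- if (use_r[idx]) mr else mf
            if (m$ident[idx] >= params$cluster_min_identity_pct &&
                m$cov_i[idx] >= 0.8 && m$cov_j[idx] >= 0.8) {
              if (find(is[idx]) != find(j))
                parent[find(j)] <- find(is[idx])
            } else {
              key <- paste0(is[idx], ":", find(j))
              assign(key, (get0(key, envir = fails,
                                inherits = FALSE) %||% 0L) + 1L,
                     envir = fails)
            }
          }
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  fams <- list()
  for (r in unique(roots)) {
    members_idx <- which(roots == r)
    if (length(members_idx) < params$min_copies) next
    # orient members against the longest member of the cluster
    ref <- members_idx[which.max(lens[members_idx])]
    members <- lapply(members_idx, function(ci) {
      cd <- candidates[[ci]]
      strand <- "+"
      if (ci != ref) {
        af <- align_pair(cd$seq, seqs[ref], mode = "local")
        ar <- align_pair(revcomp(cd$seq), seqs[ref], mode = "local")
        if (ar$score > af$score) {
          cd$seq <- revcomp(cd$seq)
          strand <- "-"
          tl <- cd$tir_left
          cd$tir_left <- revcomp(cd$tir_right)
          cd$tir_right <- revcomp(tl)
        }
      }
      cd$interval$strand <- strand
      list(interval = cd$interval, seq = cd$seq, strand = strand,
           tir_left = cd$tir_left, tir_right = cd$tir_right,
           tir_mismatches = cd$tir_mismatches)
    })
    ord <- order(vapply(members, function(m) m$interval$genome_id, ""),
                 vapply(members, function(m) m$interval$start, 0L))
    fams[[length(fams) + 1L]] <- new_mite_family(members = members[ord])
  }
  sizes <- vapply(fams, function(f) length(f$members), 0L)
  firsts <- vapply(fams, function(f) f$members[[1L]]$interval$start, 0L)
  fams[order(-sizes, firsts)]
}

#' Construct a MITE family object
#'
#' @param members List of member copies (interval, oriented seq, strand).
#' @param name,superfamily,consensus,tir,tsd_length Optional slots filled
#'   by downstream stages.
#' @param flags Character vector of quality flags.
#' @return Object of class `"mite_family"`.
#' @export
new_mite_family <- function(members, name = NA_character_,
                            superfamily = NA_character_, consensus = NULL,
                            tir = NULL, tsd_length = NA_integer_,
                            flags = character()) {
  structure(list(name = name, superfamily = superfamily,
                 consensus = consensus, tir = tir,
                 tsd_length = tsd_length, members = members,
                 flags = flags),
            class = "mite_family")
}

#' @export
print.mite_family <- function(x, ...) {
  cat(sprintf(
    "mite_family '%s' [%s]: %d members, consensus %s bp, TSD %s\n",
    x$name, x$superfamily, length(x$members),
    if (is.null(x$consensus)) "?" else nchar(x$consensus),
    x$tsd_length))
  invisible(x)
}
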