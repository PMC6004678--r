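# Consensus building, library-based copy annotation (masking),
# per-family statistics, and per-copy divergence.

#' Masking parameters
#'
#' @param min_fragment_len Hits shorter than this are excluded (default
#'   80 bp, the conventional fragment floor for MITE copy counting).
#' @param min_identity_pct Minimum identity for a hit to count as a copy.
#' @param min_copy_coverage Aligned consensus fraction at or above which a
#'   copy is labeled `full` (below: `fragment`). Default 0.8.
#' @return Validated list of class `"mask_params"`.
#' @export
mask_params <- function(min_fragment_len = 80L, min_identity_pct = 70,
                        min_copy_coverage = 0.8) {
  if (min_fragment_len < 1L) stop("min_fragment_len must be >= 1")
  structure(list(min_fragment_len = as.integer(min_fragment_len),
                 min_identity_pct = min_identity_pct,
                 min_copy_coverage = min_copy_coverage),
            class = "mask_params")
}

#' Majority-rule consensus of a multiple alignment
#'
#' Per column, the majority base among non-gap characters; columns with
#' less than 50% non-gap occupancy are dropped; ties are broken by the
#' fixed base order A < C < G < T.
#'
#' @param aligned Character vector (>= 2) of equal-length gapped strings.
#' @return The consensus DNA string.
#' @export
build_consensus <- function(aligned) {
  if (length(aligned) < 2L) stop("need >= 2 aligned sequences")
  if (length(unique(nchar(aligned))) != 1L)
    stop("aligned sequences must have equal length")
  M <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  n <- nrow(M)
  bases <- c("A", "C", "G", "T")
  cols <- vapply(seq_len(ncol(M)), function(j) {
    col <- M[, j]
    nongap <- col[col != "-"]
    if (length(nongap) < n / 2) return("")
    cnt <- vapply(bases, function(b) sum(nongap == b), 0L)
    if (all(cnt == 0L)) return("N")
    bases[which.max(cnt)]  # which.max takes the first max: A < C < G < T
  }, "")
  paste(cols[cols != ""], collapse = "")
}

#' Annotate copies of library families in a genome
#'
#' Scans the genome with each family consensus (local, both strands),
#' keeps hits at or above the identity threshold, discards fragments
#' shorter than `min_fragment_len`, and labels completeness from aligned
#' consensus coverage. Overlapping hits to the same family are already
#' merged by the scanner.
#'
#' @param genome A [genome_record()].
#' @param library List of `"mite_family"` objects with consensus built.
#' @param params A [mask_params()] list.
#' @param tsd_max_len TSD search window for per-copy TSD calls (copies
#'   without sufficient flank get `tsd = NULL`).
#' @return List of `"mite_copy"` records: `interval`, `family`,
#'   `completeness`, `divergence`, `tsd`, `identity_pct`.
#' @export
annotate_copies <- function(genome, library, params = mask_params(),
                            tsd_max_len = 10L) {
  if (!length(library)) stop("library must be non-empty")
  copies <- list()
  for (fam in library) {
    if (is.null(fam$consensus)) stop("library family without consensus")
    hits <- scan_hits(fam$consensus, genome,
                      min_identity_pct = params$min_identity_pct)
    if (!nrow(hits)) next
    hits <- hits[hits$end - hits$start >= params$min_fragment_len, ,
                 drop = FALSE]
    for (i in seq_len(nrow(hits))) {
      iv <- interval(genome$id, hits$start[i], hits$end[i],
                     hits$strand[i])
      tsd <- tryCatch(call_tsd(iv, genome, max_len = tsd_max_len),
                      error = function(e) NULL)
      copies[[length(copies) + 1L]] <- structure(list(
        interval = iv,
        family = fam$name,
        completeness = if (hits$coverage[i] >= params$min_copy_coverage)
          "full" else "fragment",
        divergence = hits$subst_frac[i],
        identity_pct = hits$identity_pct[i],
        tsd = tsd), class = "mite_copy")
    }
  }
  ord <- order(vapply(copies, function(x) x$interval$start, 0L))
  copies[ord]
}

#' Per-family statistics on one genome
#'
#' @param copies List of `"mite_copy"` records on `genome`.
#' @param genome The [genome_record()].
#' @return List of class `"family_stats"`: `copy_count`, `bp_covered`
#'   (union of copy intervals, so nested/overlapping hits never double
#'   count), `genome_fraction`, `divergence_histogram` (counts in 0.05
#'   bins).
#' @export
family_stats <- function(copies, genome) {
  bad <- vapply(copies, function(x) x$interval$genome_id != genome$id, TRUE)
  if (any(bad)) stop("copies not on genome '", genome$id, "'")
  n <- length(copies)
  if (n == 0L) {
    return(structure(list(copy_count = 0L, bp_covered = 0L,
                          genome_fraction = 0,
                          divergence_histogram = integer()),
                     class = "family_stats"))
  }
  gr <- GenomicRanges::GRanges(genome$id, IRanges::IRanges(
    start = vapply(copies, function(x) x$interval$start, 0L) + 1L,
    end = vapply(copies, function(x) x$interval$end, 0L)))
  bp <- sum(BiocGenerics::width(GenomicRanges::reduce(gr)))
  div <- vapply(copies, function(x) x$divergence, 0)
  brk <- seq(0, 1, by = 0.05)
  hist <- table(cut(pmin(div, 0.999), brk, right = FALSE))
  structure(list(copy_count = n, bp_covered = as.integer(bp),
                 genome_fraction = bp / nchar(genome$seq),
                 divergence_histogram = as.integer(hist)),
            class = "family_stats")
}

#' Genetic distance between a copy and its consensus
#'
#' Global alignment; columns with a gap in either sequence are excluded
#' (pairwise deletion). `p` is the mismatch fraction; `K2P` is the Kimura
#' two-parameter distance
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P`/`Q` the
#' transition/transversion proportions.
#'
#' @param copy_seq,consensus Non-empty DNA strings.
#' @param model `"p"` or `"K2P"`.
#' @return Distance (>= 0). K2P errors with `"saturated"` when a log
#'   argument is non-positive.
#' @export
copy_divergence <- function(copy_seq, consensus, model = c("p", "K2P")) {
  model <- match.arg(model)
  al <- align_pair(copy_seq, consensus, mode = "global")
  ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1L]]
  use <- ca != "-" & cb != "-" & ca != "N" & cb != "N"
  n <- sum(use)
  if (n == 0L) stop("no gap-free aligned sites")
  ca <- ca[use]; cb <- cb[use]
  diff <- ca != cb
  if (model == "p") return(sum(diff) / n)
  purine <- c("A", "G")
  transition <- diff & ((ca %in% purine) == (cb %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("saturated")
  -0.5 * log(w1) - 0.25 * log(w2)
}
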