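# Multiple sequence alignment via mafft (deterministic settings, input
# order preserved). Used for boundary refinement, consensus building and
# copy alignments ahead of tree inference.

#' Multiple alignment of DNA sequences
#'
#' Runs mafft (`--retree 2 --maxiterate 0`, deterministic, order
#' preserving) on the given sequences and returns the gapped alignment.
#'
#' @param seqs Character vector of DNA sequences (>= 2), optionally named.
#' @return Named character vector of equal-length gapped, upper-case
#'   sequences in input order.
#' @export
align_multi <- function(seqs) {
  stopifnot(length(seqs) >= 2L, all(nzchar(seqs)))
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  if (Sys.which("mafft") == "")
    stop("mafft executable not found on PATH; it is required for ",
         "multiple alignments")
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  # temporary safe names to avoid mafft mangling special characters
  tmpnames <- sprintf("s%06d", seq_along(seqs))
  writeLines(paste0(">", tmpnames, "\n", unname(seqs)), fa)
  out <- suppressWarnings(system2("mafft",
    c("--retree", "2", "--maxiterate", "0", "--quiet", "--nuc", fa),
    stdout = TRUE, stderr = FALSE))
  if (length(out) == 0L) stop("mafft produced no output")
  aln <- parse_fasta_lines(out)
  aln <- toupper(aln[tmpnames])
  names(aln) <- names(seqs)
  aln
}

# Minimal FASTA-from-lines parser for captured aligner stdout.
parse_fasta_lines <- function(lines) {
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in aligner output")
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  stats::setNames(unname(seqs), ids)
}

# Alignment (named gapped strings) -> character matrix (rows = sequences).
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}
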