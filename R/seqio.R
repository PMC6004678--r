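# Sequence I/O, coordinate conventions, and the pairwise-alignment primitive
# shared by every other module.

.IUPAC <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V")

# Fixed default scoring: match +2, mismatch -3, gap open 5, gap extend 2
# (penalties). BLASTn-like and fully deterministic, so identities are
# reproducible across runs and machines.
.submat <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3,
                                                     baseOnly = FALSE)
    m
  }
})

#' Create a genome record
#'
#' One assembled sequence with identifier, taxon label and role. Characters
#' outside `{A,C,G,T,N}` that are valid IUPAC ambiguity codes are collapsed
#' to `N` with a warning; anything else is an error.
#'
#' @param id Unique sequence identifier.
#' @param seq DNA string.
#' @param taxon Taxon label (defaults to `id`).
#' @param role `"virus"` or `"host"`.
#' @param circular Is the genome circular?
#' @return An object of class `"genome_record"`.
#' @export
genome_record <- function(id, seq, taxon = id, role = c("virus", "host"),
                          circular = FALSE) {
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("genome sequence must be non-empty")
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1L]])
  bad <- setdiff(chars, .IUPAC)
  if (length(bad))
    stop("non-IUPAC characters in sequence for '", id, "': ",
         paste(bad, collapse = ","))
  amb <- setdiff(chars, c("A", "C", "G", "T", "N"))
  if (length(amb)) {
    warning("collapsing IUPAC ambiguity codes (",
            paste(amb, collapse = ","), ") to N in '", id, "'")
    seq <- chartr(paste(amb, collapse = ""),
                  strrep("N", length(amb)), seq)
  }
  structure(list(id = id, taxon = taxon, role = role, seq = seq,
                 circular = isTRUE(circular)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome_record '%s' (%s, %s%s): %d bp\n", x$id, x$taxon,
              x$role, if (x$circular) ", circular" else "", nchar(x$seq)))
  invisible(x)
}

#' Read genome assemblies from a FASTA file
#'
#' The header token before the first whitespace becomes the record id;
#' sequences are upper-cased. An empty file or duplicate ids are errors.
#'
#' @param path Path to a FASTA file.
#' @param role Role of every record, `"virus"` or `"host"`.
#' @param taxon Optional taxon label(s): a single value recycled to all
#'   records, or a vector named by record id. Defaults to the record ids.
#' @param circular Logical, recycled to all records.
#' @return Named list of [genome_record()] objects, in file order.
#' @export
read_genomes <- function(path, role = c("virus", "host"), taxon = NULL,
                         circular = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  recs <- lapply(seq_along(ss), function(i) {
    tx <- if (is.null(taxon)) ids[i]
          else if (!is.null(names(taxon))) unname(taxon[ids[i]])
          else taxon[1L]
    genome_record(ids[i], as.character(ss[[i]]), taxon = tx, role = role,
                  circular = circular)
  })
  stats::setNames(recs, ids)
}

#' Write genome records or named sequences to FASTA
#'
#' @param x Named character vector of sequences, or a list of
#'   [genome_record()] objects.
#' @param path Output path; lines wrapped at 80 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.list(x) && length(x) && inherits(x[[1L]], "genome_record"))
    x <- stats::setNames(vapply(x, `[[`, "", "seq"),
                         vapply(x, `[[`, "", "id"))
  ss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Accepts IUPAC characters; `N` maps to `N`; the empty string maps to
#' itself. `revcomp` is an involution.
#'
#' @param seq DNA string.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return("")
  seq <- toupper(seq)
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1L]])
  bad <- setdiff(chars, .IUPAC)
  if (length(bad))
    stop("non-IUPAC character(s): ", paste(bad, collapse = ","))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Align two sequences
#'
#' Deterministic pairwise alignment under the package's fixed scoring
#' (match +2, mismatch -3, gap open 5, gap extend 2). `identity_pct` is
#' matches over aligned columns (there are no dual-gap columns in a
#' pairwise alignment); `coverage_of_a`/`coverage_of_b` are the fractions
#' of each input included in the aligned region (1 for global mode).
#'
#' @param a,b Non-empty DNA strings. `a` is the pattern/query.
#' @param mode `"global"` or `"local"`.
#' @return List of class `"pairwise_alignment"` with elements `aligned_a`,
#'   `aligned_b`, `identity_pct`, `coverage_of_a`, `coverage_of_b`,
#'   `score`, `a_range`, `b_range` (1-based inclusive within the inputs).
#' @export
align_pair <- function(a, b, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = mode, substitutionMatrix = .submat(),
    gapOpening = 5, gapExtension = 2)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(al_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(al_b, "", fixed = TRUE)[[1L]]
  ncols <- length(ca)
  matches <- sum(ca == cb & ca != "-")
  res_a <- sum(ca != "-")
  res_b <- sum(cb != "-")
  mm <- sum(ca != cb & ca != "-" & cb != "-")
  structure(list(
    aligned_a = al_a, aligned_b = al_b,
    identity_pct = if (ncols) 100 * matches / ncols else 0,
    coverage_of_a = res_a / nchar(a),
    coverage_of_b = res_b / nchar(b),
    score = as.numeric(BiocGenerics::score(pa)),
    n_columns = ncols, n_matches = matches, n_mismatches = mm,
    a_range = c(start(Biostrings::pattern(pa)), end(Biostrings::pattern(pa))),
    b_range = c(start(Biostrings::subject(pa)), end(Biostrings::subject(pa)))
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: %d cols, identity %.1f%%, score %.1f\n",
              x$n_columns, x$identity_pct, x$score))
  invisible(x)
}

# Extract a subsequence [start, end) in 0-based half-open coordinates,
# reverse-complemented when strand is "-".
extract_seq <- function(genome, start, end, strand = "+") {
  s <- substr(genome$seq, start + 1L, end)
  if (strand == "-") revcomp(s) else s
}
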