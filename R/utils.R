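`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genomic interval (0-based, half-open)
#'
#' Internal coordinates throughout the package are 0-based half-open
#' `[start, end)`; all serialized annotations (GFF3) are 1-based inclusive.
#'
#' @param genome_id Identifier of the genome the interval lives on.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end (`end > start`).
#' @param strand `"+"` or `"-"`.
#' @return An object of class `"mite_interval"`.
#' @export
interval <- function(genome_id, start, end, strand = "+") {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop("invalid interval: need 0 <= start < end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(genome_id = genome_id, start = start, end = end,
                 strand = strand),
            class = "mite_interval")
}

#' @export
print.mite_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d(%s)>\n", x$genome_id, x$start, x$end, x$strand))
  invisible(x)
}

iv_len <- function(iv) iv$end - iv$start

iv_overlap <- function(a, b) {
  if (!identical(a$genome_id, b$genome_id)) return(0L)
  max(0L, min(a$end, b$end) - max(a$start, b$start))
}

#' Reciprocal overlap fraction of two intervals
#'
#' @param a,b Intervals from [interval()].
#' @return `min(overlap/len(a), overlap/len(b))`, 0 when on different genomes.
#' @export
reciprocal_overlap <- function(a, b) {
  o <- iv_overlap(a, b)
  if (o == 0L) return(0)
  min(o / iv_len(a), o / iv_len(b))
}

# Per-stage seed derived from the run seed by stable hashing of the stage
# name, so stage-level results do not depend on execution order.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

# Deterministic TSV writer used for all reports (byte-stable given identical
# inputs: fixed quoting, no row names, "." decimal).
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

fmt4 <- function(x) sprintf("%.4f", x)

modal_value <- function(x) {
  if (length(x) == 0L) return(NA_integer_)
  tb <- sort(table(x), decreasing = TRUE)
  as.integer(names(tb)[1L])
}
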