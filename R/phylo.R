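# Neighbor-joining trees of full-length copies, bootstrap support, copy
# subsampling, and monophyly testing. Distances are p-distances with
# pairwise deletion; trees are unrooted.

#' Phylogeny parameters
#'
#' @param bootstrap_reps Number of bootstrap replicates (default 1000).
#' @param support_display_min Supports below this are blanked when
#'   rendering (default 70); all supports are retained on the tree object.
#' @param copy_cap Maximum number of copies per tree (default 50); larger
#'   sets are subsampled.
#' @param seed Seed for subsampling and bootstrap resampling.
#' @return Validated list of class `"phylo_params"`.
#' @export
phylo_params <- function(bootstrap_reps = 1000L, support_display_min = 70,
                         copy_cap = 50L, seed = 1L) {
  if (bootstrap_reps < 1L) stop("bootstrap_reps must be >= 1")
  if (copy_cap < 4L) stop("copy_cap must be >= 4")
  structure(list(bootstrap_reps = as.integer(bootstrap_reps),
                 support_display_min = support_display_min,
                 copy_cap = as.integer(copy_cap),
                 seed = as.integer(seed)),
            class = "phylo_params")
}

#' Subsample full-length copies for tree building
#'
#' If more than `copy_cap` copies are supplied, a uniform sample of
#' exactly `copy_cap` without replacement is drawn (reproducible under
#' the seed); otherwise all copies are returned.
#'
#' @param copies List of copies.
#' @param params A [phylo_params()] list.
#' @return Subsampled list in original relative order.
#' @export
subsample_copies <- function(copies, params = phylo_params()) {
  n <- length(copies)
  if (n <= params$copy_cap) return(copies)
  idx <- withr::with_seed(params$seed,
                          sample.int(n, params$copy_cap))
  copies[sort(idx)]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration; negative branch lengths are clamped to zero
#' with the deficit moved to the sister branch, preserving path lengths
#' through the parent node.
#'
#' @param distances Symmetric non-negative matrix with zero diagonal and
#'   at least 3 taxa (dimnames become tip labels).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(distances) {
  d <- as.matrix(distances)
  if (nrow(d) < 3L) stop("need >= 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- which(tr$edge[, 1L] == parent)
    sibs <- setdiff(sibs, e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs))
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + deficit
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# p-distance with pairwise deletion from a character alignment matrix,
# vectorized via base-indicator cross products (fast enough to sit inside
# the bootstrap loop).
pdist_matrix <- function(M) {
  bases <- c("A", "C", "G", "T")
  ok <- matrix(as.numeric(M %in% bases), nrow(M))
  valid <- tcrossprod(ok)
  matches <- matrix(0, nrow(M), nrow(M))
  for (b in bases) matches <- matches + tcrossprod((M == b) * 1)
  d <- (valid - matches) / valid
  d[valid == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(M), rownames(M))
  d
}

#' Neighbor-joining tree of aligned copies with bootstrap support
#'
#' Builds the NJ tree from pairwise-deletion p-distances on the
#' alignment, then resamples alignment columns with replacement
#' `bootstrap_reps` times; supports are the percentage of replicate trees
#' containing each internal bipartition of the original tree. Replicates
#' whose resampled columns leave some pair with no comparable site are
#' redrawn (with a message).
#'
#' @param alignment Named character vector of equal-length gapped
#'   sequences (>= 4, >= 10 columns), or a character matrix.
#' @param params A [phylo_params()] list.
#' @return An `ape::phylo` tree; `node.label` holds supports (0-100,
#'   root label empty).
#' @export
bootstrap_support <- function(alignment, params = phylo_params()) {
  M <- if (is.matrix(alignment)) alignment else aln_matrix(alignment)
  if (nrow(M) < 4L) stop("need >= 4 sequences")
  if (ncol(M) < 10L) stop("need >= 10 alignment columns")
  tr <- nj_tree(pdist_matrix(M))
  B <- params$bootstrap_reps
  boots <- vector("list", B)
  withr::with_seed(params$seed, {
    b <- 1L
    tries <- 0L
    while (b <= B) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      dm <- pdist_matrix(M[, cols, drop = FALSE])
      if (anyNA(dm)) {
        tries <- tries + 1L
        if (tries > 10L * B) stop("too many degenerate bootstrap draws")
        message("redrawing bootstrap replicate with incomparable pairs")
        next
      }
      boots[[b]] <- nj_tree(dm)
      b <- b + 1L
    }
  })
  cnt <- ape::prop.clades(tr, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  sup <- round(100 * cnt / B)
  lab <- as.character(sup)
  lab[1L] <- ""  # root of the unrooted representation
  tr$node.label <- lab
  tr
}

#' Test monophyly of a leaf subset on an unrooted tree
#'
#' TRUE iff some edge bipartition separates exactly the given subset from
#' the rest (trivial subsets of size 1, n-1 or n are monophyletic by
#' convention).
#'
#' @param tree An `ape::phylo` tree.
#' @param leaf_subset Character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, leaf_subset) {
  tips <- tree$tip.label
  unknown <- setdiff(leaf_subset, tips)
  if (length(unknown))
    stop("unknown leaves: ", paste(unknown, collapse = ", "))
  k <- length(leaf_subset)
  n <- length(tips)
  if (k <= 1L || k >= n - 1L) return(TRUE)
  parts <- ape::prop.part(tree)
  target <- sort(match(leaf_subset, tips))
  comp <- sort(setdiff(seq_len(n), target))
  for (p in parts) {
    sp <- sort(p)
    if (identical(sp, target) || identical(sp, comp)) return(TRUE)
  }
  FALSE
}

#' Build the copy tree for one family
#'
#' Extracts full-length member sequences (element orientation), subsamples
#' to the copy cap, aligns them, and returns the bootstrap-annotated NJ
#' tree. Tip labels are `taxon|genome|start-end`. Fragments are excluded
#' (with a message reporting the count).
#'
#' @param family A `"mite_family"`.
#' @param genomes Named list of [genome_record()]s.
#' @param copies Optional list of annotated `"mite_copy"`s to use instead
#'   of the family members (e.g. library-wide annotations).
#' @param params A [phylo_params()] list.
#' @return An `ape::phylo` tree with bootstrap node labels, or `NULL`
#'   when fewer than 4 full-length copies are available.
#' @export
family_copy_tree <- function(family, genomes, copies = NULL,
                             params = phylo_params()) {
  src <- copies %||% family$members
  is_full <- vapply(src, function(m)
    is.null(m$completeness) || m$completeness == "full", TRUE)
  if (sum(!is_full) > 0L)
    message(sum(!is_full), " fragment copies excluded from the tree")
  src <- src[is_full]
  if (length(src) < 4L) return(NULL)
  src <- subsample_copies(src, params)
  seqs <- vapply(src, function(m) {
    g <- genomes[[m$interval$genome_id]]
    m$seq %||% extract_seq(g, m$interval$start, m$interval$end,
                           m$interval$strand %||% m$strand %||% "+")
  }, "")
  labs <- vapply(src, function(m) {
    g <- genomes[[m$interval$genome_id]]
    sprintf("%s|%s|%d-%d", g$taxon, g$id, m$interval$start,
            m$interval$end)
  }, "")
  names(seqs) <- make.unique(labs, sep = "_")
  aln <- align_multi(seqs)
  bootstrap_support(aln, params)
}
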