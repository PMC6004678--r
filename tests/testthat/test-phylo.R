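test_that("copy subsampling caps at fifty and is seed-reproducible", {
  copies <- as.list(seq_len(90L))
  p <- phylo_params(seed = 99L)
  s1 <- subsample_copies(copies, p)
  s2 <- subsample_copies(copies, p)
  expect_length(s1, 50L)
  expect_identical(s1, s2)
  expect_false(identical(s1, subsample_copies(copies,
                                              phylo_params(seed = 100L))))
  expect_identical(subsample_copies(as.list(1:30), p), as.list(1:30))
})

test_that("NJ recovers the generating quartet against the LS oracle", {
  # additive distances from ((A:1,B:2):1,(C:3,D:1))
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 3
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 4
  d["C", "D"] <- d["D", "C"] <- 4
  tr <- nj_tree(d)
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(all(tr$edge.length >= 0))

  # independent oracle: least-squares fit of all 3 quartet topologies
  # via the four-point condition sums
  sums <- c(AB_CD = d["A", "B"] + d["C", "D"],
            AC_BD = d["A", "C"] + d["B", "D"],
            AD_BC = d["A", "D"] + d["B", "C"])
  expect_equal(names(which.min(sums)), "AB_CD")
})

test_that("the three-taxon tree uses the closed-form branch lengths", {
  d <- matrix(c(0, 2, 3,
                2, 0, 4.2,
                3, 4.2, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  # three-point formulas: bx = (dxy + dxz - dyz)/2, etc.
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(unname(bl["x"]), (2 + 3 - 4.2) / 2)
  expect_equal(unname(bl["y"]), (2 + 4.2 - 3) / 2)
  expect_equal(unname(bl["z"]), (3 + 4.2 - 2) / 2)
})

test_that("identical taxa are placed as sisters", {
  set.seed(61)
  labs <- c("u", "v", "w", "x", "y")
  base <- matrix(stats::runif(25, 0.2, 0.8), 5, 5,
                 dimnames = list(labs, labs))
  d <- (base + t(base)) / 2
  diag(d) <- 0
  d["u", "v"] <- d["v", "u"] <- 0
  tr <- nj_tree(d)
  expect_true(is_monophyletic(tr, c("u", "v")))
})

test_that("NJ is exact on additive matrices from random topologies", {
  set.seed(62)
  for (n in c(5L, 6L, 8L)) {
    for (rep in 1:3) {
      tr0 <- ape::rtree(n, br = stats::runif)
      tr0$edge.length <- tr0$edge.length + 0.05  # keep internal edges real
      d <- cophenetic(tr0)
      tr1 <- nj_tree(d[tr0$tip.label, tr0$tip.label])
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), tr1)), 0)
    }
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)))
  bad <- matrix(c(0, 1, 2, 1, 0, 3, 2.5, 3, 0), 3, 3)
  expect_error(nj_tree(bad), "symmetric")
})

# two clades of four sequences separated by fixed differences
clade_alignment <- function(n_fixed = 50L, n_cols = 200L, noise = 0.01) {
  anc <- strsplit(rand_dna(n_cols), "")[[1L]]
  other <- vapply(anc, function(b) setdiff(BASES, b)[1L], "")
  pos <- sample(n_cols, n_fixed)
  mk <- function(group) {
    ch <- anc
    if (group == 2L) ch[pos] <- other[pos]
    hit <- which(stats::runif(n_cols) < noise)
    for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
    paste(ch, collapse = "")
  }
  seqs <- c(vapply(1:4, function(i) mk(1L), ""),
            vapply(1:4, function(i) mk(2L), ""))
  names(seqs) <- c(paste0("a", 1:4), paste0("b", 1:4))
  seqs
}

test_that("bootstrap strongly supports a split backed by many sites", {
  set.seed(63)
  aln <- clade_alignment()
  tr <- bootstrap_support(aln, phylo_params(bootstrap_reps = 200L,
                                            seed = 7L))
  expect_true(is_monophyletic(tr, paste0("a", 1:4)))
  sup <- as.numeric(tr$node.label[tr$node.label != ""])
  expect_true(all(sup >= 0 & sup <= 100))
  # the a/b split is one of the supported clades at >= 95
  expect_gte(max(sup), 95)

  tr2 <- bootstrap_support(aln, phylo_params(bootstrap_reps = 200L,
                                             seed = 7L))
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("star-like data never earns strong internal support", {
  set.seed(64)
  # six sequences, each with its own private mutations only
  anc <- strsplit(rand_dna(300L), "")[[1L]]
  seqs <- vapply(1:6, function(i) {
    ch <- anc
    pos <- sample(300L, 12L)
    for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
    paste(ch, collapse = "")
  }, "")
  names(seqs) <- paste0("t", 1:6)
  tr <- bootstrap_support(seqs, phylo_params(bootstrap_reps = 200L,
                                             seed = 8L))
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] <= 70))
})

test_that("newick round-trips preserve topology and supports", {
  set.seed(65)
  aln <- clade_alignment(n_fixed = 40L)
  tr <- bootstrap_support(aln, phylo_params(bootstrap_reps = 100L,
                                            seed = 3L))
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  tr2 <- ape::read.tree(path)
  expect_equal(as.numeric(ape::dist.topo(tr, tr2)), 0)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("monophyly testing uses unrooted bipartitions", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, "A"))
  expect_true(is_monophyletic(tr, c("B", "C", "D")))  # complement of A
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")
})
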