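# Synthetic genomes with planted MITE biology: multi-copy TIR/TSD
# families at controlled divergence, truncated fragments, an autonomous
# partner with a transposase-scale ORF, deletion derivatives, paralogous
# empty sites and cross-genome HT pairs - with a complete ground-truth
# record for recovery scoring.

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Specify one planted MITE family
#'
#' @param consensus_len Element length (50-800 bp).
#' @param tir_len Perfect TIR arm length on the consensus.
#' @param tsd_len TSD length duplicated at each insertion.
#' @param n_copies Number of copies to plant.
#' @param divergence Per-copy substitution rate against the consensus.
#' @param trunc_prob Probability a copy is truncated (loses 20-60% from
#'   one end).
#' @param consensus Optional explicit consensus (otherwise generated).
#' @return A family specification list.
#' @export
family_spec <- function(consensus_len = 300L, tir_len = 12L, tsd_len = 8L,
                        n_copies = 10L, divergence = 0.05,
                        trunc_prob = 0.1, consensus = NULL) {
  stopifnot(consensus_len >= 50L, consensus_len <= 800L, n_copies >= 1L,
            divergence >= 0, divergence <= 1, trunc_prob >= 0,
            trunc_prob <= 1)
  list(consensus_len = as.integer(consensus_len),
       tir_len = as.integer(tir_len), tsd_len = as.integer(tsd_len),
       n_copies = as.integer(n_copies), divergence = divergence,
       trunc_prob = trunc_prob, consensus = consensus)
}

#' Simulation specification
#'
#' The default fixture mirrors the study scale this package targets: a
#' 200 kb "virus" genome carrying three MITE families (40, 25 and 10
#' copies; 2- and 8-bp TSDs; 5% per-copy divergence), a 2 Mb "host"
#' genome carrying the autonomous partner (3 kb, 500-aa ORF) from which
#' family 1 is an internal-deletion derivative, one HT family shared
#' between virus and host, and one planted paralogous empty site.
#'
#' @param genome_length Virus genome length.
#' @param gc_content Background GC fraction.
#' @param families List of [family_spec()]s.
#' @param autonomous `NULL`, or a list with `length`, `orf_aa`,
#'   `host_length`, `derived_family` (index of the family derived from
#'   the partner by internal deletion).
#' @param ht_pairs `NULL`, or a list with `family` (index), `n_copies`
#'   (copies planted in the host) and `cross_divergence`.
#' @param empty_site_pairs Number of planted paralogous empty sites (for
#'   family 1).
#' @param seed Seed for all randomness in the generator.
#' @return A list of class `"sim_spec"`.
#' @export
sim_spec <- function(genome_length = 200000L, gc_content = 0.5,
                     families = list(
                       family_spec(300L, 14L, 8L, 40L, 0.05, 0.1),
                       family_spec(180L, 12L, 2L, 25L, 0.05, 0.1),
                       family_spec(420L, 10L, 8L, 10L, 0.05, 0)),
                     autonomous = list(length = 3000L, orf_aa = 500L,
                                       host_length = 2000000L,
                                       derived_family = 1L),
                     ht_pairs = list(family = 2L, n_copies = 5L,
                                     cross_divergence = 0.1),
                     empty_site_pairs = 1L, seed = 1L) {
  stopifnot(genome_length >= 1000L, gc_content >= 0, gc_content <= 1)
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, families = families,
                 autonomous = autonomous, ht_pairs = ht_pairs,
                 empty_site_pairs = as.integer(empty_site_pairs),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a background genome
#'
#' i.i.d. bases at the requested GC content; reproducible under the seed.
#'
#' @param spec A [sim_spec()] (only `genome_length`, `gc_content`, `seed`
#'   are used).
#' @param id,taxon,role Passed to [genome_record()].
#' @param length Override for the genome length.
#' @return A [genome_record()].
#' @export
simulate_background <- function(spec = sim_spec(), id = "sim_virus",
                                taxon = id, role = "virus",
                                length = spec$genome_length) {
  if (length < 1000L) stop("genome_length must be >= 1000")
  seq <- withr::with_seed(stage_seed(spec$seed, paste0("bg_", id)),
                          random_seq(length, spec$gc_content))
  genome_record(id, seq, taxon = taxon, role = role)
}

# Generate a family consensus with perfect TIRs.
make_family_consensus <- function(fs, gc = 0.5) {
  arm <- random_seq(fs$tir_len, gc)
  core <- random_seq(fs$consensus_len - 2L * fs$tir_len, gc)
  paste0(arm, core, revcomp(arm))
}

empty_truth <- function() {
  data.frame(genome = character(), start = integer(), end = integer(),
             family = character(), seq = character(),
             tsd_seq = character(), tsd_len = integer(),
             divergence = numeric(), truncated = logical(),
             stringsAsFactors = FALSE)
}

# Insert `ins_seq` with TSD duplication at a collision-free position of
# `seq`; shifts existing truth coordinates. Returns list(seq, truth, rec).
insert_at_random <- function(seq, truth, ins_seq, genome_id, fam_name,
                             tsd_len, divergence, truncated,
                             margin = 300L, max_tries = 100L) {
  L <- nchar(seq)
  elen <- nchar(ins_seq)
  for (try in seq_len(max_tries)) {
    p <- sample.int(L - 2L * margin - tsd_len, 1L) + margin  # 0-based
    occ <- truth$genome == genome_id &
      truth$start - margin < p & p < truth$end + margin
    if (any(occ)) {
      message("insertion site collision, resampling")
      next
    }
    tsd <- if (tsd_len > 0L) substr(seq, p + 1L, p + tsd_len) else ""
    new_seq <- paste0(substr(seq, 1L, p + tsd_len), ins_seq, tsd,
                      substr(seq, p + tsd_len + 1L, L))
    grow <- elen + tsd_len
    shift <- truth$genome == genome_id & truth$start >= p
    truth$start[shift] <- truth$start[shift] + grow
    truth$end[shift] <- truth$end[shift] + grow
    rec <- data.frame(genome = genome_id, start = p + tsd_len,
                      end = p + tsd_len + elen, family = fam_name,
                      seq = ins_seq, tsd_seq = tsd, tsd_len = tsd_len,
                      divergence = divergence, truncated = truncated,
                      stringsAsFactors = FALSE)
    return(list(seq = new_seq, truth = rbind(truth, rec)))
  }
  stop("could not place insertion after ", max_tries, " tries")
}

#' Plant a MITE family into a genome
#'
#' Creates (or reuses) a family consensus with perfect TIRs and inserts
#' `n_copies` mutated copies, each duplicating the `tsd_len` target motif
#' on both sides. Truncated copies lose 20-60% from a random end. The
#' genome grows by exactly the sum of inserted and TSD lengths.
#'
#' @param genome A [genome_record()].
#' @param fs A [family_spec()].
#' @param fam_name Family label recorded in the truth.
#' @param seed Seed for this family's randomness.
#' @param truth Existing truth data.frame to extend.
#' @return List with `genome` (grown), `truth` (data.frame of planted
#'   insertions) and `consensus`.
#' @export
plant_family <- function(genome, fs, fam_name = "famA", seed = 1L,
                         truth = empty_truth()) {
  if (fs$n_copies * fs$consensus_len >= 0.2 * nchar(genome$seq))
    stop("family would occupy >= 20% of the genome")
  withr::with_seed(seed, {
    cons <- fs$consensus %||% make_family_consensus(fs)
    seq <- genome$seq
    for (i in seq_len(fs$n_copies)) {
      cp <- mutate_seq(cons, fs$divergence)
      truncated <- stats::runif(1L) < fs$trunc_prob
      if (truncated) {
        cut <- round(nchar(cp) * stats::runif(1L, 0.2, 0.6))
        cp <- if (stats::runif(1L) < 0.5)
          substr(cp, cut + 1L, nchar(cp))
        else substr(cp, 1L, nchar(cp) - cut)
      }
      res <- insert_at_random(seq, truth, cp, genome$id, fam_name,
                              fs$tsd_len, fs$divergence, truncated)
      seq <- res$seq
      truth <- res$truth
    }
    genome$seq <- seq
    list(genome = genome, truth = truth, consensus = cons)
  })
}

# Build an autonomous element: family termini, internal transposase ORF.
make_autonomous_seq <- function(derived_cons, total_len, orf_aa,
                                term_keep = 150L) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(as.vector(outer(bases, bases, paste0)),
                            bases, paste0))
  nonstop <- setdiff(codons, .STOPS)
  dc <- nchar(derived_cons)
  keep5 <- min(term_keep, floor(dc / 2))
  keep3 <- min(term_keep, dc - keep5)
  head5 <- substr(derived_cons, 1L, keep5)
  tail3 <- substr(derived_cons, dc - keep3 + 1L, dc)
  orf <- paste0("TAA", "ATG",
                paste(sample(nonstop, orf_aa - 1L, replace = TRUE),
                      collapse = ""), "TAA")
  mid_len <- total_len - keep5 - keep3 - nchar(orf)
  if (mid_len < 20L) stop("autonomous element too short for the ORF")
  pre <- random_seq(floor(mid_len / 2))
  post <- random_seq(mid_len - nchar(pre))
  list(seq = paste0(head5, pre, orf, post, tail3),
       orf_start_offset = keep5 + nchar(pre) + 4L,  # the ATG (1-based)
       keep5 = keep5, keep3 = keep3)
}

#' Plant an autonomous partner and record the derivation of its MITE
#'
#' Builds a 1-10 kb element carrying the derived family's termini (the
#' first/last 150 bp of the MITE consensus are retained verbatim, so the
#' MITE is an internal-deletion derivative of the partner) and an ORF of
#' the requested length, then inserts it with an 8-bp TSD.
#'
#' @param genome Host [genome_record()].
#' @param derived_cons The MITE consensus the partner must explain.
#' @param length Total element length (1000-10000).
#' @param orf_aa Transposase length in amino acids.
#' @param fam_name Name recorded for the autonomous element.
#' @param seed Seed.
#' @param truth Truth data.frame to extend.
#' @return List with `genome`, `truth`, `autonomous` (record with `seq`,
#'   `orf_aa`, retained-terminus lengths).
#' @export
plant_autonomous_and_derivative <- function(genome, derived_cons,
                                            length = 3000L, orf_aa = 500L,
                                            fam_name = "autonomous",
                                            seed = 1L,
                                            truth = empty_truth()) {
  stopifnot(length >= 1000L, length <= 10000L)
  withr::with_seed(seed, {
    aut <- make_autonomous_seq(derived_cons, length, orf_aa)
    res <- insert_at_random(genome$seq, truth, aut$seq, genome$id,
                            fam_name, 8L, 0, FALSE)
    genome$seq <- res$seq
    list(genome = genome, truth = res$truth,
         autonomous = list(seq = aut$seq, orf_aa = orf_aa,
                           keep5 = aut$keep5, keep3 = aut$keep3,
                           derived_consensus = derived_cons))
  })
}

#' Simulate a horizontal-transfer scenario
#'
#' The same family consensus is planted in two genomes at a controlled
#' cross-genome divergence. In `"single"` transfer mode all recipient
#' copies radiate from one transferred subconsensus (recipient copies are
#' monophyletic by construction); in `"multi"` mode each recipient copy
#' derives from an independent donor copy (no monophyly).
#'
#' @param fs A [family_spec()] for the shared family.
#' @param cross_divergence Donor-recipient divergence of the transfer.
#' @param mode `"single"` or `"multi"`.
#' @param donor_length,recipient_length Background genome lengths.
#' @param n_recipient Copies planted in the recipient.
#' @param gc Background GC.
#' @param seed Seed.
#' @return List with `genomes` (named list: donor "host", recipient
#'   "virus"), `truth`, `consensus`, `monophyletic_truth`.
#' @export
simulate_ht_scenario <- function(fs = family_spec(n_copies = 8L,
                                                  divergence = 0.02,
                                                  trunc_prob = 0),
                                 cross_divergence = 0.1,
                                 mode = c("single", "multi"),
                                 donor_length = 60000L,
                                 recipient_length = 60000L,
                                 n_recipient = 6L, gc = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  withr::with_seed(seed, {
    donor <- genome_record("ht_host", random_seq(donor_length, gc),
                           taxon = "host_taxon", role = "host")
    recip <- genome_record("ht_virus", random_seq(recipient_length, gc),
                           taxon = "virus_taxon", role = "virus")
    cons <- fs$consensus %||% make_family_consensus(fs)
    truth <- empty_truth()
    dseq <- donor$seq
    donor_copies <- character(fs$n_copies)
    for (i in seq_len(fs$n_copies)) {
      cp <- mutate_seq(cons, fs$divergence)
      donor_copies[i] <- cp
      res <- insert_at_random(dseq, truth, cp, donor$id, "ht_fam",
                              fs$tsd_len, fs$divergence, FALSE)
      dseq <- res$seq; truth <- res$truth
    }
    donor$seq <- dseq
    rseq <- recip$seq
    sub <- mutate_seq(cons, cross_divergence)
    for (i in seq_len(n_recipient)) {
      cp <- if (mode == "single") mutate_seq(sub, fs$divergence)
            else mutate_seq(sample(donor_copies, 1L), cross_divergence)
      res <- insert_at_random(rseq, truth, cp, recip$id, "ht_fam",
                              fs$tsd_len, fs$divergence, FALSE)
      rseq <- res$seq; truth <- res$truth
    }
    recip$seq <- rseq
    list(genomes = list(ht_host = donor, ht_virus = recip),
         truth = truth, consensus = cons,
         monophyletic_truth = (mode == "single"))
  })
}

#' Simulate the full study fixture
#'
#' Builds the virus genome with all configured families, the host genome
#' with the autonomous partner (family 1 becomes its internal-deletion
#' derivative) and HT copies, and planted paralogous empty sites. Every
#' planted feature is recorded in the truth object.
#'
#' @param spec A [sim_spec()].
#' @return List of class `"planted_truth_set"`: `genomes` (named list),
#'   `truth` (insertion data.frame), `consensi` (named list of family
#'   consensus sequences), `autonomous`, `empty_sites`, `ht_families`,
#'   `spec`.
#' @export
simulate_genomes <- function(spec = sim_spec()) {
  virus <- simulate_background(spec, id = "sim_virus",
                               taxon = "sim_virus_taxon", role = "virus")
  truth <- empty_truth()
  consensi <- list()
  autonomous <- NULL
  fam_names <- sprintf("fam%d", seq_along(spec$families))
  # derive family-1 consensus from the autonomous partner when configured
  aut_seq_info <- NULL
  if (!is.null(spec$autonomous)) {
    di <- spec$autonomous$derived_family
    fs <- spec$families[[di]]
    cons <- withr::with_seed(stage_seed(spec$seed, "derived_consensus"),
                             make_family_consensus(fs))
    spec$families[[di]]$consensus <- cons
  }
  for (i in seq_along(spec$families)) {
    res <- plant_family(virus, spec$families[[i]], fam_names[i],
                        seed = stage_seed(spec$seed, fam_names[i]),
                        truth = truth)
    virus <- res$genome
    truth <- res$truth
    consensi[[fam_names[i]]] <- res$consensus
  }
  genomes <- list(sim_virus = virus)
  ht_families <- character()
  if (!is.null(spec$autonomous) || !is.null(spec$ht_pairs)) {
    host_len <- spec$autonomous$host_length %||% 2000000L
    host <- simulate_background(spec, id = "sim_host",
                                taxon = "sim_host_taxon", role = "host",
                                length = host_len)
    if (!is.null(spec$autonomous)) {
      di <- spec$autonomous$derived_family
      res <- plant_autonomous_and_derivative(
        host, consensi[[fam_names[di]]],
        length = spec$autonomous$length,
        orf_aa = spec$autonomous$orf_aa,
        fam_name = paste0(fam_names[di], "_autonomous"),
        seed = stage_seed(spec$seed, "autonomous"), truth = truth)
      host <- res$genome
      truth <- res$truth
      autonomous <- res$autonomous
      autonomous$derived_family <- fam_names[di]
    }
    if (!is.null(spec$ht_pairs)) {
      hi <- spec$ht_pairs$family
      fs <- spec$families[[hi]]
      hseq <- host$seq
      withr::with_seed(stage_seed(spec$seed, "ht"), {
        for (i in seq_len(spec$ht_pairs$n_copies)) {
          cp <- mutate_seq(consensi[[fam_names[hi]]],
                           spec$ht_pairs$cross_divergence)
          res <- insert_at_random(hseq, truth, cp, host$id,
                                  fam_names[hi], fs$tsd_len,
                                  spec$ht_pairs$cross_divergence, FALSE)
          hseq <- res$seq; truth <- res$truth
        }
      })
      host$seq <- hseq
      ht_families <- fam_names[hi]
    }
    genomes$sim_host <- host
  }
  empty_sites <- NULL
  if (spec$empty_site_pairs > 0L) {
    withr::with_seed(stage_seed(spec$seed, "empty_sites"), {
      fam1 <- truth[truth$family == fam_names[1L] & !truth$truncated &
                    truth$genome == "sim_virus", ]
      for (k in seq_len(min(spec$empty_site_pairs, nrow(fam1)))) {
        src <- fam1[k, ]
        g <- genomes$sim_virus
        fl <- 100L
        junction <- paste0(
          substr(g$seq, src$start - fl + 1L, src$start),
          substr(g$seq, src$end + 1L, src$end + fl))
        res <- insert_at_random(g$seq, truth, junction, g$id,
                                ".empty_site", 0L, 0, FALSE)
        genomes$sim_virus$seq <- res$seq
        truth <- res$truth
        fam1 <- truth[truth$family == fam_names[1L] & !truth$truncated &
                      truth$genome == "sim_virus", ]
      }
    })
    empty_sites <- truth[truth$family == ".empty_site", ]
    truth <- truth[truth$family != ".empty_site", ]
  }
  structure(list(genomes = genomes, truth = truth, consensi = consensi,
                 autonomous = autonomous, empty_sites = empty_sites,
                 ht_families = ht_families, spec = spec),
            class = "planted_truth_set")
}

#' Score pipeline outputs against the planted truth
#'
#' Matches detections to planted insertions by >= 50% reciprocal overlap
#' and reports precision/recall/F1 at family and copy level, TSD-length
#' accuracy over matched full-length family members, copy-count error,
#' and boundary-offset statistics.
#'
#' @param truth_set A `"planted_truth_set"` from [simulate_genomes()] (or
#'   a truth data.frame).
#' @param families Detected families (members refined; TSDs called).
#' @param copies_by_genome Named list (genome id -> list of
#'   `"mite_copy"`) from [annotate_copies()].
#' @return List of class `"recovery_report"`.
#' @export
evaluate_recovery <- function(truth_set, families, copies_by_genome) {
  truth <- if (is.data.frame(truth_set)) truth_set else truth_set$truth
  tgen <- unique(truth$genome)
  if (length(copies_by_genome) &&
      !all(tgen %in% names(copies_by_genome)))
    stop("genome id mismatch between truth and pipeline outputs: ",
         paste(setdiff(tgen, names(copies_by_genome)), collapse = ", "))
  ovl <- function(iv, row) {
    if (iv$genome_id != row$genome) return(0)
    o <- max(0L, min(iv$end, row$end) - max(iv$start, row$start))
    if (o == 0L) return(0)
    min(o / (iv$end - iv$start), o / (row$end - row$start))
  }
  match_truth_idx <- function(iv) {
    if (!nrow(truth)) return(NA_integer_)
    ov <- vapply(seq_len(nrow(truth)), function(r) ovl(iv, truth[r, ]), 0)
    if (max(ov) >= 0.5) which.max(ov) else NA_integer_
  }
  truth_fams <- unique(truth$family)
  # family-level matching: majority vote of members
  fam_assign <- vapply(families, function(f) {
    hits <- vapply(f$members, function(m) {
      i <- match_truth_idx(m$interval)
      if (is.na(i)) NA_character_ else truth$family[i]
    }, "")
    hits <- hits[!is.na(hits)]
    if (length(hits) >= max(1L, length(f$members) / 2)) {
      tb <- sort(table(hits), decreasing = TRUE)
      names(tb)[1L]
    } else NA_character_
  }, "")
  fam_tp <- sum(!is.na(fam_assign))
  fam_precision <- if (length(families)) fam_tp / length(families)
                   else NA_real_
  fam_recall <- if (length(truth_fams))
    length(unique(fam_assign[!is.na(fam_assign)])) / length(truth_fams)
    else NA_real_
  fam_f1 <- if (!is.na(fam_precision) && !is.na(fam_recall) &&
                fam_precision + fam_recall > 0)
    2 * fam_precision * fam_recall / (fam_precision + fam_recall)
    else 0
  # copy-level matching over annotate_copies output
  all_copies <- unlist(copies_by_genome, recursive = FALSE)
  used <- rep(FALSE, nrow(truth))
  cp_tp <- 0L
  for (cp in all_copies) {
    i <- match_truth_idx(cp$interval)
    if (!is.na(i) && !used[i]) { used[i] <- TRUE; cp_tp <- cp_tp + 1L }
  }
  n_det <- length(all_copies)
  cp_precision <- if (n_det) cp_tp / n_det else NA_real_
  cp_recall <- if (nrow(truth)) cp_tp / nrow(truth) else NA_real_
  cp_f1 <- if (!is.na(cp_precision) && !is.na(cp_recall) &&
               cp_precision + cp_recall > 0)
    2 * cp_precision * cp_recall / (cp_precision + cp_recall) else 0
  count_error <- if (nrow(truth)) (n_det - nrow(truth)) / nrow(truth)
                 else NA_real_
  # TSD accuracy and boundary offsets over matched full family members
  tsd_ok <- 0L; tsd_tot <- 0L; offsets <- integer()
  for (f in families) for (m in f$members) {
    i <- match_truth_idx(m$interval)
    if (is.na(i) || truth$truncated[i]) next
    offsets <- c(offsets, abs(m$interval$start - truth$start[i]),
                 abs(m$interval$end - truth$end[i]))
    if (truth$tsd_len[i] < 2L) next
    tsd_tot <- tsd_tot + 1L
    if (!is.null(m$tsd) && m$tsd$length == truth$tsd_len[i] &&
        m$tsd$seq == truth$tsd_seq[i])
      tsd_ok <- tsd_ok + 1L
  }
  structure(list(
    family = list(precision = fam_precision, recall = fam_recall,
                  f1 = fam_f1),
    copies = list(precision = cp_precision, recall = cp_recall,
                  f1 = cp_f1, count_error = count_error,
                  n_detected = n_det, n_planted = nrow(truth)),
    tsd_exact_frac = if (tsd_tot) tsd_ok / tsd_tot else NA_real_,
    boundary = list(mean_offset = if (length(offsets)) mean(offsets)
                    else NA_real_,
                    max_offset = if (length(offsets)) max(offsets)
                    else NA_real_)),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    paste0("recovery_report\n  family: P=%.3f R=%.3f F1=%.3f\n",
           "  copies: P=%.3f R=%.3f F1=%.3f count_err=%+.3f\n",
           "  tsd exact: %.3f  boundary offset mean=%.2f max=%d\n"),
    x$family$precision, x$family$recall, x$family$f1,
    x$copies$precision, x$copies$recall, x$copies$f1,
    x$copies$count_error, x$tsd_exact_frac, x$boundary$mean_offset,
    as.integer(x$boundary$max_offset)))
  invisible(x)
}

# Flatten a recovery report to a data.frame for TSV serialization.
recovery_as_df <- function(rep) {
  data.frame(
    metric = c("family_precision", "family_recall", "family_f1",
               "copy_precision", "copy_recall", "copy_f1",
               "copy_count_error", "n_detected", "n_planted",
               "tsd_exact_frac", "boundary_mean_offset",
               "boundary_max_offset"),
    value = c(rep$family$precision, rep$family$recall, rep$family$f1,
              rep$copies$precision, rep$copies$recall, rep$copies$f1,
              rep$copies$count_error, rep$copies$n_detected,
              rep$copies$n_planted, rep$tsd_exact_frac,
              rep$boundary$mean_offset, rep$boundary$max_offset))
}
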