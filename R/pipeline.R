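# Configuration, orchestration, naming, and standard-format outputs.

#' Pipeline configuration
#'
#' @param genomes Named list of [genome_record()]s, or a character vector
#'   of FASTA paths (read with [read_genomes()]; names give roles
#'   `"virus"`/`"host"`, default virus).
#' @param outdir Output directory (created if missing).
#' @param seed Run seed; per-stage seeds are derived by stable hashing of
#'   stage names, so stage results do not depend on execution order.
#' @param discovery,mask,empty_site,ht,phylo Module parameter blocks.
#' @param signatures Superfamily signature table.
#' @param flank_len Flank length for boundary refinement.
#' @param stages Stages to run, a subset of
#'   `c("discover","quantify","compare","ht","autonomous","tree","evaluate")`.
#' @param truth Optional `"planted_truth_set"` for recovery scoring.
#' @return Validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(genomes, outdir, seed = 1L,
                            discovery = discovery_params(),
                            mask = mask_params(),
                            empty_site = empty_site_params(),
                            ht = ht_screen_params(),
                            phylo = phylo_params(),
                            signatures = default_signatures(),
                            flank_len = 100L,
                            stages = c("discover", "quantify", "compare",
                                       "ht", "autonomous", "tree",
                                       "evaluate"),
                            truth = NULL) {
  if (is.character(genomes)) {
    roles <- names(genomes) %||% rep("virus", length(genomes))
    gl <- list()
    for (i in seq_along(genomes)) {
      for (g in read_genomes(genomes[i],
                             role = if (roles[i] %in% c("virus", "host"))
                               roles[i] else "virus"))
        gl[[g$id]] <- g
    }
    genomes <- gl
  }
  if (!length(genomes)) stop("config invalid: no genomes supplied")
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    names(genomes) <- vapply(genomes, `[[`, "", "id")
  stopifnot(all(vapply(genomes, inherits, TRUE, "genome_record")))
  bad <- setdiff(stages, c("discover", "quantify", "compare", "ht",
                           "autonomous", "tree", "evaluate"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(genomes = genomes, outdir = outdir,
                 seed = as.integer(seed), discovery = discovery,
                 mask = mask, empty_site = empty_site, ht = ht,
                 phylo = phylo, signatures = signatures,
                 flank_len = as.integer(flank_len), stages = stages,
                 truth = truth),
            class = "pipeline_config")
}

superfamily_token <- function(superfamily) {
  if (is.na(superfamily) || superfamily == "Unknown") return("Unk")
  strsplit(superfamily, "/", fixed = TRUE)[[1L]][1L]
}

#' Assign nomenclature-style names to classified families
#'
#' Non-autonomous families are named `X-NA#` where `X` is the superfamily
#' token (`Unk` for unclassified) and `#` an ordinal assigned by
#' descending total copy number; the autonomous partner of `X-NA#` is
#' named `X-#`.
#'
#' @param families List of classified `"mite_family"`s.
#' @param copy_counts Numeric vector of total copy numbers (parallel to
#'   `families`); member counts are used when absent.
#' @return The families with `name` set, in ordinal order.
#' @export
assign_names <- function(families, copy_counts = NULL) {
  if (!length(families)) return(families)
  counts <- copy_counts %||%
    vapply(families, function(f) length(f$members), 0L)
  ord <- order(-counts, seq_along(families))
  families <- families[ord]
  for (i in seq_along(families))
    families[[i]]$name <- sprintf(
      "%s-NA%d", superfamily_token(families[[i]]$superfamily), i)
  families
}

#' Write annotated copies as GFF3
#'
#' 1-based inclusive coordinates, feature type `dispersed_repeat`,
#' attributes `Family`, `Completeness`, `Divergence` (4 decimals) and
#' `TSD`; records sorted by seqid then start.
#'
#' @param copies List of `"mite_copy"`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(copies, path) {
  if (!length(copies)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  seqid <- vapply(copies, function(x) x$interval$genome_id, "")
  st <- vapply(copies, function(x) x$interval$start, 0L) + 1L
  en <- vapply(copies, function(x) x$interval$end, 0L)
  strand <- vapply(copies, function(x) x$interval$strand, "")
  gr <- GenomicRanges::GRanges(seqid, IRanges::IRanges(st, en),
                               strand = strand)
  S4Vectors::mcols(gr)$source <- "mitescan"
  S4Vectors::mcols(gr)$type <- "dispersed_repeat"
  S4Vectors::mcols(gr)$Family <- vapply(copies, function(x)
    x$family %||% NA_character_, "")
  S4Vectors::mcols(gr)$Completeness <- vapply(copies, function(x)
    x$completeness %||% "full", "")
  S4Vectors::mcols(gr)$Divergence <- vapply(copies, function(x)
    fmt4(x$divergence %||% 0), "")
  S4Vectors::mcols(gr)$TSD <- vapply(copies, function(x)
    if (is.null(x$tsd)) "." else x$tsd$seq, "")
  o <- order(seqid, st)
  rtracklayer::export.gff3(gr[o], path)
  invisible(path)
}

#' Read copies back from a GFF3 annotation
#'
#' Inverse of [write_gff3()] (TSD flank intervals are reconstructed from
#' the stored TSD sequence and the copy boundaries).
#'
#' @param path A GFF3 file written by [write_gff3()].
#' @return List of `"mite_copy"`s.
#' @export
read_gff3_copies <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr)) return(list())
  mc <- S4Vectors::mcols(gr)
  lapply(seq_along(gr), function(i) {
    s <- BiocGenerics::start(gr)[i] - 1L
    e <- BiocGenerics::end(gr)[i]
    std <- as.character(BiocGenerics::strand(gr))[i]
    if (std == "*") std <- "+"
    gid <- as.character(GenomicRanges::seqnames(gr))[i]
    tsd <- mc$TSD[i]
    tsd_call <- if (!is.na(tsd) && tsd != ".") {
      structure(list(seq = tsd, length = nchar(tsd),
                     left_interval = interval(gid, s - nchar(tsd), s),
                     right_interval = interval(gid, e, e + nchar(tsd))),
                class = "tsd_call")
    } else NULL
    structure(list(interval = interval(gid, s, e, std),
                   family = mc$Family[i],
                   completeness = mc$Completeness[i],
                   divergence = as.numeric(mc$Divergence[i]),
                   tsd = tsd_call), class = "mite_copy")
  })
}

# Build one family from a clustered candidate set: refine boundaries,
# align members, build consensus, call the family TIR and member TSDs.
build_family <- function(fam, genomes, dparams, flank_len = 100L,
                         tsd_max_len = 10L) {
  if (length(fam$members) >= 2L)
    fam <- tryCatch(refine_boundaries(fam, genomes, flank_len),
                    error = function(e) fam)
  seqs <- vapply(fam$members, `[[`, "", "seq")
  aln <- if (length(seqs) >= 2L) align_multi(seqs) else seqs
  fam$consensus <- if (length(seqs) >= 2L) build_consensus(aln)
                   else seqs[[1L]]
  # the lexicographically smaller of (consensus, revcomp) defines the
  # family plus strand, so reruns give reproducible orientations
  if (revcomp(fam$consensus) < fam$consensus) {
    fam$consensus <- revcomp(fam$consensus)
    fam$members <- lapply(fam$members, function(m) {
      m$seq <- revcomp(m$seq)
      m$strand <- if (m$strand == "+") "-" else "+"
      m$interval$strand <- m$strand
      tl <- m$tir_left
      m$tir_left <- revcomp(m$tir_right)
      m$tir_right <- revcomp(tl)
      m
    })
  }
  fam$tir <- consensus_tir(fam$consensus, dparams)
  for (i in seq_along(fam$members)) {
    m <- fam$members[[i]]
    fam$members[[i]]$tsd <- tryCatch(
      call_tsd(m$interval, genomes[[m$interval$genome_id]],
               max_len = tsd_max_len),
      error = function(e) NULL)
  }
  lens <- member_tsd_lengths(fam)
  fam$tsd_length <- if (length(lens)) modal_value(lens) else NA_integer_
  fam
}

#' Run the full analysis pipeline
#'
#' Orchestrates discovery, filtering, consensus building, classification,
#' naming, copy annotation, comparative analyses, autonomous-partner
#' linkage, tree building and (when truth is supplied) recovery scoring;
#' writes standard-format products into the output directory. The run is
#' deterministic under a fixed config and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory products (`families`,
#'   `copies_by_genome`, `stats`, `ht_calls`, `autonomous`, `trees`,
#'   `recovery`) and `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "trees"), showWarnings = FALSE)
  logs <- character()
  note <- function(...) logs <<- c(logs, paste0(...))
  manifest <- character()
  emit <- function(f) manifest <<- c(manifest, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(manifest, paste0("INCOMPLETE at stage: ", name)),
                 file.path(outdir, "MANIFEST"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  genomes <- config$genomes
  note("genomes: ", paste(names(genomes), collapse = ","))
  note("seed: ", config$seed)
  note("discovery: ", paste(deparse(unclass(config$discovery)),
                            collapse = ""))
  virus_ids <- names(genomes)[vapply(genomes, function(g)
    g$role == "virus", TRUE)]
  host_ids <- setdiff(names(genomes), virus_ids)

  families <- list()
  if ("discover" %in% config$stages) {
    stage("discover", {
      cands <- list()
      for (gid in virus_ids) {
        cc <- find_tir_candidates(genomes[[gid]], config$discovery)
        note("candidates in ", gid, ": ", length(cc))
        cands <- c(cands, cc)
      }
      provisional <- cluster_into_families(cands, genomes,
                                           config$discovery)
      note("provisional families: ", length(provisional))
      built <- lapply(provisional, build_family, genomes = genomes,
                      dparams = config$discovery,
                      flank_len = config$flank_len)
      # two-pass filtering: the compound test only makes sense against
      # families that themselves pass the basic screens (a discarded
      # fragment cluster must not take its parent family down with it)
      basic_ok <- vapply(built, function(f)
        apply_candidate_filters(f, list(), config$discovery,
                                config$signatures)$keep, TRUE)
      for (i in which(!basic_ok))
        note("family of ", length(built[[i]]$members),
             " members filtered: ",
             apply_candidate_filters(built[[i]], list(), config$discovery,
                                     config$signatures)$reason)
      surv <- built[basic_ok]
      kept <- list()
      for (i in seq_along(surv)) {
        v <- apply_candidate_filters(surv[[i]], surv[-i],
                                     config$discovery, config$signatures)
        if (v$keep) kept[[length(kept) + 1L]] <- surv[[i]]
        else note("family of ", length(surv[[i]]$members),
                  " members filtered: ", v$reason)
      }
      for (i in seq_along(kept)) {
        kept[[i]]$superfamily <- classify_superfamily(kept[[i]],
                                                      config$signatures)
        kept[[i]]$name <- sprintf("prov%d", i)
      }
      families <- kept
    })
  }

  copies_by_genome <- stats::setNames(
    vector("list", length(genomes)), names(genomes))
  stats_rows <- list()
  if ("quantify" %in% config$stages && length(families)) {
    stage("quantify", {
      for (gid in names(genomes)) {
        copies_by_genome[[gid]] <- annotate_copies(
          genomes[[gid]], families, config$mask)
      }
      counts <- vapply(families, function(f) {
        sum(vapply(names(genomes), function(gid)
          sum(vapply(copies_by_genome[[gid]], function(cp)
            cp$family == f$name, TRUE)), 0L))
      }, 0L)
      old_names <- vapply(families, `[[`, "", "name")
      families <- assign_names(families, counts)
      new_of <- stats::setNames(vapply(families, `[[`, "", "name"),
                                old_names[order(-counts,
                                                seq_along(counts))])
      for (gid in names(genomes)) {
        copies_by_genome[[gid]] <- lapply(copies_by_genome[[gid]],
          function(cp) { cp$family <- unname(new_of[cp$family]); cp })
      }
      for (gid in names(genomes)) for (f in families) {
        fc <- Filter(function(cp) cp$family == f$name,
                     copies_by_genome[[gid]])
        st <- family_stats(fc, genomes[[gid]])
        stats_rows[[length(stats_rows) + 1L]] <- data.frame(
          genome = gid, family = f$name, superfamily = f$superfamily,
          copy_count = st$copy_count, bp_covered = st$bp_covered,
          genome_fraction = fmt4(st$genome_fraction))
      }
    })
  } else if (length(families)) {
    families <- assign_names(families)
  }

  write_fasta(stats::setNames(
    vapply(families, `[[`, "", "consensus"),
    vapply(families, `[[`, "", "name")) %||% character(),
    file.path(outdir, "families.fa"))
  emit("families.fa")
  write_gff3(unlist(copies_by_genome, recursive = FALSE) %||% list(),
             file.path(outdir, "copies.gff3"))
  emit("copies.gff3")
  write_tsv_report(
    if (length(stats_rows)) do.call(rbind, stats_rows)
    else data.frame(genome = character(), family = character(),
                    superfamily = character(), copy_count = integer(),
                    bp_covered = integer(), genome_fraction = character()),
    file.path(outdir, "stats.tsv"))
  emit("stats.tsv")

  empty_rows <- list()
  ortho <- NULL
  if ("compare" %in% config$stages && length(families)) {
    stage("compare", {
      for (gid in virus_ids) {
        g <- genomes[[gid]]
        for (f in families) {
          fc <- Filter(function(cp) cp$family == f$name,
                       copies_by_genome[[gid]] %||% list())
          fulls <- Filter(function(cp) cp$completeness == "full", fc)
          for (cp in fulls) {
            es <- tryCatch(
              find_empty_paralogs(cp, g, config$empty_site, fc),
              error = function(e) list())
            for (s in es) {
              empty_rows[[length(empty_rows) + 1L]] <- data.frame(
                family = f$name, genome = gid,
                source_start = cp$interval$start,
                source_end = cp$interval$end,
                locus_start = s$locus$start, locus_end = s$locus$end,
                left_identity = fmt4(s$left_identity_pct),
                right_identity = fmt4(s$right_identity_pct),
                gap_len = s$gap_len)
            }
          }
        }
      }
      if (length(virus_ids) >= 2L) {
        ortho <- orthologous_site_matrix(
          families, genomes[virus_ids],
          copies_by_genome[virus_ids], config$empty_site)
      }
    })
  }
  write_tsv_report(
    if (length(empty_rows)) do.call(rbind, empty_rows)
    else data.frame(family = character(), genome = character(),
                    source_start = integer(), source_end = integer(),
                    locus_start = integer(), locus_end = integer(),
                    left_identity = character(),
                    right_identity = character(), gap_len = integer()),
    file.path(outdir, "empty_sites.tsv"))
  emit("empty_sites.tsv")
  ortho_df <- if (!is.null(ortho) && length(ortho$sites)) {
    do.call(rbind, lapply(ortho$sites, function(s) {
      cbind(data.frame(family = s$family, anchor_genome = s$anchor_genome,
                       anchor_start = s$anchor$start,
                       anchor_end = s$anchor$end),
            as.data.frame(as.list(s$status)))
    }))
  } else data.frame(family = character(), anchor_genome = character(),
                    anchor_start = integer(), anchor_end = integer())
  write_tsv_report(ortho_df, file.path(outdir, "ortho_sites.tsv"))
  emit("ortho_sites.tsv")

  ht_rows <- list(); ht_calls <- list()
  if ("ht" %in% config$stages && length(families)) {
    stage("ht", {
      for (f in families) {
        src_gid <- f$members[[1L]]$interval$genome_id
        src_taxon <- genomes[[src_gid]]$taxon
        for (gid in names(genomes)) {
          if (genomes[[gid]]$taxon == src_taxon) next
          call <- ht_presence_call(f, genomes[[gid]], config$ht)
          call$query_taxon <- src_taxon
          ht_calls[[length(ht_calls) + 1L]] <- call
          ht_rows[[length(ht_rows) + 1L]] <- data.frame(
            family = f$name, query_taxon = src_taxon,
            target_genome = gid, target_taxon = genomes[[gid]]$taxon,
            identity_pct = fmt4(call$best_identity_pct),
            coverage = fmt4(call$coverage),
            present = call$present)
        }
      }
    })
  }
  write_tsv_report(
    if (length(ht_rows)) do.call(rbind, ht_rows)
    else data.frame(family = character(), query_taxon = character(),
                    target_genome = character(),
                    target_taxon = character(),
                    identity_pct = character(), coverage = character(),
                    present = logical()),
    file.path(outdir, "ht.tsv"))
  emit("ht.tsv")

  auto_rows <- list(); autonomous <- list()
  if ("autonomous" %in% config$stages && length(families)) {
    stage("autonomous", {
      scan_ids <- if (length(host_ids)) host_ids else names(genomes)
      for (f in families) {
        cands <- link_autonomous_partner(f, genomes[scan_ids])
        if (length(cands)) {
          tok <- superfamily_token(f$superfamily)
          ord <- sub("^.*-NA", "", f$name)
          partner_name <- sprintf("%s-%s", tok, ord)
          autonomous[[partner_name]] <- cands
          for (cd in cands) {
            auto_rows[[length(auto_rows) + 1L]] <- data.frame(
              partner = partner_name, family = f$name,
              genome = cd$interval$genome_id,
              start = cd$interval$start, end = cd$interval$end,
              length = cd$length,
              terminus_matches = cd$terminus_matches,
              best_orf_aa = cd$orfs[[1L]]$protein_length_aa,
              deletion_derivative = cd$deletion_derivative,
              tier = cd$evidence_tier)
          }
        } else {
          note("no autonomous partner for ", f$name)
        }
      }
    })
  }
  write_tsv_report(
    if (length(auto_rows)) do.call(rbind, auto_rows)
    else data.frame(partner = character(), family = character(),
                    genome = character(), start = integer(),
                    end = integer(), length = integer(),
                    terminus_matches = integer(), best_orf_aa = integer(),
                    deletion_derivative = logical(), tier = character()),
    file.path(outdir, "autonomous.tsv"))
  emit("autonomous.tsv")

  trees <- list()
  if ("tree" %in% config$stages && length(families)) {
    stage("tree", {
      for (f in families) {
        all_fc <- unlist(lapply(names(genomes), function(gid)
          Filter(function(cp) cp$family == f$name,
                 copies_by_genome[[gid]] %||% list())),
          recursive = FALSE)
        pp <- config$phylo
        pp$seed <- stage_seed(config$seed, paste0("tree_", f$name))
        tr <- family_copy_tree(f, genomes, copies = all_fc, params = pp)
        if (is.null(tr)) {
          note("tree skipped for ", f$name, ": < 4 full copies")
          next
        }
        trees[[f$name]] <- tr
        fp <- file.path(outdir, "trees",
                        paste0(gsub("[^A-Za-z0-9._-]", "_", f$name),
                               ".nwk"))
        ape::write.tree(tr, fp)
        emit(file.path("trees", basename(fp)))
      }
    })
  }

  recovery <- NULL
  if ("evaluate" %in% config$stages && !is.null(config$truth)) {
    stage("evaluate", {
      recovery <- evaluate_recovery(config$truth, families,
                                     copies_by_genome)
      write_tsv_report(recovery_as_df(recovery),
                       file.path(outdir, "recovery.tsv"))
      emit("recovery.tsv")
    })
  }

  writeLines(c(manifest, "complete"), file.path(outdir, "MANIFEST"))
  writeLines(logs, file.path(outdir, "log.txt"))
  invisible(list(families = families,
                 copies_by_genome = copies_by_genome,
                 stats = if (length(stats_rows)) do.call(rbind, stats_rows)
                         else NULL,
                 ht_calls = ht_calls, autonomous = autonomous,
                 trees = trees, recovery = recovery, outdir = outdir))
}
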