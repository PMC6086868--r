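#' Pipeline parameters
#'
#' Union of all stage parameters with every default overridable. Unknown
#' fields are rejected.
#'
#' @param recruit [recruit_params()].
#' @param classifier [classifier_params()].
#' @param min_contig_len Minimum contig length out of the super-scaffold.
#' @param merge_k,min_overlap,min_identity,max_rounds Merge-engine knobs,
#'   see [find_overlaps()] and [improve()].
#' @param normalize Run median k-mer digital normalization before
#'   recruitment (default off; it only reduces data volume).
#' @param norm_k,norm_target Normalizer knobs, see [normalize_reads()].
#' @param read_min_bits,contig_min_bits Minimum reported bit score of the
#'   internal aligner for read-level and contig-level searches.
#' @return Named list of class `pipeline_params`.
#' @export
pipeline_params <- function(recruit = recruit_params(),
                            classifier = classifier_params(),
                            min_contig_len = 100L,
                            merge_k = 31L, min_overlap = 100L,
                            min_identity = 0.98, max_rounds = 10L,
                            normalize = FALSE, norm_k = 21L,
                            norm_target = 40L,
                            read_min_bits = 30, contig_min_bits = 50) {
  structure(
    list(recruit = recruit, classifier = classifier,
         min_contig_len = as.integer(min_contig_len),
         merge_k = as.integer(merge_k),
         min_overlap = as.integer(min_overlap),
         min_identity = min_identity, max_rounds = as.integer(max_rounds),
         normalize = isTRUE(normalize), norm_k = as.integer(norm_k),
         norm_target = as.integer(norm_target),
         read_min_bits = read_min_bits, contig_min_bits = contig_min_bits),
    class = "pipeline_params"
  )
}

#' Load pipeline parameters from a YAML config
#'
#' Sections `recruit`, `classifier` and top-level scalar fields override
#' the corresponding [pipeline_params()] defaults. Unknown keys anywhere
#' are an error.
#'
#' @param path YAML file.
#' @return A `pipeline_params` list.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  defaults <- pipeline_params()
  known_top <- setdiff(names(defaults), c("recruit", "classifier"))
  bad <- setdiff(names(y), c(known_top, "recruit", "classifier"))
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  merge_section <- function(build_fn, given, section) {
    args <- formals(build_fn)
    bad <- setdiff(names(given), names(args))
    if (length(bad) > 0) {
      stop("unknown config key(s) in ", section, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    do.call(build_fn, given)
  }
  recruit <- merge_section(recruit_params,
                           if (is.null(y$recruit)) list() else y$recruit,
                           "recruit")
  classifier <- merge_section(classifier_params,
                              if (is.null(y$classifier)) list() else y$classifier,
                              "classifier")
  args <- y[intersect(names(y), known_top)]
  do.call(pipeline_params,
          c(list(recruit = recruit, classifier = classifier), args))
}

log_event <- function(log, stage, event, ...) {
  c(log, list(c(list(stage = stage, event = event), list(...))))
}

write_log <- function(log, path) {
  writeLines(vapply(log, function(x)
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)), ""),
    path)
  invisible(path)
}

#' Run the full pipeline on a synthetic or assembled-in-memory world
#'
#' Executes all stages: dereplication (and optional normalization), read
#' recruitment against the viral database with score-radius filtering and
#' Jaccard redundancy removal, per-genome super-scaffold construction
#' (nucleotide pileup + CDS-tiled protein evidence), gap splitting,
#' iterative merge/map/reassemble improvement together with any supplied
#' de novo contigs, read abundance, two-pass classification against the
#' comprehensive (viral + non-viral) database, and the aggregate report.
#' Deterministic: identical inputs and parameters give identical outputs.
#'
#' @param world A `synth_world` from [make_world()], or any list with the
#'   same fields (`taxonomy`, `refs`, `host`, `proteins`, `cds`, `reads`,
#'   `entry2genome`).
#' @param params [pipeline_params()].
#' @param denovo_contigs Optional contig tibble (`id`, `seq`) from an
#'   external de novo assembler, hybridized in before improvement.
#' @param out_dir Optional output directory; when given, all intermediate
#'   and final artifacts plus a JSON-lines log of filter events are
#'   written.
#' @return A `viro_run` list: `readsets`, `superscaffolds`, `contigs`,
#'   `abundance`, `classification`, `report`, `log`.
#' @export
run_pipeline <- function(world, params = pipeline_params(),
                         denovo_contigs = NULL, out_dir = NULL) {
  log <- list()
  cp <- params$classifier

  derep <- dereplicate(world$reads)
  log <- log_event(log, "dereplicate", "collapsed",
                   input = nrow(world$reads), unique = nrow(derep$reads))
  reads_work <- derep$reads
  if (params$normalize) {
    reads_work <- normalize_reads(reads_work, params$norm_k,
                                  params$norm_target)
    log <- log_event(log, "normalize", "retained", reads = nrow(reads_work))
  }

  # recruitment against the viral database
  aln_nt <- align_all(reads_work, world$refs, kind = "nt",
                      min_bits = params$read_min_bits)
  aln_aa <- align_all(reads_work, world$proteins, kind = "aa",
                      min_bits = params$read_min_bits)
  f_nt <- filter_alignments(aln_nt, "nt", params$recruit)
  f_aa <- filter_alignments(aln_aa, "aa", params$recruit)
  log <- log_event(log, "recruit", "alignment_filter",
                   nt_in = nrow(aln_nt), nt_kept = nrow(f_nt),
                   aa_in = nrow(aln_aa), aa_kept = nrow(f_aa))
  readsets <- assign_reads(dplyr::bind_rows(f_nt, f_aa), world$entry2genome)
  kept_sets <- jaccard_filter(readsets, params$recruit$jaccard_tau)
  for (g in setdiff(readsets$genome_id, kept_sets$genome_id)) {
    log <- log_event(log, "recruit", "jaccard_drop", genome = g,
                     tau = params$recruit$jaccard_tau)
  }

  # per-genome super-scaffolds
  scaffolds <- list()
  contigs <- list()
  for (gi in seq_len(nrow(kept_sets))) {
    gid <- kept_sets$genome_id[gi]
    rids <- kept_sets$read_ids[[gi]]
    glen <- nchar(world$refs$seq[world$refs$id == gid])
    g_nt <- f_nt[f_nt$subject_id == gid & f_nt$query_id %in% rids, ,
                 drop = FALSE]
    pl <- alignment_placements(g_nt, reads_work)
    np <- pileup_assemble(gid, glen, pl)
    layers <- list()
    gcds <- world$cds[world$cds$genome_id == gid, , drop = FALSE]
    for (ci in seq_len(nrow(gcds))) {
      cdsr <- gcds[ci, ]
      p_aa <- f_aa[f_aa$subject_id == cdsr$protein_id &
                     f_aa$query_id %in% rids, , drop = FALSE]
      if (nrow(p_aa) == 0) next
      plen <- nchar(world$proteins$seq[world$proteins$id == cdsr$protein_id])
      ppl <- aa_alignment_placements(p_aa, reads_work)
      pp <- pileup_assemble(cdsr$protein_id, plen, ppl, alphabet = "aa")
      calls <- aa_read_nt_calls(p_aa, reads_work, cdsr)
      layers[[length(layers) + 1L]] <-
        back_translate_tile(pp, cdsr, glen, calls)
    }
    ss <- build_superscaffold(np, layers)
    scaffolds[[gid]] <- ss
    contigs[[gid]] <- split_on_gaps(ss, params$min_contig_len)
  }
  contigs <- dplyr::bind_rows(contigs)
  if (!is.null(denovo_contigs) && nrow(denovo_contigs) > 0) {
    denovo_contigs$origin <- "denovo"
    contigs <- dplyr::bind_rows(contigs, denovo_contigs)
  }
  log <- log_event(log, "scaffold", "contigs",
                   genomes = nrow(kept_sets), contigs = nrow(contigs))

  if (nrow(contigs) == 0) {
    warning("no contigs produced; returning an empty report", call. = FALSE)
    cls <- classify_contigs(contigs, empty_alignments(), world$taxonomy, cp)
    rep <- aggregate_report(cls, NULL)
    res <- list(readsets = kept_sets, superscaffolds = scaffolds,
                contigs = contigs,
                abundance = tibble::tibble(contig_id = character(),
                                           reads = integer(),
                                           mean_depth = numeric()),
                classification = cls, report = rep, log = log)
    class(res) <- "viro_run"
    if (!is.null(out_dir)) write_run(res, out_dir)
    return(res)
  }

  improved <- improve(contigs, derep$reads, max_rounds = params$max_rounds,
                      k = params$merge_k, min_overlap = params$min_overlap,
                      min_identity = params$min_identity)
  log <- log_event(log, "improve", "converged",
                   rounds = attr(improved, "rounds"),
                   contigs = nrow(improved),
                   circular = length(attr(improved, "circular")))
  ab <- abundance(improved, derep$reads, derep$multiplicity)

  # classification against the comprehensive database (viral + host)
  nt_db <- dplyr::bind_rows(world$refs[, c("id", "seq", "taxid")],
                            world$host[, c("id", "seq", "taxid")])
  c_nt <- align_all(improved, nt_db, kind = "nt",
                    min_bits = params$contig_min_bits, seed_step = 24L)
  c_aa <- align_all(improved, world$proteins, kind = "aa",
                    min_bits = params$contig_min_bits, seed_step = 24L)
  cls <- classify_contigs(improved, dplyr::bind_rows(c_nt, c_aa),
                          world$taxonomy, cp)
  for (i in seq_len(nrow(cls$classifications))) {
    r <- cls$classifications[i, ]
    if (r$verdict != "classified") {
      log <- log_event(log, "classify", r$verdict, contig = r$contig_id,
                       bits = r$pass1_best, reason = r$reason)
    }
  }
  rep <- aggregate_report(cls, ab)
  for (i in seq_len(nrow(rep$suppressed))) {
    s <- rep$suppressed[i, ]
    log <- log_event(log, "report", "taxon_suppressed", taxid = s$taxid,
                     bits = s$total_bits,
                     threshold = cp$min_taxon_bits)
  }
  res <- list(readsets = kept_sets, superscaffolds = scaffolds,
              contigs = improved, abundance = ab, classification = cls,
              report = rep, log = log)
  class(res) <- "viro_run"
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

# convert nt alignment records into pileup placements (oriented read
# segments laid on subject coordinates)
alignment_placements <- function(records, reads) {
  if (nrow(records) == 0) {
    return(tibble::tibble(read_id = character(), ref_start = integer(),
                          bases = character()))
  }
  seqs <- stats::setNames(reads$seq, reads$id)
  seg <- substr(seqs[records$query_id], records$q_start, records$q_end)
  neg <- records$strand == "-"
  if (any(neg)) seg[neg] <- revcomp(seg[neg])
  tibble::tibble(read_id = records$query_id,
                 ref_start = records$s_start, bases = unname(seg))
}

# translated placements: the oriented read segment translated to protein
# coordinates
aa_alignment_placements <- function(records, reads) {
  if (nrow(records) == 0) {
    return(tibble::tibble(read_id = character(), ref_start = integer(),
                          bases = character()))
  }
  seqs <- stats::setNames(reads$seq, reads$id)
  seg <- substr(seqs[records$query_id], records$q_start, records$q_end)
  neg <- records$strand == "-"
  if (any(neg)) seg[neg] <- revcomp(seg[neg])
  tibble::tibble(read_id = records$query_id,
                 ref_start = records$s_start,
                 bases = translate_nt(unname(seg)))
}

#' @export
print.viro_run <- function(x, ...) {
  cat("<viro_run> ", nrow(x$contigs), " contigs, ",
      nrow(x$report$report), " reported taxa\n", sep = "")
  print(x$report)
  invisible(x)
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readsets <- res$readsets
  readr::write_tsv(
    tibble::tibble(
      genome_id = rep(readsets$genome_id, lengths(readsets$read_ids)),
      read_id = unlist(readsets$read_ids)
    ),
    file.path(out_dir, "readsets.tsv"))
  if (length(res$superscaffolds) > 0) {
    write_fasta(tibble::tibble(
      id = names(res$superscaffolds),
      seq = vapply(res$superscaffolds, function(s) s$seq, "")
    ), file.path(out_dir, "superscaffolds.fasta"))
    support <- dplyr::bind_rows(lapply(res$superscaffolds, function(s)
      tibble::tibble(genome_id = s$genome_id,
                     position = seq_along(s$source),
                     source = s$source, support = s$support)))
    readr::write_tsv(support, file.path(out_dir, "superscaffold_support.tsv"))
  }
  if (nrow(res$contigs) > 0) {
    write_fasta(res$contigs[, c("id", "seq")],
                file.path(out_dir, "contigs.fasta"))
  }
  readr::write_tsv(res$abundance, file.path(out_dir, "abundance.tsv"))
  readr::write_tsv(tidy(res$classification),
                   file.path(out_dir, "classifications.tsv"))
  readr::write_tsv(res$report$report, file.path(out_dir, "report.tsv"))
  readr::write_tsv(res$report$unclassified,
                   file.path(out_dir, "unclassified.tsv"))
  write_log(res$log, file.path(out_dir, "log.jsonl"))
  invisible(out_dir)
}

#' Score a report against a truth table
#'
#' Taxa are matched by taxid. Precision is `TP / (TP + FP)`, recall
#' `TP / (TP + FN)` and the F-score their harmonic mean
#' `2 PR / (P + R)` (0 when both are 0).
#'
#' @param report A `viro_report`, a `viro_run`, or a tibble with a `taxid`
#'   column.
#' @param truth Truth: a `synth_world`, its `truth` list, or an integer
#'   vector of planted taxids.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_score`.
#' @export
score_vs_truth <- function(report, truth) {
  found <- if (inherits(report, "viro_run")) report$report$report$taxid
           else if (inherits(report, "viro_report")) report$report$taxid
           else report$taxid
  expected <- if (inherits(truth, "synth_world")) truth$truth$taxa
              else if (is.list(truth) && !is.null(truth$taxa)) truth$taxa
              else truth
  tp <- length(intersect(found, expected))
  fp <- length(setdiff(found, expected))
  fn <- length(setdiff(expected, found))
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = p, recall = r, f_score = f)
}
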