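#' Recruitment parameters
#'
#' Score-radius margins for alignment reporting and the Jaccard redundancy
#' threshold. An alignment is reported when its bit score lies within a
#' margin `d` of the best score in its group: `bits >= (1 - d) * best`,
#' applied both per subject and per query. Defaults follow the pipeline's
#' empirical settings: translated alignments within 20% of the subject best
#' and 8% of the per-query best; nucleotide alignments within 90% and 5%.
#'
#' @param d_subject_aa,d_query_aa,d_subject_nt,d_query_nt Score-radius
#'   margins in `[0, 1]`.
#' @param jaccard_tau Jaccard *distance* threshold below which a smaller
#'   genome read set is considered redundant with a larger one (default
#'   0.05, i.e. drop when the sets are at least 95% similar).
#' @return A named list of class `recruit_params`.
#' @export
recruit_params <- function(d_subject_aa = 0.20, d_query_aa = 0.08,
                           d_subject_nt = 0.90, d_query_nt = 0.05,
                           jaccard_tau = 0.05) {
  p <- list(d_subject_aa = d_subject_aa, d_query_aa = d_query_aa,
            d_subject_nt = d_subject_nt, d_query_nt = d_query_nt,
            jaccard_tau = jaccard_tau)
  stopifnot(all(unlist(p) >= 0), all(unlist(p) <= 1))
  structure(p, class = "recruit_params")
}

#' Collapse exact-duplicate reads
#'
#' Exact sequence duplicates are collapsed to the first-seen read;
#' multiplicities are kept so abundance accounting can re-expand them later.
#'
#' @param reads Tibble with `id`, `seq` (and optionally `qual`).
#' @return List with `reads` (tibble of unique reads, input order of first
#'   occurrence) and `multiplicity` (named integer vector keyed by the
#'   representative read id).
#' @export
dereplicate <- function(reads) {
  first <- !duplicated(reads$seq)
  rep_id <- reads$id[first][match(reads$seq, reads$seq[first])]
  mult <- table(factor(rep_id, levels = reads$id[first]))
  list(
    reads = reads[first, , drop = FALSE],
    multiplicity = stats::setNames(as.integer(mult), names(mult))
  )
}

#' Median k-mer digital normalization
#'
#' A simplified streaming coverage normalizer: reads are processed in input
#' order against a running k-mer count sketch; a read is discarded when the
#' median count of its k-mers already exceeds `target` (its k-mers are then
#' not added). Reads shorter than `k` pass through untouched. Deterministic
#' for a fixed input order. Optional — the downstream pipeline is correct
#' without it; it only reduces data volume.
#'
#' @param reads Tibble with `id`, `seq`.
#' @param k K-mer size (default 21).
#' @param target Target median depth (default 40).
#' @return Tibble of retained reads, input order preserved.
#' @export
normalize_reads <- function(reads, k = 21L, target = 40L) {
  if (nrow(reads) == 0) return(reads)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    km <- kmers_of(reads$seq[i], k)
    if (length(km) == 0) { keep[i] <- TRUE; next }
    cts <- vapply(km, function(x) {
      v <- counts[[x]]
      if (is.null(v)) 0L else v
    }, 0L, USE.NAMES = FALSE)
    if (stats::median(cts) > target) next
    keep[i] <- TRUE
    for (x in km) {
      v <- counts[[x]]
      counts[[x]] <- if (is.null(v)) 1L else v + 1L
    }
  }
  reads[keep, , drop = FALSE]
}

#' Apply score-radius reporting thresholds to alignments
#'
#' Keeps record `r` iff `bits(r) >= (1 - d_subject) * best bits among
#' records sharing r's subject` and `bits(r) >= (1 - d_query) * best bits
#' among records sharing r's query`. Margins are taken from `params`
#' according to `kind`. Idempotent.
#'
#' @param records Alignment tibble (one kind).
#' @param kind `"nt"` or `"aa"`.
#' @param params A [recruit_params()] list.
#' @return Filtered alignment tibble, input order preserved.
#' @export
filter_alignments <- function(records, kind = c("nt", "aa"),
                              params = recruit_params()) {
  kind <- match.arg(kind)
  if (nrow(records) == 0) return(records)
  d_subject <- if (kind == "aa") params$d_subject_aa else params$d_subject_nt
  d_query <- if (kind == "aa") params$d_query_aa else params$d_query_nt
  best_s <- stats::ave(records$bits, records$subject_id, FUN = max)
  best_q <- stats::ave(records$bits, records$query_id, FUN = max)
  records[records$bits >= (1 - d_subject) * best_s &
            records$bits >= (1 - d_query) * best_q, , drop = FALSE]
}

#' Assign reads to candidate genomes
#'
#' A read belongs to every genome that any of its surviving alignment
#' records points to (multi-membership is allowed and resolved later by
#' [jaccard_filter()]). Protein subjects are mapped to their originating
#' genome through `entry2genome`.
#'
#' @param records Threshold-filtered alignment tibble (nt and aa may be
#'   concatenated).
#' @param entry2genome Named character vector mapping subject entry id to
#'   genome id. Subjects without a mapping are skipped with a warning.
#' @return Nested tibble: `genome_id`, `read_ids` (list column of unique
#'   read ids), `n_reads`; sorted by `n_reads` descending then `genome_id`.
#' @export
assign_reads <- function(records, entry2genome) {
  if (nrow(records) == 0) {
    return(tibble::tibble(genome_id = character(), read_ids = list(),
                          n_reads = integer()))
  }
  genome <- unname(entry2genome[records$subject_id])
  if (anyNA(genome)) {
    missing <- unique(records$subject_id[is.na(genome)])
    warning("no genome mapping for subject(s): ",
            paste(missing, collapse = ", "), "; records skipped",
            call. = FALSE)
  }
  ok <- !is.na(genome)
  tibble::tibble(genome_id = genome[ok], read_id = records$query_id[ok]) |>
    dplyr::distinct() |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(read_ids = list(sort(.data$read_id)),
                     n_reads = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_reads), .data$genome_id)
}

#' Drop redundant genome read sets by Jaccard distance
#'
#' Sets are visited largest first (ties by genome id); a set is dropped when
#' its Jaccard distance `1 - |A ∩ B| / |A ∪ B|` to any already-retained set
#' is at most `tau`. The largest set is never dropped; retained sets are
#' pairwise more than `tau` apart from every larger retained set.
#'
#' @param readsets Nested tibble from [assign_reads()].
#' @param tau Distance threshold (default from [recruit_params()]).
#' @return Filtered readsets tibble, same columns.
#' @export
jaccard_filter <- function(readsets, tau = recruit_params()$jaccard_tau) {
  if (nrow(readsets) == 0) return(readsets)
  o <- order(-readsets$n_reads, readsets$genome_id)
  readsets <- readsets[o, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(readsets))) {
    b <- readsets$read_ids[[i]]
    redundant <- FALSE
    for (j in kept) {
      a <- readsets$read_ids[[j]]
      d <- 1 - length(intersect(a, b)) / length(union(a, b))
      if (d <= tau) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, i)
  }
  readsets[kept, , drop = FALSE]
}
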