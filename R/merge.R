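#' Split a super-scaffold into gap-free contigs
#'
#' Maximal runs without `-` become contigs; runs shorter than
#' `min_contig_len` are discarded. Masked positions (`N`) are kept.
#'
#' @param superscaffold A `superscaffold` object or a plain character
#'   sequence over `{A,C,G,T,N,-}`.
#' @param min_contig_len Minimum retained run length (default 100).
#' @param id_prefix Prefix for contig ids (default the genome id, or
#'   `"contig"`).
#' @return Contig tibble: `id`, `seq`, `origin`.
#' @export
split_on_gaps <- function(superscaffold, min_contig_len = 100L,
                          id_prefix = NULL) {
  if (inherits(superscaffold, "superscaffold")) {
    s <- superscaffold$seq
    if (is.null(id_prefix)) id_prefix <- superscaffold$genome_id
  } else {
    s <- superscaffold
    if (is.null(id_prefix)) id_prefix <- "contig"
  }
  runs <- gregexpr("[^-]+", s)[[1]]
  if (runs[1] == -1) {
    return(tibble::tibble(id = character(), seq = character(),
                          origin = character()))
  }
  len <- attr(runs, "match.length")
  keep <- len >= min_contig_len
  starts <- as.integer(runs)[keep]
  len <- len[keep]
  tibble::tibble(
    id = paste0(id_prefix, ":", seq_along(starts)),
    seq = substring(s, starts, starts + len - 1L),
    origin = "mapping"
  )
}

#' Find end overlaps between contigs
#'
#' K-mer anchored, ungapped-extended dovetail overlaps: a suffix of one
#' contig against a prefix of another (containments count as overlaps of
#' the contained length), in either orientation. Self-overlaps are
#' excluded; a contig whose own suffix matches its own prefix — the
#' signature of a circular genome — is detected and reported through the
#' `circular` attribute but never joined: the merge engine assumes a linear
#' genome.
#'
#' @param contigs Contig tibble (`id`, `seq`).
#' @param k Anchor k-mer size (default 31).
#' @param min_overlap Minimum overlap length (default 100).
#' @param min_identity Minimum overlap identity (default 0.98).
#' @return Overlap tibble: `a_id`, `b_id`, `a_start`, `a_end`, `b_start`,
#'   `b_end`, `orientation` (`same`/`reverse`; `b` coordinates are in the
#'   reverse-complement frame for `reverse`), `identity`, `length`; sorted
#'   by length then identity descending. Attribute `circular`: ids of
#'   contigs with a self end-overlap.
#' @export
find_overlaps <- function(contigs, k = 31L, min_overlap = 100L,
                          min_identity = 0.98) {
  n <- nrow(contigs)
  empty <- tibble::tibble(a_id = character(), b_id = character(),
                          a_start = integer(), a_end = integer(),
                          b_start = integer(), b_end = integer(),
                          orientation = character(), identity = numeric(),
                          length = integer())
  circular <- character(0)
  if (n == 0) return(structure(empty, circular = circular))

  # self end-overlap (circularity) detection
  for (i in seq_len(n)) {
    ov <- best_diagonal_overlap(contigs$seq[i], contigs$seq[i], k,
                                min_overlap, min_identity,
                                exclude_shift0 = TRUE)
    if (!is.null(ov)) circular <- c(circular, contigs$id[i])
  }
  if (n < 2) return(structure(empty, circular = circular))

  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1L, n)) {
      a <- contigs$seq[i]
      for (orient in c("same", "reverse")) {
        b <- if (orient == "same") contigs$seq[j] else revcomp(contigs$seq[j])
        ov <- best_diagonal_overlap(a, b, k, min_overlap, min_identity)
        if (is.null(ov)) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          a_id = contigs$id[i], b_id = contigs$id[j],
          a_start = ov$a_start, a_end = ov$a_end,
          b_start = ov$b_start, b_end = ov$b_end,
          orientation = orient, identity = ov$identity,
          length = ov$length
        )
        break  # one orientation per pair: take the first that qualifies
      }
    }
  }
  out <- if (length(rows) == 0) empty else dplyr::bind_rows(rows)
  out <- out[order(-out$length, -out$identity, out$a_id, out$b_id), ,
             drop = FALSE]
  structure(out, circular = unique(circular))
}

# Best qualifying ungapped dovetail window between two sequences, anchored
# on shared k-mers. Returns NULL or list(a_start, a_end, b_start, b_end,
# identity, length).
best_diagonal_overlap <- function(a, b, k, min_overlap, min_identity,
                                  exclude_shift0 = FALSE) {
  la <- nchar(a); lb <- nchar(b)
  if (la < k || lb < k) return(NULL)
  ka <- kmers_of(a, k); kb <- kmers_of(b, k)
  hit <- match(ka, kb)
  ia <- which(!is.na(hit))
  if (length(ia) == 0) return(NULL)
  shifts <- unique(ia - hit[ia])  # a position i aligns b position i - t
  if (exclude_shift0) shifts <- setdiff(shifts, 0L)
  ar <- charToRaw(a); br <- charToRaw(b)
  best <- NULL
  for (t in shifts) {
    a_from <- max(1L, t + 1L); a_to <- min(la, t + lb)
    len <- a_to - a_from + 1L
    if (len < min_overlap) next
    seg_a <- ar[a_from:a_to]
    seg_b <- br[(a_from - t):(a_to - t)]
    ident <- sum(seg_a == seg_b) / len
    if (ident < min_identity) next
    cand <- list(a_start = a_from, a_end = a_to,
                 b_start = a_from - t, b_end = a_to - t,
                 identity = ident, length = len)
    if (is.null(best) || cand$length > best$length ||
        (cand$length == best$length && cand$identity > best$identity)) {
      best <- cand
    }
  }
  best
}

#' Merge two contigs across an accepted overlap
#'
#' The merged sequence is the union of `a` and `b` laid on a common
#' coordinate frame; positions where the two disagree inside the overlap
#' are masked `N`. Merged length is `len(a) + len(b) - overlap$length` for
#' dovetails. For `reverse` orientation `b` is reverse-complemented first.
#'
#' @param a,b One-row contig tibbles (or lists with `id`, `seq`).
#' @param overlap One row of [find_overlaps()] output for this pair.
#' @return One-row contig tibble, `origin = "merged"`.
#' @export
merge_pair <- function(a, b, overlap) {
  b_seq <- if (overlap$orientation == "reverse") revcomp(b$seq) else b$seq
  la <- nchar(a$seq); lb <- nchar(b_seq)
  t <- overlap$a_start - overlap$b_start
  if (overlap$a_end - t != overlap$b_end) {
    stop("overlap coordinates are not a single diagonal", call. = FALSE)
  }
  lo <- min(1L, t + 1L); hi <- max(la, t + lb)
  L <- hi - lo + 1L
  off_a <- 1L - lo          # merged index of a position p: p + off_a
  off_b <- t + 1L - lo      # merged index of b position p: p + t + off_a
  out <- rep(NA_character_, L)
  ach <- s_chars(a$seq); bch <- s_chars(b_seq)
  out[seq_len(la) + off_a] <- ach
  bi <- seq_len(lb) + off_b
  conflict <- !is.na(out[bi]) & out[bi] != bch
  fill <- is.na(out[bi])
  out[bi[fill]] <- bch[fill]
  out[bi[conflict]] <- "N"
  tibble::tibble(id = paste0(a$id, "+", b$id),
                 seq = paste0(out, collapse = ""),
                 origin = "merged")
}

#' Map reads onto contigs with an exact-seed, ungapped-extension mapper
#'
#' Desk-scale internal mapper used by [improve()] and [abundance()]: seeds
#' at several read offsets are matched exactly against an index of contig
#' k-mers, candidate diagonals are scored by ungapped comparison over the
#' full read span (clipped at contig ends), both orientations are tried,
#' and the best placement per read is kept. For real-scale data an external
#' SAM can be supplied to the callers instead.
#'
#' @param reads Read tibble (`id`, `seq`).
#' @param contigs Contig tibble (`id`, `seq`).
#' @param k Seed size (default 31).
#' @param seed_step Spacing between seed offsets within a read (default 40).
#' @param min_identity Minimum identity over the aligned span (default 0.8).
#' @param min_len Minimum aligned span (default `k`).
#' @return Placement tibble: `read_id`, `ref_id`, `ref_start`, `bases`
#'   (aligned, possibly clipped, oriented to the contig), `matches`,
#'   `aligned_len`, `score`.
#' @export
map_reads <- function(reads, contigs, k = 31L, seed_step = 40L,
                      min_identity = 0.8, min_len = k) {
  empty <- tibble::tibble(read_id = character(), ref_id = character(),
                          ref_start = integer(), bases = character(),
                          matches = integer(), aligned_len = integer(),
                          score = numeric())
  if (nrow(reads) == 0 || nrow(contigs) == 0) return(empty)

  idx_kmer <- character(0); idx_cid <- integer(0); idx_pos <- integer(0)
  for (ci in seq_len(nrow(contigs))) {
    km <- kmers_of(contigs$seq[ci], k)
    idx_kmer <- c(idx_kmer, km)
    idx_cid <- c(idx_cid, rep.int(ci, length(km)))
    idx_pos <- c(idx_pos, seq_along(km))
  }
  if (length(idx_kmer) == 0) return(empty)
  km_groups <- list2env(split(seq_along(idx_kmer), idx_kmer),
                        hash = TRUE, parent = emptyenv())

  contig_raw <- lapply(contigs$seq, charToRaw)
  contig_len <- nchar(contigs$seq)
  rows <- vector("list", nrow(reads))

  for (ri in seq_len(nrow(reads))) {
    s_fwd <- reads$seq[ri]
    lr <- nchar(s_fwd)
    if (lr < k) next
    best <- NULL
    for (orient in c("+", "-")) {
      s <- if (orient == "+") s_fwd else revcomp(s_fwd)
      offs <- unique(c(seq.int(1L, lr - k + 1L, by = seed_step), lr - k + 1L))
      seeds <- substring(s, offs, offs + k - 1L)
      cand <- unique(do.call(rbind, lapply(seq_along(seeds), function(si) {
        g <- get0(seeds[si], envir = km_groups, inherits = FALSE)
        if (is.null(g)) return(NULL)
        cbind(cid = idx_cid[g], start = idx_pos[g] - offs[si] + 1L)
      })))
      if (is.null(cand) || nrow(cand) == 0) next
      rr <- charToRaw(s)
      for (ci in seq_len(nrow(cand))) {
        cid <- cand[ci, "cid"]; st <- cand[ci, "start"]
        q_from <- max(1L, 2L - st)
        q_to <- min(lr, contig_len[cid] - st + 1L)
        len <- q_to - q_from + 1L
        if (len < min_len) next
        ref_from <- st + q_from - 1L
        m <- sum(rr[q_from:q_to] ==
                   contig_raw[[cid]][ref_from:(ref_from + len - 1L)])
        if (m / len < min_identity) next
        score <- 2 * m - len  # matches - mismatches
        cand_row <- list(cid = cid, ref_start = ref_from,
                         bases = substr(s, q_from, q_to),
                         matches = m, len = len, score = score)
        if (is.null(best) || score > best$score ||
            (score == best$score &&
               (contig_len[cid] > contig_len[best$cid] ||
                  (contig_len[cid] == contig_len[best$cid] &&
                     contigs$id[cid] < contigs$id[best$cid])))) {
          best <- cand_row
        }
      }
    }
    if (!is.null(best)) {
      rows[[ri]] <- tibble::tibble(
        read_id = reads$id[ri], ref_id = contigs$id[best$cid],
        ref_start = best$ref_start, bases = best$bases,
        matches = best$matches, aligned_len = best$len, score = best$score
      )
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) empty else dplyr::bind_rows(rows)
}

#' Iterative contig improvement
#'
#' Runs the merge / map / pile-up / reassemble cycle until the contig set
#' converges (same sequences) or `max_rounds` is reached. Merging is greedy,
#' largest overlap first, each contig joining at most once per round.
#' Reassembly is a pileup polish: the consensus over mapped reads replaces
#' each contig, positions without read coverage keeping their prior call.
#' After each round contigs are deduplicated and canonically reordered
#' (length descending, then sequence), so the result is independent of the
#' input order. Reads should be the dereplicated, non-normalized set.
#'
#' @param contigs Contig tibble (`id`, `seq`, optionally `origin`).
#' @param reads Read tibble.
#' @param max_rounds Round cap (default 10); non-convergence at the cap
#'   returns the current set with a warning.
#' @param placements Optional externally computed placements (e.g. from
#'   [read_sam_placements()]) used for the first reassembly instead of the
#'   internal mapper.
#' @param k,min_overlap,min_identity Overlap acceptance parameters, see
#'   [find_overlaps()].
#' @return Contig tibble in canonical order, ids `contig_1..n`. Attribute
#'   `rounds`: number of completed rounds; attribute `circular`: contig ids
#'   with detected (never joined) circular self-overlaps.
#' @export
improve <- function(contigs, reads, max_rounds = 10L, placements = NULL,
                    k = 31L, min_overlap = 100L, min_identity = 0.98) {
  canonical <- function(ct) {
    ct <- ct[!duplicated(ct$seq), , drop = FALSE]
    ct <- ct[order(-nchar(ct$seq), ct$seq), , drop = FALSE]
    ct$id <- paste0("contig_", seq_len(nrow(ct)))
    ct
  }
  contigs <- canonical(contigs)
  circular_seen <- character(0)
  rounds <- 0L
  repeat {
    if (rounds >= max_rounds) {
      warning("contigs did not converge within ", max_rounds, " rounds",
              call. = FALSE)
      break
    }
    prev <- sort(contigs$seq)
    ovl <- find_overlaps(contigs, k = k, min_overlap = min_overlap,
                         min_identity = min_identity)
    circular_seen <- union(circular_seen, attr(ovl, "circular"))
    consumed <- character(0)
    merged <- list()
    for (oi in seq_len(nrow(ovl))) {
      o <- ovl[oi, ]
      if (o$a_id %in% consumed || o$b_id %in% consumed) next
      a <- contigs[contigs$id == o$a_id, ]
      b <- contigs[contigs$id == o$b_id, ]
      merged[[length(merged) + 1L]] <- merge_pair(a, b, o)
      consumed <- c(consumed, o$a_id, o$b_id)
    }
    keep <- contigs[!contigs$id %in% consumed, , drop = FALSE]
    contigs <- canonical(dplyr::bind_rows(c(list(keep), merged)))

    pl <- if (rounds == 0L && !is.null(placements)) placements
          else map_reads(reads, contigs, k = k)
    contigs$seq <- vapply(seq_len(nrow(contigs)), function(ci) {
      sub <- pl[pl$ref_id == contigs$id[ci], , drop = FALSE]
      if (nrow(sub) == 0) return(contigs$seq[ci])
      p <- pileup_assemble(contigs$id[ci], nchar(contigs$seq[ci]), sub)
      cons <- s_chars(p$consensus)
      old <- s_chars(contigs$seq[ci])
      cons[cons == "-"] <- old[cons == "-"]
      paste0(cons, collapse = "")
    }, "")
    contigs <- canonical(contigs)
    rounds <- rounds + 1L
    if (identical(sort(contigs$seq), prev)) break
  }
  structure(contigs, rounds = rounds, circular = circular_seen)
}

#' Per-contig read abundance
#'
#' Maps the dereplicated reads to the final contigs, assigns each read once
#' to its best-scoring contig (ties: longer contig, then lexicographically
#' smaller id — resolved inside the mapper), and re-expands dereplication
#' multiplicities.
#'
#' @param contigs Final contig tibble.
#' @param reads Dereplicated read tibble.
#' @param multiplicity Named integer vector from [dereplicate()] (default:
#'   every read counts once).
#' @return Tibble: `contig_id`, `reads` (multiplicity-expanded count),
#'   `mean_depth`.
#' @export
abundance <- function(contigs, reads, multiplicity = NULL) {
  if (is.null(multiplicity)) {
    multiplicity <- stats::setNames(rep(1L, nrow(reads)), reads$id)
  }
  pl <- map_reads(reads, contigs)
  if (nrow(pl) == 0) {
    return(tibble::tibble(contig_id = contigs$id, reads = 0L,
                          mean_depth = 0))
  }
  pl$mult <- as.integer(multiplicity[pl$read_id])
  per <- pl |>
    dplyr::group_by(contig_id = .data$ref_id) |>
    dplyr::summarise(reads = sum(.data$mult),
                     bases = sum(as.numeric(.data$aligned_len) * .data$mult),
                     .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(contig_id = contigs$id,
                                         len = nchar(contigs$seq)),
                          per, by = "contig_id")
  out$reads[is.na(out$reads)] <- 0L
  out$bases[is.na(out$bases)] <- 0
  tibble::tibble(contig_id = out$contig_id, reads = out$reads,
                 mean_depth = out$bases / out$len)
}
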