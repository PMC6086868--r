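#' Simulation configuration for a synthetic test world
#'
#' Describes a mock community: several viruses, each a diverged copy of a
#' database reference genome, sequenced with substitution errors against a
#' non-viral host background. Defaults emulate a small purified mock
#' community: four viruses spanning 5-15% divergence from their nearest
#' database entry, 20x coverage, 1% per-base error, 30% host reads.
#'
#' @param seed Integer seed; all randomness in [make_world()] flows from it.
#' @param n_viruses Number of planted viruses.
#' @param genome_len Length range (min, max) of viral reference genomes.
#' @param divergence Substitution fraction between each sample virus and its
#'   reference: a single value, a (min, max) range spread evenly across
#'   viruses, or one value per virus. Must be in `[0, 0.5)`.
#' @param read_len Read length.
#' @param coverage Per-virus fold coverage (single value or per virus).
#' @param error_rate Per-base substitution error rate in `[0, 0.1]`.
#' @param host_fraction Fraction of reads drawn from the host genome.
#' @param host_genome_len Host genome length.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_viruses = 4L,
                       genome_len = c(2000L, 3000L),
                       divergence = c(0.05, 0.15),
                       read_len = 150L, coverage = 20,
                       error_rate = 0.01, host_fraction = 0.3,
                       host_genome_len = 10000L) {
  stopifnot(all(divergence >= 0), all(divergence < 0.5),
            all(coverage > 0), error_rate >= 0, error_rate <= 0.1,
            host_fraction >= 0, host_fraction < 1)
  div <- if (length(divergence) == n_viruses) divergence
         else if (length(divergence) == 2 && n_viruses > 1)
           seq(divergence[1], divergence[2], length.out = n_viruses)
         else rep(divergence[1], n_viruses)
  cov <- if (length(coverage) == n_viruses) coverage
         else rep(coverage[1], n_viruses)
  structure(
    list(seed = as.integer(seed), n_viruses = as.integer(n_viruses),
         genome_len = as.integer(genome_len), divergence = div,
         read_len = as.integer(read_len), coverage = cov,
         error_rate = error_rate, host_fraction = host_fraction,
         host_genome_len = as.integer(host_genome_len)),
    class = "sim_config"
  )
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- s_chars(s)
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste0(ch, collapse = "")
}

#' Generate a complete synthetic test world
#'
#' Builds an internally consistent world from one seed: a mini taxonomy
#' (viral superkingdom with families, genera and species, an unranked
#' intermediate clade, and a non-viral host lineage), viral reference
#' genomes with plus- and minus-strand CDS annotations and their protein
#' translations, diverged sample viruses, error-bearing reads from sample
#' viruses and host, and a truth table. Deterministic for a fixed seed. The
#' RNG state is set from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the world is written out
#'   as `nodes.dmp`, `names.dmp`, `refs.fasta`, `proteins.fasta`,
#'   `cds.tsv`, `reads.fastq`, `truth_reads.tsv`, `truth_viruses.fasta`.
#' @return A `synth_world` list: `taxonomy`, `refs` (tibble id, seq,
#'   taxid), `proteins` (tibble id, seq, taxid, genome_id), `cds`,
#'   `reads`, `truth` (list: `reads`, `viruses`, `taxa`), `entry2genome`,
#'   `config`.
#' @export
make_world <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$seed)
  n <- config$n_viruses

  # taxonomy: root(1) > superkingdoms Viruses(10239)/Bacteria(2);
  # 20000 is an unranked clade under Viruses (rank-walk transparency);
  # families 30001.., genera 40001.., species 50001.. ; host species 60002.
  n_fam <- ceiling(n / 2)
  fam_of <- ceiling(seq_len(n) / 2)
  taxid <- c(1L, 10239L, 2L, 20000L,
             30000L + seq_len(n_fam),
             40000L + seq_len(n), 50000L + seq_len(n),
             60001L, 60002L)
  parent <- c(1L, 1L, 1L, 10239L,
              rep(20000L, n_fam),
              30000L + fam_of, 40000L + seq_len(n),
              2L, 60001L)
  rank <- c("no rank", "superkingdom", "superkingdom", "no rank",
            rep("family", n_fam), rep("genus", n), rep("species", n),
            "genus", "species")
  name <- c("root", "Viruses", "Bacteria", "Synthovirae",
            paste0("Synthoviridae_", seq_len(n_fam)),
            paste0("Synthovirus_g", seq_len(n)),
            paste0("synthetic virus ", seq_len(n)),
            "Synthobacter", "Synthobacter host")
  tree <- new_taxonomy(taxid, parent, rank, name)
  virus_taxids <- 50000L + seq_len(n)

  glen <- sample(seq(config$genome_len[1], config$genome_len[2]), n,
                 replace = TRUE)
  refs <- tibble::tibble(
    id = paste0("refv", seq_len(n)),
    seq = vapply(glen, random_dna, ""),
    taxid = virus_taxids
  )
  host <- tibble::tibble(id = "host1",
                         seq = random_dna(config$host_genome_len),
                         taxid = 60002L)

  # two CDS per genome: one plus-strand, one minus-strand, in frame
  cds <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    L <- glen[i]
    s1 <- round(0.08 * L); l1 <- (round(0.30 * L) %/% 3L) * 3L
    s2 <- round(0.55 * L); l2 <- (round(0.20 * L) %/% 3L) * 3L
    tibble::tibble(
      protein_id = paste0(refs$id[i], "_p", 1:2),
      genome_id = refs$id[i],
      g_start = c(s1, s2),
      g_end = c(s1 + l1 - 1L, s2 + l2 - 1L),
      strand = c("+", "-")
    )
  }))
  proteins <- dplyr::bind_rows(lapply(seq_len(nrow(cds)), function(j) {
    g <- refs$seq[refs$id == cds$genome_id[j]]
    segment <- substr(g, cds$g_start[j], cds$g_end[j])
    if (cds$strand[j] == "-") segment <- revcomp(segment)
    tibble::tibble(id = cds$protein_id[j], seq = translate_nt(segment),
                   taxid = refs$taxid[refs$id == cds$genome_id[j]],
                   genome_id = cds$genome_id[j])
  }))

  sample_seq <- vapply(seq_len(n), function(i)
    mutate_seq(refs$seq[i], config$divergence[i]), "")

  # reads: expected viral read count from coverage, host share on top
  w <- config$coverage * glen
  n_viral_nominal <- sum(w) / config$read_len
  n_reads <- max(1L, round(n_viral_nominal / (1 - config$host_fraction)))
  is_host <- stats::runif(n_reads) < config$host_fraction
  src <- integer(n_reads)           # 0 = host, i = virus i
  src[!is_host] <- sample.int(n, sum(!is_host), replace = TRUE,
                              prob = w / sum(w))
  rl <- config$read_len
  tmpl <- ifelse(src == 0L, host$seq, sample_seq[pmax(src, 1L)])
  start <- floor(stats::runif(n_reads) * (nchar(tmpl) - rl + 1)) + 1L
  read_seq <- substring(tmpl, start, start + rl - 1L)
  flip <- stats::runif(n_reads) < 0.5
  if (any(flip)) read_seq[flip] <- revcomp(read_seq[flip])
  if (config$error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    m <- matrix(unlist(strsplit(read_seq, "", fixed = TRUE)), nrow = rl)
    hit <- which(stats::runif(length(m)) < config$error_rate)
    if (length(hit) > 0) {
      cur <- match(m[hit], bases)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      m[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
    read_seq <- apply(m, 2, paste0, collapse = "")
  }
  reads <- tibble::tibble(
    id = sprintf("read%06d", seq_len(n_reads)),
    seq = read_seq,
    qual = strrep("I", rl)
  )
  truth <- list(
    reads = tibble::tibble(
      read_id = reads$id,
      source = ifelse(src == 0L, "host1", paste0("virus", src)),
      taxid = ifelse(src == 0L, 60002L, 50000L + src)
    ),
    viruses = tibble::tibble(
      virus_id = paste0("virus", seq_len(n)),
      ref_id = refs$id, taxid = virus_taxids,
      divergence = config$divergence,
      seq_true = sample_seq
    ),
    taxa = virus_taxids
  )
  e2g <- stats::setNames(c(refs$id, host$id, proteins$genome_id),
                         c(refs$id, host$id, proteins$id))
  world <- structure(
    list(taxonomy = tree, refs = refs, host = host, proteins = proteins,
         cds = cds, reads = reads, truth = truth, entry2genome = e2g,
         config = config),
    class = "synth_world"
  )
  if (!is.null(out_dir)) write_world(world, out_dir)
  world
}

#' @export
print.synth_world <- function(x, ...) {
  cat("<synth_world> ", nrow(x$refs), " viruses (",
      paste(round(100 * x$config$divergence, 1), collapse = "/"),
      "% divergence), ", nrow(x$reads), " reads, host fraction ",
      x$config$host_fraction, "\n", sep = "")
  invisible(x)
}

write_world <- function(world, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- world$taxonomy$nodes
  writeLines(paste0(nodes$taxid, "\t|\t", nodes$parent, "\t|\t", nodes$rank,
                    "\t|"),
             file.path(out_dir, "nodes.dmp"))
  writeLines(paste0(nodes$taxid, "\t|\t", nodes$name,
                    "\t|\t\t|\tscientific name\t|"),
             file.path(out_dir, "names.dmp"))
  write_fasta(dplyr::bind_rows(world$refs[, c("id", "seq")],
                               world$host[, c("id", "seq")]),
              file.path(out_dir, "refs.fasta"))
  write_fasta(world$proteins[, c("id", "seq")],
              file.path(out_dir, "proteins.fasta"))
  write_cds_table(world$cds, file.path(out_dir, "cds.tsv"))
  write_fastq(world$reads, file.path(out_dir, "reads.fastq"))
  readr::write_tsv(world$truth$reads, file.path(out_dir, "truth_reads.tsv"))
  write_fasta(tibble::tibble(id = world$truth$viruses$virus_id,
                             seq = world$truth$viruses$seq_true),
              file.path(out_dir, "truth_viruses.fasta"))
  invisible(out_dir)
}

# --- stand-in local aligner -------------------------------------------------

# nt scoring: match +1, mismatch -1; lambda fixed so a perfect alignment
# scores exactly 2 bits/base: bits = lambda * score / ln 2, lambda = 2 ln 2.
NT_BITS_PER_SCORE <- 2
# aa scoring: BLOSUM62 with the standard gapless lambda.
AA_LAMBDA <- 0.267

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Align two sequences with the stand-in exhaustive-seed aligner
#'
#' Ungapped local alignment used wherever an external aligner's tabular
#' output would normally be consumed: shared k-mer seeds propose diagonals,
#' every proposed diagonal is scored per position (nt: match +1 /
#' mismatch -1; aa: BLOSUM62) and its maximal-scoring segment located. The
#' best segment over all diagonals and orientations is reported. Bit
#' scores are `lambda * score / ln 2` with a fixed nucleotide `lambda`
#' chosen so a perfect nucleotide alignment yields exactly 2 bits per
#' base; they are strictly decreasing in the number of mismatches at fixed
#' length. For `kind = "aa"` the query is nucleotide, searched in all six
#' frames against a protein subject, and query coordinates are reported in
#' nucleotide space.
#'
#' @param query,subject Sequences (query always nucleotide; subject
#'   nucleotide for `"nt"`, amino acid for `"aa"`).
#' @param kind `"nt"` or `"aa"`.
#' @param query_id,subject_id,subject_taxid Identifiers for the emitted
#'   record.
#' @param min_bits Minimum bit score to report (default 30).
#' @return Alignment tibble with 0 or 1 row (layout of
#'   [read_alignments()]).
#' @export
score_alignment <- function(query, subject, kind = c("nt", "aa"),
                            query_id = "q", subject_id = "s",
                            subject_taxid = 1L, min_bits = 30) {
  kind <- match.arg(kind)
  qt <- tibble::tibble(id = query_id, seq = query)
  st <- tibble::tibble(id = subject_id, seq = subject,
                       taxid = as.integer(subject_taxid))
  recs <- align_all(qt, st, kind = kind, min_bits = min_bits)
  if (nrow(recs) > 1) recs <- recs[which.max(recs$bits), , drop = FALSE]
  recs
}

#' Align many queries against a subject database
#'
#' Batch form of [score_alignment()]: one best local alignment per
#' (query, subject) pair sharing at least one seed. This is the package's
#' internal stand-in for an external aligner's tabular output; it trades
#' sensitivity for simplicity and is adequate for desk-scale worlds.
#'
#' @param queries Tibble `id`, `seq` (nucleotide).
#' @param subjects Tibble `id`, `seq`, `taxid` (nucleotide for `"nt"`,
#'   protein for `"aa"`).
#' @param kind `"nt"` or `"aa"`.
#' @param min_bits Minimum bit score to report.
#' @param k_nt,k_aa Seed sizes.
#' @param seed_step Query seed spacing (nt space).
#' @return Alignment tibble (layout of [read_alignments()]).
#' @export
align_all <- function(queries, subjects, kind = c("nt", "aa"),
                      min_bits = 30, k_nt = 11L, k_aa = 4L,
                      seed_step = 8L) {
  kind <- match.arg(kind)
  if (kind == "nt") {
    align_all_nt(queries, subjects, min_bits, k_nt, seed_step)
  } else {
    align_all_aa(queries, subjects, min_bits, k_aa,
                 max(1L, seed_step %/% 3L))
  }
}

# shared: hashed index of subject k-mers -> matrix(sid, pos)
build_seed_index <- function(seqs, k) {
  sid <- integer(0); pos <- integer(0); km <- character(0)
  for (i in seq_along(seqs)) {
    x <- kmers_of(seqs[i], k)
    km <- c(km, x); sid <- c(sid, rep.int(i, length(x)))
    pos <- c(pos, seq_along(x))
  }
  if (length(km) == 0) return(new.env(hash = TRUE, parent = emptyenv()))
  list2env(lapply(split(seq_along(km), km),
                  function(ix) cbind(sid = sid[ix], pos = pos[ix])),
           hash = TRUE, parent = emptyenv())
}

align_all_nt <- function(queries, subjects, min_bits, k, seed_step) {
  out <- list()
  idx <- build_seed_index(subjects$seq, k)
  s_raw <- lapply(subjects$seq, charToRaw)
  s_len <- nchar(subjects$seq)
  if (nrow(queries) == 0) return(empty_alignments())
  q_rc <- revcomp(queries$seq)
  for (qi in seq_len(nrow(queries))) {
    lq <- nchar(queries$seq[qi])
    if (lq < k) next
    best_by_subject <- list()
    for (orient in c("+", "-")) {
      s <- if (orient == "+") queries$seq[qi] else q_rc[qi]
      offs <- unique(c(seq.int(1L, lq - k + 1L, by = seed_step), lq - k + 1L))
      seeds <- substring(s, offs, offs + k - 1L)
      cand <- list()
      for (si in seq_along(seeds)) {
        hits <- get0(seeds[si], envir = idx, inherits = FALSE)
        if (is.null(hits)) next
        cand[[length(cand) + 1L]] <-
          cbind(sid = hits[, "sid"], diag = hits[, "pos"] - offs[si])
      }
      if (length(cand) == 0) next
      cand <- unique(do.call(rbind, cand))
      q_raw <- charToRaw(s)
      for (ci in seq_len(nrow(cand))) {
        sid <- cand[ci, "sid"]; dg <- cand[ci, "diag"]
        q_from <- max(1L, 1L - dg)
        q_to <- min(lq, s_len[sid] - dg)
        if (q_to - q_from + 1L < k) next
        qs <- q_raw[q_from:q_to]
        ss <- s_raw[[sid]][(q_from + dg):(q_to + dg)]
        scores <- ifelse(qs == ss, 1, -1)
        seg <- max_segment(scores)
        bits <- NT_BITS_PER_SCORE * seg$score
        if (bits < min_bits) next
        a_from <- q_from + seg$start - 1L
        a_to <- q_from + seg$end - 1L
        len <- a_to - a_from + 1L
        ident <- sum(qs[seg$start:seg$end] == ss[seg$start:seg$end]) / len
        # coordinates on the forward strand of the query
        if (orient == "+") { fq1 <- a_from; fq2 <- a_to }
        else { fq1 <- lq - a_to + 1L; fq2 <- lq - a_from + 1L }
        rec <- tibble::tibble(
          query_id = queries$id[qi], subject_id = subjects$id[sid],
          subject_taxid = subjects$taxid[sid], kind = "nt",
          identity = ident, q_start = fq1, q_end = fq2,
          s_start = a_from + dg, s_end = a_to + dg,
          strand = orient, bits = bits, aligned_len_q = len
        )
        key <- as.character(sid)
        if (is.null(best_by_subject[[key]]) ||
            bits > best_by_subject[[key]]$bits) {
          best_by_subject[[key]] <- rec
        }
      }
    }
    out <- c(out, unname(best_by_subject))
  }
  if (length(out) == 0) empty_alignments() else dplyr::bind_rows(out)
}

align_all_aa <- function(queries, subjects, min_bits, k, seed_step) {
  B <- blosum62()
  out <- list()
  idx <- build_seed_index(subjects$seq, k)
  s_chr <- lapply(subjects$seq, s_chars)
  s_len <- nchar(subjects$seq)
  if (nrow(queries) == 0) return(empty_alignments("aa"))
  # six-frame translations, batched (one translate call per orientation/frame)
  q_len <- nchar(queries$seq)
  frames <- list(`+` = vector("list", 3), `-` = vector("list", 3))
  q_rc <- revcomp(queries$seq)
  for (frame in 0:2) {
    frames[["+"]][[frame + 1L]] <- translate_nt(substring(queries$seq,
                                                          frame + 1L))
    frames[["-"]][[frame + 1L]] <- translate_nt(substring(q_rc, frame + 1L))
  }
  for (qi in seq_len(nrow(queries))) {
    lq <- q_len[qi]
    best_by_subject <- list()
    for (orient in c("+", "-")) {
      for (frame in 0:2) {
        aa <- frames[[orient]][[frame + 1L]][qi]
        la <- nchar(aa)
        if (la < k) next
        offs <- unique(c(seq.int(1L, la - k + 1L, by = seed_step), la - k + 1L))
        seeds <- substring(aa, offs, offs + k - 1L)
        cand <- list()
        for (si in seq_along(seeds)) {
          hits <- get0(seeds[si], envir = idx, inherits = FALSE)
          if (is.null(hits)) next
          cand[[length(cand) + 1L]] <-
            cbind(sid = hits[, "sid"], diag = hits[, "pos"] - offs[si])
        }
        if (length(cand) == 0) next
        cand <- unique(do.call(rbind, cand))
        q_chr <- s_chars(aa)
        for (ci in seq_len(nrow(cand))) {
          sid <- cand[ci, "sid"]; dg <- cand[ci, "diag"]
          a_from <- max(1L, 1L - dg)
          a_to <- min(la, s_len[sid] - dg)
          if (a_to - a_from + 1L < k) next
          qs <- q_chr[a_from:a_to]
          ss <- s_chr[[sid]][(a_from + dg):(a_to + dg)]
          ok <- qs %in% rownames(B) & ss %in% colnames(B)
          scores <- numeric(length(qs))
          scores[ok] <- B[cbind(qs[ok], ss[ok])]
          scores[!ok] <- -4
          seg <- max_segment(scores)
          bits <- AA_LAMBDA * seg$score / log(2)
          if (bits < min_bits) next
          i1 <- a_from + seg$start - 1L; i2 <- a_from + seg$end - 1L
          len_aa <- i2 - i1 + 1L
          ident <- sum(qs[seg$start:seg$end] == ss[seg$start:seg$end]) / len_aa
          # frame coords -> forward nucleotide coords of the query
          p1 <- frame + 3L * (i1 - 1L) + 1L
          p2 <- frame + 3L * i2
          if (orient == "+") { fq1 <- p1; fq2 <- p2 }
          else { fq1 <- lq - p2 + 1L; fq2 <- lq - p1 + 1L }
          rec <- tibble::tibble(
            query_id = queries$id[qi], subject_id = subjects$id[sid],
            subject_taxid = subjects$taxid[sid], kind = "aa",
            identity = ident, q_start = fq1, q_end = fq2,
            s_start = i1 + dg, s_end = i2 + dg,
            strand = orient, bits = bits, aligned_len_q = 3L * len_aa
          )
          key <- as.character(sid)
          if (is.null(best_by_subject[[key]]) ||
              bits > best_by_subject[[key]]$bits) {
            best_by_subject[[key]] <- rec
          }
        }
      }
    }
    out <- c(out, unname(best_by_subject))
  }
  if (length(out) == 0) empty_alignments("aa") else dplyr::bind_rows(out)
}

#' Randomly subsample reads
#'
#' Each read is kept independently with probability `fraction`;
#' deterministic for a fixed seed.
#'
#' @param reads Read tibble.
#' @param fraction Keep probability in `(0, 1]`.
#' @param seed Integer seed.
#' @return Subsampled read tibble, input order preserved.
#' @export
subsample_reads <- function(reads, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(reads)
  set.seed(seed)
  reads[stats::runif(nrow(reads)) <= fraction, , drop = FALSE]
}
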