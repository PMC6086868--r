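#' Read a FASTA file into a tibble
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning the tabular
#' representation used across the package: one row per record.
#'
#' @param path FASTA path.
#' @return Tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence ", ids[which(empty)[1]], call. = FALSE)
  }
  tibble::tibble(id = ids, seq = unname(seqs))
}

#' Write a tibble of sequences as FASTA
#'
#' @param records Tibble with columns `id`, `seq`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path.
#' @return Tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    id = sub("\\s.*$", "", names(set)),
    seq = unname(as.character(set)),
    qual = unname(as.character(S4Vectors::mcols(set)$qualities))
  )
}

#' Write a tibble of reads as FASTQ
#'
#' @param reads Tibble with `id`, `seq` and optionally `qual` (constant
#'   maximum quality is written when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    vapply(nchar(reads$seq), function(n) strrep("I", n), "")
  set <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(
    set, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual)
  )
  invisible(path)
}

#' Read tabular alignments
#'
#' Parses the 9-column, tab-separated alignment dialect used throughout the
#' pipeline (a BLAST outfmt-6-like layout extended with the subject taxid):
#' `query, subject, taxid, identity(%), q_start, q_end, s_start, s_end, bits`.
#' Lines starting with `#` are comments. Percent identity is stored as a
#' fraction. Coordinates are normalized so `q_start <= q_end`; a reversed
#' input pair is recorded as strand `-`. For translated (`kind = "aa"`)
#' records the query coordinates are in nucleotide space (translated-search
#' convention), so per-base scores from both kinds are commensurable.
#'
#' @param path TSV path.
#' @param kind `"nt"` or `"aa"`.
#' @return Tibble with columns `query_id`, `subject_id`, `subject_taxid`,
#'   `kind`, `identity`, `q_start`, `q_end`, `s_start`, `s_end`, `strand`,
#'   `bits`, `aligned_len_q`.
#' @export
read_alignments <- function(path, kind = c("nt", "aa")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_alignments(kind))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    stop("expected 9 tab-separated columns (line ", lineno[which(nf < 9)[1]], ")",
         call. = FALSE)
  }
  col <- function(i) vapply(fields, `[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      stop("non-numeric ", what, " (line ", lineno[which(is.na(v))[1]], ")",
           call. = FALSE)
    }
    v
  }
  taxid <- num(3, "taxid")
  if (any(taxid <= 0)) {
    stop("taxid must be positive (line ", lineno[which(taxid <= 0)[1]], ")",
         call. = FALSE)
  }
  qs <- num(5, "q_start"); qe <- num(6, "q_end")
  strand <- ifelse(qs <= qe, "+", "-")
  bits <- num(9, "bits")
  if (any(bits <= 0)) {
    stop("bits must be positive (line ", lineno[which(bits <= 0)[1]], ")",
         call. = FALSE)
  }
  tibble::tibble(
    query_id = col(1),
    subject_id = col(2),
    subject_taxid = as.integer(taxid),
    kind = kind,
    identity = num(4, "identity") / 100,
    q_start = as.integer(pmin(qs, qe)),
    q_end = as.integer(pmax(qs, qe)),
    s_start = as.integer(num(7, "s_start")),
    s_end = as.integer(num(8, "s_end")),
    strand = strand,
    bits = bits,
    aligned_len_q = as.integer(pmax(qs, qe) - pmin(qs, qe) + 1)
  )
}

empty_alignments <- function(kind = "nt") {
  tibble::tibble(
    query_id = character(), subject_id = character(),
    subject_taxid = integer(), kind = character(),
    identity = numeric(), q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(), strand = character(),
    bits = numeric(), aligned_len_q = integer()
  )[0, ]
}

#' Write tabular alignments
#'
#' Inverse of [read_alignments()]: writes the 9-column dialect (identity as
#' percent, coordinates re-reversed for `-` strand records so a round trip
#' is lossless).
#'
#' @param records Alignment tibble as returned by [read_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(records, path) {
  qs <- ifelse(records$strand == "-", records$q_end, records$q_start)
  qe <- ifelse(records$strand == "-", records$q_start, records$q_end)
  out <- data.frame(
    records$query_id, records$subject_id, records$subject_taxid,
    formatC(records$identity * 100, format = "f", digits = 2),
    qs, qe, records$s_start, records$s_end, records$bits
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a CDS annotation table
#'
#' Five tab-separated columns: `protein_id, genome_id, g_start, g_end,
#' strand` with 1-based inclusive genome coordinates. A CDS whose length is
#' not divisible by 3 is kept with a warning (truncated annotations occur in
#' real data); `g_start > g_end` is an error.
#'
#' @param path TSV path.
#' @return Tibble with the five columns above.
#' @export
read_cds_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(protein_id = character(), genome_id = character(),
                          g_start = integer(), g_end = integer(),
                          strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  cds <- tibble::tibble(
    protein_id = vapply(fields, `[`, "", 1),
    genome_id = vapply(fields, `[`, "", 2),
    g_start = as.integer(vapply(fields, `[`, "", 3)),
    g_end = as.integer(vapply(fields, `[`, "", 4)),
    strand = vapply(fields, `[`, "", 5)
  )
  bad <- cds$g_start > cds$g_end
  if (any(bad)) {
    stop("CDS with g_start > g_end: ", cds$protein_id[which(bad)[1]],
         call. = FALSE)
  }
  if (!all(cds$strand %in% c("+", "-"))) {
    stop("CDS strand must be '+' or '-'", call. = FALSE)
  }
  len <- cds$g_end - cds$g_start + 1L
  if (any(len %% 3L != 0L)) {
    warning("CDS length not divisible by 3: ",
            paste(cds$protein_id[len %% 3L != 0L], collapse = ", "),
            call. = FALSE)
  }
  cds
}

#' Write a CDS annotation table
#' @param cds Tibble as returned by [read_cds_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_table <- function(cds, path) {
  readr::write_tsv(cds[, c("protein_id", "genome_id", "g_start", "g_end", "strand")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read read-to-contig placements from a SAM file
#'
#' Uses Rsamtools to parse SAM (converted transiently to BAM). Only mapped,
#' primary records are returned. The aligned base string is the read
#' sequence projected to reference coordinates through the CIGAR: insertions
#' are dropped, deletions become `-`, so the result can feed
#' [pileup_assemble()] directly.
#'
#' @param path SAM path.
#' @return Placement tibble: `read_id`, `ref_id`, `ref_start` (1-based),
#'   `bases`.
#' @export
read_sam_placements <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read SAM files", call. = FALSE)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "seq", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  bases <- mapply(project_cigar, as.character(b$seq), b$cigar,
                  USE.NAMES = FALSE)
  tibble::tibble(
    read_id = b$qname,
    ref_id = as.character(b$rname),
    ref_start = b$pos,
    bases = bases
  )
}

# Project a read sequence onto reference coordinates through its CIGAR:
# M/=/X consume both, I/S consume query only (dropped), D/N consume
# reference only (emitted as '-').
project_cigar <- function(seq, cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  out <- character(0)
  qpos <- 1L
  for (tok in toks) {
    n <- as.integer(sub("[A-Z=]$", "", tok))
    op <- sub("^\\d+", "", tok)
    if (op %in% c("M", "=", "X")) {
      out <- c(out, substr(seq, qpos, qpos + n - 1L))
      qpos <- qpos + n
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + n
    } else if (op %in% c("D", "N")) {
      out <- c(out, strrep("-", n))
    }
  }
  paste0(out, collapse = "")
}
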