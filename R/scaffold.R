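#' Naive pileup assembly
#'
#' Per-position majority-vote consensus over placed reads. Each placement
#' gives a reference start and an aligned base string already projected to
#' reference coordinates (insertions dropped, deletions as `-`; see
#' [read_sam_placements()]). The consensus call at a position is the strict
#' plurality base; a tie among top bases is masked (`N` for nucleotide, `X`
#' for amino-acid pileups); zero coverage is `-`. A deletion (`-`) wins a
#' position only when its count strictly exceeds every base count, keeping
#' the consensus conservative at deletion edges. `N`/`X` characters inside
#' placed reads are treated as no-calls.
#'
#' @param ref_id Reference identifier.
#' @param ref_length Reference length.
#' @param placements Tibble with `ref_start` (1-based) and `bases`.
#' @param alphabet `"nt"` or `"aa"`.
#' @return A `pileup` object: list with `ref_id`, `length`, `consensus`
#'   (single string), `depth` (integer vector), `counts` (letters x L
#'   matrix, gap row `-`).
#' @export
pileup_assemble <- function(ref_id, ref_length, placements,
                            alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  mask_char <- if (alphabet == "nt") "N" else "X"
  L <- as.integer(ref_length)
  if (nrow(placements) > 0) {
    ends <- placements$ref_start + nchar(placements$bases) - 1L
    if (any(placements$ref_start < 1L) || any(ends > L)) {
      stop("placement exceeds reference bounds on ", ref_id, call. = FALSE)
    }
    pos <- unlist(mapply(function(s, b) seq.int(s, s + nchar(b) - 1L),
                         placements$ref_start, placements$bases,
                         SIMPLIFY = FALSE), use.names = FALSE)
    ch <- unlist(strsplit(placements$bases, "", fixed = TRUE), use.names = FALSE)
    nocall <- ch == mask_char
    pos <- pos[!nocall]; ch <- ch[!nocall]
  } else {
    pos <- integer(0); ch <- character(0)
  }
  letters_seen <- sort(setdiff(unique(ch), "-"))
  if (length(letters_seen) == 0) letters_seen <- if (alphabet == "nt")
    c("A", "C", "G", "T") else "A"
  m <- vapply(letters_seen, function(l) tabulate(pos[ch == l], nbins = L),
              integer(L))
  m <- t(matrix(m, nrow = L, dimnames = list(NULL, letters_seen)))
  gap <- tabulate(pos[ch == "-"], nbins = L)
  depth <- as.integer(colSums(m) + gap)

  bmax <- Reduce(pmax, asplit(m, 1))
  nwin <- colSums(m == matrix(bmax, nrow(m), L, byrow = TRUE)) * (bmax > 0)
  win <- rownames(m)[max.col(t(m), ties.method = "first")]
  cons <- rep("-", L)
  has_base <- bmax > 0 & gap <= bmax
  cons[has_base] <- ifelse(nwin[has_base] > 1, mask_char, win[has_base])

  structure(
    list(ref_id = ref_id, length = L,
         consensus = paste0(cons, collapse = ""),
         depth = depth,
         counts = rbind(m, `-` = gap)),
    class = "pileup"
  )
}

#' @export
print.pileup <- function(x, ...) {
  cov <- sum(x$depth > 0)
  cat("<pileup> ", x$ref_id, ": ", x$length, " positions, ",
      cov, " covered (", round(100 * cov / max(1, x$length), 1), "%), ",
      "mean depth ", round(mean(x$depth), 2), "\n", sep = "")
  invisible(x)
}

#' Tile a reconstructed protein back onto its genome
#'
#' Each confidently reconstructed amino acid (consensus neither masked nor
#' uncovered) flags its three genome positions, located through the
#' annotated CDS coordinates, as supported by protein-level evidence.
#' Back-translation is degenerate, so amino acids never invent nucleotides:
#' actual base calls enter the evidence layer only where the aa-supporting
#' reads supply nucleotide-level calls (`nt_calls`), and only at supported
#' positions. Within those calls, a strict majority is required; conflicts
#' are masked `N`.
#'
#' @param protein_pileup An amino-acid [pileup_assemble()] result.
#' @param cds One-row CDS annotation (tibble or list with `protein_id`,
#'   `genome_id`, `g_start`, `g_end`, `strand`).
#' @param genome_length Length of the originating genome.
#' @param nt_calls Optional tibble of genome-space nucleotide calls from the
#'   aa-supporting reads: columns `pos`, `base`.
#' @return An aa evidence layer: list with `protein_id`, `supported`
#'   (logical, length `genome_length`), `calls` (character vector, `-` where
#'   no base call), `depth` (integer vector).
#' @export
back_translate_tile <- function(protein_pileup, cds, genome_length,
                                nt_calls = NULL) {
  L <- as.integer(genome_length)
  if (cds$g_start < 1L || cds$g_end > L) {
    stop("CDS ", cds$protein_id, " outside genome bounds", call. = FALSE)
  }
  cons <- s_chars(protein_pileup$consensus)
  confident <- which(!cons %in% c("-", "X"))
  supported <- logical(L)
  for (j in confident) {
    g <- if (cds$strand == "+") cds$g_start + 3L * (j - 1L) + 0:2
         else cds$g_end - 3L * (j - 1L) - (0:2)
    g <- g[g >= 1L & g <= L & g >= cds$g_start & g <= cds$g_end]
    supported[g] <- TRUE
  }
  calls <- rep("-", L)
  depth <- integer(L)
  if (!is.null(nt_calls) && nrow(nt_calls) > 0) {
    nt_calls <- nt_calls[supported[nt_calls$pos], , drop = FALSE]
    if (nrow(nt_calls) > 0) {
      letters_seen <- sort(unique(nt_calls$base))
      m <- vapply(letters_seen,
                  function(l) tabulate(nt_calls$pos[nt_calls$base == l], nbins = L),
                  integer(L))
      m <- t(matrix(m, nrow = L, dimnames = list(NULL, letters_seen)))
      bmax <- Reduce(pmax, asplit(m, 1))
      nwin <- colSums(m == matrix(bmax, nrow(m), L, byrow = TRUE)) * (bmax > 0)
      win <- rownames(m)[max.col(t(m), ties.method = "first")]
      has <- bmax > 0
      calls[has] <- ifelse(nwin[has] > 1, "N", win[has])
      depth <- as.integer(colSums(m))
    }
  }
  list(protein_id = cds$protein_id, supported = supported,
       calls = calls, depth = depth)
}

#' Build the per-genome nucleotide super-scaffold
#'
#' Layers the genome's own nucleotide pileup consensus with the aa evidence
#' layers produced by [back_translate_tile()]. Per position: the nucleotide
#' call (including its masks) takes precedence whenever the position has any
#' nucleotide coverage; otherwise an aa-layer base call is used, with
#' disagreements between aa layers masked `N`; positions with no evidence in
#' any layer stay `-`.
#'
#' @param genome_nt_pileup Nucleotide [pileup_assemble()] result for the
#'   genome entry.
#' @param aa_layers List of aa evidence layers (possibly empty).
#' @return A `superscaffold` object: list with `genome_id`, `seq`, `source`
#'   (per-position `"nt"`/`"aa"`/`"none"`), `support` (per-position depth).
#' @export
build_superscaffold <- function(genome_nt_pileup, aa_layers = list()) {
  L <- genome_nt_pileup$length
  for (lay in aa_layers) {
    if (length(lay$supported) != L) {
      stop("aa layer length mismatch: ", lay$protein_id, call. = FALSE)
    }
  }
  nt <- s_chars(genome_nt_pileup$consensus)
  seq <- nt
  source <- ifelse(nt != "-", "nt", "none")
  support <- ifelse(nt != "-", genome_nt_pileup$depth, 0L)

  if (length(aa_layers) > 0) {
    call_mat <- vapply(aa_layers, function(l) l$calls, character(L))
    depth_mat <- vapply(aa_layers, function(l) l$depth, integer(L))
    call_mat <- matrix(call_mat, nrow = L)
    depth_mat <- matrix(depth_mat, nrow = L)
    open <- which(nt == "-")
    for (p in open) {
      calls <- call_mat[p, ]
      calls <- calls[calls != "-"]
      if (length(calls) == 0) next
      distinct <- unique(calls)
      seq[p] <- if (length(distinct) == 1L) distinct else "N"
      source[p] <- "aa"
      support[p] <- sum(depth_mat[p, ])
    }
  }
  structure(
    list(genome_id = genome_nt_pileup$ref_id,
         seq = paste0(seq, collapse = ""),
         source = source, support = as.integer(support)),
    class = "superscaffold"
  )
}

#' @export
print.superscaffold <- function(x, ...) {
  src <- table(factor(x$source, levels = c("nt", "aa", "none")))
  cat("<superscaffold> ", x$genome_id, ": ", nchar(x$seq), " positions (nt ",
      src[["nt"]], ", aa ", src[["aa"]], ", none ", src[["none"]], ")\n",
      sep = "")
  invisible(x)
}

#' Per-position coverage plot for a super-scaffold
#'
#' @param x A `superscaffold`.
#' @return A ggplot object: support depth along the genome, colored by the
#'   evidence source of each position.
#' @export
plot_superscaffold <- function(x) {
  df <- tibble::tibble(position = seq_along(x$source),
                       support = x$support, source = x$source)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$support,
                                   fill = .data$source)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(title = x$genome_id, x = "genome position",
                  y = "read support", fill = "evidence") +
    ggplot2::theme_minimal()
}

# Genome-space nucleotide calls contributed by aa-supporting reads.
# For every translated alignment record of `protein_id`, the aligned read
# segment is decoded codon-wise through the CDS onto genome coordinates.
aa_read_nt_calls <- function(records, reads, cds) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  seq_lk <- stats::setNames(reads$seq, reads$id)
  seg <- substr(seq_lk[records$query_id], records$q_start, records$q_end)
  neg <- records$strand == "-"
  if (any(neg)) seg[neg] <- revcomp(seg[neg])
  pieces <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    n_nt <- (nchar(seg[i]) %/% 3L) * 3L
    if (n_nt == 0L) next
    ch <- s_chars(substr(seg[i], 1L, n_nt))
    # codon c of protein position j lands on the genome through the CDS
    j <- records$s_start[i] + (seq_len(n_nt) - 1L) %/% 3L
    cpos <- (seq_len(n_nt) - 1L) %% 3L
    if (cds$strand == "+") {
      g <- cds$g_start + 3L * (j - 1L) + cpos
      b <- ch
    } else {
      g <- cds$g_end - 3L * (j - 1L) - cpos
      b <- unname(comp[ch])
    }
    ok <- g >= cds$g_start & g <= cds$g_end & !is.na(b)
    pieces[[i]] <- tibble::tibble(pos = g[ok], base = b[ok])
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0) return(tibble::tibble(pos = integer(),
                                                 base = character()))
  dplyr::bind_rows(pieces)
}
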