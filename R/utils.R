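# Internal sequence utilities shared across modules.

s_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

revcomp <- function(s) {
  # vectorized over a character vector
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

translate_nt <- function(s) {
  # translate frame-0 nucleotide strings; trailing partial codons dropped;
  # vectorized over a character vector
  n <- nchar(s) - nchar(s) %% 3L
  out <- character(length(s))
  ok <- n >= 3L
  if (any(ok)) {
    out[ok] <- suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAStringSet(substr(s[ok], 1L, n[ok])),
                            if.fuzzy.codon = "X")
    ))
  }
  out
}

# Maximal-scoring contiguous segment (Kadane with positions).
# Returns list(start, end, score); score of an empty segment is -Inf.
max_segment <- function(scores) {
  best <- -Inf; best_s <- 0L; best_e <- -1L
  cur <- 0; cur_s <- 1L
  for (i in seq_along(scores)) {
    if (cur <= 0) { cur <- scores[i]; cur_s <- i } else cur <- cur + scores[i]
    if (cur > best) { best <- cur; best_s <- cur_s; best_e <- i }
  }
  list(start = best_s, end = best_e, score = best)
}

# All k-mers of a string as a character vector (empty if too short).
kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}
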