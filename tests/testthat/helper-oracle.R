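# Literal per-position brute-force implementations of the two scoring
# passes, kept deliberately naive and independent of the package's
# vectorized code paths.

aln_rec <- function(query_id = "c1", subject_id, subject_taxid, kind = "nt",
                    q_start, q_end, bits, identity = 0.9,
                    s_start = 1L, s_end = q_end - q_start + 1L,
                    strand = "+") {
  tibble::tibble(
    query_id = query_id, subject_id = subject_id,
    subject_taxid = as.integer(subject_taxid), kind = kind,
    identity = identity, q_start = as.integer(q_start),
    q_end = as.integer(q_end), s_start = as.integer(s_start),
    s_end = as.integer(s_end), strand = strand, bits = bits,
    aligned_len_q = as.integer(q_end - q_start + 1L)
  )
}

empty_aln <- function() {
  aln_rec(subject_id = "x", subject_taxid = 1, q_start = 1, q_end = 1,
          bits = 1)[0, ]
}

brute_pass1 <- function(records, L) {
  taxa <- sort(unique(records$subject_taxid))
  top <- matrix(0, nrow = length(taxa), ncol = L)
  for (i in seq_len(nrow(records))) {
    s <- records$bits[i] / (records$q_end[i] - records$q_start[i] + 1)
    t <- which(taxa == records$subject_taxid[i])
    for (p in records$q_start[i]:records$q_end[i]) {
      if (s > top[t, p]) top[t, p] <- s
    }
  }
  global_top <- numeric(L)
  for (p in seq_len(L)) global_top[p] <- max(0, top[, p])
  score <- numeric(length(taxa))
  for (t in seq_along(taxa)) score[t] <- sum(top[t, ])
  list(taxa = taxa, top = top, global_top = global_top,
       pass1_score = stats::setNames(score, taxa))
}

brute_pass2 <- function(records, L, p_nt = 3, p_aa = 27) {
  b1 <- brute_pass1(records, L)
  vol <- stats::setNames(numeric(length(b1$taxa)), b1$taxa)
  for (i in seq_len(nrow(records))) {
    s <- records$bits[i] / (records$q_end[i] - records$q_start[i] + 1)
    expo <- if (records$kind[i] == "aa") p_aa else p_nt
    contribution <- 0
    for (p in records$q_start[i]:records$q_end[i]) {
      r <- min(1, s / b1$global_top[p])
      contribution <- contribution + s * r^expo
    }
    key <- as.character(records$subject_taxid[i])
    vol[key] <- vol[key] + contribution
  }
  vol
}

random_scoring_instance <- function(n_taxa_max = 5, n_records_max = 20,
                                    L_max = 50) {
  L <- sample(10:L_max, 1)
  n_taxa <- sample(1:n_taxa_max, 1)
  n_rec <- sample(1:n_records_max, 1)
  recs <- lapply(seq_len(n_rec), function(i) {
    q1 <- sample.int(L, 1)
    q2 <- q1 + sample.int(L - q1 + 1L, 1) - 1L
    taxid <- sample(seq_len(n_taxa), 1) * 100L
    aln_rec(subject_id = paste0("e", sample(1:8, 1)),
            subject_taxid = taxid,
            kind = sample(c("nt", "aa"), 1),
            q_start = q1, q_end = q2,
            bits = round(stats::runif(1, 0.2, 3) * (q2 - q1 + 1), 3))
  })
  list(records = dplyr::bind_rows(recs), L = L)
}

# A fixed hand-built taxonomy shared by classifier tests:
# root(1) -> Viruses(10239), Bacteria(2)
# Viruses -> family 300 -> genus 310 -> species 311, 312
#                       -> genus 320 -> species 321
# Viruses -> family 400 -> genus 410 -> species 411
# Bacteria -> species 21
test_tree <- function() {
  new_taxonomy(
    taxid  = c(1, 10239, 2, 300, 310, 311, 312, 320, 321, 400, 410, 411, 21),
    parent = c(1, 1, 1, 10239, 300, 310, 310, 300, 320, 10239, 400, 410, 2),
    rank = c("no rank", "superkingdom", "superkingdom", "family", "genus",
             "species", "species", "genus", "species", "family", "genus",
             "species", "species"),
    name = c("root", "Viruses", "Bacteria", "famA", "genA1", "spA1a",
             "spA1b", "genA2", "spA2a", "famB", "genB1", "spB1a", "bact")
  )
}
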