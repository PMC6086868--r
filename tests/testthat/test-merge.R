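rand_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

test_that("gap splitting keeps only runs above the minimum length", {
  set.seed(31)
  long_run <- rand_dna(150)
  s <- paste0("ACGT", "----", long_run)
  ct <- split_on_gaps(s, min_contig_len = 100)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$seq, long_run)

  gapless <- rand_dna(200)
  ct2 <- split_on_gaps(gapless, min_contig_len = 100)
  expect_equal(ct2$seq, gapless)

  expect_equal(nrow(split_on_gaps(strrep("-", 300), 100)), 0)
})

test_that("overlap detection respects length and identity thresholds", {
  set.seed(32)
  shared <- rand_dna(150)
  a <- paste0(rand_dna(250), shared)
  b <- paste0(shared, rand_dna(150))
  contigs <- tibble::tibble(id = c("a", "b"), seq = c(a, b))
  ov <- find_overlaps(contigs)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$length, 150L)
  expect_equal(ov$identity, 1.0)
  expect_equal(ov$orientation, "same")

  # 80-base sharing: below min_overlap
  shared80 <- rand_dna(80)
  c2 <- tibble::tibble(id = c("a", "b"),
                       seq = c(paste0(rand_dna(200), shared80),
                               paste0(shared80, rand_dna(200))))
  expect_equal(nrow(find_overlaps(c2)), 0)

  # overlap at 96% identity: rejected at the default 98%
  shared_mut <- strsplit(shared, "")[[1]]
  pos <- sample(150, 6)
  for (i in pos) shared_mut[i] <- setdiff(c("A", "C", "G", "T"),
                                          shared_mut[i])[1]
  b96 <- paste0(paste0(shared_mut, collapse = ""), rand_dna(150))
  c3 <- tibble::tibble(id = c("a", "b"), seq = c(a, b96))
  expect_equal(nrow(find_overlaps(c3)), 0)
  expect_equal(nrow(find_overlaps(c3, min_identity = 0.95)), 1)
})

test_that("reverse-orientation overlaps are found and merged via revcomp", {
  set.seed(33)
  genome <- rand_dna(700)
  a <- substr(genome, 1, 400)
  b_fwd <- substr(genome, 251, 700)
  b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b_fwd)))
  contigs <- tibble::tibble(id = c("a", "b"), seq = c(a, b))
  ov <- find_overlaps(contigs)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$orientation, "reverse")
  expect_equal(ov$length, 150L)
  merged <- merge_pair(contigs[1, ], contigs[2, ], ov[1, ])
  expect_equal(merged$seq, genome)
})

test_that("merging joins across the overlap and masks disagreements", {
  set.seed(34)
  left <- rand_dna(250); shared <- rand_dna(150); right <- rand_dna(150)
  a <- paste0(left, shared)
  b <- paste0(shared, right)
  contigs <- tibble::tibble(id = c("a", "b"), seq = c(a, b))
  ov <- find_overlaps(contigs)
  merged <- merge_pair(contigs[1, ], contigs[2, ], ov[1, ])
  expect_equal(nchar(merged$seq), 400 + 300 - 150)
  expect_equal(merged$seq, paste0(left, shared, right))
  expect_equal(merged$origin, "merged")

  # one mismatch inside the overlap -> exactly one masked position
  shared_chars <- strsplit(shared, "")[[1]]
  shared_chars[75] <- setdiff(c("A", "C", "G", "T"), shared_chars[75])[1]
  b_mut <- paste0(paste0(shared_chars, collapse = ""), right)
  c2 <- tibble::tibble(id = c("a", "b"), seq = c(a, b_mut))
  ov2 <- find_overlaps(c2, min_identity = 0.99)
  merged2 <- merge_pair(c2[1, ], c2[2, ], ov2[1, ])
  chars <- strsplit(merged2$seq, "")[[1]]
  expect_equal(sum(chars == "N"), 1)
  expect_equal(which(chars == "N"), 250 + 75)
})

test_that("circular self-overlaps are detected but never joined", {
  set.seed(35)
  core <- rand_dna(500)
  circularish <- paste0(substr(core, 351, 500), core)  # ends share 150 bases
  contigs <- tibble::tibble(id = "c1", seq = circularish)
  ov <- find_overlaps(contigs)
  expect_equal(nrow(ov), 0)
  expect_equal(attr(ov, "circular"), "c1")
})

test_that("tiling fragments converge to the source genome and improve is idempotent", {
  set.seed(36)
  genome <- rand_dna(900)
  frags <- tibble::tibble(
    id = c("f1", "f2", "f3"),
    seq = c(substr(genome, 1, 400), substr(genome, 251, 650),
            substr(genome, 501, 900)),
    origin = "mapping"
  )
  starts <- seq(1, 801, by = 9)
  reads <- tibble::tibble(id = paste0("r", seq_along(starts)),
                          seq = substring(genome, starts, starts + 99))

  out <- improve(frags, reads)
  expect_equal(nrow(out), 1)
  expect_equal(out$seq, genome)

  again <- improve(out, reads)
  expect_equal(again$seq, out$seq)

  # input order never matters
  perm <- improve(frags[c(3, 1, 2), ], reads)
  expect_equal(perm$seq, out$seq)

  # no overlaps + self-consistent reads -> fixed point in one round
  lone <- tibble::tibble(id = "x", seq = genome, origin = "mapping")
  fixed <- improve(lone, reads)
  expect_equal(fixed$seq, genome)
  expect_equal(attr(fixed, "rounds"), 1L)
})

test_that("abundance assigns each read once with deterministic tie-breaks", {
  set.seed(37)
  g1 <- rand_dna(500); g2 <- rand_dna(400)
  contigs <- tibble::tibble(id = c("c1", "c2"), seq = c(g1, g2))
  starts <- seq(1, 401, by = 4)
  reads <- tibble::tibble(id = paste0("r", seq_along(starts)),
                          seq = substring(g1, starts, starts + 99))
  ab <- abundance(contigs, reads)
  expect_equal(ab$reads[ab$contig_id == "c1"], length(starts))
  expect_equal(ab$reads[ab$contig_id == "c2"], 0L)

  # a read present identically in both contigs goes to the longer one
  shared <- substr(g1, 101, 200)
  contigs2 <- tibble::tibble(id = c("c1", "c2"),
                             seq = c(g1, paste0(substr(g2, 1, 300), shared)))
  one <- tibble::tibble(id = "rx", seq = shared)
  ab2 <- abundance(contigs2, one)
  expect_equal(ab2$reads[ab2$contig_id == "c1"], 1L)

  # multiplicities re-expand
  ab3 <- abundance(contigs, reads[1, ], multiplicity = c(r1 = 7L))
  expect_equal(ab3$reads[ab3$contig_id == "c1"], 7L)

  # conservation: total assigned <= total reads
  expect_lte(sum(ab$reads), nrow(reads))
})
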