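test_that("pileup consensus follows majority, tie and coverage rules", {
  ref_len <- 100L
  seg <- strrep("ACGTA", 10)  # 50 bases
  pl <- tibble::tibble(read_id = c("r1", "r2", "r3"),
                       ref_start = c(1L, 1L, 1L),
                       bases = rep(seg, 3))
  p <- pileup_assemble("ref", ref_len, pl)
  expect_equal(substr(p$consensus, 1, 50), seg)
  expect_equal(substr(p$consensus, 51, 100), strrep("-", 50))
  expect_equal(p$depth[1:50], rep(3L, 50))

  # majority 2A vs 1G -> A; tie 2A vs 2G -> N
  pl2 <- tibble::tibble(read_id = paste0("r", 1:4),
                        ref_start = c(1L, 1L, 1L, 2L),
                        bases = c("AA", "AG", "GG", "A"))
  p2 <- pileup_assemble("ref", 3L, pl2)
  expect_equal(substr(p2$consensus, 1, 1), "A")  # {A:2, G:1}
  expect_equal(substr(p2$consensus, 2, 2), "N")  # {A:2, G:2}
})

test_that("pileup handles deletions conservatively and validates bounds", {
  # gap wins only on strict majority over every base
  pl <- tibble::tibble(read_id = paste0("r", 1:3),
                       ref_start = 1L, bases = c("A-", "--", "A-"))
  p <- pileup_assemble("ref", 2L, pl)
  expect_equal(p$consensus, "A-")
  expect_equal(p$depth, c(3L, 3L))

  expect_error(pileup_assemble("ref", 5L,
                               tibble::tibble(read_id = "r", ref_start = 3L,
                                              bases = "ACGT")),
               "exceeds reference bounds")
})

test_that("error-free pileup reproduces the genome over covered positions", {
  set.seed(21)
  genome <- paste0(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                   collapse = "")
  starts <- seq(1, 401, by = 20)
  pl <- tibble::tibble(read_id = paste0("r", seq_along(starts)),
                       ref_start = as.integer(starts),
                       bases = substring(genome, starts, starts + 99))
  p <- pileup_assemble("g", 500L, pl)
  expect_equal(p$consensus, genome)
})

test_that("noisy pileup at depth >= 10 recovers >= 99.9% identity", {
  set.seed(22)
  genome <- paste0(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                   collapse = "")
  n_reads <- 200  # 100-base reads over 1 kb -> 20x nominal
  starts <- sample(1:901, n_reads, replace = TRUE)
  mutate1 <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste0(ch, collapse = "")
  }
  pl <- tibble::tibble(
    read_id = paste0("r", seq_len(n_reads)),
    ref_start = as.integer(starts),
    bases = vapply(starts, function(s)
      mutate1(substr(genome, s, s + 99), 0.01), "")
  )
  p <- pileup_assemble("g", 1000L, pl)
  cons <- strsplit(p$consensus, "")[[1]]
  true <- strsplit(genome, "")[[1]]
  deep <- p$depth >= 10   # the guarantee is about adequately covered bases
  expect_gt(sum(deep), 800)
  expect_gte(mean(cons[deep] == true[deep]), 0.999)
})

test_that("CDS tiling flags supported codons on both strands", {
  # protein of 100 aa fully confident on a 400-base genome, CDS 10..309 (+)
  pp <- list(ref_id = "p1", length = 100L,
             consensus = strrep("K", 100), depth = rep(5L, 100))
  cds <- tibble::tibble(protein_id = "p1", genome_id = "g1",
                        g_start = 10L, g_end = 309L, strand = "+")
  layer <- back_translate_tile(pp, cds, 400L)
  expect_true(all(layer$supported[10:309]))
  expect_false(any(layer$supported[c(1:9, 310:400)]))

  # masked amino acid 5 -> genome positions 22..24 unsupported
  cons <- strsplit(strrep("K", 100), "")[[1]]; cons[5] <- "X"
  pp$consensus <- paste0(cons, collapse = "")
  layer <- back_translate_tile(pp, cds, 400L)
  expect_false(any(layer$supported[22:24]))
  expect_true(all(layer$supported[c(10:21, 25:309)]))

  # minus strand: protein position 1 maps to g_end..g_end-2
  pp2 <- list(ref_id = "p2", length = 10L,
              consensus = paste0(c("M", rep("-", 9)), collapse = ""),
              depth = rep(1L, 10))
  cds2 <- tibble::tibble(protein_id = "p2", genome_id = "g1",
                         g_start = 101L, g_end = 130L, strand = "-")
  layer2 <- back_translate_tile(pp2, cds2, 400L)
  expect_equal(which(layer2$supported), 128:130)

  expect_error(back_translate_tile(pp, cds, 200L), "outside genome bounds")
})

test_that("superscaffold gives nucleotide calls precedence and masks aa conflicts", {
  np <- list(ref_id = "g1", length = 6L, consensus = "A--x--", depth = c(3L, 0L, 0L, 0L, 0L, 0L))
  np$consensus <- "A-----"
  mk_layer <- function(calls, depth = 2L) {
    list(protein_id = "p", supported = calls != ".",
         calls = ifelse(calls == ".", "-", calls),
         depth = ifelse(calls == ".", 0L, depth))
  }
  layer1 <- mk_layer(c("G", "C", ".", ".", "T", "."))
  layer2 <- mk_layer(c(".", "C", ".", ".", "G", "."))
  ss <- build_superscaffold(np, list(layer1, layer2))
  s <- strsplit(ss$seq, "")[[1]]
  expect_equal(s[1], "A")                  # nt beats aa disagreement
  expect_equal(ss$source[1], "nt")
  expect_equal(s[2], "C")                  # two aa layers agree
  expect_equal(ss$source[2], "aa")
  expect_equal(s[5], "N")                  # aa layers conflict -> masked
  expect_equal(s[3], "-")                  # no evidence anywhere
  expect_equal(ss$source[3], "none")
  # no base without evidence
  expect_true(all((s == "-") == (ss$source == "none")))

  bad <- mk_layer(c("G", "."))
  bad$supported <- c(TRUE, FALSE)
  bad$calls <- c("G", "-"); bad$depth <- c(1L, 0L)
  expect_error(build_superscaffold(np, list(bad)), "length mismatch")
})
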