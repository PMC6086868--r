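test_that("pass-1 profiles match hand arithmetic on the two-taxon example", {
  recs <- dplyr::bind_rows(
    aln_rec(subject_id = "eA", subject_taxid = 311, q_start = 1, q_end = 10,
            bits = 20),
    aln_rec(subject_id = "eB", subject_taxid = 312, q_start = 1, q_end = 5,
            bits = 15)
  )
  prof <- pass1(recs, L = 10)
  expect_equal(prof$global_top, c(rep(3, 5), rep(2, 5)))
  expect_equal(unname(prof$pass1_score[c("311", "312")]), c(20, 15))
})

test_that("pass-1 conserves single-record bits and takes per-position maxima", {
  one <- aln_rec(subject_id = "e1", subject_taxid = 100, q_start = 1,
                 q_end = 25, bits = 50)
  expect_equal(unname(pass1(one, 30)$pass1_score), 50)

  # overlapping records of one taxon: max per position, not sum
  two <- dplyr::bind_rows(
    aln_rec(subject_id = "e1", subject_taxid = 100, q_start = 1, q_end = 20,
            bits = 20),   # s = 1.0
    aln_rec(subject_id = "e2", subject_taxid = 100, q_start = 11, q_end = 20,
            bits = 20)    # s = 2.0 on 11..20
  )
  prof <- pass1(two, 20)
  expect_equal(unname(prof$pass1_score), 10 * 1 + 10 * 2)

  expect_error(pass1(aln_rec(subject_id = "e", subject_taxid = 1,
                             q_start = 5, q_end = 40, bits = 10), 30),
               "outside contig")
})

test_that("pass-2 volumes match hand arithmetic and the perfect-hit fixed point", {
  recs <- dplyr::bind_rows(
    aln_rec(subject_id = "eA", subject_taxid = 311, q_start = 1, q_end = 10,
            bits = 20),
    aln_rec(subject_id = "eB", subject_taxid = 312, q_start = 1, q_end = 5,
            bits = 15)
  )
  prof <- pass1(recs, 10)
  vol <- pass2(recs, prof)
  # A: 5 pos at s=2, r=2/3 -> 5 * 2 * (2/3)^3; 5 pos at r=1 -> 10
  expect_equal(unname(vol$volume["311"]), 5 * 2 * (2 / 3)^3 + 10,
               tolerance = 1e-12)
  expect_equal(unname(vol$volume["312"]), 15, tolerance = 1e-12)

  # a taxon holding the global top everywhere: volume equals pass-1 score
  solo <- aln_rec(subject_id = "e1", subject_taxid = 100, q_start = 1,
                  q_end = 40, bits = 55)
  p <- pass1(solo, 40)
  expect_equal(unname(pass2(solo, p)$volume["100"]),
               unname(p$pass1_score["100"]))

  # duplicate identical entries double volume but not pass-1 score
  dup <- dplyr::bind_rows(solo,
                          aln_rec(subject_id = "e2", subject_taxid = 100,
                                  q_start = 1, q_end = 40, bits = 55))
  pd <- pass1(dup, 40)
  expect_equal(unname(pd$pass1_score["100"]), 55)
  expect_equal(unname(pass2(dup, pd)$volume["100"]), 110)
})

test_that("pass-1/pass-2 agree with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:250) {
    inst <- random_scoring_instance()
    prof <- pass1(inst$records, inst$L)
    b1 <- brute_pass1(inst$records, inst$L)
    expect_equal(prof$global_top, b1$global_top, tolerance = 1e-12)
    expect_equal(prof$pass1_score, b1$pass1_score, tolerance = 1e-12)
    v <- pass2(inst$records, prof)
    b2 <- brute_pass2(inst$records, inst$L)
    expect_equal(v$volume, b2, tolerance = 1e-9)
  }
})

test_that("scoring is monotone in bits and in added records", {
  set.seed(102)
  inst <- random_scoring_instance()
  prof <- pass1(inst$records, inst$L)
  vol <- pass2(inst$records, prof)
  # raise one record's bits
  i <- sample(nrow(inst$records), 1)
  up <- inst$records
  up$bits[i] <- up$bits[i] * 1.5
  t <- as.character(up$subject_taxid[i])
  prof_up <- pass1(up, inst$L)
  expect_gte(prof_up$pass1_score[[t]], prof$pass1_score[[t]])
  # add a record for one taxon
  extra <- dplyr::bind_rows(inst$records,
                            aln_rec(subject_id = "new",
                                    subject_taxid = inst$records$subject_taxid[i],
                                    q_start = 1, q_end = 5, bits = 6))
  vol_extra <- pass2(extra, pass1(extra, inst$L))
  expect_gte(vol_extra$volume[[t]], vol$volume[[t]] - 1e-12)
})

test_that("pass-2 weights are 1 at identity, monotone, and harsher for protein", {
  r <- seq(0.05, 1, by = 0.05)
  w_nt <- r^3
  w_aa <- r^27
  expect_equal(w_nt[length(r)], 1)
  expect_equal(w_aa[length(r)], 1)
  expect_true(all(diff(w_nt) > 0))
  expect_true(all(w_aa[r < 1] < w_nt[r < 1]))
})

test_that("viral filter drops non-viral top taxa and host-dominated contigs", {
  tree <- test_tree()
  # top taxon bacterial
  recs <- dplyr::bind_rows(
    aln_rec(subject_id = "bact", subject_taxid = 21, q_start = 1, q_end = 100,
            bits = 200),
    aln_rec(subject_id = "vir", subject_taxid = 311, q_start = 1, q_end = 100,
            bits = 100)
  )
  vf <- viral_filter(pass1(recs, 100), tree)
  expect_false(vf$pass)
  expect_match(vf$reason, "outside the viral superkingdom")

  # viral top but 60% of aligned bases topped by host
  recs2 <- dplyr::bind_rows(
    aln_rec(subject_id = "vir", subject_taxid = 311, q_start = 1, q_end = 100,
            bits = 150),                                  # s = 1.5 everywhere
    aln_rec(subject_id = "bact", subject_taxid = 21, q_start = 1, q_end = 60,
            bits = 120)                                   # s = 2.0 on 1..60
  )
  vf2 <- viral_filter(pass1(recs2, 100), tree)
  expect_false(vf2$pass)
  expect_equal(vf2$nonviral_fraction, 0.6)

  # all records viral
  vf3 <- viral_filter(pass1(recs2[1, ], 100), tree)
  expect_true(vf3$pass)

  # ties at a position count as viral: equal scores -> keep
  recs3 <- dplyr::bind_rows(
    aln_rec(subject_id = "vir", subject_taxid = 311, q_start = 1, q_end = 100,
            bits = 200),
    aln_rec(subject_id = "bact", subject_taxid = 21, q_start = 1, q_end = 100,
            bits = 200)
  )
  vf4 <- viral_filter(pass1(recs3, 100), tree)
  expect_true(vf4$pass)
  expect_equal(vf4$nonviral_fraction, 0)
})

test_that("the candidate radius widens as the best hit weakens", {
  params <- classifier_params()
  # q = 1: perfect full-length self-alignment -> radius_min
  prof1 <- pass1(aln_rec(subject_id = "e", subject_taxid = 311, q_start = 1,
                         q_end = 100, bits = 200), 100)
  prof_weak <- pass1(dplyr::bind_rows(
    aln_rec(subject_id = "e1", subject_taxid = 311, q_start = 1, q_end = 100,
            bits = 40),                      # q = 40/200 = 0.2
    aln_rec(subject_id = "e2", subject_taxid = 312, q_start = 1, q_end = 100,
            bits = 40 * 0.82)                # within 20.4% radius
  ), 100)
  # strong hit: a sibling 18% below is outside the 2% radius
  prof_strong <- pass1(dplyr::bind_rows(
    aln_rec(subject_id = "e1", subject_taxid = 311, q_start = 1, q_end = 100,
            bits = 200),
    aln_rec(subject_id = "e2", subject_taxid = 312, q_start = 1, q_end = 100,
            bits = 200 * 0.82)
  ), 100)
  expect_equal(candidate_set(prof_strong, params), 311L)
  # weak hit: radius = 0.02 + 0.8 * 0.23 = 0.204 -> both enter
  expect_equal(candidate_set(prof_weak, params), c(311L, 312L))
  expect_equal(candidate_set(prof1, params), 311L)
})

test_that("the dynamic majority threshold decreases in volume and stays bounded", {
  params <- classifier_params()
  V <- c(0, 10, 100, 1000, 2000, 10000, 1e6, 1e9)
  m <- vapply(V, majority_threshold, 0, params = params)
  expect_true(all(diff(m) < 0))
  expect_true(all(m <= 0.95))
  expect_true(all(m > params$lca_base_majority))
  expect_equal(m[1], 0.95)  # capped at zero volume
  expect_equal(majority_threshold(1e12, params), 0.5, tolerance = 1e-6)
})

test_that("the volume-weighted LCA resolves species, genus and fallback cases", {
  tree <- test_tree()
  params <- classifier_params()

  # single candidate species
  res <- lca_classify(311L, c("311" = 500), tree, params)
  expect_equal(res$taxid, 311L)
  expect_equal(res$rank, "species")

  # dominant sibling at large V: m -> 0.5+, 90% majority wins at species
  res2 <- lca_classify(c(311L, 312L),
                       c("311" = 90000, "312" = 10000), tree, params)
  expect_equal(res2$taxid, 311L)
  expect_equal(res2$rank, "species")

  # balanced siblings at small V: m ~ 0.9, no species majority -> genus
  res3 <- lca_classify(c(311L, 312L), c("311" = 55, "312" = 45), tree, params)
  expect_equal(res3$taxid, 310L)
  expect_equal(res3$rank, "genus")

  # cross-family candidates with balanced volumes and tiny V: no rank
  # below superkingdom reaches majority -> argmax-volume fallback
  res4 <- lca_classify(c(311L, 411L), c("311" = 30, "411" = 29), tree, params)
  expect_equal(res4$taxid, 311L)

  expect_error(lca_classify(integer(0), numeric(0), tree, params),
               "empty candidate set")
})

test_that("classify_contig runs the whole gauntlet with the stated filters", {
  tree <- test_tree()
  contig <- list(id = "c1", seq = strrep("ACGT", 100))  # L = 400

  # 250 aggregate bits -> low information
  low <- aln_rec(query_id = "c1", subject_id = "e", subject_taxid = 311,
                 q_start = 1, q_end = 250, bits = 250)
  out <- classify_contig(contig, low, tree)
  expect_equal(out$verdict, "filtered_lowinfo")

  # clean self-hit -> species-level classification
  strong <- aln_rec(query_id = "c1", subject_id = "e", subject_taxid = 311,
                    q_start = 1, q_end = 400, bits = 800)
  out2 <- classify_contig(contig, strong, tree)
  expect_equal(out2$verdict, "classified")
  expect_equal(out2$taxid, 311L)
  expect_equal(out2$rank, "species")
  expect_equal(out2$pass1_best, 800)

  # equidistant between two genera of one family, balanced volumes -> family
  sym <- dplyr::bind_rows(
    aln_rec(query_id = "c1", subject_id = "e1", subject_taxid = 311,
            q_start = 1, q_end = 400, bits = 480),
    aln_rec(query_id = "c1", subject_id = "e2", subject_taxid = 321,
            q_start = 1, q_end = 400, bits = 480)
  )
  out3 <- classify_contig(contig, sym, tree)
  expect_equal(out3$verdict, "classified")
  expect_equal(out3$taxid, 300L)
  expect_equal(out3$rank, "family")

  # no alignments at all
  out4 <- classify_contig(contig, empty_aln(), tree)
  expect_equal(out4$verdict, "filtered_lowinfo")
  expect_match(out4$reason, "no alignments")
})

test_that("report aggregation applies the per-taxon bit filter and lists unclassifiable contigs", {
  tree <- test_tree()
  params <- classifier_params()
  cl <- tibble::tibble(
    contig_id = c("c1", "c2", "c3", "c4", "c5"),
    length = c(800L, 700L, 600L, 520L, 450L),
    taxid = c(311L, 311L, 312L, NA, NA),
    name = c("spA1a", "spA1a", "spA1b", NA, NA),
    rank = c("species", "species", "species", NA, NA),
    pass1_best = c(600, 500, 999, 120, 80),
    total_volume = c(550, 480, 900, 0, 0),
    verdict = c("classified", "classified", "classified",
                "filtered_lowinfo", "filtered_lowinfo"),
    reason = c("", "", "", "weak", "weak")
  )
  rep <- aggregate_report(cl, params = params)
  # 311: 1100 bits >= 1000 reported; 312: 999 < 1000 suppressed
  expect_equal(rep$report$taxid, 311L)
  expect_equal(rep$report$total_bits, 1100)
  expect_equal(rep$suppressed$taxid, 312L)
  # unclassifiable contigs >= 500 bp listed; shorter ones not
  expect_equal(rep$unclassified$contig_id, "c4")
})

test_that("tidy and glance summarize a classification object", {
  tree <- test_tree()
  contigs <- tibble::tibble(id = c("c1", "c2"),
                            seq = c(strrep("ACGT", 100), strrep("ACGT", 50)))
  recs <- dplyr::bind_rows(
    aln_rec(query_id = "c1", subject_id = "e", subject_taxid = 311,
            q_start = 1, q_end = 400, bits = 800),
    aln_rec(query_id = "c2", subject_id = "bact", subject_taxid = 21,
            q_start = 1, q_end = 200, bits = 400)
  )
  cls <- classify_contigs(contigs, recs, tree)
  td <- tidy(cls)
  expect_equal(nrow(td), 2)
  gl <- glance(cls)
  expect_equal(gl$n_classified, 1L)
  expect_equal(gl$n_nonviral, 1L)
  expect_equal(gl$n_taxa, 1L)
})
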