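test_that("the pLoF consequence set matches the loss-of-function taxonomy", {
  expect_true(all(is_plof(c("frameshift_variant", "stop_gained", "stop_lost",
                            "start_lost", "splice_acceptor_variant",
                            "splice_donor_variant"))))
  expect_false(any(is_plof(c("missense_variant", "synonymous_variant",
                             "intron_variant", "other"))))
  # compound VEP annotations count if any term is pLoF
  expect_true(is_plof("stop_gained&splice_region_variant"))
})

# 5-exon transcript on +: exons 100-250, 500-650, 900-1050, 1300-1450, 1700-1850
five_exon_plus <- function() {
  tx_model("TXA", "GA", "1", "+",
           list(c(100L, 250L), c(500L, 650L), c(900L, 1050L),
                c(1300L, 1450L), c(1700L, 1850L)))
}

test_that("last-exon and NMD-escape-window variants are LOW confidence", {
  tx <- five_exon_plus()
  # stop in the final exon
  last <- assess_lof_confidence(lof_event(1800, "stop_gained"), tx)
  expect_equal(last$confidence, "LOW")
  expect_equal(last$flags, "LAST_EXON")
  # stop in exon 1, far from any terminal boundary
  early <- assess_lof_confidence(lof_event(150, "stop_gained"), tx)
  expect_equal(early$confidence, "HIGH")
  expect_equal(early$flags, "")
  # stop 30 bp upstream of the penultimate exon's 3' boundary
  near <- assess_lof_confidence(lof_event(1420, "stop_gained"), tx)
  expect_equal(near$confidence, "LOW")
  expect_equal(near$flags, "NEAR_END_50BP")
  # same position but a splice term is not a premature-stop consequence
  near_splice <- assess_lof_confidence(lof_event(1420, "stop_lost"), tx)
  expect_equal(near_splice$confidence, "HIGH")
})

test_that("single-exon transcripts always flag", {
  tx1 <- tx_model("TXA", "GA", "1", "+", list(c(100L, 1000L)))
  call <- assess_lof_confidence(lof_event(500, "stop_gained"), tx1)
  expect_equal(call$confidence, "LOW")
  expect_true(grepl("SINGLE_EXON", call$flags))
})

test_that("flags are strand-symmetric under coordinate reflection", {
  L <- 2000L
  exons_plus <- list(c(100L, 250L), c(500L, 650L), c(900L, 1050L),
                     c(1300L, 1450L), c(1700L, 1850L))
  tx_plus <- tx_model("TXA", "GA", "1", "+", exons_plus)
  exons_minus <- lapply(exons_plus, function(e) c(L - e[2], L - e[1]))
  tx_minus <- tx_model("TXA", "GA", "1", "-", exons_minus)
  for (pos in c(150L, 1420L, 1800L, 620L)) {
    a <- assess_lof_confidence(lof_event(pos, "stop_gained"), tx_plus)
    b <- assess_lof_confidence(lof_event(L - pos, "stop_gained"), tx_minus)
    expect_equal(a$flags, b$flags, info = paste("pos", pos))
    expect_equal(a$confidence, b$confidence, info = paste("pos", pos))
  }
})

test_that("confidence assessment is a pure function of its inputs", {
  tx <- five_exon_plus()
  ev <- lof_event(1420, "stop_gained")
  first <- assess_lof_confidence(ev, tx)
  again <- assess_lof_confidence(ev, tx)
  expect_identical(first, again)
})

test_that("non-pLoF rows are NOT_APPLICABLE and missing transcripts unevaluable", {
  tx <- five_exon_plus()
  mis <- assess_lof_confidence(lof_event(150, "missense_variant"), tx)
  expect_equal(mis$confidence, "NOT_APPLICABLE")
  expect_message(
    orphan <- assess_lof_confidence(
      lof_event(150, "stop_gained", transcript_id = "TX_MISSING"), tx),
    "unevaluable")
  expect_false(orphan$evaluable)
  # unevaluable calls are excluded, never silently HIGH
  expect_equal(nrow(filter_high_confidence(orphan)), 0L)
})

test_that("splice dinucleotide check fires only with a reference FASTA", {
  skip_if_not_installed("Biostrings")
  tx <- tx_model("TXA", "GA", "chrT", "+", list(c(11L, 20L), c(31L, 40L)))
  # reference: donor site (bases 21-22) is AA, i.e. non-canonical
  seq <- paste(rep("A", 60), collapse = "")
  fa <- write_lines_tmp(c(">chrT", seq), ".fa")
  ev <- lof_event(21, "splice_donor_variant", chrom = "chrT")
  no_fa <- assess_lof_confidence(ev, tx)
  expect_equal(no_fa$confidence, "HIGH")
  with_fa <- assess_lof_confidence(ev, tx, fasta = fa)
  expect_equal(with_fa$confidence, "LOW")
  expect_true(grepl("NON_CANONICAL_SPLICE", with_fa$flags))
  # canonical GT donor does not flag
  seq2 <- paste0(paste(rep("A", 20), collapse = ""), "GT",
                 paste(rep("A", 38), collapse = ""))
  fa2 <- write_lines_tmp(c(">chrT", seq2), ".fa")
  canon <- assess_lof_confidence(ev, tx, fasta = fa2)
  expect_equal(canon$confidence, "HIGH")
})

test_that("filter_high_confidence subsets, preserves order and tallies LOW flags", {
  tx <- five_exon_plus()
  ev <- dplyr::bind_rows(
    lof_event(150, "stop_gained"),
    lof_event(1800, "stop_gained"),
    lof_event(520, "stop_gained"),
    lof_event(1420, "frameshift_variant")
  )
  calls <- assess_lof_confidence(ev, tx)
  high <- filter_high_confidence(calls)
  expect_equal(high$pos, c(150L, 520L))
  low <- attr(high, "low_breakdown")
  expect_setequal(low$flags, c("LAST_EXON", "NEAR_END_50BP"))
  # subset relation
  expect_true(all(high$variant_key %in% calls$variant_key))

  all_low <- assess_lof_confidence(
    dplyr::bind_rows(lof_event(1800, "stop_gained"),
                     lof_event(1750, "frameshift_variant")), tx)
  none <- filter_high_confidence(all_low)
  expect_equal(nrow(none), 0L)
  expect_equal(sum(attr(none, "low_breakdown")$n_calls), 2L)
})
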