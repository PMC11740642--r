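test_that("Fisher's exact test reproduces known values", {
  # the class-3 (10/50) vs class-2 (2/49) publication table
  p <- fisher_exact_two_sided(10, 40, 2, 47)
  expect_lt(abs(p - 0.027), 1e-3)
  # no association possible when one column is empty
  expect_equal(fisher_exact_two_sided(0, 10, 0, 10), 1)
  # perfectly discordant 5/5 table: only 2 of the C(10,5) assignments
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / choose(10, 5),
               tolerance = 1e-12)
})

test_that("Fisher implementation matches enumeration and stats::fisher.test", {
  set.seed(7)
  for (i in 1:60) {
    cells <- as.integer(rmultinom(1, sample(4:24, 1), rep(0.25, 4)))
    p <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12, info = paste(cells, collapse = ","))
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p, min(ref, 1), tolerance = 1e-9,
                 info = paste(cells, collapse = ","))
  }
})

test_that("Fisher p is symmetric, bounded and 1 for proportional rows", {
  set.seed(8)
  for (i in 1:40) {
    cells <- as.integer(rmultinom(1, sample(2:30, 1), rep(0.25, 4)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    p <- fisher_exact_two_sided(a, b, c, d)
    expect_gt(p, 0); expect_lte(p, 1)
    # simultaneous row and column swap leaves p unchanged
    expect_equal(p, fisher_exact_two_sided(d, c, b, a), tolerance = 1e-12)
  }
  # proportional rows carry no association signal
  expect_equal(fisher_exact_two_sided(4, 6, 2, 3), 1)
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("mark_published flags genes via the snapshot or the literature", {
  contenders <- tibble::tibble(gene = c("GA", "GB", "GC"),
                               gene_class = c(1L, 2L, 3L))
  known_t1 <- tibble::tibble(gene = "GA", inheritance = "dominant")
  out <- mark_published(contenders, known_t1, literature = "GB")
  expect_equal(out$published, c(TRUE, TRUE, FALSE))
})

ref_contenders <- function() {
  # per-class gene counts and published counts mirroring a large-cohort
  # validation: 18 class-1 (11 published), 49 class-2 (2), 50 class-3 (10)
  tibble::tibble(
    gene = sprintf("G%03d", 1:117),
    gene_class = rep(c(1L, 2L, 3L), c(18, 49, 50)),
    published = c(rep(c(TRUE, FALSE), c(11, 7)),
                  rep(c(TRUE, FALSE), c(2, 47)),
                  rep(c(TRUE, FALSE), c(10, 40)))
  )
}

test_that("summarize_validation tallies classes and conserves totals", {
  v <- summarize_validation(ref_contenders(), alt_diagnoses = sprintf("P%d", 1:15))
  expect_equal(v$per_class$n_genes, c(18L, 49L, 50L))
  expect_equal(v$per_class$n_published, c(11L, 2L, 10L))
  expect_equal(v$per_class$proportion[1], 11 / 18)
  expect_equal(v$overall$n_contenders, 117L)
  expect_equal(sum(v$per_class$n_genes), v$overall$n_contenders)
  expect_equal(v$overall$n_published, 23L)
  expect_equal(v$fisher_class3_vs_class2,
               fisher_exact_two_sided(10, 40, 2, 47))
  expect_equal(v$alternative_diagnosis_patients, 15L)
  g <- glance(v)
  expect_equal(g$n_published, 23L)
})

test_that("an empty class makes its Fisher test not applicable, never 1", {
  no_class1 <- dplyr::filter(ref_contenders(), gene_class != 1L)
  v <- summarize_validation(no_class1)
  expect_true(is.na(v$fisher_class1_vs_rest))
  expect_false(is.na(v$fisher_class3_vs_class2))

  all_pub <- dplyr::mutate(ref_contenders(), published = TRUE)
  v2 <- summarize_validation(all_pub)
  expect_equal(v2$per_class$proportion, c(1, 1, 1))
  expect_equal(v2$fisher_class1_vs_rest, 1)
})

test_that("under the null the class-1 Fisher p behaves like a p-value", {
  set.seed(123)
  n_sim <- 400
  hits <- 0L
  for (i in seq_len(n_sim)) {
    flags <- runif(40) < 0.3
    cls <- rep(c(1L, 2L, 3L), c(10, 15, 15))
    contenders <- tibble::tibble(gene = sprintf("G%02d", 1:40),
                                 gene_class = cls, published = flags)
    p <- summarize_validation(contenders)$fisher_class1_vs_rest
    if (p < 0.05) hits <- hits + 1L
  }
  # exact tests are conservative: rejection rate at or below ~5% within
  # binomial noise
  expect_lt(hits / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("phenotype concordance reports exact term overlaps per gene", {
  ev <- tibble::tibble(gene = c("SPENL", "SPENL", "GX"),
                       child_id = c("P1", "P2", "P3"))
  pheno <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P3"),
    term = c("HP:0001249", "HP:0000001", "HP:0001249", "HP:0000002")
  )
  pub <- tibble::tibble(
    gene = c("SPENL", "SPENL", "GX"),
    term = c("HP:0001249", "HP:0009999", "HP:0007777")
  )
  rep <- phenotype_concordance_report(ev, pheno, pub)
  # only the intellectual-disability-style shared term overlaps
  expect_equal(rep$n_overlap[rep$gene == "SPENL"], 1L)
  expect_equal(rep$overlap[rep$gene == "SPENL"][[1]], "HP:0001249")
  expect_equal(rep$n_overlap[rep$gene == "GX"], 0L)

  multi <- phenotype_concordance_report(
    tibble::tibble(gene = "GY", child_id = "P1"),
    tibble::tibble(patient_id = "P1",
                   term = sprintf("HP:000000%d", 1:5)),
    tibble::tibble(gene = "GY", term = sprintf("HP:000000%d", c(1:3, 8, 9))))
  expect_equal(multi$n_overlap, 3L)
})
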