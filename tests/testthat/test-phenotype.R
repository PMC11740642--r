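dag_fixture <- function() read_ontology(obo_fixture())

test_that("exact HPO overlap is plain set intersection without ontology credit", {
  # sibling terms never match, however close in the hierarchy
  expect_length(exact_hpo_overlap("HP:0001249", "HP:0001256"), 0L)
  expect_equal(exact_hpo_overlap(c("HP:0001249", "HP:0001250"), "HP:0001249"),
               "HP:0001249")
  p <- c("HP:0000001", "HP:0000002")
  expect_setequal(exact_hpo_overlap(p, p), p)
  # symmetric, and idempotent under duplication
  expect_equal(exact_hpo_overlap(p, rev(p)), exact_hpo_overlap(rev(p), p))
  expect_equal(exact_hpo_overlap(c(p, p), p), exact_hpo_overlap(p, p))
})

test_that("upscaling maps leaves to their organ-system branches", {
  dag <- dag_fixture()
  expect_equal(upscale_to_systems("HP:9100001", dag), "HP:0000707")
  expect_equal(upscale_to_systems("HP:9100002", dag), "HP:0001626")
  # two parents in two systems yield both system terms
  expect_setequal(upscale_to_systems("HP:9100003", dag),
                  c("HP:0000707", "HP:0001626"))
  # a system term upscales to itself
  expect_equal(upscale_to_systems("HP:0000707", dag), "HP:0000707")
  # invariant to term order
  expect_equal(upscale_to_systems(c("HP:9100001", "HP:9100002"), dag),
               upscale_to_systems(c("HP:9100002", "HP:9100001"), dag))
  expect_message(none <- upscale_to_systems("HP:7777777", dag), "skipped")
  expect_length(none, 0L)
})

kindreds <- function(...) {
  rows <- list(...)
  tibble::tibble(
    family_id = vapply(rows, `[[`, "", 1),
    child_id = vapply(rows, `[[`, "", 2),
    terms = lapply(rows, `[[`, 3)
  )
}

ext_rec <- function(gene, vclass = "missense", de_novo = TRUE,
                    systems = "HP:0000707") {
  tibble::tibble(gene = gene, variant_class = vclass, de_novo = de_novo,
                 high_level_phenotypes = list(systems))
}

test_that("classify_gene implements the three-tier rules", {
  dag <- dag_fixture()
  # two kindreds sharing one exact term -> class 1
  c1 <- classify_gene("G1", kindreds(
    list("F1", "F1_C", c("HP:9100001", "HP:9100002")),
    list("F2", "F2_C", "HP:9100001")), NULL, dag)
  expect_equal(c1$gene_class, 1L)
  expect_equal(c1$shared_terms[[1]], "HP:9100001")

  # one kindred, system overlap with an external de novo missense record
  c2 <- classify_gene("G2", kindreds(list("F1", "F1_C", "HP:9100001")),
                      ext_rec("G2"), dag)
  expect_equal(c2$gene_class, 2L)
  expect_equal(c2$external_systems[[1]], "HP:0000707")

  # one kindred, no external record for the gene -> class 3
  c3 <- classify_gene("G3", kindreds(list("F1", "F1_C", "HP:9100001")),
                      ext_rec("OTHER"), dag)
  expect_equal(c3$gene_class, 3L)

  # non-de-novo external records give no class 2 credit
  c3b <- classify_gene("G4", kindreds(list("F1", "F1_C", "HP:9100001")),
                       ext_rec("G4", de_novo = FALSE), dag)
  expect_equal(c3b$gene_class, 3L)

  # mismatched organ systems give no class 2 credit
  c3c <- classify_gene("G5", kindreds(list("F1", "F1_C", "HP:9100001")),
                       ext_rec("G5", systems = "HP:0001626"), dag)
  expect_equal(c3c$gene_class, 3L)
})

test_that("multi-kindred genes without exact overlap fall through to class 2", {
  dag <- dag_fixture()
  kp <- kindreds(list("F1", "F1_C", "HP:9100001"),
                 list("F2", "F2_C", "HP:9100002"))
  with_ext <- classify_gene("G1", kp, ext_rec("G1"), dag)
  expect_equal(with_ext$gene_class, 2L)
  without <- classify_gene("G1", kp, NULL, dag)
  expect_equal(without$gene_class, 3L)
  # affected siblings in one family are one kindred, not two
  sibs <- classify_gene("G1", kindreds(
    list("F1", "F1_C1", "HP:9100001"),
    list("F1", "F1_C2", "HP:9100001")), NULL, dag)
  expect_equal(sibs$gene_class, 3L)
})

test_that("classify_all partitions contender genes and engineered branches land correctly", {
  dag <- dag_fixture()
  ev <- tibble::tibble(
    variant_key = sprintf("1:%d:G:A", 1:5 * 10),
    gene = c("G1", "G1", "G2", "G3", "G4"),
    family_id = c("F1", "F2", "F3", "F4", "F5"),
    child_id = c("F1_C", "F2_C", "F3_C", "F4_C", "F5_C")
  )
  pheno <- tibble::tibble(
    patient_id = c("F1_C", "F2_C", "F3_C", "F4_C"),
    term = c("HP:9100001", "HP:9100001", "HP:9100002", "HP:9100001")
  )
  ext <- ext_rec("G2", systems = "HP:0001626")
  expect_message(cand <- classify_all(ev, pheno, ext, dag), "no phenotype")
  expect_equal(cand$gene_class[match(c("G1", "G2", "G3", "G4"), cand$gene)],
               c(1L, 2L, 3L, 3L))
  tal <- attr(cand, "tally")
  expect_equal(sum(tal$n_genes), dplyr::n_distinct(ev$gene))
  expect_equal(attr(cand, "n_multi_kindred"), 1L)
})

test_that("adding phenotype terms never demotes a gene's class", {
  dag <- dag_fixture()
  set.seed(42)
  leaves <- c("HP:9100001", "HP:9100002", "HP:9100003")
  for (rep in 1:20) {
    k <- sample(2:3, 1)
    base <- do.call(kindreds, lapply(seq_len(k), function(i)
      list(sprintf("F%d", i), sprintf("F%d_C", i),
           sample(leaves, sample(0:2, 1)))))
    ext <- if (runif(1) < 0.5) ext_rec("GX") else NULL
    before <- classify_gene("GX", base, ext, dag)$gene_class
    richer <- base
    add_to <- sample(k, 1)
    richer$terms[[add_to]] <- union(richer$terms[[add_to]],
                                    sample(leaves, 1))
    after <- classify_gene("GX", richer, ext, dag)$gene_class
    expect_lte(after, before)
  }
})
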