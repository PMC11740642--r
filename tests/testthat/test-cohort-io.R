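test_that("read_pedigree keeps only complete trios and reports exclusions", {
  expect_message(trios <- read_pedigree(ped_three_trios_one_duo()),
                 "1 family excluded")
  expect_equal(nrow(trios), 3L)
  expect_setequal(trios$family_id, c("F1", "F2", "F3"))
  expect_true(all(trios$child_affected))
  expect_equal(attr(trios, "n_excluded"), 1L)
})

test_that("read_pedigree handles empty files and dangling parent references", {
  empty <- write_lines_tmp(character(), ".ped")
  expect_equal(nrow(read_pedigree(empty)), 0L)

  # child's father ID points at a row that does not exist
  dangling <- write_lines_tmp(c(
    "F1\tC1\tFA1\tMO1\t1\t2",
    "F1\tMO1\t0\t0\t2\t1"
  ), ".ped")
  expect_message(trios <- read_pedigree(dangling), "excluded")
  expect_equal(nrow(trios), 0L)
})

test_that("read_pedigree rejects malformed lines and duplicate IDs", {
  bad <- write_lines_tmp(c("F1\tC1\tFA1\tMO1\t1"), ".ped")
  expect_error(read_pedigree(bad), "line 1")
  dup <- write_lines_tmp(c(
    "F1\tC1\tFA1\tMO1\t1\t2",
    "F2\tC1\t0\t0\t1\t1"
  ), ".ped")
  expect_error(read_pedigree(dup), "duplicate sample ID")
})

test_that("read_variants decomposes multiallelics and pairs annotations per transcript", {
  vcf <- read_variants(vcf_mixed_fixture())
  # 1 biallelic + 2 decomposed units + 1 biallelic = 4 units
  expect_equal(nrow(vcf$sites), 4L)
  # annotations: 1 + (1 per decomposed allele) + 2 transcripts = 5
  expect_equal(nrow(vcf$variants), 5L)
  two_tx <- vcf$variants[vcf$variants$pos == 300, ]
  expect_equal(nrow(two_tx), 2L)
  expect_setequal(two_tx$gene, c("G2", "G3"))
  expect_true(all(vcf$variants$af_afr >= 0 & vcf$variants$af_afr <= 1,
                  na.rm = TRUE))
})

test_that("multiallelic decomposition conserves ALT allele observations", {
  vcf <- read_variants(vcf_mixed_fixture())
  units_200 <- vcf$sites[vcf$sites$pos == 200, "variant_key", drop = TRUE]
  expect_length(units_200, 2L)
  g <- vcf$genotypes[vcf$genotypes$variant_key %in% units_200, ]
  count_alt <- function(gt) {
    sum(vapply(strsplit(gt, "/"), function(a)
      sum(suppressWarnings(as.integer(a)) == 1L, na.rm = TRUE), integer(1)))
  }
  # original record S1=1/2, S2=0/1, S3=0/2 carries 4 ALT alleles in total
  expect_equal(count_alt(g$gt), 4L)
})

test_that("read_variants reports unknown consequence terms as 'other'", {
  lines <- c(vcf_header("S1"),
             paste("1", 10, ".", "A", "T", 50, "PASS",
                   "CSQ=T|made_up_term|G1|TX1||", "GT", "0/1", sep = "\t"))
  expect_warning(vcf <- read_variants(write_lines_tmp(lines, ".vcf")),
                 "unrecognized consequence")
  expect_equal(vcf$variants$consequence, "other")
})

test_that("read_variants requires GT in FORMAT", {
  lines <- c(vcf_header("S1")[-(3:6)],
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
             paste("1", 10, ".", "A", "T", 50, "PASS",
                   "CSQ=T|stop_gained|G1|TX1||", "DP", "30", sep = "\t"))
  # drop the #CHROM line ordering problem: rebuild properly
  hdr <- vcf_header("S1")
  lines <- c(hdr[1:2],
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
             hdr[7],
             paste("1", 10, ".", "A", "T", 50, "PASS",
                   "CSQ=T|stop_gained|G1|TX1||", "DP", "30", sep = "\t"))
  expect_error(read_variants(write_lines_tmp(lines, ".vcf")), "GT")
})

test_that("read_constraint drops NA scores and rejects conflicts", {
  path <- write_lines_tmp(c("gene\toe_lof_upper",
                            "GENE1\t0.15", "GENE2\tNA", "GENE3\t0.4"), ".tsv")
  tbl <- read_constraint(path)
  expect_equal(nrow(tbl), 2L)
  expect_equal(tbl$loeuf[tbl$gene == "GENE1"], 0.15)
  expect_false("GENE2" %in% tbl$gene)

  conflict <- write_lines_tmp(c("gene\toe_lof_upper",
                                "GENE1\t0.15", "GENE1\t0.3"), ".tsv")
  expect_error(read_constraint(conflict), "conflicting")
})

test_that("read_ontology builds the DAG and finds system terms", {
  dag <- read_ontology(obo_fixture())
  expect_s3_class(dag, "hpo_dag")
  expect_setequal(dag$system_terms, c("HP:0000707", "HP:0001626"))
  # 4-level chain: leaf reaches exactly one system term
  expect_equal(intersect(hpo_ancestors(dag, "HP:9100001"), dag$system_terms),
               "HP:0000707")
  # multi-parent leaf reaches both systems
  expect_setequal(intersect(hpo_ancestors(dag, "HP:9100003"), dag$system_terms),
                  c("HP:0000707", "HP:0001626"))
})

test_that("read_ontology rejects cycles and undeclared is_a targets", {
  cyc <- write_lines_tmp(c(
    "[Term]", "id: HP:0000001", "name: a", "is_a: HP:0000002", "",
    "[Term]", "id: HP:0000002", "name: b", "is_a: HP:0000001", ""
  ), ".obo")
  expect_error(read_ontology(cyc, anchor = "HP:0000001"), "cycle")
  und <- write_lines_tmp(c(
    "[Term]", "id: HP:0000001", "name: a", "is_a: HP:0009999", ""
  ), ".obo")
  expect_error(read_ontology(und, anchor = "HP:0000001"), "undeclared")
})

test_that("parsed tables round-trip through their writers", {
  cons <- tibble::tibble(gene = c("A1", "B2"), loeuf = c(0.11, 0.52))
  expect_equal(read_constraint(write_constraint(cons, tempfile())), cons)

  known <- tibble::tibble(gene = c("A1", "B2"),
                          inheritance = c("dominant", "recessive,other"))
  expect_equal(as.data.frame(read_known_genes(write_known_genes(known, tempfile()))),
               as.data.frame(known))

  pheno <- tibble::tibble(patient_id = c("P1", "P1", "P2"),
                          term = c("HP:0000001", "HP:0000002", "HP:0000001"))
  rt <- read_phenotypes(write_phenotypes(pheno, tempfile()))
  expect_equal(dplyr::arrange(rt, patient_id, term),
               dplyr::arrange(pheno, patient_id, term))

  ext <- tibble::tibble(gene = "A1", variant_class = "pLoF", de_novo = TRUE,
                        high_level_phenotypes = list(c("HP:0000707", "HP:0001626")))
  expect_equal(read_external_db(write_external_db(ext, tempfile())), ext)

  tx <- tx_model("TXA", "GA", "1", "+", list(c(100L, 200L), c(400L, 500L)))
  rt_tx <- read_transcripts(write_transcripts(tx, tempfile()))
  expect_equal(as.data.frame(rt_tx), as.data.frame(tx[, names(rt_tx)]))
})

test_that("phenotype reader validates HPO identifier syntax", {
  bad <- write_lines_tmp(c("patient_id\thpo_terms", "P1\tHP:12"), ".tsv")
  expect_error(read_phenotypes(bad), "invalid HPO term")
})
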