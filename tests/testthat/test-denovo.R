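test_that("is_denovo implements the trio genotype and quality gates", {
  q <- list(child_gq = 60, child_dp = 30, child_ad_ref = 15,
            child_ad_alt = 15, father_gq = 60, mother_gq = 60)
  ok <- is_denovo("0/1", "0/0", "0/0", q)
  expect_true(ok$denovo)
  expect_equal(ok$reason, "pass")

  inh <- is_denovo("0/1", "0/1", "0/0", q)
  expect_false(inh$denovo)
  expect_equal(inh$reason, "inherited")

  lowgq <- is_denovo("0/1", "0/0", "0/0",
                     modifyList(q, list(child_gq = 10)))
  expect_false(lowgq$denovo)
  expect_equal(lowgq$reason, "child_gq")

  miss <- is_denovo("0/1", "./.", "0/0", q)
  expect_equal(miss$reason, "missing_gt")

  homref <- is_denovo("0/0", "0/0", "0/0", q)
  expect_equal(homref$reason, "child_not_het")

  ab <- is_denovo("0/1", "0/0", "0/0",
                  modifyList(q, list(child_ad_ref = 28, child_ad_alt = 2)))
  expect_equal(ab$reason, "child_ab")

  mosaic <- is_denovo("0/1", "0/0", "0/0",
                      modifyList(q, list(father_ad_ref = 18,
                                         father_ad_alt = 2)))
  expect_equal(mosaic$reason, "parent_alt_reads")
})

test_that("call_denovos finds singleton events and respects other trios' parents", {
  cohort <- random_cohort(1, 10, seed = 1)
  g <- cohort$genotypes
  g$gt <- "0/0"; g$gq <- 60; g$dp <- 30; g$ad_ref <- 30L; g$ad_alt <- 0L
  # het in exactly one child
  g$gt[g$sample_id == "F03_C"] <- "0/1"
  g$ad_ref[g$sample_id == "F03_C"] <- 15L
  g$ad_alt[g$sample_id == "F03_C"] <- 15L
  # same variant het in ANOTHER trio's child whose father also carries it
  for (s in c("F07_C", "F07_F")) {
    g$gt[g$sample_id == s] <- "0/1"
    g$ad_ref[g$sample_id == s] <- 15L
    g$ad_alt[g$sample_id == s] <- 15L
  }
  vcf <- list(sites = cohort$sites, genotypes = g)
  ev <- call_denovos(vcf, cohort$trios)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$child_id, "F03_C")
  aud <- denovo_audit(ev)
  expect_true(any(aud$child_id == "F07_C" & aud$reason == "inherited"))
})

test_that("trios with members absent from the VCF are skipped with a warning", {
  cohort <- random_cohort(2, 3, seed = 2)
  g <- cohort$genotypes[cohort$genotypes$sample_id != "F02_F", ]
  vcf <- list(sites = cohort$sites, genotypes = g)
  expect_warning(ev <- call_denovos(vcf, cohort$trios), "skipped")
  expect_false("F02_C" %in% ev$child_id)
})

test_that("de novo caller matches the brute-force triple-loop oracle", {
  for (seed in c(11, 23, 37)) {
    cohort <- random_cohort(30, 8, seed = seed)
    vcf <- list(sites = cohort$sites, genotypes = cohort$genotypes)
    ev <- call_denovos(vcf, cohort$trios)
    got <- strip_event_keys(ev)
    want <- oracle_denovos(vcf, cohort$trios, dn_config())
    rownames(want) <- NULL
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("raising quality thresholds never increases the event count", {
  cohort <- random_cohort(40, 6, seed = 5)
  vcf <- list(sites = cohort$sites, genotypes = cohort$genotypes)
  base <- nrow(call_denovos(vcf, cohort$trios, dn_config()))
  for (gq in c(30, 50, 70)) {
    n <- nrow(call_denovos(vcf, cohort$trios, dn_config(min_gq = gq)))
    expect_lte(n, base)
    base_dp <- nrow(call_denovos(vcf, cohort$trios,
                                 dn_config(min_gq = gq, min_dp = 25)))
    expect_lte(base_dp, n)
  }
})

test_that("no event is emitted for hom-ref or missing child genotypes", {
  cohort <- random_cohort(25, 6, seed = 9)
  vcf <- list(sites = cohort$sites, genotypes = cohort$genotypes)
  ev <- call_denovos(vcf, cohort$trios)
  if (nrow(ev) > 0) {
    expect_true(all(ev$child_gt == "0/1"))
  }
  succeed()
})
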