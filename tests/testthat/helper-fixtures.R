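# fixtures are built in code at test time; nothing binary is shipped

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# --- pedigree fixtures --------------------------------------------------

ped_three_trios_one_duo <- function() {
  write_lines_tmp(c(
    "F1\tF1_C\tF1_F\tF1_M\t1\t2",
    "F1\tF1_F\t0\t0\t1\t1",
    "F1\tF1_M\t0\t0\t2\t1",
    "F2\tF2_C\tF2_F\tF2_M\t2\t2",
    "F2\tF2_F\t0\t0\t1\t1",
    "F2\tF2_M\t0\t0\t2\t1",
    "F3\tF3_C\tF3_F\tF3_M\t1\t2",
    "F3\tF3_F\t0\t0\t1\t1",
    "F3\tF3_M\t0\t0\t2\t1",
    "F4\tF4_C\t0\tF4_M\t1\t2",
    "F4\tF4_M\t0\t0\t2\t1"
  ), ".ped")
}

# --- VCF fixture: biallelic, multiallelic, multi-transcript -------------

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Format: ",
           "Allele|Consequence|SYMBOL|Feature|AF_afr|AF_nfe\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_mixed_fixture <- function() {
  samples <- c("S1", "S2", "S3")
  g <- function(...) paste(c(...), collapse = "\t")
  body <- c(
    # biallelic stop_gained, one transcript
    g("1", 100, ".", "A", "T", 50, "PASS",
      "CSQ=T|stop_gained|G1|TX1||", "GT:GQ:DP:AD",
      "0/1:60:30:15,15", "0/0:60:30:30,0", "0/0:60:30:30,0"),
    # triallelic: two decomposed units, per-allele CSQ
    g("1", 200, ".", "G", "A,C", 50, "PASS",
      "CSQ=A|missense_variant|G1|TX1|0.0002|,C|stop_gained|G1|TX1||",
      "GT:GQ:DP:AD",
      "1/2:60:40:10,15,15", "0/1:60:30:15,15", "0/2:60:30:15,0,15"),
    # one unit annotated on two transcripts (two genes)
    g("2", 300, ".", "C", "T", 50, "PASS",
      "CSQ=T|stop_gained|G2|TX2||,T|splice_donor_variant|G3|TX3||",
      "GT:GQ:DP:AD",
      "0/1:60:30:14,16", "0/0:60:30:30,0", "./.:.:.:."))
  write_lines_tmp(c(vcf_header(samples), body), ".vcf")
}

# --- transcript model builders ------------------------------------------

# exons given as list of c(start, end) in genomic order
tx_model <- function(transcript_id, gene, chrom, strand, exons) {
  df <- tibble::tibble(
    transcript_id = transcript_id, gene = gene, chrom = chrom,
    strand = strand,
    exon_start = vapply(exons, `[`, integer(1), 1L),
    exon_end = vapply(exons, `[`, integer(1), 2L)
  )
  ord <- if (strand == "+") order(df$exon_start) else order(-df$exon_start)
  df <- df[ord, ]
  df$exon_index <- seq_len(nrow(df))
  df$n_exons <- nrow(df)
  df
}

# minimal annotated-event row for the LoF-confidence unit tests
lof_event <- function(pos, consequence, transcript_id = "TXA",
                      gene = "GA", chrom = "1") {
  tibble::tibble(
    variant_key = paste(chrom, pos, "G", "A", sep = ":"),
    chrom = chrom, pos = as.integer(pos), ref = "G", alt = "A",
    family_id = "F1", child_id = "F1_C", gene = gene,
    transcript_id = transcript_id, consequence = consequence
  )
}

# --- mini ontology OBO fixture ------------------------------------------

obo_fixture <- function() {
  write_lines_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: HP:0000001", "name: All", "",
    "[Term]", "id: HP:0000118", "name: Phenotypic abnormality",
    "is_a: HP:0000001", "",
    "[Term]", "id: HP:0000707", "name: Abnormality of the nervous system",
    "is_a: HP:0000118", "",
    "[Term]", "id: HP:0001626", "name: Abnormality of the cardiovascular system",
    "is_a: HP:0000118", "",
    "[Term]", "id: HP:9000001", "name: Neuro finding group",
    "is_a: HP:0000707", "",
    "[Term]", "id: HP:9000002", "name: Cardio finding group",
    "is_a: HP:0001626", "",
    "[Term]", "id: HP:9100001", "name: Hydrocephalus-like leaf",
    "is_a: HP:9000001", "",
    "[Term]", "id: HP:9100002", "name: Atrial-septal-defect-like leaf",
    "is_a: HP:9000002", "",
    "[Term]", "id: HP:9100003", "name: Dual-system leaf",
    "is_a: HP:9000001", "is_a: HP:9000002", ""
  ), ".obo")
}

# --- independent brute-force de novo oracle ------------------------------
# deliberately written as a naive triple loop over sites x trios with
# scalar checks, sharing no code with call_denovos()

oracle_denovos <- function(vcf, trios, cfg) {
  geno <- as.data.frame(vcf$genotypes)
  lookup <- function(key, sample) {
    row <- geno[geno$variant_key == key & geno$sample_id == sample, ]
    if (nrow(row) == 0) NULL else row
  }
  alleles <- function(gt) {
    if (is.na(gt)) return(c(NA, NA))
    suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  }
  out <- list()
  for (s in seq_len(nrow(vcf$sites))) {
    key <- vcf$sites$variant_key[s]
    for (t in seq_len(nrow(trios))) {
      ch <- lookup(key, trios$child_id[t])
      fa <- lookup(key, trios$father_id[t])
      mo <- lookup(key, trios$mother_id[t])
      if (is.null(ch) || is.null(fa) || is.null(mo)) next
      ca <- alleles(ch$gt); faa <- alleles(fa$gt); moa <- alleles(mo$gt)
      if (any(is.na(c(ca, faa, moa)))) next
      if (!setequal(ca, c(0L, 1L))) next
      if (any(faa != 0L) || any(moa != 0L)) next
      if (!is.na(ch$gq) && ch$gq < cfg$min_gq) next
      if (!is.na(ch$dp) && ch$dp < cfg$min_dp) next
      if (!is.na(ch$ad_ref) && !is.na(ch$ad_alt) &&
          (ch$ad_ref + ch$ad_alt) > 0) {
        ab <- ch$ad_alt / (ch$ad_ref + ch$ad_alt)
        if (ab < cfg$ab_range[1] || ab > cfg$ab_range[2]) next
      }
      if (isTRUE(cfg$require_parent_hom_ref_gq)) {
        if ((!is.na(fa$gq) && fa$gq < cfg$min_gq) ||
            (!is.na(mo$gq) && mo$gq < cfg$min_gq)) next
      }
      bad_parent <- FALSE
      for (par in list(fa, mo)) {
        if (!is.na(par$ad_ref) && !is.na(par$ad_alt) &&
            (par$ad_ref + par$ad_alt) > 0 &&
            par$ad_alt / (par$ad_ref + par$ad_alt) > cfg$max_parent_alt_frac) {
          bad_parent <- TRUE
        }
      }
      if (bad_parent) next
      out[[length(out) + 1L]] <- data.frame(
        variant_key = key, child_id = trios$child_id[t],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(variant_key = character(), child_id = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$variant_key, res$child_id), , drop = FALSE]
}

# random small trio cohort built directly as a trio_vcf-shaped list
random_cohort <- function(n_sites, n_trios, seed) {
  set.seed(seed)
  trios <- tibble::tibble(
    family_id = sprintf("F%02d", seq_len(n_trios)),
    child_id = sprintf("F%02d_C", seq_len(n_trios)),
    father_id = sprintf("F%02d_F", seq_len(n_trios)),
    mother_id = sprintf("F%02d_M", seq_len(n_trios)),
    child_affected = TRUE
  )
  samples <- c(trios$child_id, trios$father_id, trios$mother_id)
  sites <- tibble::tibble(
    chrom = "1", pos = seq_len(n_sites) * 10L, ref = "G", alt = "A"
  )
  sites$variant_key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt,
                             sep = ":")
  gts <- c("0/0", "0/1", "1/1", "./.")
  geno <- expand.grid(variant_key = sites$variant_key, sample_id = samples,
                      stringsAsFactors = FALSE)
  n <- nrow(geno)
  geno$gt <- sample(gts, n, replace = TRUE, prob = c(0.75, 0.15, 0.05, 0.05))
  geno$gq <- sample(c(NA, 5:80), n, replace = TRUE)
  geno$dp <- sample(c(NA, 2:60), n, replace = TRUE)
  geno$ad_alt <- ifelse(geno$gt %in% c("0/1", "1/1"),
                        sample(0:30, n, replace = TRUE),
                        sample(c(0L, 0L, 0L, 2L), n, replace = TRUE))
  geno$ad_ref <- ifelse(is.na(geno$dp), 20L, pmax(geno$dp - geno$ad_alt, 0L))
  list(sites = sites, genotypes = tibble::as_tibble(geno), trios = trios,
       samples = samples)
}

# --- independent Fisher oracle: exhaustive enumeration with choose() ----

oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# normalize a call set for comparison against the oracle
strip_event_keys <- function(ev) {
  d <- as.data.frame(ev[order(ev$variant_key, ev$child_id),
                        c("variant_key", "child_id")])
  attr(d, "audit") <- NULL
  rownames(d) <- NULL
  d
}
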