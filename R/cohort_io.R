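#' Read a pedigree file and extract complete trios
#'
#' Parses a 6-column whitespace-delimited PED file (family, individual,
#' father, mother, sex, phenotype) and returns one row per *complete* trio:
#' a child whose father and mother IDs are both non-zero and are themselves
#' present as rows of the file. Incomplete families (duos, singletons,
#' dangling parent references) are dropped with an informative message.
#'
#' @param path Path to a PED file.
#' @return A tibble with columns `family_id`, `child_id`, `father_id`,
#'   `mother_id`, `child_affected` (logical; PED phenotype code 2). The
#'   number of excluded families is attached as attribute `n_excluded`.
#' @export
read_pedigree <- function(path) {
  assert_file(path, "pedigree")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    out <- tibble(
      family_id = character(), child_id = character(),
      father_id = character(), mother_id = character(),
      child_affected = logical()
    )
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  fields <- stringr::str_split(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 6L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed PED line %d: expected 6 columns, found %d",
                  bad[1], length(fields[[bad[1]]])))
  }
  ped <- tibble(
    family_id = purrr::map_chr(fields, 1),
    id        = purrr::map_chr(fields, 2),
    father_id = purrr::map_chr(fields, 3),
    mother_id = purrr::map_chr(fields, 4),
    sex       = purrr::map_chr(fields, 5),
    phenotype = purrr::map_chr(fields, 6)
  )
  if (anyDuplicated(ped$id)) {
    abort(sprintf("duplicate sample ID in pedigree: %s",
                  ped$id[duplicated(ped$id)][1]))
  }
  present <- ped$id
  trios <- ped %>%
    filter(.data$father_id != "0", .data$mother_id != "0",
           .data$father_id %in% present, .data$mother_id %in% present) %>%
    mutate(child_affected = .data$phenotype == "2") %>%
    select("family_id", child_id = "id", "father_id", "mother_id",
           "child_affected")
  bad_ids <- unique(c(trios$child_id, trios$father_id, trios$mother_id))
  n_excluded <- length(setdiff(unique(ped$family_id), unique(trios$family_id)))
  if (n_excluded > 0L) {
    inform(sprintf("%d famil%s excluded (no complete trio)",
                   n_excluded, if (n_excluded == 1L) "y" else "ies"))
  }
  stopifnot(all(trios$child_id != trios$father_id),
            all(trios$child_id != trios$mother_id),
            all(trios$father_id != trios$mother_id))
  attr(trios, "n_excluded") <- n_excluded
  trios
}

#' Describe where consequence and allele-frequency annotations live in a VCF
#'
#' By default annotations are taken from a VEP-style `CSQ` INFO field whose
#' subfield order is read from the VCF header (`Format: Allele|Consequence|...`).
#' Population allele frequencies are the CSQ subfields whose names start with
#' `af_prefix`. Alternatively (`mode = "info"`) annotations may live in
#' dedicated INFO keys, one annotation per record.
#'
#' @param mode `"csq"` (VEP-style, default) or `"info"` (dedicated keys).
#' @param field Name of the CSQ INFO field.
#' @param allele,consequence,symbol,feature Names of the CSQ subfields
#'   carrying the allele, consequence term, gene symbol and transcript ID.
#' @param af_prefix Prefix identifying population-AF CSQ subfields; the
#'   population label is the remainder of the name.
#' @param format Optional explicit CSQ subfield order (character vector);
#'   when `NULL` it is parsed from the VCF header.
#' @param info_keys For `mode = "info"`: named character vector with entries
#'   `consequence`, `gene`, `transcript` giving the INFO key names.
#' @param info_af_keys For `mode = "info"`: named character vector mapping
#'   population label to INFO key.
#' @return A `csq_spec` list.
#' @export
csq_spec <- function(mode = c("csq", "info"), field = "CSQ",
                     allele = "Allele", consequence = "Consequence",
                     symbol = "SYMBOL", feature = "Feature",
                     af_prefix = "AF_", format = NULL,
                     info_keys = c(consequence = "Consequence", gene = "Gene",
                                   transcript = "Feature"),
                     info_af_keys = character()) {
  structure(list(
    mode = match.arg(mode), field = field, allele = allele,
    consequence = consequence, symbol = symbol, feature = feature,
    af_prefix = af_prefix, format = format, info_keys = info_keys,
    info_af_keys = info_af_keys
  ), class = "csq_spec")
}

# Sequence Ontology terms accepted as-is; anything else becomes "other"
so_vocabulary <- function() c(
  "stop_gained", "frameshift_variant", "splice_acceptor_variant",
  "splice_donor_variant", "start_lost", "stop_lost",
  "missense_variant", "synonymous_variant", "intron_variant",
  "splice_region_variant", "inframe_deletion", "inframe_insertion",
  "5_prime_UTR_variant", "3_prime_UTR_variant", "upstream_gene_variant",
  "downstream_gene_variant", "intergenic_variant", "stop_retained_variant",
  "coding_sequence_variant", "protein_altering_variant", "other"
)

# trim a (pos, ref, alt) pair: shared suffix first, then shared prefix
# (left alignment at the reported locus); both kept >= 1 base
decompose_allele <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# VEP-style minimal allele representation used in CSQ Allele fields
vep_allele <- function(ref, alt) {
  if (nchar(ref) > 1L || nchar(alt) > 1L) {
    if (substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      trimmed <- substr(alt, 2L, nchar(alt))
      return(if (trimmed == "") "-" else trimmed)
    }
  }
  alt
}

#' Read a trio VCF with consequence and allele-frequency annotations
#'
#' Reads a VCF 4.2 file, decomposes multiallelic records into biallelic
#' units (shared-suffix/prefix trimming, per-sample genotype recoding with
#' non-focal ALT alleles mapped to the reference allele), and pairs each
#' unit with its transcript annotations. One annotation row is produced per
#' (variant unit, transcript).
#'
#' @param path Path to a VCF file. `GT` is required in FORMAT; `GQ`, `DP`
#'   and `AD` are used when present.
#' @param spec A [csq_spec()] describing where annotations live.
#' @return An object of class `trio_vcf`: a list with
#'   \describe{
#'     \item{sites}{tibble of decomposed variant units (`variant_key`,
#'       `chrom`, `pos`, `ref`, `alt`).}
#'     \item{variants}{tibble of annotations, one row per (unit, transcript):
#'       site columns plus `gene`, `transcript_id`, `consequence` and one
#'       `af_<population>` column per population.}
#'     \item{genotypes}{long tibble: `variant_key`, `sample_id`, `gt`, `gq`,
#'       `dp`, `ad_ref`, `ad_alt`.}
#'     \item{samples}{character vector of sample IDs.}
#'   }
#' @export
read_variants <- function(path, spec = csq_spec()) {
  assert_file(path, "VCF")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0L) {
    abort("VCF contains no variant records")
  }
  fmt <- vcf@gt[, 1]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    abort("VCF FORMAT is missing the required GT field")
  }
  samples <- colnames(vcf@gt)[-1]
  gt_m <- vcfR::extract.gt(vcf, element = "GT")
  gq_m <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  dp_m <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  ad_m <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                   error = function(e) NULL)
  as_mat <- function(m) {
    if (is.null(m)) return(NULL)
    if (is.null(dim(m))) matrix(m, nrow = n_rec) else m
  }
  gt_m <- as_mat(gt_m); gq_m <- as_mat(gq_m); dp_m <- as_mat(dp_m)
  ad_m <- as_mat(ad_m)

  info <- unname(vcf@fix[, "INFO"])
  if (is.null(spec$format) && spec$mode == "csq") {
    spec$format <- parse_csq_format(vcf@meta, spec$field)
  }

  sites <- list(); annotations <- list(); geno <- list()
  unknown_terms <- character()
  for (r in seq_len(n_rec)) {
    chrom <- fix[r, "CHROM"]
    pos0 <- as.integer(fix[r, "POS"])
    ref0 <- fix[r, "REF"]
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    csq_entries <- if (spec$mode == "csq") parse_csq_info(info[r], spec) else NULL
    for (i in seq_along(alts)) {
      dec <- decompose_allele(pos0, ref0, alts[i])
      if (dec$ref == dec$alt || dec$ref == "" || dec$alt == "") {
        abort(sprintf("invalid REF/ALT pair at %s:%d", chrom, pos0))
      }
      key <- variant_key(chrom, dec$pos, dec$ref, dec$alt)
      sites[[length(sites) + 1L]] <- tibble(
        variant_key = key, chrom = chrom, pos = dec$pos,
        ref = dec$ref, alt = dec$alt
      )
      ann <- if (spec$mode == "csq") {
        match_csq_entries(csq_entries, alts[i], ref0, length(alts), spec)
      } else {
        info_mode_annotation(info[r], spec)
      }
      if (!is.null(ann) && nrow(ann) > 0L) {
        bad <- !vapply(strsplit(ann$consequence, "&", fixed = TRUE),
                       function(p) all(p %in% so_vocabulary()), logical(1))
        if (any(bad)) {
          unknown_terms <- c(unknown_terms, ann$consequence[bad])
          ann$consequence[bad] <- "other"
        }
        annotations[[length(annotations) + 1L]] <- dplyr::bind_cols(
          tibble(variant_key = key, chrom = chrom, pos = dec$pos,
                 ref = dec$ref, alt = dec$alt),
          ann
        )
      }
      geno[[length(geno) + 1L]] <- recode_genotypes(
        key, samples, gt_m[r, ], gq_m[r, ], dp_m[r, ],
        if (is.null(ad_m)) NULL else ad_m[r, ], i
      )
    }
  }
  if (length(unknown_terms) > 0L) {
    warn(sprintf("%d annotation(s) with unrecognized consequence term(s) (%s) kept as \"other\"",
                 length(unknown_terms),
                 paste(unique(unknown_terms)[1:min(3, length(unique(unknown_terms)))],
                       collapse = ", ")))
  }
  variants <- if (length(annotations)) bind_rows(annotations) else
    tibble(variant_key = character(), chrom = character(), pos = integer(),
           ref = character(), alt = character(), gene = character(),
           transcript_id = character(), consequence = character())
  af_cols <- grep("^af_", names(variants), value = TRUE)
  for (col in af_cols) {
    v <- variants[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      abort(sprintf("allele frequency outside [0,1] in column %s", col))
    }
  }
  structure(list(
    sites = bind_rows(sites),
    variants = variants,
    genotypes = bind_rows(geno),
    samples = samples
  ), class = "trio_vcf")
}

# pull "Format: A|B|C" out of the ##INFO=<ID=CSQ,...> header line
parse_csq_format <- function(meta, field) {
  pat <- sprintf("^##INFO=<ID=%s[,>]", field)
  line <- grep(pat, meta, value = TRUE)
  if (length(line) == 0L) {
    abort(sprintf("VCF header has no ##INFO line for %s; supply csq_spec(format=)", field))
  }
  m <- stringr::str_match(line[1], "Format:\\s*([A-Za-z0-9_|]+)")
  if (is.na(m[1, 2])) {
    abort(sprintf("could not parse Format from the %s header line", field))
  }
  strsplit(m[1, 2], "|", fixed = TRUE)[[1]]
}

parse_csq_info <- function(info, spec) {
  kv <- strsplit(info, ";", fixed = TRUE)[[1]]
  hit <- grep(paste0("^", spec$field, "="), kv, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  entries <- strsplit(sub(paste0("^", spec$field, "="), "", hit[1]),
                      ",", fixed = TRUE)[[1]]
  mat <- stringr::str_split_fixed(entries, stringr::fixed("|"),
                                  length(spec$format))
  colnames(mat) <- spec$format
  mat
}

match_csq_entries <- function(entries, alt_raw, ref_raw, n_alts, spec) {
  if (is.null(entries) || nrow(entries) == 0L) return(NULL)
  al <- entries[, spec$allele]
  keep <- if (n_alts == 1L) rep(TRUE, nrow(entries)) else
    al == alt_raw | al == vep_allele(ref_raw, alt_raw)
  if (!any(keep)) return(NULL)
  ent <- entries[keep, , drop = FALSE]
  af_fields <- grep(paste0("^", spec$af_prefix), spec$format, value = TRUE)
  ann <- tibble(
    gene = unname(ent[, spec$symbol]),
    transcript_id = unname(ent[, spec$feature]),
    consequence = unname(ent[, spec$consequence])
  )
  for (f in af_fields) {
    pop <- tolower(sub(paste0("^", spec$af_prefix), "", f))
    v <- ent[, f]
    v[v %in% c("", ".")] <- NA
    ann[[paste0("af_", pop)]] <- suppressWarnings(as.numeric(v))
  }
  ann
}

info_mode_annotation <- function(info, spec) {
  kv <- strsplit(info, ";", fixed = TRUE)[[1]]
  get1 <- function(key) {
    hit <- grep(paste0("^", key, "="), kv, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    sub(paste0("^", key, "="), "", hit[1])
  }
  ann <- tibble(
    gene = get1(spec$info_keys[["gene"]]),
    transcript_id = get1(spec$info_keys[["transcript"]]),
    consequence = get1(spec$info_keys[["consequence"]])
  )
  for (pop in names(spec$info_af_keys)) {
    v <- get1(spec$info_af_keys[[pop]])
    ann[[paste0("af_", tolower(pop))]] <- suppressWarnings(as.numeric(v))
  }
  ann
}

# per-sample genotype recoding for the i-th ALT allele of a record
recode_genotypes <- function(key, samples, gt, gq, dp, ad, alt_idx) {
  al <- parse_gt(gt)
  code <- function(a) ifelse(is.na(a), NA_integer_, ifelse(a == alt_idx, 1L, 0L))
  a1 <- code(al[, 1]); a2 <- code(al[, 2])
  gt_new <- ifelse(is.na(a1) | is.na(a2), "./.",
                   paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
  ad_ref <- ad_alt <- rep(NA_integer_, length(samples))
  if (!is.null(ad)) {
    parts <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
    ad_ref <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 1L) p[1] else NA_character_, character(1))))
    ad_alt <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= alt_idx + 1L) p[alt_idx + 1L] else NA_character_,
      character(1))))
  }
  tibble(
    variant_key = key, sample_id = samples, gt = unname(gt_new),
    gq = unname(as.numeric(gq)), dp = unname(as.numeric(dp)),
    ad_ref = unname(ad_ref), ad_alt = unname(ad_alt)
  )
}

#' Read a gene constraint (LOEUF) table
#'
#' @param path Tab-delimited file with a header row.
#' @param gene_col,loeuf_col Column names holding the gene symbol and the
#'   LOEUF score (gnomAD ships it as `oe_lof_upper`).
#' @return Tibble with columns `gene`, `loeuf`; genes with missing scores
#'   are dropped. Duplicate genes with conflicting scores are an error.
#' @export
read_constraint <- function(path, gene_col = "gene", loeuf_col = "oe_lof_upper") {
  assert_file(path, "constraint")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c(gene_col, loeuf_col) %in% names(df))) {
    abort(sprintf("constraint table must have columns %s and %s",
                  gene_col, loeuf_col))
  }
  out <- tibble(gene = as.character(df[[gene_col]]),
                loeuf = suppressWarnings(as.numeric(df[[loeuf_col]]))) %>%
    filter(!is.na(.data$loeuf))
  if (any(out$loeuf < 0)) abort("negative LOEUF score in constraint table")
  dups <- out %>% distinct() %>% count(.data$gene) %>% filter(.data$n > 1L)
  if (nrow(dups) > 0L) {
    abort(sprintf("conflicting LOEUF scores for gene %s", dups$gene[1]))
  }
  distinct(out)
}

#' Read a known disease gene snapshot
#'
#' @param path Tab-delimited file with columns `gene` and `inheritance`
#'   (comma-separated modes among dominant/recessive/other).
#' @param snapshot Optional label (e.g. `"2019-10"`) stored as the
#'   `snapshot_date` attribute.
#' @return Tibble with columns `gene`, `inheritance`.
#' @export
read_known_genes <- function(path, snapshot = NULL) {
  assert_file(path, "known-genes")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "inheritance") %in% names(df))) {
    abort("known-genes table must have columns gene and inheritance")
  }
  if (anyDuplicated(df$gene)) {
    abort(sprintf("duplicate gene in known-genes snapshot: %s",
                  df$gene[duplicated(df$gene)][1]))
  }
  out <- tibble(gene = as.character(df$gene),
                inheritance = as.character(df$inheritance))
  attr(out, "snapshot_date") <- snapshot %||% attr(df, "snapshot_date")
  out
}

#' Read patient phenotype profiles
#'
#' @param path Tab-delimited file with columns `patient_id` and `hpo_terms`
#'   (comma-separated `HP:NNNNNNN` identifiers; may be empty).
#' @return Long tibble with columns `patient_id`, `term` (one row per term).
#' @export
read_phenotypes <- function(path) {
  assert_file(path, "phenotype")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("patient_id", "hpo_terms") %in% names(df))) {
    abort("phenotype table must have columns patient_id and hpo_terms")
  }
  out <- df %>%
    mutate(term = stringr::str_split(
      ifelse(is.na(.data$hpo_terms), "", .data$hpo_terms), ",")) %>%
    select("patient_id", "term") %>%
    tidyr::unnest("term") %>%
    mutate(term = trimws(.data$term)) %>%
    filter(.data$term != "")
  bad <- out$term[!is_hpo_id(out$term)]
  if (length(bad) > 0L) {
    abort(sprintf("invalid HPO term ID in phenotype table: %s", bad[1]))
  }
  distinct(out)
}

#' Read an external gene-phenotype database
#'
#' Records of de novo pLoF/missense variants in external patients together
#' with organ-system-level phenotype terms (DECIPHER-style).
#'
#' @param path Tab-delimited file with columns `gene`, `variant_class`
#'   (`pLoF` or `missense`), `de_novo` (TRUE/FALSE), and
#'   `high_level_phenotypes` (comma-separated system-level term IDs).
#' @return Tibble with one row per record; `high_level_phenotypes` is a
#'   list-column of character vectors.
#' @export
read_external_db <- function(path) {
  assert_file(path, "external phenotype database")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  need <- c("gene", "variant_class", "de_novo", "high_level_phenotypes")
  if (!all(need %in% names(df))) {
    abort(sprintf("external database must have columns %s",
                  paste(need, collapse = ", ")))
  }
  if (!all(df$variant_class %in% c("pLoF", "missense"))) {
    abort("external database variant_class must be 'pLoF' or 'missense'")
  }
  tibble(
    gene = df$gene,
    variant_class = df$variant_class,
    de_novo = toupper(df$de_novo) %in% c("TRUE", "T", "1", "YES"),
    high_level_phenotypes = purrr::map(
      ifelse(is.na(df$high_level_phenotypes), "", df$high_level_phenotypes),
      function(x) {
        v <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
        v[v != ""]
      })
  )
}

#' Read transcript exon models
#'
#' @param path Tab-delimited file with columns `transcript_id`, `gene`,
#'   `chrom`, `strand`, `exon_start`, `exon_end` (1-based inclusive), one
#'   row per exon. Exons are re-sorted into transcription order (ascending
#'   coordinates on `+`, descending on `-`).
#' @return Tibble, one row per exon, with an `exon_index` column numbering
#'   exons in transcription order.
#' @export
read_transcripts <- function(path) {
  assert_file(path, "transcript model")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("transcript_id", "gene", "chrom", "strand", "exon_start", "exon_end")
  if (!all(need %in% names(df))) {
    abort(sprintf("transcript table must have columns %s",
                  paste(need, collapse = ", ")))
  }
  if (!all(df$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(df$exon_start < 1L | df$exon_end < df$exon_start)) {
    abort("exon coordinates must be positive with end >= start")
  }
  out <- df %>%
    mutate(chrom = as.character(.data$chrom),
           exon_start = as.integer(.data$exon_start),
           exon_end = as.integer(.data$exon_end)) %>%
    group_by(.data$transcript_id) %>%
    arrange(ifelse(.data$strand == "+", 1L, -1L) * .data$exon_start,
            .by_group = TRUE) %>%
    mutate(exon_index = row_number(), n_exons = n()) %>%
    ungroup() %>%
    select(dplyr::all_of(need), "exon_index", "n_exons")
  overlaps <- out %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$exon_start, .by_group = TRUE) %>%
    summarise(bad = any(.data$exon_start[-1] <= head(.data$exon_end, -1)),
              .groups = "drop")
  if (any(overlaps$bad)) {
    abort(sprintf("overlapping exons in transcript %s",
                  overlaps$transcript_id[overlaps$bad][1]))
  }
  out
}

# ---- writers (round-trip counterparts used by the generator and pipeline) ----

#' Write tables in the formats the readers accept
#'
#' Each writer is the exact inverse of its reader so that write-then-read
#' round-trips reproduce the in-memory structure.
#'
#' @param x Table to write (see the corresponding reader for its shape).
#' @param path Output path.
#' @return `path`, invisibly.
#' @name cohort_writers
NULL

#' @rdname cohort_writers
#' @export
write_constraint <- function(x, path) {
  readr::write_tsv(tibble(gene = x$gene, oe_lof_upper = x$loeuf), path)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_known_genes <- function(x, path) {
  readr::write_tsv(x[, c("gene", "inheritance")], path)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_phenotypes <- function(x, path) {
  wide <- x %>%
    group_by(.data$patient_id) %>%
    summarise(hpo_terms = paste(sort(.data$term), collapse = ","),
              .groups = "drop")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_external_db <- function(x, path) {
  flat <- x %>%
    mutate(high_level_phenotypes = purrr::map_chr(
      .data$high_level_phenotypes, paste, collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_transcripts <- function(x, path) {
  readr::write_tsv(
    x[, c("transcript_id", "gene", "chrom", "strand", "exon_start", "exon_end")],
    path)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_pedigree <- function(x, path) {
  # children plus synthesized parent rows; sex unknown (0) where not tracked
  rows <- c(
    sprintf("%s\t%s\t%s\t%s\t0\t%d", x$family_id, x$child_id, x$father_id,
            x$mother_id, ifelse(x$child_affected, 2L, 1L)),
    sprintf("%s\t%s\t0\t0\t1\t1", x$family_id, x$father_id),
    sprintf("%s\t%s\t0\t0\t2\t1", x$family_id, x$mother_id)
  )
  writeLines(rows, path)
  invisible(path)
}
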