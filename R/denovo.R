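#' Quality and genotype gates for trio de novo calling
#'
#' Thresholds applied on top of the basic trio genotype configuration
#' (child heterozygous, both parents homozygous reference). The variant
#' caller that produced the genotypes is assumed to have done its own
#' upstream QC; these gates guard the de novo configuration specifically.
#'
#' @param min_gq Minimum genotype quality for the child (and, when
#'   `require_parent_hom_ref_gq`, for each parent). Default 20.
#' @param min_dp Minimum read depth for the child. Default 10.
#' @param ab_range Inclusive allele-balance interval for the child's ALT
#'   reads when AD is available. Default `c(0.2, 0.8)`.
#' @param require_parent_hom_ref_gq Require parental GQ at or above
#'   `min_gq` to trust the hom-ref calls. Default `TRUE`.
#' @param max_parent_alt_frac A parent with more than this fraction of ALT
#'   reads (when AD is available) fails the hom-ref gate, guarding against
#'   under-called parental mosaicism. Default 0.05.
#' @param exclude_nonautosomes Drop variants outside chromosomes 1-22
#'   before calling. Default `FALSE` (diploid logic applied everywhere).
#' @return A `dn_config` list.
#' @export
dn_config <- function(min_gq = 20, min_dp = 10, ab_range = c(0.2, 0.8),
                      require_parent_hom_ref_gq = TRUE,
                      max_parent_alt_frac = 0.05,
                      exclude_nonautosomes = FALSE) {
  stopifnot(length(ab_range) == 2L, ab_range[1] >= 0, ab_range[2] <= 1,
            ab_range[1] < ab_range[2], min_gq >= 0, min_dp >= 0)
  structure(list(
    min_gq = min_gq, min_dp = min_dp, ab_range = ab_range,
    require_parent_hom_ref_gq = require_parent_hom_ref_gq,
    max_parent_alt_frac = max_parent_alt_frac,
    exclude_nonautosomes = exclude_nonautosomes
  ), class = "dn_config")
}

# vectorized gate logic over a joined (variant unit x trio) frame with
# columns child_gt/.., child_gq, child_dp, child_ad_ref, child_ad_alt,
# father_gq, mother_gq, father_ad_ref/alt, mother_ad_ref/alt.
# Returns the frame with `denovo` (lgl), `reason` (chr), `child_ab` (dbl).
denovo_gate <- function(df, config) {
  nr <- nrow(df)
  reason <- rep(NA_character_, nr)
  set <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason <<- ifelse(is.na(reason) & cond, code, reason)
  }
  miss <- gt_is_missing(df$child_gt) | gt_is_missing(df$father_gt) |
    gt_is_missing(df$mother_gt)
  set(miss, "missing_gt")
  set(!gt_is_het_alt(df$child_gt), "child_not_het")
  set(gt_has_alt(df$father_gt) | gt_has_alt(df$mother_gt), "inherited")
  set(!is.na(df$child_gq) & df$child_gq < config$min_gq, "child_gq")
  set(!is.na(df$child_dp) & df$child_dp < config$min_dp, "child_dp")
  ab <- ifelse(!is.na(df$child_ad_ref) & !is.na(df$child_ad_alt) &
                 (df$child_ad_ref + df$child_ad_alt) > 0,
               df$child_ad_alt / (df$child_ad_ref + df$child_ad_alt), NA_real_)
  set(!is.na(ab) & (ab < config$ab_range[1] | ab > config$ab_range[2]),
      "child_ab")
  if (isTRUE(config$require_parent_hom_ref_gq)) {
    set((!is.na(df$father_gq) & df$father_gq < config$min_gq) |
          (!is.na(df$mother_gq) & df$mother_gq < config$min_gq), "parent_gq")
  }
  pfrac <- function(r, a) {
    ifelse(!is.na(r) & !is.na(a) & (r + a) > 0, a / (r + a), NA_real_)
  }
  ff <- pfrac(df$father_ad_ref, df$father_ad_alt)
  mf <- pfrac(df$mother_ad_ref, df$mother_ad_alt)
  set((!is.na(ff) & ff > config$max_parent_alt_frac) |
        (!is.na(mf) & mf > config$max_parent_alt_frac), "parent_alt_reads")
  df$denovo <- unname(is.na(reason))
  df$reason <- unname(ifelse(is.na(reason), "pass", reason))
  df$child_ab <- unname(ab)
  df
}

#' Decide whether a single trio genotype configuration is de novo
#'
#' A call is de novo when the child is heterozygous for the ALT allele,
#' both parents are homozygous reference, and all configured quality gates
#' pass. Otherwise the reason code names the first failed gate, in the
#' order: `missing_gt`, `child_not_het`, `inherited`, `child_gq`,
#' `child_dp`, `child_ab`, `parent_gq`, `parent_alt_reads`.
#'
#' @param child_gt,father_gt,mother_gt Genotype strings (`"0/1"`, `"0|0"`,
#'   `"./."`, ...).
#' @param quality Named list of optional quality fields: `child_gq`,
#'   `child_dp`, `child_ad_ref`, `child_ad_alt`, `father_gq`, `mother_gq`,
#'   `father_ad_ref`, `father_ad_alt`, `mother_ad_ref`, `mother_ad_alt`.
#'   Absent fields skip their gate.
#' @param config A [dn_config()].
#' @return List with `denovo` (logical) and `reason` (character).
#' @export
is_denovo <- function(child_gt, father_gt, mother_gt, quality = list(),
                      config = dn_config()) {
  q <- function(f) {
    v <- quality[[f]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  df <- tibble(
    child_gt = child_gt, father_gt = father_gt, mother_gt = mother_gt,
    child_gq = q("child_gq"), child_dp = q("child_dp"),
    child_ad_ref = q("child_ad_ref"), child_ad_alt = q("child_ad_alt"),
    father_gq = q("father_gq"), mother_gq = q("mother_gq"),
    father_ad_ref = q("father_ad_ref"), father_ad_alt = q("father_ad_alt"),
    mother_ad_ref = q("mother_ad_ref"), mother_ad_alt = q("mother_ad_alt")
  )
  res <- denovo_gate(df, config)
  list(denovo = res$denovo, reason = res$reason)
}

#' Call de novo events across a cohort of trios
#'
#' Evaluates every (variant unit, trio) pair against [is_denovo()]'s gates.
#' Trios with a member absent from the VCF sample set are skipped with a
#' warning. Output order is deterministic: chromosome, position, ALT
#' allele, child ID.
#'
#' @param vcf A `trio_vcf` from [read_variants()], or a list with `sites`
#'   and `genotypes` tibbles of that shape.
#' @param trios Trio table from [read_pedigree()].
#' @param config A [dn_config()].
#' @return Tibble of events: `variant_key`, `chrom`, `pos`, `ref`, `alt`,
#'   `family_id`, `child_id`, `child_gt`, `child_gq`, `child_dp`,
#'   `child_ab`. The companion audit of near-misses (child carries the ALT
#'   allele but a gate failed) is attached as attribute `audit` and
#'   retrievable with [denovo_audit()].
#' @export
call_denovos <- function(vcf, trios, config = dn_config()) {
  sites <- vcf$sites
  geno <- vcf$genotypes
  if (isTRUE(config$exclude_nonautosomes)) {
    sites <- filter(sites, .data$chrom %in% autosomes())
  }
  sample_set <- unique(geno$sample_id)
  complete <- trios$child_id %in% sample_set &
    trios$father_id %in% sample_set & trios$mother_id %in% sample_set
  if (any(!complete)) {
    warn(sprintf("%d trio(s) skipped: member(s) absent from VCF samples",
                 sum(!complete)))
    trios <- trios[complete, , drop = FALSE]
  }
  empty <- tibble(
    variant_key = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), family_id = character(),
    child_id = character(), child_gt = character(), child_gq = double(),
    child_dp = double(), child_ab = double()
  )
  if (nrow(trios) == 0L || nrow(sites) == 0L) {
    attr(empty, "audit") <- tibble(variant_key = character(),
                                   child_id = character(), reason = character())
    return(empty)
  }
  member <- function(role, ids) {
    geno %>%
      filter(.data$sample_id %in% ids) %>%
      rename_with_prefix(role)
  }
  pairs <- cross_join(sites, trios)
  joined <- pairs %>%
    inner_join(member("child", unique(trios$child_id)),
               by = c(variant_key = "variant_key", child_id = "child_sample_id")) %>%
    inner_join(member("father", unique(trios$father_id)),
               by = c(variant_key = "variant_key", father_id = "father_sample_id")) %>%
    inner_join(member("mother", unique(trios$mother_id)),
               by = c(variant_key = "variant_key", mother_id = "mother_sample_id"))
  res <- denovo_gate(joined, config) %>%
    arrange(chrom_rank(.data$chrom), .data$pos, .data$alt, .data$child_id)
  events <- res %>%
    filter(.data$denovo) %>%
    select("variant_key", "chrom", "pos", "ref", "alt", "family_id",
           "child_id", "child_gt", "child_gq", "child_dp", "child_ab")
  audit <- res %>%
    filter(!.data$denovo, gt_has_alt(.data$child_gt)) %>%
    select("variant_key", "chrom", "pos", "family_id", "child_id", "reason")
  attr(events, "audit") <- audit
  events
}

# rename genotype columns with a role prefix for trio-wise joins
rename_with_prefix <- function(df, role) {
  names(df) <- ifelse(names(df) == "variant_key", "variant_key",
                      paste0(role, "_", names(df)))
  df
}

#' Retrieve the near-miss audit attached to a de novo call set
#'
#' @param events Result of [call_denovos()].
#' @return Tibble of excluded (variant, child) pairs where the child
#'   carries the ALT allele, with the first failed gate as `reason`.
#' @export
denovo_audit <- function(events) {
  attr(events, "audit") %||%
    tibble(variant_key = character(), child_id = character(),
           reason = character())
}
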