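# shared internal helpers

# valid HPO identifier: "HP:" + 7 digits
is_hpo_id <- function(x) grepl("^HP:\\d{7}$", x)

assert_file <- function(path, what) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, as.character(path)[1]))
  }
  invisible(path)
}

# variant unit identity used everywhere downstream
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# parse "a/b" or "a|b" genotype strings into a two-column integer matrix;
# missing alleles (".") become NA
parse_gt <- function(gt) {
  gt <- ifelse(is.na(gt) | gt == "", "./.", gt)
  parts <- stringr::str_split_fixed(gt, "[/|]", 2)
  a1 <- suppressWarnings(as.integer(parts[, 1]))
  a2 <- suppressWarnings(as.integer(parts[, 2]))
  cbind(a1, a2)
}

gt_is_missing <- function(gt) {
  al <- parse_gt(gt)
  is.na(al[, 1]) | is.na(al[, 2])
}

gt_has_alt <- function(gt) {
  al <- parse_gt(gt)
  (al[, 1] > 0 | al[, 2] > 0) & !(is.na(al[, 1]) | is.na(al[, 2]))
}

gt_is_het_alt <- function(gt) {
  al <- parse_gt(gt)
  !is.na(al[, 1]) & !is.na(al[, 2]) & ((al[, 1] == 0 & al[, 2] == 1) |
    (al[, 1] == 1 & al[, 2] == 0))
}

gt_is_hom_ref <- function(gt) {
  al <- parse_gt(gt)
  !is.na(al[, 1]) & !is.na(al[, 2]) & al[, 1] == 0 & al[, 2] == 0
}

autosomes <- function() c(as.character(1:22), paste0("chr", 1:22))

# deterministic chromosome sort key (1..22, X, Y, MT, then lexicographic)
chrom_rank <- function(chrom) {
  stripped <- sub("^chr", "", chrom)
  ord <- c(as.character(1:22), "X", "Y", "MT", "M")
  r <- match(stripped, ord)
  ifelse(is.na(r), 100L + as.integer(factor(stripped)), r)
}
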