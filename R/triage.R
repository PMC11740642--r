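#' Rarity and constraint gate thresholds
#'
#' Both gates are strict inequalities: an event survives when its maximum
#' population allele frequency is strictly below `af_max` *and* its gene's
#' LOEUF score is strictly below `loeuf_max`. A gene absent from the
#' constraint table can never satisfy the constraint gate.
#'
#' @param af_max Maximum population AF cut-off. Default 0.001.
#' @param loeuf_max LOEUF cut-off; 0.2 is the first decile of the gnomAD
#'   v2.1.1 distribution, the genes most intolerant to inactivation.
#' @return A `filter_config` list.
#' @export
filter_config <- function(af_max = 0.001, loeuf_max = 0.2) {
  stopifnot(af_max > 0, af_max <= 1, loeuf_max > 0, loeuf_max <= 1)
  structure(list(af_max = af_max, loeuf_max = loeuf_max),
            class = "filter_config")
}

#' Maximum allele frequency across populations
#'
#' Absent populations are unobserved and contribute 0, so a variant seen
#' in no reference population ("Absent") has a maximum frequency of 0.
#'
#' @param pop_afs Named (or unnamed) numeric vector of per-population
#'   allele fractions; may be empty; `NA` entries are unobserved.
#' @return A single number in \[0, 1\].
#' @export
max_population_af <- function(pop_afs) {
  pop_afs <- unlist(pop_afs, use.names = FALSE)
  pop_afs <- pop_afs[!is.na(pop_afs)]
  if (length(pop_afs) == 0L) return(0)
  if (any(pop_afs < 0 | pop_afs > 1)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  max(pop_afs)
}

# row-wise max over af_* columns, NA treated as unobserved (0)
max_af_column <- function(df) {
  af_cols <- grep("^af_", names(df), value = TRUE)
  if (length(af_cols) == 0L) return(rep(0, nrow(df)))
  m <- as.matrix(df[, af_cols])
  m[is.na(m)] <- 0
  if (any(m < 0 | m > 1)) abort("allele frequencies must lie in [0, 1]")
  apply(m, 1L, max)
}

# one funnel row from a set of surviving event rows; events are counted
# per (variant unit, child) so the funnel is monotone even when a variant
# annotates several genes
funnel_row <- function(stage, df) {
  has_gene <- "gene" %in% names(df)
  ev <- distinct(df, .data$variant_key, .data$child_id)
  tibble(
    stage = stage,
    n_events = nrow(ev),
    n_genes = if (has_gene) n_distinct(df$gene[!is.na(df$gene)]) else NA_integer_,
    n_patients = n_distinct(df$child_id)
  )
}

#' Apply the allele-frequency and LOEUF gates
#'
#' Events are first reduced to one row per (variant unit, child, gene) —
#' a variant passing on several transcripts of one gene is a single event,
#' while transcripts of different genes contribute one event per gene.
#' Then the strict AF and constraint gates are applied.
#'
#' @param events High-confidence pLoF event rows (from
#'   [filter_high_confidence()]); must carry `gene` and `af_*` columns.
#' @param constraint Constraint table from [read_constraint()].
#' @param config A [filter_config()].
#' @return Retained events with added `max_af` and `loeuf` columns.
#'   Attributes: `funnel` (tibble of stage counts) and `n_no_loeuf`
#'   (events dropped because their gene has no constraint score).
#' @export
apply_gates <- function(events, constraint, config = filter_config()) {
  events <- events %>% mutate(max_af = max_af_column(events))
  dedup <- events %>%
    group_by(.data$variant_key, .data$child_id, .data$gene) %>%
    summarise(across(dplyr::any_of(c("chrom", "ref", "alt", "family_id",
                                     "consequence", "transcript_id")), first),
              pos = first(.data$pos), max_af = max(.data$max_af),
              .groups = "drop") %>%
    arrange(chrom_rank(.data$chrom), .data$pos, .data$alt, .data$child_id,
            .data$gene)
  rare <- dedup %>% filter(.data$max_af < config$af_max)
  withloeuf <- rare %>% inner_join(constraint, by = "gene")
  retained <- withloeuf %>% filter(.data$loeuf < config$loeuf_max)
  funnel <- bind_rows(
    funnel_row("high_confidence_plof", dedup),
    funnel_row(sprintf("rare_af_lt_%g", config$af_max), rare),
    funnel_row(sprintf("constrained_loeuf_lt_%g", config$loeuf_max), retained)
  )
  attr(retained, "funnel") <- funnel
  attr(retained, "n_no_loeuf") <- nrow(rare) - nrow(withloeuf)
  retained
}

#' Split retained events into known disease genes and novel contenders
#'
#' A gene is "known" when it appears in the knowledge snapshot with *any*
#' inheritance mode — dominant, recessive or other all exclude a gene from
#' contention, since the aim is genes with no disease association at all.
#'
#' @param retained Gated events from [apply_gates()].
#' @param known Known-gene snapshot from [read_known_genes()].
#' @return List with `known_events`, `contender_events` (a partition of
#'   `retained`) and `contender_genes` (deduplicated, sorted).
#' @export
triage_genes <- function(retained, known) {
  is_known <- retained$gene %in% known$gene
  list(
    known_events = retained[is_known, , drop = FALSE],
    contender_events = retained[!is_known, , drop = FALSE],
    contender_genes = sort(unique(retained$gene[!is_known]))
  )
}
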