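#' Declarative pipeline configuration
#'
#' All inputs and thresholds for a run, auditable in one object. Accepts a
#' YAML file path or a named list; missing parameters take the package
#' defaults.
#'
#' @param vcf,pedigree,constraint,known_genes,transcripts Required input
#'   paths (trio VCF, PED file, LOEUF table, known-gene snapshot at the
#'   analysis date, exon models).
#' @param phenotypes,ontology,external_db Paths needed for classification.
#' @param known_genes_t1,literature_t1 Later knowledge snapshot and
#'   literature-only gene list (one symbol per line), needed for
#'   validation.
#' @param fasta Optional reference FASTA for the splice dinucleotide check.
#' @param af_max,loeuf_max Gate thresholds (see [filter_config()]).
#' @param min_gq,min_dp,ab_range,require_parent_hom_ref_gq,max_parent_alt_frac,exclude_nonautosomes
#'   De novo gates (see [dn_config()]).
#' @param anchor Ontology anchor term for system-level upscaling.
#' @param snapshot_t0,snapshot_t1 Labels for the two knowledge snapshots.
#' @param alt_diagnoses Character vector of patient IDs with alternative
#'   diagnoses (echoed into the validation summary).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf = NULL, pedigree = NULL, constraint = NULL,
                            known_genes = NULL, transcripts = NULL,
                            phenotypes = NULL, ontology = NULL,
                            external_db = NULL, known_genes_t1 = NULL,
                            literature_t1 = NULL, fasta = NULL,
                            af_max = 0.001, loeuf_max = 0.2,
                            min_gq = 20, min_dp = 10, ab_range = c(0.2, 0.8),
                            require_parent_hom_ref_gq = TRUE,
                            max_parent_alt_frac = 0.05,
                            exclude_nonautosomes = FALSE,
                            anchor = "HP:0000118",
                            snapshot_t0 = "T0", snapshot_t1 = "T1",
                            alt_diagnoses = character()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param x A YAML path, named list, or `pipeline_config`.
#' @export
as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  if (is.character(x) && length(x) == 1L) {
    assert_file(x, "pipeline config")
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) abort("config must be a pipeline_config, list or YAML path")
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(x), known)
  if (length(extra) > 0L) {
    abort(sprintf("unknown config field(s): %s", paste(extra, collapse = ", ")))
  }
  do.call(pipeline_config, x)
}

#' Configuration for a synthetic cohort bundle directory
#'
#' @param dir Directory written by [simulate_cohort()].
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config` pointing at the bundle's files.
#' @export
bundle_config <- function(dir, ...) {
  p <- function(f) file.path(dir, f)
  pipeline_config(
    vcf = p("cohort.vcf"), pedigree = p("pedigree.ped"),
    constraint = p("constraint.tsv"), known_genes = p("known_genes_t0.tsv"),
    known_genes_t1 = p("known_genes_t1.tsv"),
    literature_t1 = p("literature_t1.txt"),
    phenotypes = p("phenotypes.tsv"), ontology = p("ontology.obo"),
    external_db = p("external_db.tsv"), transcripts = p("transcripts.tsv"),
    ...
  )
}

pipeline_stages <- function() {
  c("denovo", "plof", "confidence", "gates", "triage", "classify", "validate")
}

check_config_inputs <- function(config, last_stage) {
  need <- c("vcf", "pedigree", "transcripts")
  rank <- match(last_stage, pipeline_stages())
  if (rank >= match("gates", pipeline_stages())) need <- c(need, "constraint")
  if (rank >= match("triage", pipeline_stages())) need <- c(need, "known_genes")
  if (rank >= match("classify", pipeline_stages())) {
    need <- c(need, "phenotypes", "ontology", "external_db")
  }
  if (rank >= match("validate", pipeline_stages())) need <- c(need, "known_genes_t1")
  for (f in need) {
    if (is.null(config[[f]])) {
      abort(sprintf("config is missing required input '%s' for stage '%s'",
                    f, last_stage))
    }
    assert_file(config[[f]], f)
  }
  invisible(need)
}

#' Run the gene-to-patient discovery pipeline end to end
#'
#' Fixed stage order: de novo calling, pLoF selection, LoF-confidence
#' filtering, allele-frequency/LOEUF gating, known-gene triage, phenotype
#' classification, and (when a later snapshot is configured) validation.
#' All tabular outputs are written deterministically so identical inputs
#' give byte-identical files.
#'
#' @param config A [pipeline_config()], list or YAML path.
#' @param out_dir Output directory; created if needed. `NULL` skips
#'   writing files.
#' @param stop_after Optional stage name after which to stop (one of
#'   `r paste(pipeline_stages(), collapse = ", ")`).
#' @return An object of class `g2p_result` holding every intermediate:
#'   `trios`, `events` (+audit), `annotated`, `calls`, `high_conf`,
#'   `retained`, `triage`, `funnel`, `candidates`, `validation`,
#'   `event_fates`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, stop_after = NULL) {
  config <- as_pipeline_config(config)
  last_stage <- stop_after %||% "validate"
  if (!last_stage %in% pipeline_stages()) {
    abort(sprintf("unknown stage '%s'", last_stage))
  }
  if (is.null(config$known_genes_t1) && is.null(stop_after)) {
    last_stage <- "classify"
  }
  rank <- match(last_stage, pipeline_stages())
  check_config_inputs(config, last_stage)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tic <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  res <- list(config = config)
  class(res) <- "g2p_result"

  dn_cfg <- dn_config(
    min_gq = config$min_gq, min_dp = config$min_dp,
    ab_range = config$ab_range,
    require_parent_hom_ref_gq = config$require_parent_hom_ref_gq,
    max_parent_alt_frac = config$max_parent_alt_frac,
    exclude_nonautosomes = config$exclude_nonautosomes
  )
  fc <- filter_config(af_max = config$af_max, loeuf_max = config$loeuf_max)

  trios <- read_pedigree(config$pedigree)
  vcf <- read_variants(config$vcf)
  transcripts <- read_transcripts(config$transcripts)
  res$trios <- trios

  events <- tic("denovo", call_denovos(vcf, trios, dn_cfg))
  ann_all <- annotate_events(events, vcf$variants)
  res$events <- events
  res$annotated <- ann_all
  funnel <- tibble(
    stage = "de_novo",
    n_events = nrow(distinct(events, .data$variant_key, .data$child_id)),
    n_genes = n_distinct(ann_all$gene[!is.na(ann_all$gene)]),
    n_patients = n_distinct(events$child_id)
  )
  if (rank >= 2L) {
    ann_plof <- ann_all %>% filter(is_plof(.data$consequence))
    funnel <- bind_rows(funnel, funnel_row("plof", ann_plof))
  }
  if (rank >= 3L) {
    calls <- tic("confidence",
                 assess_lof_confidence(ann_plof, transcripts,
                                       fasta = config$fasta))
    high <- filter_high_confidence(calls)
    res$calls <- calls
    res$high_conf <- high
    funnel <- bind_rows(funnel, funnel_row("high_confidence", high))
  }
  if (rank >= 4L) {
    constraint <- read_constraint(config$constraint)
    retained <- tic("gates", apply_gates(high, constraint, fc))
    res$retained <- retained
    res$constraint <- constraint
    funnel <- bind_rows(funnel, attr(retained, "funnel")[-1, ])
  }
  if (rank >= 5L) {
    known_t0 <- read_known_genes(config$known_genes,
                                 snapshot = config$snapshot_t0)
    tri <- tic("triage", triage_genes(retained, known_t0))
    res$known_t0 <- known_t0
    res$triage <- tri
    res$event_fates <- compute_event_fates(res, constraint, known_t0, fc)
  }
  if (rank >= 6L) {
    phenotypes <- read_phenotypes(config$phenotypes)
    dag <- read_ontology(config$ontology, anchor = config$anchor)
    external_db <- read_external_db(config$external_db)
    candidates <- tic("classify",
                      classify_all(tri$contender_events, phenotypes,
                                   external_db, dag))
    res$phenotypes <- phenotypes
    res$dag <- dag
    res$candidates <- candidates
  }
  if (rank >= 7L) {
    known_t1 <- read_known_genes(config$known_genes_t1,
                                 snapshot = config$snapshot_t1)
    literature <- if (!is.null(config$literature_t1) &&
                      file.exists(config$literature_t1)) {
      readLines(config$literature_t1)
    } else character()
    marked <- mark_published(candidates, known_t1, literature)
    res$candidates <- marked
    res$validation <- tic("validate",
                          summarize_validation(marked, config$alt_diagnoses))
  }
  res$funnel <- structure(funnel, class = c("g2p_funnel", class(funnel)))
  res$timings <- timings
  if (!is.null(out_dir)) {
    write_pipeline_outputs(res, out_dir, rank)
  }
  res
}

# realized per-(variant, child) filter fate from pipeline intermediates;
# when a variant spans genes the furthest-surviving fate is reported
compute_event_fates <- function(res, constraint, known_t0, fc) {
  audit <- denovo_audit(res$events)
  fates <- list()
  if (nrow(audit) > 0L) {
    fates[[1]] <- audit %>%
      distinct(.data$variant_key, .data$child_id) %>%
      mutate(fate = "fail-denovo")
  }
  ev <- distinct(res$events, .data$variant_key, .data$child_id)
  ann <- res$annotated
  plof_keys <- ann %>%
    filter(is_plof(.data$consequence)) %>%
    distinct(.data$variant_key, .data$child_id)
  fates[[length(fates) + 1L]] <- ev %>%
    anti_join(plof_keys, by = c("variant_key", "child_id")) %>%
    mutate(fate = "fail-not-plof")
  calls <- res$calls
  evaluable <- calls %>% filter(.data$evaluable)
  high_keys <- evaluable %>%
    filter(.data$confidence == "HIGH") %>%
    distinct(.data$variant_key, .data$child_id)
  fates[[length(fates) + 1L]] <- plof_keys %>%
    anti_join(high_keys, by = c("variant_key", "child_id")) %>%
    mutate(fate = ifelse(
      paste(.data$variant_key, .data$child_id) %in%
        paste(evaluable$variant_key, evaluable$child_id),
      "fail-LOW-confidence", "fail-unevaluable"))
  high <- res$high_conf %>%
    mutate(max_af = max_af_column(res$high_conf)) %>%
    group_by(.data$variant_key, .data$child_id, .data$gene) %>%
    summarise(max_af = max(.data$max_af), .groups = "drop") %>%
    left_join(constraint, by = "gene") %>%
    mutate(gene_fate = dplyr::case_when(
      max_af >= fc$af_max ~ "fail-AF",
      is.na(loeuf) | loeuf >= fc$loeuf_max ~ "fail-LOEUF",
      gene %in% known_t0$gene ~ "fail-known-gene",
      TRUE ~ "pass"
    ))
  precedence <- c("fail-AF", "fail-LOEUF", "fail-known-gene", "pass")
  fates[[length(fates) + 1L]] <- high %>%
    mutate(rank = match(.data$gene_fate, precedence)) %>%
    group_by(.data$variant_key, .data$child_id) %>%
    summarise(fate = precedence[max(.data$rank)], .groups = "drop")
  bind_rows(fates) %>%
    arrange(.data$variant_key, .data$child_id)
}

write_pipeline_outputs <- function(res, out_dir, rank) {
  p <- function(f) file.path(out_dir, f)
  ev_out <- res$events
  if (!is.null(res$annotated)) {
    first_ann <- res$annotated %>%
      group_by(.data$variant_key, .data$child_id) %>%
      summarise(gene = paste(sort(unique(.data$gene)), collapse = ","),
                consequence = paste(sort(unique(.data$consequence)),
                                    collapse = ","),
                .groups = "drop")
    ev_out <- ev_out %>%
      left_join(first_ann, by = c("variant_key", "child_id"))
  }
  readr::write_tsv(ev_out, p("denovo_events.tsv"))
  readr::write_tsv(denovo_audit(res$events), p("denovo_audit.tsv"))
  readr::write_tsv(res$funnel, p("funnel.tsv"))
  if (!is.null(res$triage)) {
    readr::write_tsv(tibble(gene = res$triage$contender_genes),
                     p("contender_genes.tsv"))
    readr::write_tsv(res$event_fates, p("event_fates.tsv"))
  }
  if (!is.null(res$candidates) && rank >= 6L) {
    flat <- res$candidates %>%
      mutate(shared_terms = purrr::map_chr(.data$shared_terms, paste,
                                           collapse = ","),
             external_systems = purrr::map_chr(.data$external_systems, paste,
                                               collapse = ","))
    readr::write_tsv(flat, p("candidates.tsv"))
  }
  if (!is.null(res$validation)) {
    v <- res$validation
    jsonlite::write_json(list(
      per_class = as.data.frame(v$per_class),
      overall = v$overall,
      fisher_class1_vs_rest = v$fisher_class1_vs_rest,
      fisher_class3_vs_class2 = v$fisher_class3_vs_class2,
      alternative_diagnosis_patients = v$alternative_diagnosis_patients
    ), p("validation_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  }
  cfg <- res$config
  inputs <- purrr::compact(cfg[c("vcf", "pedigree", "constraint",
                                 "known_genes", "known_genes_t1",
                                 "literature_t1", "phenotypes", "ontology",
                                 "external_db", "transcripts", "fasta")])
  manifest <- list(
    package = "triolof",
    version = as.character(utils::packageVersion("triolof")),
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    stage_timings_s = res$timings,
    decisions = c(
      "events counted once per (variant unit, child) per gene; multiple transcripts of one gene collapse to a single event",
      "genes without a LOEUF score cannot pass the constraint gate",
      "known-gene exclusion uses any inheritance mode"
    )
  )
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.g2p_result <- function(x, ...) {
  cat("gene-to-patient pipeline result\n")
  if (!is.null(x$funnel)) {
    cat("filter funnel:\n")
    f <- x$funnel
    for (i in seq_len(nrow(f))) {
      cat(sprintf("  %-28s %5d events %5s genes %5d patients\n", f$stage[i],
                  f$n_events[i],
                  ifelse(is.na(f$n_genes[i]), "-", f$n_genes[i]),
                  f$n_patients[i]))
    }
  }
  if (!is.null(x$candidates)) {
    tal <- attr(x$candidates, "tally")
    if (!is.null(tal)) {
      cat(sprintf("candidate classes: %s\n",
                  paste(sprintf("class %d: %d", tal$gene_class, tal$n_genes),
                        collapse = ", ")))
    }
  }
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}
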