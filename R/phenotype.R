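#' Exact HPO term overlap between two phenotype profiles
#'
#' Plain set intersection of term identifiers: no credit is given for
#' ancestor/descendant relationships, so e.g. intellectual disability
#' (HP:0001249) does not match mild intellectual disability (HP:0001256).
#'
#' @param a,b Character vectors of HPO term IDs (a patient's profile).
#' @return Character vector of shared term IDs (sorted).
#' @export
exact_hpo_overlap <- function(a, b) {
  sort(intersect(unique(a), unique(b)))
}

#' Upscale a phenotype profile to organ-system-level terms
#'
#' Maps each term to the system-level vocabulary (the direct children of
#' the DAG's anchor term) it falls under, following `is_a` edges; a term
#' lying under several systems contributes all of them, and a term that
#' *is* a system term contributes itself. Terms unknown to the ontology
#' are skipped with a message.
#'
#' @param terms Character vector of HPO term IDs.
#' @param dag An `hpo_dag` from [read_ontology()].
#' @return Sorted character vector of system-level term IDs.
#' @export
upscale_to_systems <- function(terms, dag) {
  stopifnot(inherits(dag, "hpo_dag"))
  terms <- unique(terms)
  unknown <- terms[!terms %in% dag$terms$id]
  if (length(unknown) > 0L) {
    inform(sprintf("%d term(s) not in ontology skipped during upscaling",
                   length(unknown)))
  }
  hits <- lapply(setdiff(terms, unknown), function(t) {
    intersect(dag$ancestors[[t]], dag$system_terms)
  })
  sort(unique(unlist(hits)))
}

#' Classify one candidate gene into evidence class 1, 2 or 3
#'
#' * **Class 1**: pLoF events in two or more unrelated kindreds and at
#'   least one pair of affected children from *different* families shares
#'   at least one exact HPO term.
#' * **Class 2**: otherwise, some kindred's organ-system-level phenotypes
#'   intersect the high-level phenotypes of at least one external de novo
#'   record (pLoF or missense) for the same gene. Multi-kindred genes that
#'   fail the internal match fall through to this external test.
#' * **Class 3**: neither form of support.
#'
#' @param gene Gene symbol.
#' @param kindred_profiles Tibble with one row per carrier child:
#'   `family_id`, `child_id`, `terms` (list-column of HPO IDs).
#' @param external_records External database rows for this gene
#'   (shape of [read_external_db()]); only `de_novo = TRUE` records of
#'   class pLoF/missense count.
#' @param dag An `hpo_dag` for upscaling.
#' @return One-row tibble: `gene`, `gene_class`, `n_kindreds`,
#'   `shared_terms` (list), `external_systems` (list of system terms shared
#'   with external records), `n_external_matches`.
#' @export
classify_gene <- function(gene, kindred_profiles, external_records = NULL, dag) {
  stopifnot(nrow(kindred_profiles) >= 1L)
  fams <- unique(kindred_profiles$family_id)
  shared <- character()
  if (length(fams) >= 2L) {
    # any cross-family pair of affected children sharing >= 1 exact term
    rows <- seq_len(nrow(kindred_profiles))
    for (i in rows) for (j in rows) {
      if (j <= i) next
      if (kindred_profiles$family_id[i] == kindred_profiles$family_id[j]) next
      shared <- union(shared, exact_hpo_overlap(
        kindred_profiles$terms[[i]], kindred_profiles$terms[[j]]))
    }
  }
  if (length(fams) >= 2L && length(shared) > 0L) {
    return(tibble(
      gene = gene, gene_class = 1L, n_kindreds = length(fams),
      shared_terms = list(sort(shared)), external_systems = list(character()),
      n_external_matches = 0L
    ))
  }
  ext_systems <- character(); n_matches <- 0L
  if (!is.null(external_records) && nrow(external_records) > 0L) {
    recs <- external_records %>%
      filter(.data$gene == !!gene, .data$de_novo,
             .data$variant_class %in% c("pLoF", "missense"))
    if (nrow(recs) > 0L) {
      # per-kindred upscaled systems: union over that family's carriers
      fam_systems <- lapply(fams, function(f) {
        terms <- unlist(kindred_profiles$terms[kindred_profiles$family_id == f])
        upscale_to_systems(terms, dag)
      })
      for (r in seq_len(nrow(recs))) {
        hl <- recs$high_level_phenotypes[[r]]
        hit <- unlist(lapply(fam_systems, intersect, y = hl))
        if (length(hit) > 0L) {
          n_matches <- n_matches + 1L
          ext_systems <- union(ext_systems, hit)
        }
      }
    }
  }
  if (n_matches > 0L) {
    return(tibble(
      gene = gene, gene_class = 2L, n_kindreds = length(fams),
      shared_terms = list(character()),
      external_systems = list(sort(ext_systems)),
      n_external_matches = n_matches
    ))
  }
  tibble(
    gene = gene, gene_class = 3L, n_kindreds = length(fams),
    shared_terms = list(character()), external_systems = list(character()),
    n_external_matches = 0L
  )
}

#' Classify all contender genes
#'
#' Groups contender events by gene, assembles each gene's kindred
#' phenotype profiles (children with no recorded profile get an empty one,
#' with a message), and applies [classify_gene()]. Every contender gene
#' receives exactly one class, so the three classes partition the gene
#' list.
#'
#' @param contender_events Contender events from [triage_genes()].
#' @param phenotypes Long phenotype tibble from [read_phenotypes()].
#' @param external_db External records from [read_external_db()].
#' @param dag An `hpo_dag` from [read_ontology()].
#' @return Tibble of candidate genes (one row per gene, sorted by symbol)
#'   with the columns of [classify_gene()]. The class tally (and the
#'   multi-kindred vs singleton split) is attached as attribute `tally`.
#' @export
classify_all <- function(contender_events, phenotypes, external_db, dag) {
  empty <- tibble(gene = character(), gene_class = integer(),
                  n_kindreds = integer(), shared_terms = list(),
                  external_systems = list(), n_external_matches = integer())
  if (nrow(contender_events) == 0L) {
    attr(empty, "tally") <- tibble(gene_class = 1:3, n_genes = 0L)
    return(empty)
  }
  prof <- split(phenotypes$term, phenotypes$patient_id)
  carriers <- contender_events %>%
    distinct(.data$gene, .data$family_id, .data$child_id)
  missing <- setdiff(unique(carriers$child_id), names(prof))
  if (length(missing) > 0L) {
    inform(sprintf("%d carrier(s) with no phenotype profile: treated as empty",
                   length(missing)))
  }
  carriers$terms <- lapply(carriers$child_id, function(id)
    prof[[id]] %||% character(0))
  out <- carriers %>%
    group_by(.data$gene) %>%
    dplyr::group_map(function(df, key) {
      classify_gene(key$gene, df, external_db, dag)
    }) %>%
    bind_rows() %>%
    arrange(.data$gene)
  tally <- tibble(gene_class = 1:3) %>%
    left_join(count(out, .data$gene_class, name = "n_genes"),
              by = "gene_class") %>%
    mutate(n_genes = tidyr::replace_na(.data$n_genes, 0L))
  attr(out, "tally") <- tally
  attr(out, "n_multi_kindred") <- sum(out$n_kindreds >= 2L)
  attr(out, "n_singleton") <- sum(out$n_kindreds == 1L)
  out
}
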