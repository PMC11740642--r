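#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric computation from first principles with
#' log-factorials for numerical stability. For the table
#' \code{rbind(c(a, b), c(c, d))} with fixed margins, the two-sided p-value
#' sums the point probabilities of every table whose probability does not
#' exceed the observed one, with relative tolerance \code{1 + 1e-7} (the
#' dominant convention in statistical software).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise.
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0L) return(1)
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  x <- lo:hi
  logp <- lgamma(r1 + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) +
    lgamma(r2 + 1) - lgamma(c1 - x + 1) - lgamma(r2 - c1 + x + 1) -
    (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(n - c1 + 1))
  p_obs <- logp[x == a]
  min(1, sum(exp(logp[logp <= p_obs + log1p(1e-7)])))
}

#' Flag contender genes published by a later knowledge snapshot
#'
#' A gene counts as published when it appears in the later known-gene
#' snapshot *or* in a supplied literature gene list (mirroring manual
#' curation of publications not yet indexed).
#'
#' @param contenders Candidate tibble (needs a `gene` column).
#' @param known_t1 Later known-gene snapshot (tibble from
#'   [read_known_genes()] or a character vector of gene symbols).
#' @param literature Character vector of genes published in the literature
#'   only.
#' @return `contenders` with a logical `published` column.
#' @export
mark_published <- function(contenders, known_t1, literature = character()) {
  known_genes <- if (is.data.frame(known_t1)) known_t1$gene else known_t1
  contenders %>%
    mutate(published = .data$gene %in% union(known_genes, literature))
}

#' Summarize contender validation at a later knowledge snapshot
#'
#' Tallies published genes per class and computes the two headline
#' contingency statistics: class 1 against classes 2+3 combined, and
#' class 3 against class 2. A class with zero genes makes its test
#' not applicable (`NA`), never 1.
#'
#' @param contenders Candidate tibble with `gene`, `gene_class` and
#'   `published` columns (see [mark_published()]).
#' @param alt_diagnoses Character vector of patient IDs with an alternative
#'   diagnosis in a known gene made between the snapshots (reported as a
#'   count).
#' @return Object of class `validation_summary`: list with `per_class`
#'   (tibble: class, n_genes, n_published, proportion), `overall`,
#'   `fisher_class1_vs_rest`, `fisher_class3_vs_class2`, the underlying
#'   2x2 `tables`, and `alternative_diagnosis_patients`.
#' @export
summarize_validation <- function(contenders, alt_diagnoses = character()) {
  stopifnot(all(c("gene", "gene_class", "published") %in% names(contenders)))
  if (any(!contenders$gene_class %in% 1:3)) {
    abort("gene_class must be 1, 2 or 3")
  }
  per_class <- tibble(gene_class = 1:3) %>%
    left_join(
      contenders %>%
        group_by(.data$gene_class) %>%
        summarise(n_genes = n(), n_published = sum(.data$published),
                  .groups = "drop"),
      by = "gene_class") %>%
    mutate(
      n_genes = tidyr::replace_na(.data$n_genes, 0L),
      n_published = tidyr::replace_na(as.integer(.data$n_published), 0L),
      proportion = ifelse(.data$n_genes > 0, .data$n_published / .data$n_genes,
                          NA_real_)
    )
  n1 <- per_class$n_genes[1]; p1 <- per_class$n_published[1]
  n2 <- per_class$n_genes[2]; p2 <- per_class$n_published[2]
  n3 <- per_class$n_genes[3]; p3 <- per_class$n_published[3]
  t1 <- matrix(c(p1, n1 - p1, p2 + p3, (n2 + n3) - (p2 + p3)), 2,
               byrow = TRUE,
               dimnames = list(c("class1", "class2+3"),
                               c("published", "unpublished")))
  t2 <- matrix(c(p3, n3 - p3, p2, n2 - p2), 2, byrow = TRUE,
               dimnames = list(c("class3", "class2"),
                               c("published", "unpublished")))
  f1 <- if (n1 > 0 && (n2 + n3) > 0)
    fisher_exact_two_sided(t1[1, 1], t1[1, 2], t1[2, 1], t1[2, 2]) else NA_real_
  f2 <- if (n2 > 0 && n3 > 0)
    fisher_exact_two_sided(t2[1, 1], t2[1, 2], t2[2, 1], t2[2, 2]) else NA_real_
  structure(list(
    per_class = per_class,
    overall = list(
      n_contenders = sum(per_class$n_genes),
      n_published = sum(per_class$n_published),
      proportion = if (sum(per_class$n_genes) > 0)
        sum(per_class$n_published) / sum(per_class$n_genes) else NA_real_
    ),
    fisher_class1_vs_rest = f1,
    fisher_class3_vs_class2 = f2,
    tables = list(class1_vs_rest = t1, class3_vs_class2 = t2),
    alternative_diagnosis_patients = length(unique(alt_diagnoses))
  ), class = "validation_summary")
}

#' Per-gene phenotype concordance with published term lists
#'
#' For each gene, intersects the HPO terms of the cohort's carrier
#' patients with the term list reported in the literature — the data
#' behind an "overlapping features" column, leaving judgement to the
#' analyst.
#'
#' @param events Event rows carrying `gene` and `child_id`.
#' @param phenotypes Long phenotype tibble (`patient_id`, `term`).
#' @param published_terms Tibble with columns `gene`, `term` (HPO IDs
#'   reported in the literature for that gene).
#' @param genes Optional subset of genes to report (default: genes present
#'   in `published_terms`).
#' @return Tibble: `gene`, `overlap` (list of shared term IDs),
#'   `n_overlap`, `n_cohort_terms`, `n_published_terms`.
#' @export
phenotype_concordance_report <- function(events, phenotypes, published_terms,
                                         genes = NULL) {
  genes <- genes %||% sort(unique(published_terms$gene))
  purrr::map_dfr(genes, function(g) {
    kids <- unique(events$child_id[events$gene == g])
    cohort_terms <- unique(phenotypes$term[phenotypes$patient_id %in% kids])
    pub <- unique(published_terms$term[published_terms$gene == g])
    ov <- exact_hpo_overlap(cohort_terms, pub)
    tibble(gene = g, overlap = list(ov), n_overlap = length(ov),
           n_cohort_terms = length(cohort_terms),
           n_published_terms = length(pub))
  })
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("Validation against later knowledge snapshot\n")
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  class %d: %d/%d published (%s)\n", pc$gene_class[i],
                pc$n_published[i], pc$n_genes[i],
                ifelse(is.na(pc$proportion[i]), "-",
                       sprintf("%.0f%%", 100 * pc$proportion[i]))))
  }
  cat(sprintf("  overall: %d/%d published (%.0f%%)\n",
              x$overall$n_published, x$overall$n_contenders,
              100 * x$overall$proportion))
  cat(sprintf("  Fisher class 1 vs classes 2+3: p = %s\n",
              format(x$fisher_class1_vs_rest, digits = 3)))
  cat(sprintf("  Fisher class 3 vs class 2:     p = %s\n",
              format(x$fisher_class3_vs_class2, digits = 3)))
  if (x$alternative_diagnosis_patients > 0) {
    cat(sprintf("  patients with alternative diagnoses: %d\n",
                x$alternative_diagnosis_patients))
  }
  invisible(x)
}
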