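#' Tidy a pipeline result into its candidate-gene table
#'
#' @param x A `g2p_result` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble of candidate genes with class, kindred count, shared
#'   terms and (after validation) published flag.
#' @method tidy g2p_result
#' @export
tidy.g2p_result <- function(x, ...) {
  if (is.null(x$candidates)) {
    return(tibble(gene = character(), gene_class = integer()))
  }
  x$candidates %>%
    mutate(shared_terms = purrr::map_chr(.data$shared_terms, paste,
                                         collapse = ","),
           external_systems = purrr::map_chr(.data$external_systems, paste,
                                             collapse = ","))
}

#' One-row summary of a pipeline run
#'
#' @param x A `g2p_result`.
#' @param ... Unused.
#' @return One-row tibble: trio count, de novo events, retained events,
#'   contender genes and per-class counts.
#' @method glance g2p_result
#' @export
glance.g2p_result <- function(x, ...) {
  tal <- if (!is.null(x$candidates)) attr(x$candidates, "tally") else NULL
  tibble(
    n_trios = nrow(x$trios %||% tibble()),
    n_denovo_events = nrow(x$events %||% tibble()),
    n_retained_events = nrow(x$retained %||% tibble()),
    n_known_gene_events = if (!is.null(x$triage)) nrow(x$triage$known_events) else NA_integer_,
    n_contender_genes = if (!is.null(x$triage)) length(x$triage$contender_genes) else NA_integer_,
    n_class1 = if (!is.null(tal)) tal$n_genes[1] else NA_integer_,
    n_class2 = if (!is.null(tal)) tal$n_genes[2] else NA_integer_,
    n_class3 = if (!is.null(tal)) tal$n_genes[3] else NA_integer_
  )
}

#' @method tidy validation_summary
#' @export
tidy.validation_summary <- function(x, ...) x$per_class

#' @method glance validation_summary
#' @export
glance.validation_summary <- function(x, ...) {
  tibble(
    n_contenders = x$overall$n_contenders,
    n_published = x$overall$n_published,
    proportion_published = x$overall$proportion,
    fisher_class1_vs_rest = x$fisher_class1_vs_rest,
    fisher_class3_vs_class2 = x$fisher_class3_vs_class2,
    alternative_diagnosis_patients = x$alternative_diagnosis_patients
  )
}

#' Plot the filter funnel
#'
#' @param object A `g2p_funnel` tibble (the `funnel` element of a
#'   [run_pipeline()] result).
#' @param ... Unused.
#' @return A ggplot: events remaining per filtering stage.
#' @method autoplot g2p_funnel
#' @export
autoplot.g2p_funnel <- function(object, ...) {
  df <- object %>%
    mutate(stage = factor(.data$stage, levels = rev(unique(.data$stage))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_events, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_events), hjust = -0.2,
                       size = 3) +
    ggplot2::labs(x = "events remaining", y = NULL,
                  title = "Variant filter funnel") +
    ggplot2::theme_minimal()
}

#' @method autoplot g2p_result
#' @export
autoplot.g2p_result <- function(object, ...) {
  autoplot(object$funnel, ...)
}

#' Plot per-class publication outcomes of a validation summary
#'
#' @param object A `validation_summary` from [summarize_validation()].
#' @param ... Unused.
#' @return A ggplot of published vs unpublished gene counts per class.
#' @method autoplot validation_summary
#' @export
autoplot.validation_summary <- function(object, ...) {
  df <- object$per_class %>%
    mutate(unpublished = .data$n_genes - .data$n_published) %>%
    select("gene_class", published = "n_published", "unpublished") %>%
    tidyr::pivot_longer(c("published", "unpublished"), names_to = "status",
                        values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$gene_class), y = .data$n,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(published = "forestgreen",
                                          unpublished = "grey70")) +
    ggplot2::labs(x = "candidate class", y = "genes",
                  title = "Candidate genes published by the later snapshot") +
    ggplot2::theme_minimal()
}
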