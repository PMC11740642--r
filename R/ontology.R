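#' Read a minimal OBO ontology into a phenotype DAG
#'
#' Parses `[Term]` stanzas (`id`, `name`, `is_a` tags only) into a directed
#' acyclic graph. The organ-system vocabulary used for phenotype upscaling
#' is the set of direct children of `anchor` (by default `HP:0000118`,
#' "Phenotypic abnormality", whose children are the HPO top-level
#' organ-system branches).
#'
#' @param path Path to an OBO 1.2 file.
#' @param anchor Term ID whose direct children define the system-level
#'   vocabulary.
#' @return An object of class `hpo_dag`: list with `terms` (tibble of `id`,
#'   `name`), `parents` (named list, term -> parent IDs), `ancestors`
#'   (named list, term -> all ancestors *including the term itself*),
#'   `system_terms` (character) and `anchor`.
#' @export
read_ontology <- function(path, anchor = "HP:0000118") {
  assert_file(path, "ontology")
  lines <- readLines(path)
  ids <- character(); names_ <- character(); parents <- list()
  cur_id <- NULL; cur_name <- NA_character_; cur_parents <- character()
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur_id)) {
      ids[[length(ids) + 1L]] <<- cur_id
      names_[[length(names_) + 1L]] <<- cur_name
      parents[[cur_id]] <<- cur_parents
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); cur_id <- NULL; cur_name <- NA_character_
      cur_parents <- character(); in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(); cur_id <- NULL; in_term <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur_id <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^name:", ln)) {
      cur_name <- trimws(sub("^name:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur_parents <- c(cur_parents, tgt)
    }
  }
  flush()
  if (length(ids) == 0L) abort("no [Term] stanzas found in ontology file")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate term ID in ontology: %s", ids[duplicated(ids)][1]))
  }
  undeclared <- setdiff(unique(unlist(parents)), ids)
  if (length(undeclared) > 0L) {
    abort(sprintf("is_a reference to undeclared term: %s", undeclared[1]))
  }
  anc <- transitive_ancestors(ids, parents)
  if (!anchor %in% ids) {
    abort(sprintf("anchor term %s not present in ontology", anchor))
  }
  system_terms <- ids[vapply(ids, function(t) anchor %in% parents[[t]], logical(1))]
  structure(list(
    terms = tibble(id = ids, name = names_),
    parents = parents,
    ancestors = anc,
    system_terms = sort(system_terms),
    anchor = anchor
  ), class = "hpo_dag")
}

# ancestor closure (self-inclusive) via topological propagation;
# errors on cycles
transitive_ancestors <- function(ids, parents) {
  n_parents <- vapply(ids, function(t) length(parents[[t]]), integer(1))
  children <- list()
  for (t in ids) for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  anc <- setNames(vector("list", length(ids)), ids)
  queue <- ids[n_parents == 0L]
  remaining <- setNames(n_parents, ids)
  done <- 0L
  while (length(queue) > 0L) {
    t <- queue[[1]]; queue <- queue[-1]; done <- done + 1L
    anc[[t]] <- unique(c(t, unlist(anc[parents[[t]]], use.names = FALSE)))
    for (ch in children[[t]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (done < length(ids)) abort("cycle detected in ontology is_a graph")
  anc
}

#' Ancestors of a term (including the term itself)
#'
#' @param dag An `hpo_dag` from [read_ontology()].
#' @param term A term ID.
#' @return Character vector of ancestor IDs (self-inclusive); unknown terms
#'   return `character(0)`.
#' @export
hpo_ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "hpo_dag"))
  dag$ancestors[[term]] %||% character(0)
}
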