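# consequences counted as predicted loss-of-function: canonical splice
# site, frameshift, stop gain, start loss, stop loss
plof_terms <- function() c(
  "splice_acceptor_variant", "splice_donor_variant", "frameshift_variant",
  "stop_gained", "start_lost", "stop_lost"
)

#' Is a consequence term predicted loss-of-function?
#'
#' Vectorized; a VEP-style compound annotation (`"a&b"`) is pLoF when any
#' of its terms is.
#'
#' @param consequence Character vector of Sequence Ontology terms.
#' @return Logical vector.
#' @export
is_plof <- function(consequence) {
  vapply(strsplit(ifelse(is.na(consequence), "", consequence), "&", fixed = TRUE),
         function(p) any(p %in% plof_terms()), logical(1))
}

#' Join de novo events with their transcript annotations
#'
#' @param events Events from [call_denovos()].
#' @param variants Annotation tibble (`vcf$variants` from [read_variants()]).
#' @return One row per (event, transcript annotation): event columns plus
#'   `gene`, `transcript_id`, `consequence` and the `af_*` columns.
#' @export
annotate_events <- function(events, variants) {
  ann_cols <- setdiff(names(variants), c("chrom", "pos", "ref", "alt"))
  events %>%
    inner_join(variants[, ann_cols], by = "variant_key",
               relationship = "many-to-many")
}

#' Assign loss-of-function confidence with a reduced LOFTEE-style heuristic
#'
#' A pLoF call is LOW confidence when any of four flags fires:
#' \describe{
#'   \item{LAST_EXON}{the variant lies in the transcript's terminal exon,
#'     where a premature stop typically escapes nonsense-mediated decay;}
#'   \item{NEAR_END_50BP}{a stop-gain or frameshift within 50 bp of the 3'
#'     end of the penultimate exon (the canonical NMD-escape window
#'     upstream of the last exon-exon junction);}
#'   \item{SINGLE_EXON}{the transcript has a single exon (no junction, no
#'     NMD);}
#'   \item{NON_CANONICAL_SPLICE}{a splice donor/acceptor call whose
#'     intronic dinucleotide on the coding strand is not GT/AG; only
#'     checkable when a reference FASTA is supplied, otherwise splice
#'     annotations are trusted as canonical.}
#' }
#' Calls with no flag are HIGH confidence; non-pLoF rows get confidence
#' `NOT_APPLICABLE`. Rows whose transcript is absent from `transcripts`
#' cannot be evaluated: they are returned with `evaluable = FALSE` and an
#' informative message, and must not be treated as HIGH.
#'
#' @param events_ann Annotated events from [annotate_events()].
#' @param transcripts Exon models from [read_transcripts()].
#' @param fasta Optional path to a reference FASTA (requires Biostrings)
#'   enabling the splice dinucleotide check.
#' @return `events_ann` with columns `is_plof`, `confidence`
#'   (`HIGH`/`LOW`/`NOT_APPLICABLE`), `flags` (comma-joined), `evaluable`.
#' @export
assess_lof_confidence <- function(events_ann, transcripts, fasta = NULL) {
  tx_index <- split(
    transcripts[, c("chrom", "strand", "exon_start", "exon_end",
                    "exon_index", "n_exons")],
    transcripts$transcript_id
  )
  ref_seq <- NULL
  if (!is.null(fasta)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("the splice dinucleotide check needs the Biostrings package")
    }
    ref_seq <- Biostrings::readDNAStringSet(fasta)
    names(ref_seq) <- sub("\\s.*$", "", names(ref_seq))
  }
  n <- nrow(events_ann)
  plof <- is_plof(events_ann$consequence)
  confidence <- ifelse(plof, "HIGH", "NOT_APPLICABLE")
  flags <- character(n)
  evaluable <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!plof[i]) next
    tx <- tx_index[[events_ann$transcript_id[i]]]
    if (is.null(tx)) {
      evaluable[i] <- FALSE
      next
    }
    f <- lof_flags(events_ann$pos[i], events_ann$consequence[i], tx, ref_seq)
    flags[i] <- paste(f, collapse = ",")
    if (length(f) > 0L) confidence[i] <- "LOW"
  }
  n_bad <- sum(!evaluable)
  if (n_bad > 0L) {
    inform(sprintf(
      "%d pLoF call(s) excluded as unevaluable: transcript model not found", n_bad))
  }
  out <- events_ann
  out$is_plof <- plof
  out$confidence <- confidence
  out$flags <- flags
  out$evaluable <- evaluable
  out
}

# flag computation for one call; tx rows are in transcription order
lof_flags <- function(pos, consequence, tx, ref_seq) {
  flags <- character()
  k <- tx$n_exons[1]
  in_exon <- which(pos >= tx$exon_start & pos <= tx$exon_end)
  exon_idx <- if (length(in_exon) > 0L) tx$exon_index[in_exon[1]] else NA_integer_
  if (k == 1L) flags <- c(flags, "SINGLE_EXON")
  if (!is.na(exon_idx) && exon_idx == k && k > 1L) {
    flags <- c(flags, "LAST_EXON")
  }
  terms <- strsplit(consequence, "&", fixed = TRUE)[[1]]
  if (!is.na(exon_idx) && exon_idx == k - 1L && k > 1L &&
      any(terms %in% c("stop_gained", "frameshift_variant"))) {
    pen <- tx[tx$exon_index == k - 1L, ]
    dist3 <- if (pen$strand[1] == "+") pen$exon_end[1] - pos else pos - pen$exon_start[1]
    if (dist3 <= 50L) flags <- c(flags, "NEAR_END_50BP")
  }
  if (!is.null(ref_seq) &&
      any(terms %in% c("splice_donor_variant", "splice_acceptor_variant"))) {
    if (!splice_site_canonical(pos, terms, tx, ref_seq)) {
      flags <- c(flags, "NON_CANONICAL_SPLICE")
    }
  }
  flags
}

# reference-context check of the GT/AG intronic dinucleotide adjacent to
# the exon boundary the splice variant sits at
splice_site_canonical <- function(pos, terms, tx, ref_seq) {
  chrom <- tx$chrom[1]
  if (!chrom %in% names(ref_seq)) return(TRUE)
  seq <- ref_seq[[chrom]]
  get2 <- function(start) {
    if (start < 1L || start + 1L > length(seq)) return(NA_character_)
    as.character(seq[start:(start + 1L)])
  }
  revcomp2 <- function(s) {
    if (is.na(s)) return(NA_character_)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  plus <- tx$strand[1] == "+"
  ok <- TRUE
  for (e in seq_len(nrow(tx))) {
    s <- tx$exon_start[e]; en <- tx$exon_end[e]
    # donor: 2 intronic bases just past the exon's transcription 3' end
    donor_win <- if (plus) c(en + 1L, en + 2L) else c(s - 2L, s - 1L)
    # acceptor: 2 intronic bases just before the exon's transcription 5' end
    acc_win <- if (plus) c(s - 2L, s - 1L) else c(en + 1L, en + 2L)
    if ("splice_donor_variant" %in% terms &&
        pos >= donor_win[1] && pos <= donor_win[2]) {
      di <- get2(donor_win[1])
      if (!plus) di <- revcomp2(di)
      if (!is.na(di) && di != "GT") ok <- FALSE
    }
    if ("splice_acceptor_variant" %in% terms &&
        pos >= acc_win[1] && pos <= acc_win[2]) {
      di <- get2(acc_win[1])
      if (!plus) di <- revcomp2(di)
      if (!is.na(di) && di != "AG") ok <- FALSE
    }
  }
  ok
}

#' Keep only high-confidence pLoF calls
#'
#' Subsets to rows with confidence `HIGH`, preserving input order. The
#' breakdown of LOW calls by flag (for the filter funnel) is attached as
#' attribute `low_breakdown`.
#'
#' @param calls Output of [assess_lof_confidence()].
#' @return The retained subset.
#' @export
filter_high_confidence <- function(calls) {
  low <- calls %>%
    filter(.data$evaluable, .data$confidence == "LOW") %>%
    tidyr::separate_rows("flags", sep = ",") %>%
    count(.data$flags, name = "n_calls")
  out <- calls %>% filter(.data$evaluable, .data$confidence == "HIGH")
  attr(out, "low_breakdown") <- low
  out
}
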