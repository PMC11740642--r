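#' Configuration for the synthetic trio cohort generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' trio genotypes with de novo events arriving at a Poisson rate per
#' child, a LOEUF score distribution with a configurable constrained
#' fraction (the first-decile gate at 0.2), implanted "true" disease genes
#' whose unrelated carriers share exact HPO terms, singleton implants
#' covered by an external phenotype database, decoy events engineered to
#' fail one specific filter each, and background patients with random
#' phenotype terms.
#'
#' @param n_trios Number of complete trios.
#' @param n_genes Number of genes (each with one transcript model).
#' @param frac_constrained Fraction of genes with LOEUF < 0.2.
#' @param n_known_genes_t0 Known disease genes at the analysis snapshot.
#' @param n_implanted_disease_genes Implanted class-1 genes (multi-kindred,
#'   shared phenotype terms).
#' @param kindreds_per_implanted_gene Carrier kindreds per implanted gene
#'   (at least 2).
#' @param n_singleton_implants Implanted single-kindred genes (class 2
#'   when covered by the external database).
#' @param denovo_rate_per_trio Poisson mean of background coding de novo
#'   events per trio.
#' @param plof_fraction Fraction of background de novo events with a pLoF
#'   consequence.
#' @param background_hpo_range Inclusive range (length-2 integer) of
#'   background HPO terms per patient.
#' @param shared_terms_per_disease_gene Exact HPO terms shared by an
#'   implanted gene's carriers (at least 1).
#' @param external_db_coverage Fraction of singleton implants with a
#'   matching de novo external record.
#' @param af_noise List with `prob_absent`, `meanlog`, `sdlog`: each
#'   population AF of a background variant is absent with `prob_absent`,
#'   otherwise log-normal.
#' @param decoys Named integer vector of decoy events among
#'   `last_exon` (pLoF in the terminal exon, LOW confidence),
#'   `high_af` (population AF 0.01), `loeuf_boundary` (gene LOEUF exactly
#'   0.2, exercising the strict gate) and `inherited` (father carries the
#'   allele).
#' @param publish_fraction_class1 Fraction of implanted class-1 genes
#'   "published" by the later snapshot (split between the later known-gene
#'   snapshot and a literature-only list).
#' @param publish_fraction_other Publication probability for other
#'   contender genes.
#' @param n_incomplete_families Extra non-trio families written to the
#'   pedigree (excluded by [read_pedigree()]).
#' @param seed Integer seed; the whole bundle is a deterministic function
#'   of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_trios = 200, n_genes = 500, frac_constrained = 0.1,
                       n_known_genes_t0 = 40, n_implanted_disease_genes = 5,
                       kindreds_per_implanted_gene = 2,
                       n_singleton_implants = 3, denovo_rate_per_trio = 1.5,
                       plof_fraction = 0.1, background_hpo_range = c(1L, 5L),
                       shared_terms_per_disease_gene = 1,
                       external_db_coverage = 1,
                       af_noise = list(prob_absent = 0.5, meanlog = -9,
                                       sdlog = 1.5),
                       decoys = c(last_exon = 1L, high_af = 1L,
                                  loeuf_boundary = 1L, inherited = 1L),
                       publish_fraction_class1 = 0.6,
                       publish_fraction_other = 0.1,
                       n_incomplete_families = 2, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_trios >= 1, n_genes >= 1,
      frac_constrained >= 0, frac_constrained <= 1,
      plof_fraction >= 0, plof_fraction <= 1,
      external_db_coverage >= 0, external_db_coverage <= 1,
      publish_fraction_class1 >= 0, publish_fraction_class1 <= 1,
      publish_fraction_other >= 0, publish_fraction_other <= 1,
      kindreds_per_implanted_gene >= 2,
      shared_terms_per_disease_gene >= 1,
      length(background_hpo_range) == 2,
      background_hpo_range[1] >= 1,
      background_hpo_range[2] >= background_hpo_range[1],
      denovo_rate_per_trio >= 0
    )
    n_con <- round(frac_constrained * n_genes)
    if (n_implanted_disease_genes + n_singleton_implants > n_con) {
      abort("infeasible configuration: more implanted genes than constrained genes")
    }
    n_special <- n_implanted_disease_genes + n_singleton_implants +
      sum(decoys) + n_known_genes_t0
    if (n_special > n_genes) {
      abort("infeasible configuration: special genes exceed n_genes")
    }
    n_carriers <- n_implanted_disease_genes * kindreds_per_implanted_gene +
      n_singleton_implants + sum(decoys)
    if (n_carriers > n_trios) {
      abort("infeasible configuration: more carrier kindreds than trios")
    }
  })
  invisible(cfg)
}

# ---- mini ontology -----------------------------------------------------

# five organ-system branches under the standard phenotypic-abnormality
# anchor, with synthetic mid-level and leaf terms (HP:9xxxxxx range)
mini_ontology_terms <- function() {
  systems <- tibble(
    id = c("HP:0000707", "HP:0001626", "HP:0000924", "HP:0000478",
           "HP:0001507"),
    name = c("Abnormality of the nervous system",
             "Abnormality of the cardiovascular system",
             "Abnormality of the skeletal system",
             "Abnormality of the eye",
             "Growth abnormality"),
    parent = "HP:0000118"
  )
  mids <- purrr::map_dfr(seq_len(nrow(systems)), function(s) {
    tibble(
      id = sprintf("HP:90%02d%03d", s, 1:2),
      name = sprintf("Synthetic %s finding group %d",
                     sub("Abnormality of the ", "", systems$name[s]), 1:2),
      parent = systems$id[s]
    )
  })
  leaves <- purrr::map_dfr(seq_len(nrow(mids)), function(m) {
    tibble(
      id = sprintf("HP:91%02d%03d", m, 1:3),
      name = sprintf("Synthetic leaf phenotype %d-%d", m, 1:3),
      parent = mids$id[m]
    )
  })
  # one leaf with a second parent in a different system branch
  multi <- tibble(id = leaves$id[1], name = leaves$name[1],
                  parent = mids$id[nrow(mids)])
  roots <- tibble(
    id = c("HP:0000001", "HP:0000118"),
    name = c("All", "Phenotypic abnormality"),
    parent = c(NA_character_, "HP:0000001")
  )
  list(terms = bind_rows(roots, systems, mids, leaves, multi),
       systems = systems, mids = mids, leaves = leaves)
}

write_obo <- function(terms, path) {
  by_id <- split(terms$parent, terms$id)
  ids <- unique(terms$id)
  nm <- terms$name[match(ids, terms$id)]
  lines <- c("format-version: 1.2", "")
  for (i in seq_along(ids)) {
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]), paste0("name: ", nm[i]))
    for (p in by_id[[ids[i]]]) {
      if (!is.na(p)) lines <- c(lines, paste0("is_a: ", p))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- transcript layout -------------------------------------------------

make_transcripts <- function(n_genes) {
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  txs <- sprintf("TX%04d", seq_len(n_genes))
  chroms <- as.character(((seq_len(n_genes) - 1L) %% 22L) + 1L)
  slot <- ceiling(seq_len(n_genes) / 22L)
  start0 <- 100000L + (slot - 1L) * 50000L
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  n_exons <- sample(2:7, n_genes, replace = TRUE)
  purrr::map_dfr(seq_len(n_genes), function(i) {
    lens <- sample(120:180, n_exons[i], replace = TRUE)
    starts <- integer(n_exons[i]); ends <- integer(n_exons[i])
    cur <- start0[i]
    for (e in seq_len(n_exons[i])) {
      starts[e] <- cur
      ends[e] <- cur + lens[e] - 1L
      cur <- ends[e] + 301L
    }
    tibble(transcript_id = txs[i], gene = genes[i], chrom = chroms[i],
           strand = strand[i], exon_start = starts, exon_end = ends)
  })
}

# transcription-order exon table for one transcript
tx_exons <- function(transcripts, gene) {
  tx <- transcripts[transcripts$gene == gene, ]
  if (tx$strand[1] == "+") tx[order(tx$exon_start), ]
  else tx[order(-tx$exon_start), ]
}

#' Build one injected variant record for a trio
#'
#' Places a variant of the requested consequence in a gene's transcript
#' under a positional policy, with the child heterozygous and both parents
#' homozygous reference (unless `inherited`, where the father is also a
#' carrier). Used by [simulate_cohort()]; exported for building bespoke
#' fixtures.
#'
#' @param trio One-row trio tibble (`family_id`, `child_id`, `father_id`,
#'   `mother_id`).
#' @param gene Gene symbol (must appear in `transcripts`).
#' @param consequence Sequence Ontology consequence term.
#' @param transcripts Exon model table (shape of [read_transcripts()]
#'   input).
#' @param policy Positional policy: `"mid"` (inside the first exon, clear
#'   of NMD-escape windows), `"last_exon"` (inside the terminal exon) or
#'   `"splice_donor"` (first intronic base past the first exon).
#' @param af Named numeric vector of population AFs (e.g.
#'   `c(nfe = 0.01)`); empty means absent from all populations.
#' @param inherited If `TRUE` the father is heterozygous too.
#' @param offset Extra base offset to keep multiple events in one gene at
#'   distinct positions.
#' @return One-row tibble describing the VCF record and trio genotypes.
#' @export
inject_event <- function(trio, gene, consequence, transcripts,
                         policy = c("mid", "last_exon", "splice_donor"),
                         af = numeric(), inherited = FALSE, offset = 0L) {
  policy <- match.arg(policy)
  tx <- tx_exons(transcripts, gene)
  if (nrow(tx) == 0L) abort(sprintf("gene %s has no transcript model", gene))
  plus <- tx$strand[1] == "+"
  k <- nrow(tx)
  pos <- switch(policy,
    mid = if (plus) tx$exon_start[1] + 10L + offset
          else tx$exon_end[1] - 10L - offset,
    last_exon = if (plus) tx$exon_start[k] + 10L + offset
                else tx$exon_end[k] - 10L - offset,
    splice_donor = {
      if (k < 2L) abort("splice_donor policy needs a multi-exon transcript")
      if (plus) tx$exon_end[1] + 1L else tx$exon_start[1] - 1L
    }
  )
  if (consequence == "frameshift_variant") {
    ref <- "GA"; alt <- "G"
  } else {
    ref <- "G"; alt <- "A"
  }
  afv <- setNames(rep(NA_real_, 3), c("afr", "nfe", "eas"))
  afv[names(af)] <- af
  tibble(
    chrom = tx$chrom[1], pos = as.integer(pos), ref = ref, alt = alt,
    gene = gene, transcript_id = tx$transcript_id[1],
    consequence = consequence,
    af_afr = afv[["afr"]], af_nfe = afv[["nfe"]], af_eas = afv[["eas"]],
    family_id = trio$family_id, child_id = trio$child_id,
    father_id = trio$father_id, mother_id = trio$mother_id,
    child_gt = "0/1:60:30:15,15",
    father_gt = if (inherited) "0/1:55:30:14,16" else "0/0:60:32:32,0",
    mother_gt = "0/0:60:32:32,0"
  )
}

# expected filter fate under the pipeline's stage order
expected_fate <- function(consequence, policy, inherited, max_af, loeuf,
                          known, af_max = 0.001, loeuf_max = 0.2) {
  if (inherited) return("fail-denovo")
  if (!consequence %in% plof_terms()) return("fail-not-plof")
  if (policy == "last_exon") return("fail-LOW-confidence")
  if (!is.na(max_af) && max_af >= af_max) return("fail-AF")
  if (is.na(loeuf) || loeuf >= loeuf_max) return("fail-LOEUF")
  if (known) return("fail-known-gene")
  "pass"
}

#' Generate a complete synthetic cohort bundle
#'
#' Writes every input the pipeline consumes — trio VCF, pedigree, LOEUF
#' constraint table, two known-gene snapshots plus a literature-only list,
#' patient phenotypes, a mini phenotype ontology, an external phenotype
#' database and transcript exon models — together with a ground-truth
#' manifest recording each injected event's expected filter fate and each
#' implanted gene's expected class. The bundle is a deterministic function
#' of the configuration (byte-identical for identical seeds).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json` in `dir`), with a `paths` element naming every file.
#' @export
simulate_cohort <- function(config = sim_config(), dir) {
  validate_sim_config(config)
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  transcripts <- make_transcripts(config$n_genes)
  genes <- unique(transcripts$gene)

  # --- special gene roles ---
  shuffled <- sample(genes)
  n_imp <- config$n_implanted_disease_genes
  n_sing <- config$n_singleton_implants
  decoy_types <- rep(names(config$decoys), config$decoys)
  take <- function(n) {
    out <- shuffled[seq_len(n)]
    shuffled <<- shuffled[-seq_len(n)]
    out
  }
  implanted <- if (n_imp > 0) take(n_imp) else character()
  singletons <- if (n_sing > 0) take(n_sing) else character()
  decoy_genes <- if (length(decoy_types) > 0) take(length(decoy_types)) else character()
  names(decoy_genes) <- make.unique(decoy_types)
  known_t0 <- if (config$n_known_genes_t0 > 0) take(config$n_known_genes_t0) else character()
  plain <- shuffled

  # --- LOEUF scores ---
  n_con <- round(config$frac_constrained * config$n_genes)
  forced_con <- c(implanted, singletons,
                  decoy_genes[decoy_types != "loeuf_boundary"])
  known_con <- head(known_t0, max(0L, min(length(known_t0),
                                          round(config$n_known_genes_t0 / 2))))
  fill <- setdiff(plain, forced_con)
  n_fill <- max(0L, n_con - length(forced_con) - length(known_con))
  constrained <- c(forced_con, known_con, head(sample(fill), n_fill))
  boundary_gene <- unname(decoy_genes[decoy_types == "loeuf_boundary"])
  loeuf_tbl <- tibble(gene = genes) %>%
    mutate(loeuf = ifelse(.data$gene %in% constrained,
                          round(runif(length(genes), 0.03, 0.19), 4),
                          round(runif(length(genes), 0.25, 1.8), 4)))
  loeuf_tbl$loeuf[loeuf_tbl$gene %in% boundary_gene] <- 0.2
  # a few plain genes get NA scores or are missing entirely
  na_genes <- head(setdiff(plain, constrained), 3)
  drop_genes <- head(setdiff(setdiff(plain, constrained), na_genes), 5)
  loeuf_out <- loeuf_tbl %>%
    mutate(loeuf = ifelse(.data$gene %in% na_genes, NA_real_, .data$loeuf)) %>%
    filter(!.data$gene %in% drop_genes)
  readr::write_tsv(tibble(gene = loeuf_out$gene,
                          oe_lof_upper = loeuf_out$loeuf), p("constraint.tsv"))
  loeuf_of <- setNames(loeuf_tbl$loeuf, loeuf_tbl$gene)
  loeuf_of[c(na_genes, drop_genes)] <- NA_real_

  # --- ontology ---
  onto <- mini_ontology_terms()
  write_obo(onto$terms, p("ontology.obo"))
  branch_of_mid <- setNames(onto$mids$parent, onto$mids$id)
  leaf_system <- setNames(branch_of_mid[onto$leaves$parent], onto$leaves$id)
  all_leaves <- onto$leaves$id
  leaves_by_system <- split(onto$leaves$id, leaf_system)

  # --- trios ---
  trios <- tibble(
    family_id = sprintf("FAM%04d", seq_len(config$n_trios)),
    child_id = sprintf("FAM%04d_C", seq_len(config$n_trios)),
    father_id = sprintf("FAM%04d_F", seq_len(config$n_trios)),
    mother_id = sprintf("FAM%04d_M", seq_len(config$n_trios)),
    child_affected = TRUE
  )
  ped_lines <- c(
    sprintf("%s\t%s\t%s\t%s\t0\t2", trios$family_id, trios$child_id,
            trios$father_id, trios$mother_id),
    sprintf("%s\t%s\t0\t0\t1\t1", trios$family_id, trios$father_id),
    sprintf("%s\t%s\t0\t0\t2\t1", trios$family_id, trios$mother_id)
  )
  if (config$n_incomplete_families > 0) {
    idx <- seq_len(config$n_incomplete_families)
    ped_lines <- c(ped_lines,
      sprintf("DUO%03d\tDUO%03d_C\t0\tDUO%03d_M\t0\t2", idx, idx, idx),
      sprintf("DUO%03d\tDUO%03d_M\t0\t0\t2\t1", idx, idx))
  }
  writeLines(ped_lines, p("pedigree.ped"))

  # --- carrier assignment (special events use disjoint trios) ---
  carrier_pool <- sample(seq_len(config$n_trios))
  take_trio <- function(n) {
    out <- carrier_pool[seq_len(n)]
    carrier_pool <<- carrier_pool[-seq_len(n)]
    out
  }
  branches <- onto$systems$id
  implant_info <- purrr::map(seq_along(implanted), function(i) {
    branch <- branches[((i - 1L) %% length(branches)) + 1L]
    list(gene = implanted[i], branch = branch,
         shared_terms = sort(sample(leaves_by_system[[branch]],
                                    config$shared_terms_per_disease_gene)),
         trio_rows = take_trio(config$kindreds_per_implanted_gene))
  })
  singleton_info <- purrr::map(seq_along(singletons), function(i) {
    branch <- branches[((i + length(implanted) - 1L) %% length(branches)) + 1L]
    list(gene = singletons[i], branch = branch,
         own_terms = sort(sample(leaves_by_system[[branch]], 2)),
         trio_row = take_trio(1L))
  })
  decoy_rows <- if (length(decoy_types) > 0) take_trio(length(decoy_types)) else integer()

  # --- events ---
  events <- list()
  add_event <- function(trio_row, gene, consequence, policy, af, inherited,
                        origin, offset = 0L) {
    known <- gene %in% known_t0
    ev <- inject_event(trios[trio_row, ], gene, consequence, transcripts,
                       policy = policy, af = af, inherited = inherited,
                       offset = offset)
    ev$origin <- origin
    max_af <- suppressWarnings(max(c(ev$af_afr, ev$af_nfe, ev$af_eas), na.rm = TRUE))
    if (!is.finite(max_af)) max_af <- NA_real_
    ev$expected_fate <- expected_fate(consequence, policy, inherited, max_af,
                                      loeuf_of[[gene]], known)
    events[[length(events) + 1L]] <<- ev
  }
  plof_choices <- c("stop_gained", "frameshift_variant")
  for (info in implant_info) {
    for (j in seq_along(info$trio_rows)) {
      add_event(info$trio_rows[j], info$gene, sample(plof_choices, 1),
                "mid", numeric(), FALSE, "implant_class1", offset = 3L * (j - 1L))
    }
  }
  for (info in singleton_info) {
    add_event(info$trio_row, info$gene, sample(plof_choices, 1),
              "mid", numeric(), FALSE, "implant_singleton")
  }
  for (i in seq_along(decoy_types)) {
    type <- decoy_types[i]
    g <- decoy_genes[i]
    add_event(decoy_rows[i], g,
              consequence = "stop_gained",
              policy = if (type == "last_exon") "last_exon" else "mid",
              af = if (type == "high_af") c(nfe = 0.01, afr = 0.002) else numeric(),
              inherited = type == "inherited",
              origin = paste0("decoy_", type))
  }
  # background events
  n_bg <- rpois(config$n_trios, config$denovo_rate_per_trio)
  bg_plof_pool <- sample(c(known_t0, setdiff(plain, c(na_genes, drop_genes))))
  bg_any_pool <- c(known_t0, plain)
  gene_occupancy <- new.env(parent = emptyenv())
  next_offset <- function(g) {
    cur <- get0(g, envir = gene_occupancy, ifnotfound = 0L)
    assign(g, cur + 1L, envir = gene_occupancy)
    cur
  }
  draw_af <- function() {
    af <- c(afr = NA_real_, nfe = NA_real_, eas = NA_real_)
    for (popn in names(af)) {
      if (runif(1) >= config$af_noise$prob_absent) {
        af[[popn]] <- min(rlnorm(1, config$af_noise$meanlog,
                                 config$af_noise$sdlog), 0.9)
      }
    }
    af[!is.na(af)]
  }
  for (t in seq_len(config$n_trios)) {
    if (n_bg[t] == 0L) next
    for (e in seq_len(n_bg[t])) {
      if (runif(1) < config$plof_fraction && length(bg_plof_pool) > 0L) {
        g <- bg_plof_pool[1]
        bg_plof_pool <- bg_plof_pool[-1]
        cons <- sample(c(plof_choices, "splice_donor_variant"), 1,
                       prob = c(0.45, 0.45, 0.1))
        pol <- if (cons == "splice_donor_variant") "splice_donor" else "mid"
        add_event(t, g, cons, pol, draw_af(), FALSE, "background_plof",
                  offset = 3L * next_offset(g))
      } else {
        g <- sample(bg_any_pool, 1)
        cons <- sample(c("missense_variant", "synonymous_variant"), 1,
                       prob = c(0.7, 0.3))
        add_event(t, g, cons, "mid", draw_af(), FALSE, "background_other",
                  offset = 3L * next_offset(g))
      }
    }
  }
  events <- bind_rows(events) %>%
    arrange(chrom_rank(.data$chrom), .data$pos, .data$alt, .data$child_id)
  events$variant_key <- variant_key(events$chrom, events$pos, events$ref,
                                    events$alt)
  if (anyDuplicated(events$variant_key)) {
    abort("internal error: duplicate injected variant positions")
  }

  # --- VCF ---
  write_sim_vcf(events, trios, p("cohort.vcf"))

  # --- phenotypes ---
  pheno <- purrr::map_dfr(seq_len(config$n_trios), function(t) {
    k <- sample(config$background_hpo_range[1]:config$background_hpo_range[2], 1)
    tibble(patient_id = trios$child_id[t],
           term = sample(all_leaves, min(k, length(all_leaves))))
  })
  for (info in implant_info) {
    pheno <- bind_rows(pheno, tibble(
      patient_id = rep(trios$child_id[info$trio_rows],
                       each = length(info$shared_terms)),
      term = rep(info$shared_terms, length(info$trio_rows))
    ))
  }
  for (info in singleton_info) {
    pheno <- bind_rows(pheno, tibble(
      patient_id = trios$child_id[info$trio_row], term = info$own_terms))
  }
  pheno <- distinct(pheno) %>% arrange(.data$patient_id, .data$term)
  write_phenotypes(pheno, p("phenotypes.tsv"))

  # --- known gene snapshots ---
  t0 <- tibble(
    gene = known_t0,
    inheritance = sample(c("dominant", "recessive", "other"),
                         length(known_t0), replace = TRUE,
                         prob = c(0.5, 0.4, 0.1))
  ) %>% arrange(.data$gene)
  write_known_genes(t0, p("known_genes_t0.tsv"))

  n_pub1 <- round(config$publish_fraction_class1 * length(implanted))
  pub_class1 <- head(sample(implanted), n_pub1)
  other_contenders <- c(
    singletons,
    unique(events$gene[events$origin == "background_plof" &
                         events$expected_fate == "pass"])
  )
  pub_other <- other_contenders[
    rbinom(length(other_contenders), 1, config$publish_fraction_other) == 1L]
  published <- c(pub_class1, pub_other)
  to_omim <- published[seq_along(published) %% 2L == 1L]
  to_lit <- setdiff(published, to_omim)
  t1 <- bind_rows(t0, tibble(gene = to_omim, inheritance = "dominant")) %>%
    arrange(.data$gene)
  write_known_genes(t1, p("known_genes_t1.tsv"))
  writeLines(sort(to_lit), p("literature_t1.txt"))

  # --- external database ---
  n_cov <- round(config$external_db_coverage * length(singletons))
  covered <- purrr::map_lgl(seq_along(singleton_info),
                            function(i) i <= n_cov)
  ext <- purrr::map_dfr(seq_along(singleton_info), function(i) {
    info <- singleton_info[[i]]
    tibble(gene = info$gene,
           variant_class = sample(c("pLoF", "missense"), 1),
           de_novo = covered[i],
           high_level_phenotypes = info$branch)
  })
  eventless <- setdiff(plain, events$gene)
  distract <- head(eventless, 3)
  if (length(distract) > 0) {
    ext <- bind_rows(ext, tibble(
      gene = distract, variant_class = "missense", de_novo = TRUE,
      high_level_phenotypes = sample(branches, length(distract), replace = TRUE)
    ))
  }
  readr::write_tsv(ext %>% arrange(.data$gene), p("external_db.tsv"))

  # --- transcripts ---
  write_transcripts(transcripts, p("transcripts.tsv"))

  # --- manifest ---
  manifest <- list(
    config = unclass(config),
    implanted_class1 = purrr::map(implant_info, function(info) list(
      gene = info$gene, branch = info$branch,
      shared_terms = info$shared_terms,
      families = trios$family_id[info$trio_rows],
      expected_class = 1L,
      published = info$gene %in% published
    )),
    singleton_implants = purrr::map(seq_along(singleton_info), function(i) {
      info <- singleton_info[[i]]
      list(gene = info$gene, branch = info$branch,
           external_matched = covered[i],
           expected_class = if (covered[i]) 2L else 3L,
           published = info$gene %in% published)
    }),
    decoys = purrr::map(seq_along(decoy_types), function(i) list(
      type = decoy_types[i], gene = unname(decoy_genes[i]),
      family = trios$family_id[decoy_rows[i]]
    )),
    events = as.data.frame(events[, c("variant_key", "chrom", "pos", "ref",
                                      "alt", "gene", "consequence",
                                      "family_id", "child_id", "origin",
                                      "expected_fate")]),
    published_t1 = sort(published),
    literature_only_t1 = sort(to_lit),
    counts = list(
      n_trios = config$n_trios,
      n_events_total = nrow(events),
      n_background = sum(n_bg),
      n_expected_pass = sum(events$expected_fate == "pass")
    )
  )
  paths <- list(
    vcf = p("cohort.vcf"), pedigree = p("pedigree.ped"),
    constraint = p("constraint.tsv"),
    known_genes_t0 = p("known_genes_t0.tsv"),
    known_genes_t1 = p("known_genes_t1.tsv"),
    literature_t1 = p("literature_t1.txt"),
    phenotypes = p("phenotypes.tsv"), ontology = p("ontology.obo"),
    external_db = p("external_db.tsv"), transcripts = p("transcripts.tsv"),
    manifest = p("manifest.json")
  )
  manifest$files <- lapply(paths, basename)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$paths <- paths
  invisible(manifest)
}

# write the cohort VCF: one column per trio member, CSQ annotations with
# per-population AFs
write_sim_vcf <- function(events, trios, path) {
  samples <- as.vector(rbind(trios$child_id, trios$father_id, trios$mother_id))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations. Format: Allele|Consequence|SYMBOL|Feature|AF_afr|",
           "AF_nfe|AF_eas\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  col_of <- setNames(seq_along(samples), samples)
  fmt_af <- function(x) ifelse(is.na(x), "", sprintf("%.6e", x))
  default_gt <- "0/0:50:30:30,0"
  body <- character(nrow(events))
  gmat <- matrix(default_gt, nrow = nrow(events), ncol = length(samples))
  for (i in seq_len(nrow(events))) {
    gmat[i, col_of[[events$child_id[i]]]] <- events$child_gt[i]
    gmat[i, col_of[[events$father_id[i]]]] <- events$father_gt[i]
    gmat[i, col_of[[events$mother_id[i]]]] <- events$mother_gt[i]
  }
  csq <- sprintf("CSQ=%s|%s|%s|%s|%s|%s|%s", events$alt, events$consequence,
                 events$gene, events$transcript_id, fmt_af(events$af_afr),
                 fmt_af(events$af_nfe), fmt_af(events$af_eas))
  for (i in seq_len(nrow(events))) {
    body[i] <- paste(c(events$chrom[i], events$pos[i], ".", events$ref[i],
                       events$alt[i], "100", "PASS", csq[i], "GT:GQ:DP:AD",
                       gmat[i, ]), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
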