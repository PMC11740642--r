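---
title: "Methods: gene-to-patient discovery of de novo pLoF variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-to-patient discovery of de novo pLoF variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis model

`triolof` implements a deliberately *non-statistical* cohort-wide filter
for dominant novel disease genes. Rather than modelling per-gene de novo
mutation rates (the DeNovoWEST/DeNovolyzeR family of approaches, which
need large phenotypically homogeneous cohorts), it relies on the
compounding specificity of four orthogonal filters, each of which is
individually simple:

1. **De novo configuration.** A variant counts only when the affected
   child of a complete parent–offspring trio is heterozygous and both
   parents are homozygous reference, with configurable genotype-quality
   gates on top (`dn_config()`).
2. **pLoF consequence.** Only consequences expected to abolish the gene
   product: stop gained, frameshift, canonical splice acceptor/donor,
   start lost, stop lost. Start/stop loss are retained in the set even
   though their selective signatures are closer to missense; they are a
   small minority of calls and flow through the same confidence flags.
3. **LoF confidence.** A reduced LOFTEE-style heuristic
   (`assess_lof_confidence()`) demotes calls unlikely to trigger
   nonsense-mediated decay: variants in the terminal exon, premature
   stops/frameshifts within 50 bp of the 3' end of the penultimate exon
   (the canonical NMD-escape window upstream of the last exon–exon
   junction), single-exon transcripts, and — when a reference FASTA is
   supplied — splice calls whose intronic dinucleotide is not GT/AG.
4. **Rarity and constraint.** Maximum allele frequency across reference
   populations strictly below 0.001, and gene LOEUF strictly below 0.2
   (the first decile of the gnomAD v2.1.1 distribution, the genes most
   intolerant to inactivation and hence most plausibly haploinsufficient).

Surviving events in genes already carrying *any* disease association
(dominant, recessive or other) are set aside; the rest are novel disease
gene contenders, tiered by phenotype evidence into classes 1–3 (exact
internal HPO matching; organ-system-level external matching; no support).
A later knowledge snapshot then measures, per class, how many contenders
were independently published — with exact contingency statistics.

### Assumptions

* Gene identity is by symbol, case-sensitively; all inputs (constraint
  table, knowledge snapshots, external database) are assumed to share a
  symbol namespace. Symbol drift across resources is out of scope.
* Family IDs demarcate relatedness: distinct families are treated as
  unrelated kindreds, affected siblings within one family as a single
  kindred. No genetic relatedness check is performed.
* Upstream variant calling is trusted; the quality gates guard the de novo
  configuration specifically, not call quality in general.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `af_max` | 0.001 | allele fraction | liberal rarity bound; dominant pathogenic variants can persist at low frequency via incomplete penetrance |
| `loeuf_max` | 0.2 | LOEUF score | first-decile constraint, maximally enriched for haploinsufficiency |
| `min_gq` | 20 | phred | conventional genotype-quality floor |
| `min_dp` | 10 | reads | conventional depth floor for trusting a het call |
| `ab_range` | [0.2, 0.8] | fraction | heterozygous allele-balance window |
| `max_parent_alt_frac` | 0.05 | fraction | a parent with > 5 % ALT reads fails hom-ref, guarding against under-called mosaicism |
| `anchor` | HP:0000118 | HPO term | its direct children are the organ-system vocabulary used for upscaling |

Both filter thresholds are **strict** inequalities: a variant at AF exactly
0.001 is removed, a gene at LOEUF exactly 0.2 is removed. The synthetic
generator plants a decoy gene at LOEUF = 0.2 precisely to pin this
boundary. Genes absent from the constraint table (or with missing scores)
can never satisfy the constraint gate; their count is reported separately.

## Design choices where the design was open

* **Multi-kindred exact matching.** With three or more kindreds, class 1
  requires only that *some* pair of children from different families
  shares an exact term. Any-pair matching maximizes class-1 sensitivity,
  which is the point of the tier; requiring all pairs to match would
  punish exactly the variable phenotyping depth the exact-match rule
  already struggles with.
* **Multi-kindred genes without an internal match** fall through to the
  class-2 external test rather than straight to class 3 — external
  evidence does not stop being evidence because a second kindred exists.
* **Events spanning genes.** One (variant, child) pair passing on several
  transcripts of the same gene is a single event; on transcripts of
  different genes it contributes one event per gene. The funnel counts
  events per (variant, child) so it remains monotone regardless.
* **Exact test convention.** `fisher_exact_two_sided()` sums hypergeometric
  point probabilities not exceeding the observed one with relative
  tolerance `1 + 1e-7`, computed with log-factorials — the dominant
  convention in statistical software, adopted because no alternative
  two-sided rule was specified for the analysis it reproduces. A class
  with zero genes makes its test not-applicable (`NA`), never 1.
* **Missing population AF** means unobserved and contributes 0 to the
  maximum ("absent from the reference database" is itself evidence of
  rarity).
* **LOFTEE reduction.** The full LOFTEE rule set (ancestral alleles,
  pext, intron size, ...) is reduced to the four flags above: they cover
  the dominant NMD-escape failure modes while remaining auditable from an
  exon table alone. Without a FASTA the splice dinucleotide check cannot
  fire and splice annotations are trusted as canonical. "Terminal coding
  exon" is approximated by the terminal exon of the model, so no CDS
  sub-annotation is required.
* **Degenerate inputs.** A pLoF call whose transcript is missing from the
  exon models is *unevaluable*: it is excluded with a logged reason, never
  silently promoted to high confidence. Patients without a phenotype
  profile get an empty one (they can still anchor class-2 evidence through
  other kindreds, but never an exact match).

## What the synthetic cohort emulates — and what it does not

The generator (`simulate_cohort()`) reproduces the statistical structure
the pipeline's correctness depends on: Poisson-distributed background de
novo events (default 1.5 per trio, of which 10 % pLoF), a LOEUF mixture
with a configurable constrained fraction (default 0.1, mirroring the
first-decile gate), implanted class-1 genes whose carriers in unrelated
families share exact HPO leaf terms drawn from one ontology branch,
singleton implants covered by external de novo records at the matching
organ-system term, decoys engineered to fail exactly one filter each
(last-exon placement, AF 0.01, LOEUF exactly 0.2, paternal inheritance),
and background patients with 1–5 uniformly drawn phenotype terms.

Two structural guarantees make the ground truth identifiable at any seed:
background pLoF events are placed in *distinct* genes (recurrence across
kindreds is reserved for implanted genes — in this framework recurrence
*is* the signal), and external-database distractor records only name genes
without events. Defaults (200 trios, 500 genes, 5 implanted class-1 genes
× 2 kindreds, 3 singleton implants, 4 decoys, 60 % of class-1 implants
published at the later snapshot) were fixed once as a desk-scale image of
the cohort structure this method targets.

The generator does **not** emulate: read-level sequencing error, per-gene
mutation-rate variation, population structure in allele frequencies,
phenotype-term correlation beyond the implanted branches, symbol-mapping
noise, or enrichment of the cohort for one clinical specialty. Passing
recovery tests on synthetic data therefore demonstrates the *logic* of the
filters and classifier, not robustness to the noise sources of a real
aggregate VCF.

## Verification strategy and problem sizes

The test suite checks each operation against an independent oracle where
one exists: the de novo caller against a naive triple-loop
reimplementation on random 30–50-variant × 8–10-trio cohorts; the exact
test against exhaustive enumeration with `choose()` over all 2×2 tables
with total at most 30, and against `stats::fisher.test`; the classifier
against hand-built single-branch fixtures and a monotonicity property
(adding phenotype terms never demotes a gene). End-to-end, the pipeline is
required to assign every injected event its manifest fate and to recover
all and only the implanted class-1 genes, on the default 200-trio bundle
and across 100 randomly drawn 15–40-trio configurations. Validation
statistics are exercised on the bundled reference per-class tallies
(18/49/50 contender genes with 11/2/10 published), for which the class-3
vs class-2 two-sided test gives p ≈ 0.0277 and the class-1 vs rest test
p ≈ 2.3 × 10⁻⁵.

## Known limitations

* Exact HPO matching misses near-synonymous terms (intellectual
  disability vs mild intellectual disability); this is faithful to the
  method, which accepts the sensitivity cost in exchange for objectivity.
* System-level external matching is coarse, and including external
  missense records trades precision for coverage; the validation
  statistics exist precisely to quantify that trade.
* Recessive/biallelic discovery is out of scope by construction
  (constraint gate targets haploinsufficiency).
* The simplified LoF-confidence heuristic will differ from full LOFTEE on
  edge cases (ancestral-allele rescues, pext-low exons, minimal introns).
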