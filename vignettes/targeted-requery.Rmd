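---
title: "Targeted re-query of clinical exome stores driven by literature alerts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted re-query of clinical exome stores driven by literature alerts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litquery)
```

## The problem

Exome sequencing (ES) leaves the majority of probands with developmental
disorders or intellectual disability (DD/ID) undiagnosed at first analysis,
largely because causative genes are published faster than curated databases
(OMIM, ClinVar) and diagnostic pipelines absorb them. Periodic full
reanalysis recovers some of these diagnoses but is organizationally heavy.
An alternative is *targeted* reanalysis: a biologist monitors the
literature daily, and every newly implicated gene triggers an immediate
whole-word text query over the laboratory's accumulated per-sample variant
tables. `litquery` implements that strategy as a reusable engine:

1. **store_io** — read/write/scan a heterogeneous store of annotated
   variant tables produced by multiple pipeline versions;
2. **query_engine** — the basic whole-word query (v1), the scripted query
   adding duplicate removal and schema harmonization (v2), and the
   end-point batch re-query with delta detection against a seen-variant
   ledger;
3. **alerts** — structured gene-alert records modelling the bibliographic
   monitoring output;
4. **triage** — rarity filtration and matching of hits against the alert's
   reported variant class and inheritance mode;
5. **acmg** — ACMG–AMP evidence combination and segregation-driven
   reclassification;
6. **reporting** — query metrics, classification tallies, diagnostic
   yields, delay statistics, and a deterministic report renderer;
7. **synthetic** — a seeded store simulator with planted ground truth.

## The variant store and its dialects

Analysis files are tab-separated text tables derived from VCF (hg19,
1-based coordinates, chromosome labels preserved as given) with the eight
VCF core columns first and custom annotations after: population allele
frequencies and occurrence counts (ESP, ExAC, gnomAD exome/genome, an
internal control count, a batch count), in-silico scores (Polyphen, GERP,
Grantham, CADD, misZ, pLI), OMIM name/number/mode and the ClinVar class.
A second pipeline generation (`schema_v2()`) added the o/e
loss-of-function ratio with its bounds, a splicing prediction flag and the
CCR percentile. Missing cells are a single gap token, `"."` by default; in
memory they are `NA`, never silently zero.

Two design points were genuinely open and are resolved as follows:

* **"Most recent analysis".** Nothing in a text table says when it was
  produced. We read `analysis_timestamp` from a JSON manifest shipped with
  the store rather than from filesystem mtime, so a store scans
  identically wherever it is copied. Timestamp ties are broken by version
  tag (descending) then path; a full duplicate is an ambiguity error.
* **Coordinates.** No normalization between `"6"` and `"chr6"` is
  attempted; mixed stores are rejected with a clear error, because silent
  relabelling is how cross-pipeline stores acquire duplicate variants.

HGVS-g position strings from diagnostic reports
(`"chr2:g.130914204_130914206del"`) parse into variant keys with symbolic
`DEL`/`DUP` alternate tokens and the stated span; substitutions parse
ref/alt literally.

## Query semantics

The v1 query emulates `grep -w`: a whole-word, case-sensitive match where
token characters are `[A-Za-z0-9_-]`. Including `-` in the token class
means `NKX2-5` is one token — a plain word-boundary regex would split at
the hyphen and let a query for `NKX2` hit `NKX2-5`. A query for `GENE1`
never matches `GENE10`. By default matching is scoped to the gene-symbol
column (precision); `full_line = TRUE` searches every text field, which is
the faithful emulation of a text grep and is what the tokenizer-oracle
property tests exercise.

The v2 query is `harmonize_rows(dedup_latest(v1))`: one row per (sample,
variant) from the most recent analysis, made rectangular under a master
schema with gaps filled. Its line count is therefore never larger than
v1's, and on a store where every sample has *k* analyses the v1/v2 ratio
is exactly *k* — duplication across reanalyses is the only inflation
source, which is also the property asserted on simulated stores.

The end-point re-query replays all previously searched genes against the
grown store and returns only (gene, sample, variant) triples absent from
an append-only ledger. Cumulative daily deltas over a growing store equal
a single final query — the equivalence is tested over simulated growth.

## Triage rules

Rarity is a strict `max(AF) < 1%` over the configured population sources;
the maximum is the most conservative aggregate. Variants missing every
frequency annotation are treated as rare by default (absence from
population databases is evidence of rarity, and early pipeline versions
lack some sources entirely). Internal cohort counts are reported but not
thresholded.

Candidate matching follows the reported-association principle: a hit is a
candidate only if its effect class is among those the source manuscript
reported (protein-truncating; missense, optionally restricted to a
protein domain; splice) *and* its family segregation is compatible with a
reported inheritance mode, or unknown. Three deliberate choices:

* **Inherited hits under de-novo-only alerts are kept, flagged**
  `inherited-from-asymptomatic-parent`, not dropped. Inheritance from an
  asymptomatic parent is the main reason such variants end as VUS rather
  than likely pathogenic, and silently discarding them would lose exactly
  the stratum most often reclassified later.
* **In-frame single-residue indels** pass through the missense gates
  (they are position-bearing single-residue changes, so the domain check
  applies), not the truncating gate.
* **Unknown-consequence (`p.?`) variants** match only alerts that report
  a splice class by default (`splice_requires_alert_class = TRUE`); the
  lenient alternative is a configuration flag, because practice on such
  variants varies when the source manuscript reported only truncating
  alleles.

Compound heterozygotes under recessive alerts are paired from *stated*
segregation only (a maternal and a paternal row in the same sample); no
read-backed phasing is attempted. Since a sample-level map cannot
distinguish the two arms, a per-variant `segregation` column on the rows
takes precedence over the map.

Truncating variants in loss-of-function-intolerant genes (pLI > 0.9 or
o/e < 0.3) are flagged `lof_intolerant` — the stratum easiest to
interpret — but the flag does not gate candidacy.

## ACMG–AMP combination

`combine_criteria()` implements the unmodified combining table of the
ACMG–AMP standard (no laboratory-specific strength overrides; strength is
a pure function of the code). Pathogenic and likely-pathogenic rules are
evaluated before benign rules; simultaneous satisfaction of both sides is
a VUS with rationale `"conflicting"`, and no rule at all a VUS with
`"insufficient"`. The implementation is checked against an independently
coded rule-table oracle over all 256 subsets of the eight codes occurring
in the packaged retrospective-criteria cells, plus random subsets of the
full code set.

Segregation evidence is applied afterwards: under a de-novo-only alert a
parentally inherited candidate has any provisional P/LP downgraded to VUS
(`"inherited-unreported"`); a trio-confirmed de novo adds PS2 before
recombination; unknown segregation only flags `segregation-pending`. The
operation is idempotent and logs reclassifications as `before->after`.
A later upgrade (new publication superseding an alert) is modelled as a
new alert record, never as mutation of history.

## Reporting conventions

Per-gene line-count means truncate toward zero (82,156 lines over 52
genes prints as 1,579, not 1,580), matching how such means are printed;
yields round half-up, cohort-level yields to one decimal and gene-level
fractions to integers. Delay statistics use the sample SD (n−1); unknown
("ND") delays are excluded and counted, and the SD of a single delay is
reported `NA`. The report renderer sorts candidates by gene then position
and uses fixed number formats, so identical inputs give byte-identical
output.

## Packaged example data

`candidate_fixture()` is a 56-row transcription of the candidate-variant
table of a diagnostic exome reanalysis programme (36 genes, 53 affected
individuals; per-row classification marks and, for 19 rows, retrospective
ACMG–AMP criteria). Because the source table prints patient counts per
gene block, the `individual_ids` column is a curated reading of how those
counts distribute over rows — biallelic pairs share one individual, an
affected sib pair shares both rows — and reproduces the programme's 53
distinct flagged individuals and 21 individuals with a causative variant.
Gene-level tallies that are not derivable from the printed table (19
causal genes, 25 daily-positive genes, 44 causative-or-VUS individuals)
are carried as reported constants in `monitoring_summary()` and used as
inputs to `cohort_yields()`, exactly like the cohort counts in
`cohort_summary()`.

`monitoring_alerts()` is a 128-record alert set with the documented
category totals (100 novel / 9 distinct disorder in a known gene / 19
phenotype updates; 37 of the novel genes not yet OMIM-morbid and one
absent). The 36 candidate-table genes appear under their real symbols
with curated inheritance and class profiles; the other 92 records are
synthetic (`SYNG...`), as are all protein-domain intervals — the file is
named accordingly.

## The synthetic store generator

`simulate_store()` emulates the store, not the biology: independent
background variants (no linkage or haplotype structure), a configurable
common/rare frequency mixture around the 1% threshold, one to three
analyses per sample with version-appropriate schemas (earlier analyses on
the narrow v1 schema, the latest on v2), and planted variants with known
expected outcomes. Defaults — 20 samples, analyses weights 0.3/0.5/0.2,
40 background variants per sample, 30% common — are a deliberately small
slice of a clinical store that still exercises every contract:
duplication, harmonization, rarity, whole-word decoys (`GENE1` vs
`GENE10`), hyphenated symbols. The seed fully determines the output;
byte-identical regeneration is a test. Passing tests on this generator
demonstrate the engine's contracts (recall of planted candidates,
rejection of common or class-mismatched plants), *not* performance on real
exomes: real annotation noise, multi-allelic sites, pipeline-specific
quirks and genuine splice annotations are out of its scope.

Property suites run on problem sizes chosen to keep the whole test run in
well under a minute of simulation time: stores of 6–10 samples with ~20
background variants, 20 seeded recall configurations, and one 10,000-draw
frequency-mixture check.

## Worked example

```{r example}
cfg <- sim_config(
  n_samples = 8,
  planted = plant_variant("GENE1", "S0002", "chr7", 1234567L, "A", "T",
                          "p.(Arg100*)", segregation = "de_novo"),
  seed = 42)
sim <- simulate_store(cfg, file.path(tempdir(), "demo_store"))

v1 <- grep_word_v1("GENE1", sim$store)
v2 <- query_gene_v2("GENE1", sim$store)
c(v1 = v1$line_count, v2 = v2$line_count)

alert <- gene_alert("GENE1", inheritance = "de_novo_dominant",
                    classes = "protein_truncating")
cand <- run_query_pipeline(alert, sim$store, sim$segregations)
cand$criteria <- "PVS1,PM2"
cand <- apply_segregation_evidence(cand, alert, trio_confirmed = TRUE)
cand[, c("GENE", "POS", "effect_class", "segregation", "classification")]
```

And the published-surface computations:

```{r fixture}
fx <- candidate_fixture()
classification_summary(fx, queried_genes = 128)[
  c("n_variants", "n_genes", "n_individuals", "individuals_causative")]
all(replay_retrospective_criteria(fx)$agree)
unlist(cohort_yields(21, 53, 44, 19, 25, 128))
```

## Known limitations

* No variant calling, normalization/left-alignment, liftover, CNV,
  mitochondrial or non-coding logic: the store is taken as produced
  upstream, and only rare nuclear SNVs/indels are in scope.
* No gene alias resolution or fuzzy matching: queries are literal symbols,
  as in the workflow modelled; a warning is emitted when a symbol is
  absent from every file.
* No automated evidence derivation (e.g. computing PM2 from gnomAD):
  criteria come from the analyst or explicit upstream mappings.
* No PubMed querying or text mining: alerts are local records; the OMIM
  status is a curation-time snapshot precisely because OMIM lags
  publication.
* Printed delay averages of the source programme are not asserted
  anywhere: their unit and averaging population are ambiguous, so the
  package computes delay statistics but treats them as descriptive.
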