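# litquery

Targeted reanalysis of clinical exome databases driven by literature
alerts.

## The problem

Exome sequencing leaves most probands with developmental disorders or
intellectual disability (DD/ID) undiagnosed at first pass, and newly
published disease genes take months to reach OMIM/ClinVar and the
diagnostic pipelines that depend on them. Full periodic reanalysis
recovers diagnoses but is heavy; a lighter alternative is *targeted*
re-query: every gene flagged by daily bibliographic monitoring is
immediately searched, as a whole word, across the laboratory's accumulated
per-sample annotated variant tables, and the hits are triaged against what
the source manuscript reported.

`litquery` implements that strategy end to end for laboratories whose
variant store is a directory of tab-separated, VCF-derived tables written
by successive pipeline versions:

* **whole-word gene queries** — the basic query (v1, duplicates retained,
  `GENE1` never matches `GENE10`) and the scripted query (v2) that keeps
  only the most recently analyzed file per sample and fills annotation
  gaps with `"."` to give one rectangular spreadsheet;
* **end-point re-queries** — batch replay of all previously searched genes
  with an append-only ledger, returning only unseen (sample, variant)
  pairs; cumulative daily deltas provably equal one final query;
* **triage** — rare-variant filtration (max population allele frequency
  < 1%) and matching against the alert's reported variant classes
  (protein-truncating / in-domain missense / splice) and inheritance mode,
  with compound-het pairing from stated segregation;
* **ACMG–AMP classification** — the unmodified combining rules
  (`combine_criteria()`), plus segregation-driven reclassification
  (inherited-under-de-novo-alert downgrades to VUS, trio-confirmed de novo
  adds PS2);
* **reporting** — line-count metrics and v1/v2 fold reduction, positive /
  negative query tallies, diagnostic yields at printed precision, delay
  statistics, and a byte-deterministic report renderer;
* **synthetic stores** — a seeded generator with planted ground truth so
  the whole engine is testable offline.

## Worked example

```r
library(litquery)

cfg <- sim_config(
  n_samples = 8,
  planted = plant_variant("GENE1", "S0002", "chr7", 1234567L, "A", "T",
                          "p.(Arg100*)", segregation = "de_novo"),
  seed = 42)
sim <- simulate_store(cfg, file.path(tempdir(), "demo_store"))

v1 <- grep_word_v1("GENE1", sim$store)
v2 <- query_gene_v2("GENE1", sim$store)
c(v1 = v1$line_count, v2 = v2$line_count)
#> v1 v2
#> 21 10

alert <- gene_alert("GENE1", inheritance = "de_novo_dominant",
                    classes = "protein_truncating")
cand <- run_query_pipeline(alert, sim$store, sim$segregations)
cand$criteria <- "PVS1,PM2"
cand <- apply_segregation_evidence(cand, alert, trio_confirmed = TRUE)
cand[, c("GENE", "POS", "segregation", "classification")]
#> # A tibble: 1 × 4
#>   GENE      POS segregation classification
#>   <chr>   <int> <chr>       <chr>
#> 1 GENE1 1234567 de_novo     pathogenic
```

The v1 query returns 21 lines (the planted variant plus background hits in
the same gene, duplicated across each sample's one to three reanalyses);
the scripted v2 query collapses them to the 10 distinct variants from each
sample's latest analysis. Triage keeps the rare de
novo truncating hit, and the ACMG–AMP combiner classifies it pathogenic
once trio confirmation adds PS2 to PVS1 + PM2.

The packaged example data reproduce the headline numbers of the
reanalysis programme the package models:

```r
fx <- candidate_fixture()
classification_summary(fx, queried_genes = 128)[
  c("n_variants", "n_genes", "n_individuals", "individuals_causative")]
#> $n_variants    [1] 56
#> $n_genes       [1] 36
#> $n_individuals [1] 53
#> $individuals_causative [1] 21

unlist(cohort_yields(21, 53, 44, 19, 25, 128))
#>       causal_yield_undiagnosed_pct                flagged_proband_pct
#>                                0.7                                1.4
#>        causative_among_flagged_pct causative_or_vus_among_flagged_pct
#>                               39.6                               83.0
#>                    causal_gene_pct                  positive_gene_pct
#>                               15.0                               20.0
```

A thin command-line front-end over these functions ships as
`inst/scripts/litquery.R` (subcommands `grep`, `endpoint`,
`alerts-validate`, `simulate`, `report`).

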