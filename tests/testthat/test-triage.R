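test_that("protein-change strings classify into effect classes", {
  eff <- classify_variant_effect(c("p.(Arg423*)", "p.(Gly792Glu)",
                                   "p.Phe419del", "p.?",
                                   "p.(Glu2054Lysfs*14)", "p.Gln1292*",
                                   "p.(Ala116Cysfs*81)"))
  expect_equal(eff$effect_class,
               c("protein_truncating", "missense", "inframe_indel",
                 "unknown_splice", "protein_truncating",
                 "protein_truncating", "protein_truncating"))
  expect_equal(eff$protein_position[2], 792L)
  expect_equal(eff$protein_position[3], 419L)
  expect_warning(odd <- classify_variant_effect("p.oddball"), "unparseable")
  expect_equal(odd$effect_class, "unknown_splice")
  # every protein change in the packaged candidate table parses cleanly
  expect_silent(fx <- classify_variant_effect(candidate_fixture()$protein_change))
  expect_true(all(fx$effect_class %in% c("protein_truncating", "missense",
                                         "inframe_indel", "unknown_splice")))
})

test_that("rarity filtering thresholds the maximum population frequency", {
  rows <- harmonize_rows(tibble::tibble(
    CHROM = "chr1", POS = 1:4 * 100L, ID = NA, REF = "A", ALT = "T",
    QUAL = "50", FILTER = "PASS", INFO = NA, GENE = "GENE1",
    AF_GNOMAD_EXOME = c(0.02, 0.0001, NA, 0.005),
    AF_GNOMAD_GENOME = c(NA, NA, NA, 0.03)))
  kept <- filter_rare(rows)
  expect_equal(kept$POS, c(200L, 300L)) # 0.02 and max(0.005, 0.03) excluded
  strict <- filter_rare(rows, triage_config(treat_missing_af_as_rare = FALSE))
  expect_equal(strict$POS, 200L)
  expect_error(filter_rare(rows, triage_config(af_sources = "AF_NOPE")),
               "AF_NOPE")
})

test_that("the kept set shrinks monotonically with the threshold", {
  set.seed(31)
  for (rep in 1:5) {
    rows <- harmonize_rows(random_rows(40))
    tight <- filter_rare(rows, triage_config(af_threshold = 0.005))
    loose <- filter_rare(rows, triage_config(af_threshold = 0.01))
    expect_true(all(paste(tight$CHROM, tight$POS) %in%
                      paste(loose$CHROM, loose$POS)))
  }
})

test_that("segregation descriptions parse onto the closed vocabulary", {
  expect_equal(
    parse_segregation(c("De novo", "Maternally inherited",
                        "Paternally and maternally inherited", "ND",
                        "Not maternally inherited",
                        "Probable paternal inheritance", NA, "de_novo")),
    c("de_novo", "maternally_inherited", "biparental", "unknown",
      "not_maternal", "paternally_inherited", "unknown", "de_novo"))
})

triage_row <- function(gene = "ZNF292", protein = "p.(Glu2054Lysfs*14)",
                       af = NA_real_, sample = "S1", pos = 1000L) {
  harmonize_rows(tibble::tibble(
    CHROM = "chr6", POS = pos, ID = NA, REF = "A", ALT = "T", QUAL = "50",
    FILTER = "PASS", INFO = NA, GENE = gene, PROTEIN = protein,
    AF_GNOMAD_EXOME = af, sample_id = sample))
}

test_that("candidates require the reported class and inheritance", {
  alert <- gene_alert("ZNF292", inheritance = "de_novo_dominant",
                      classes = "protein_truncating")
  denovo <- match_candidates(triage_row(), alert, c(S1 = "de_novo"))
  expect_equal(nrow(denovo), 1L)
  expect_match(denovo$match_reasons, "class:protein_truncating")
  expect_match(denovo$match_reasons, "inheritance:de_novo_dominant")

  # a common missense row fails both the class and the frequency gate
  common <- triage_row(protein = "p.(Ala10Gly)", af = 0.2)
  expect_equal(nrow(match_candidates(common, alert, c(S1 = "de_novo"))), 0L)

  # inherited truncating under a de-novo-only alert is kept but flagged
  inh <- match_candidates(triage_row(), alert,
                          c(S1 = "paternally_inherited"))
  expect_equal(inh$flags, "inherited-from-asymptomatic-parent")

  # unknown-consequence variants need a reported splice class
  splice_row <- triage_row(protein = "p.?")
  expect_equal(nrow(match_candidates(splice_row, alert,
                                     c(S1 = "de_novo"))), 0L)
  alert_sp <- gene_alert("ZNF292", classes = c("protein_truncating",
                                               "splice"))
  expect_equal(nrow(match_candidates(splice_row, alert_sp,
                                     c(S1 = "de_novo"))), 1L)
  expect_error(match_candidates(triage_row(),
                                structure(list(gene = "ZNF292",
                                               inheritance = "de_novo_dominant",
                                               classes = character()),
                                          class = "gene_alert"),
                                c(S1 = "de_novo")),
               "no reported variant classes")
})

test_that("in-domain missense matching uses the alert's domain intervals", {
  alert <- gene_alert("GRIA2", classes = "missense_in_domain",
                      inheritance = "de_novo_dominant",
                      domains = list(c(760L, 820L)))
  inside <- triage_row("GRIA2", "p.(Gly792Glu)")
  outside <- triage_row("GRIA2", "p.(Gly100Glu)")
  expect_equal(nrow(match_candidates(inside, alert, c(S1 = "de_novo"))), 1L)
  expect_equal(nrow(match_candidates(outside, alert, c(S1 = "de_novo"))), 0L)
})

test_that("recessive alerts pair opposite parental origins as compound hets", {
  alert <- gene_alert("HPDL", inheritance = "autosomal_recessive",
                      classes = c("protein_truncating", "missense_any"))
  pair <- dplyr::bind_rows(
    triage_row("HPDL", "p.(Thr263Met)", pos = 100L),
    triage_row("HPDL", "p.(Ala116Cysfs*81)", pos = 200L))
  # stated biparental transmission on a single row
  bip <- match_candidates(pair[1, ], alert, c(S1 = "biparental"))
  expect_match(bip$match_reasons, "recessive-biparental")
  # compound het: one maternal, one paternal row in the same sample
  segs <- c(S1 = "maternally_inherited")
  one_sided <- match_candidates(pair, alert, segs)
  expect_equal(nrow(one_sided), 0L)
  pair$sample_id <- "S1"
  both <- match_candidates(pair, alert,
                           stats::setNames("maternally_inherited", "S1"))
  expect_equal(nrow(both), 0L)
  # need per-row segregation: emulate via two samples? phase comes from
  # stated segregation, so give the two rows opposite origins
  rows2 <- pair
  seg_by_row <- c("maternally_inherited", "paternally_inherited")
  # match_candidates keys segregation by sample; split rows across calls is
  # wrong, so feed a two-row sample with mixed origins via the seg map of a
  # synthetic duplicated sample id and per-row override below
  rows2$sample_id <- c("S1", "S1")
  # emulate a maternal+paternal pair by the documented convention: the
  # sample-level map cannot carry two values, so the pairing rule reads the
  # per-row segregation when a `segregation` column is present
  rows2$segregation <- seg_by_row
  both2 <- match_candidates(rows2, alert, character())
  expect_equal(nrow(both2), 2L)
  expect_true(all(grepl("recessive-biparental", both2$match_reasons)))
})

test_that("candidate emission agrees with a brute-force rule oracle", {
  effects <- list(
    c("p.(Arg100*)", "protein_truncating"),
    c("p.(Ala100Gly)", "missense"),
    c("p.Phe100del", "inframe_indel"),
    c("p.?", "unknown_splice"))
  segs <- c("de_novo", "maternally_inherited", "paternally_inherited",
            "biparental", "not_maternal", "unknown")
  class_sets <- list("protein_truncating", "missense_any",
                     c("missense_in_domain"), "splice",
                     c("protein_truncating", "missense_any", "splice"))
  mode_sets <- list("de_novo_dominant", "autosomal_dominant_inherited",
                    "autosomal_recessive",
                    c("de_novo_dominant", "autosomal_recessive"))
  domains <- list(c(50L, 150L))
  for (ef in effects) for (sg in segs) for (cs in class_sets)
    for (ms in mode_sets) {
      alert <- gene_alert("GENE1", inheritance = ms, classes = cs,
                          domains = domains)
      row <- triage_row("GENE1", ef[1])
      got <- nrow(match_candidates(row, alert,
                                   stats::setNames(sg, "S1"))) == 1L
      want <- oracle_is_candidate(ef[2], 100L, sg, cs, ms, domains)
      expect_equal(got, want,
                   info = paste(ef[1], sg, paste(cs, collapse = "+"),
                                paste(ms, collapse = "+")))
    }
})
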