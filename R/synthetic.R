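#' Simulation configuration for synthetic variant stores
#'
#' Describes a synthetic exome variant store with known ground truth: the
#' number of samples, the distribution of analyses per sample (repeated
#' analyses under successive pipeline versions are the duplication source a
#' scripted query must remove), the background variant load, the allele
#' frequency spectrum (a mixture of common and rare variants around the 1
#' percent rarity threshold), the gene universe, and a table of planted
#' variants with their expected triage outcome. The seed fully determines
#' the generated store: two runs with one seed are byte-identical.
#'
#' Defaults emulate a small slice of a clinical exome store: 20 samples,
#' one to three analyses each (weights 0.3/0.5/0.2), 40 background
#' variants per sample, and 30 percent common / 70 percent rare background
#' frequencies. The gene universe deliberately contains symbol families
#' with shared prefixes (`GENE1`, `GENE10`, `GENE11`, ...) to exercise
#' whole-word matching.
#'
#' @param n_samples Number of samples.
#' @param analyses_weights Probabilities over 1, 2 or 3 analyses per sample.
#' @param background_per_sample Background variants per sample.
#' @param common_fraction Fraction of background variants with allele
#'   frequency at or above 0.01.
#' @param genes Gene universe for background variants.
#' @param planted Tibble of planted variants (see [plant_variant()]).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 20L,
                       analyses_weights = c(0.3, 0.5, 0.2),
                       background_per_sample = 40L,
                       common_fraction = 0.3,
                       genes = default_gene_universe(),
                       planted = empty_planted(),
                       seed = 1L) {
  stopifnot(n_samples >= 1L, length(analyses_weights) == 3L,
            all(analyses_weights >= 0), sum(analyses_weights) > 0,
            common_fraction >= 0, common_fraction <= 1)
  if (nrow(planted) && !all(planted$gene %in% genes)) {
    stop("planted genes must belong to the simulated gene universe",
         call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 analyses_weights = analyses_weights / sum(analyses_weights),
                 background_per_sample = as.integer(background_per_sample),
                 common_fraction = common_fraction,
                 genes = genes, planted = planted, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_gene_universe <- function() {
  c(paste0("GENE", 1:15), paste0("GENE1", 0:5), # whole-word decoys: GENE1 vs GENE10..15
    paste0("SYNG", sprintf("%03d", 1:20)), "NKX2-5")
}

#' @rdname sim_config
#' @export
empty_planted <- function() {
  tibble::tibble(gene = character(), sample_id = character(),
                 chrom = character(), pos = integer(), ref = character(),
                 alt = character(), protein_change = character(),
                 af = numeric(), segregation = character(),
                 expected_candidate = logical())
}

#' Describe one planted variant
#'
#' @param gene,sample_id,chrom,pos,ref,alt Variant identity.
#' @param protein_change HGVS-p style consequence.
#' @param af Population allele frequency written to the store (`NA` for
#'   absent from population databases).
#' @param segregation Status token (see [parse_segregation()]).
#' @param expected_candidate Whether full triage under the matching alert
#'   should emit this variant.
#' @return One-row planted tibble.
#' @export
plant_variant <- function(gene, sample_id, chrom, pos, ref, alt,
                          protein_change, af = NA_real_,
                          segregation = "de_novo",
                          expected_candidate = TRUE) {
  tibble::tibble(gene = gene, sample_id = sample_id, chrom = chrom,
                 pos = as.integer(pos), ref = ref, alt = alt,
                 protein_change = protein_change, af = af,
                 segregation = segregation,
                 expected_candidate = expected_candidate)
}

random_protein_change <- function(n) {
  res <- c("Ala", "Arg", "Gly", "Leu", "Ser", "Thr", "Glu", "Lys")
  kind <- sample(c("mis", "stop", "fs"), n, replace = TRUE,
                 prob = c(0.7, 0.15, 0.15))
  pos <- sample(20:900, n, replace = TRUE)
  a <- sample(res, n, replace = TRUE)
  b <- sample(res, n, replace = TRUE)
  ifelse(kind == "mis", paste0("p.(", a, pos, b, ")"),
         ifelse(kind == "stop", paste0("p.(", a, pos, "*)"),
                paste0("p.(", a, pos, b, "fs*", sample(2:60, n, TRUE), ")")))
}

simulate_background <- function(cfg, sample_id) {
  n <- cfg$background_per_sample
  if (!n) return(NULL)
  common <- stats::runif(n) < cfg$common_fraction
  af <- ifelse(common,
               stats::runif(n, 0.01, 0.5),
               stats::runif(n, 1e-6, 0.0099))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  tibble::tibble(
    CHROM = paste0("chr", sample(1:22, n, replace = TRUE)),
    POS = sample.int(49990000L, n) + 10000L,
    ID = ".", REF = ref, ALT = unname(alt),
    QUAL = as.character(round(stats::runif(n, 30, 3000))),
    FILTER = "PASS", INFO = ".",
    GENE = sample(cfg$genes, n, replace = TRUE),
    PROTEIN = random_protein_change(n),
    AF_ESP = NA_real_, AF_EXAC = NA_real_,
    AF_GNOMAD_EXOME = af,
    AF_GNOMAD_GENOME = ifelse(stats::runif(n) < 0.5, af, NA_real_),
    INTERNAL_COUNT = sample(0:5, n, replace = TRUE),
    BATCH_COUNT = sample(0:3, n, replace = TRUE),
    POLYPHEN = sample(c("benign", "possibly_damaging", "probably_damaging"),
                      n, replace = TRUE),
    GERP = round(stats::runif(n, -2, 6), 2),
    GRANTHAM = sample(5:215, n, replace = TRUE),
    CADD = round(stats::runif(n, 0, 40), 1),
    MISZ = round(stats::rnorm(n), 2),
    PLI = round(stats::runif(n), 3),
    OMIM_NAME = NA_character_, OMIM_NUMBER = NA_character_,
    OMIM_MODE = NA_character_, CLINVAR = NA_character_
  )
}

planted_rows <- function(planted) {
  if (!nrow(planted)) return(NULL)
  tibble::tibble(
    CHROM = planted$chrom, POS = planted$pos, ID = ".",
    REF = planted$ref, ALT = planted$alt, QUAL = "1500", FILTER = "PASS",
    INFO = ".",
    GENE = planted$gene, PROTEIN = planted$protein_change,
    AF_ESP = NA_real_, AF_EXAC = NA_real_,
    AF_GNOMAD_EXOME = planted$af, AF_GNOMAD_GENOME = NA_real_,
    INTERNAL_COUNT = 1, BATCH_COUNT = 1,
    POLYPHEN = "probably_damaging", GERP = 5.1, GRANTHAM = 101,
    CADD = 28, MISZ = 1.2, PLI = 0.99,
    OMIM_NAME = NA_character_, OMIM_NUMBER = NA_character_,
    OMIM_MODE = NA_character_, CLINVAR = NA_character_
  )
}

# v2-only annotations added to rows written under the second schema
add_v2_annotations <- function(rows) {
  n <- nrow(rows)
  rows$OE <- round(stats::runif(n, 0.05, 1.2), 2)
  rows$OE_LOWER <- round(pmax(0, rows$OE - 0.1), 2)
  rows$OE_UPPER <- round(rows$OE + 0.1, 2)
  rows$SPIP <- sample(c("low_risk", "high_risk", NA), n, replace = TRUE)
  rows$CCR <- round(stats::runif(n, 0, 100), 1)
  rows
}

#' Simulate a variant store on disk
#'
#' Writes a synthetic store under `dir`: one tab-separated analysis file per
#' (sample, analysis), a JSON manifest with per-file sample, timestamp and
#' pipeline version, and version-appropriate schemas -- a sample with k
#' analyses has the same variants duplicated across its k files, earlier
#' analyses under the first-generation schema and the latest under the
#' second (so harmonization and dedup have real work to do). Planted
#' variants are inserted into every analysis of their sample; a background
#' variant colliding with a planted one is regenerated with a warning.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created; must not already contain a store).
#' @return A list: `store` (from [scan_store()]), `truth` (the planted
#'   table), `segregations` (named vector for [match_candidates()]).
#' @export
simulate_store <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(cfg$seed)

  sample_ids <- sprintf("S%04d", seq_len(cfg$n_samples))
  k_analyses <- sample(1:3, cfg$n_samples, replace = TRUE,
                       prob = cfg$analyses_weights)
  manifest <- list()
  for (i in seq_len(cfg$n_samples)) {
    sid <- sample_ids[i]
    bg <- simulate_background(cfg, sid)
    pl <- planted_rows(cfg$planted[cfg$planted$sample_id == sid, ])
    if (!is.null(bg) && !is.null(pl)) {
      clash <- paste(bg$CHROM, bg$POS) %in% paste(pl$CHROM, pl$POS)
      tries <- 0L
      while (any(clash) && tries < 10L) {
        warning("regenerating background variant colliding with a planted one",
                call. = FALSE)
        bg$POS[clash] <- sample.int(49990000L, sum(clash)) + 10000L
        clash <- paste(bg$CHROM, bg$POS) %in% paste(pl$CHROM, pl$POS)
        tries <- tries + 1L
      }
    }
    rows <- dplyr::bind_rows(bg, pl)
    rows <- rows[order(rows$CHROM, rows$POS, method = "radix"), ]
    for (a in seq_len(k_analyses[i])) {
      latest <- a == k_analyses[i]
      schema <- if (latest) schema_v2() else schema_v1()
      out <- rows
      if (latest) out <- add_v2_annotations(out)
      fname <- sprintf("%s_a%d_%s.tsv", sid, a, schema$version_tag)
      write_variant_table(out, schema, file.path(dir, fname))
      manifest[[length(manifest) + 1L]] <- list(
        path = fname, sample_id = sid,
        analysis_timestamp = sprintf("2020-%02d-0%d", a * 3, a),
        version_tag = schema$version_tag)
    }
  }
  jsonlite::write_json(list(files = manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  segs <- if (nrow(cfg$planted)) {
    stats::setNames(parse_segregation(cfg$planted$segregation),
                    cfg$planted$sample_id)
  } else {
    character()
  }
  list(store = scan_store(dir), truth = cfg$planted, segregations = segs)
}

#' Run the full targeted re-query pipeline for one alert
#'
#' Scripted query (dedup + harmonization), rarity filter, and alert
#' matching, in the enforced order; the convenience entry point used by the
#' recall checks and the command-line tool.
#'
#' @param alert A `gene_alert` (or one-row alert tibble).
#' @param store A `variant_store`.
#' @param segregations Named sample -> status vector.
#' @param cfg A [triage_config()].
#' @param master Master schema.
#' @return Candidate tibble from [match_candidates()].
#' @export
run_query_pipeline <- function(alert, store, segregations = character(),
                               cfg = triage_config(), master = schema_v2()) {
  alert <- as_gene_alert_any(alert)
  res <- suppressWarnings(query_gene_v2(alert$gene, store, master))
  match_candidates(res$rows, alert, segregations, cfg)
}
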