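# Shared fixture builders and independent oracles.
# Oracles are deliberately written with a different mechanism than the code
# they check (tokenizers, counting, rule-table lookups, brute-force
# enumeration).

# random annotated rows on a given schema (character/numeric typed like the
# reader produces); missingness injected at the given rate
random_rows <- function(n, schema = schema_v2(), genes = c("GENE1", "GENE10"),
                        miss_rate = 0.2) {
  bases <- c("A", "C", "G", "T")
  tab <- tibble::tibble(
    CHROM = paste0("chr", sample(1:22, n, replace = TRUE)),
    POS = sample.int(1e7, n),
    ID = NA_character_, # "." on disk is the missing marker in memory
    REF = sample(bases, n, replace = TRUE),
    ALT = sample(bases, n, replace = TRUE),
    QUAL = as.character(sample(100:999, n, replace = TRUE)),
    FILTER = "PASS",
    INFO = NA_character_
  )
  for (col in setdiff(schema$columns, core_columns())) {
    v <- if (col == "GENE") {
      sample(genes, n, replace = TRUE)
    } else if (col == "PROTEIN") {
      paste0("p.(Arg", sample(10:500, n, replace = TRUE), "*)")
    } else if (col %in% litquery:::numeric_columns()) {
      if (col %in% af_columns()) {
        round(stats::runif(n, 0, 0.05), 6)
      } else {
        round(stats::runif(n, 0, 10), 3)
      }
    } else {
      paste0("txt", sample(1:99, n, replace = TRUE))
    }
    if (!col %in% c("GENE", "PROTEIN")) { # mandatory in practice
      v[stats::runif(n) < miss_rate] <- NA
    }
    tab[[col]] <- v
  }
  tab
}

# write a store directory by hand: `entries` is a list of
# list(sample, timestamp, version, rows)
build_store <- function(dir, entries) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    schema <- schema_for_version(e$version)
    fname <- sprintf("%s_%02d.tsv", e$sample, i)
    write_variant_table(e$rows, schema, file.path(dir, fname))
    manifest[[i]] <- list(path = fname, sample_id = e$sample,
                          analysis_timestamp = e$timestamp,
                          version_tag = e$version)
  }
  jsonlite::write_json(list(files = manifest),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  scan_store(dir)
}

# whole-word oracle: tokenize every character field on non-token characters
# and test exact token membership
oracle_word_hits <- function(rows, gene) {
  if (!nrow(rows)) return(logical(0))
  chr_cols <- setdiff(names(rows)[vapply(rows, is.character, TRUE)],
                      litquery:::provenance_columns())
  vapply(seq_len(nrow(rows)), function(i) {
    cells <- unlist(rows[i, chr_cols], use.names = FALSE)
    cells[is.na(cells)] <- "."
    toks <- unlist(strsplit(cells, "[^A-Za-z0-9_-]+"))
    gene %in% toks
  }, TRUE)
}

# independent ACMG-AMP rule table: explicit enumeration over evidence counts
# (distinct mechanism from the package's nested conditionals)
oracle_combine <- function(codes) {
  strength <- c(PVS1 = "vs",
                stats::setNames(rep("s", 4), paste0("PS", 1:4)),
                stats::setNames(rep("m", 6), paste0("PM", 1:6)),
                stats::setNames(rep("p", 5), paste0("PP", 1:5)),
                BA1 = "ba",
                stats::setNames(rep("bs", 4), paste0("BS", 1:4)),
                stats::setNames(rep("bp", 7), paste0("BP", 1:7)))
  cnt <- table(factor(unname(strength[codes]),
                      levels = c("vs", "s", "m", "p", "ba", "bs", "bp")))
  vs <- cnt[["vs"]]; s <- cnt[["s"]]; m <- cnt[["m"]]; p <- cnt[["p"]]
  ba <- cnt[["ba"]]; bs <- cnt[["bs"]]; bp <- cnt[["bp"]]
  patho <- (vs >= 1 && (s >= 1 || m >= 2 || (m == 1 && p == 1) || p >= 2)) ||
    s >= 2 ||
    (s == 1 && (m >= 3 || (m == 2 && p >= 2) || (m == 1 && p >= 4)))
  lpatho <- (vs >= 1 && m == 1) ||
    (s == 1 && (m == 1 || m == 2)) ||
    (s == 1 && p >= 2) ||
    m >= 3 || (m == 2 && p >= 2) || (m == 1 && p >= 4)
  ben <- ba >= 1 || bs >= 2
  lben <- (bs >= 1 && bp >= 1) || bp >= 2
  p_side <- patho || lpatho
  b_side <- ben || lben
  if (p_side && b_side) return("VUS")
  if (patho) return("pathogenic")
  if (lpatho) return("likely_pathogenic")
  if (ben) return("benign")
  if (lben) return("likely_benign")
  "VUS"
}

# brute-force candidate predicate used against match_candidates on
# single-row inputs (no compound-het pairing in this oracle)
oracle_is_candidate <- function(effect, position, seg, alert_classes,
                                alert_modes, domains = list()) {
  class_ok <-
    (effect == "protein_truncating" && "protein_truncating" %in% alert_classes) ||
    (effect %in% c("missense", "inframe_indel") &&
       ("missense_any" %in% alert_classes ||
          ("missense_in_domain" %in% alert_classes && !is.na(position) &&
             any(vapply(domains, function(d) position >= d[1] &&
                          position <= d[2], TRUE))))) ||
    (effect == "unknown_splice" && "splice" %in% alert_classes)
  if (!class_ok) return(FALSE)
  if (seg == "unknown") return(TRUE)
  comp <- list(
    de_novo_dominant = c("de_novo", "not_maternal", "not_paternal"),
    autosomal_dominant_inherited = c("de_novo", "maternally_inherited",
                                     "paternally_inherited", "biparental",
                                     "not_maternal", "not_paternal"),
    autosomal_recessive = "biparental",
    x_linked = c("de_novo", "maternally_inherited", "not_paternal"))
  inh_ok <- any(vapply(alert_modes, function(md) seg %in% comp[[md]], TRUE))
  if (inh_ok) return(TRUE)
  # de-novo-only alerts retain inherited hits (flagged VUS stratum)
  identical(alert_modes, "de_novo_dominant") &&
    seg %in% c("maternally_inherited", "paternally_inherited", "biparental")
}

# deterministic tiny planted scenario used by several suites
planted_scenario <- function(seed, n_samples = 6, expected_only = TRUE) {
  planted <- dplyr::bind_rows(
    plant_variant("GENE1", "S0002", "chr7", 1234567L, "A", "T",
                  "p.(Arg100*)", NA, "de_novo", TRUE),
    if (!expected_only) {
      plant_variant("GENE2", "S0003", "chr8", 7654321L, "C", "G",
                    "p.(Ala50Gly)", 0.2, "de_novo", FALSE)
    }
  )
  sim_config(n_samples = n_samples, background_per_sample = 20L,
             planted = planted, seed = seed)
}
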