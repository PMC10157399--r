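#' Triage configuration
#'
#' Controls rare-variant filtration and constraint flags. The rarity
#' threshold is a population variant allele frequency below 1 percent by
#' default, aggregated as the maximum over the configured frequency sources
#' (the most conservative choice). Variants missing every frequency
#' annotation are treated as rare by default (absence from population
#' databases is itself evidence of rarity). Internal cohort occurrence
#' counts are reported but never thresholded. The pLI and o/e thresholds
#' flag truncating variants in loss-of-function-intolerant genes
#' (pLI > 0.9 or o/e < 0.3), the stratum easiest to interpret.
#'
#' @param af_threshold Rarity threshold on the aggregated frequency
#'   (fraction, `0 < af_threshold <= 1`).
#' @param af_sources Frequency column names aggregated for the rarity gate.
#' @param lof_pli_threshold pLI above which a gene counts as LoF-intolerant.
#' @param lof_oe_threshold o/e below which a gene counts as LoF-intolerant.
#' @param treat_missing_af_as_rare Keep rows missing every frequency field.
#' @param splice_requires_alert_class If `TRUE` (default), variants of
#'   unknown consequence (`p.?`) match only alerts that report a splice
#'   class; if `FALSE` they pass the class gate for any alert.
#' @return A list of class `triage_config`.
#' @export
triage_config <- function(af_threshold = 0.01,
                          af_sources = af_columns(),
                          lof_pli_threshold = 0.9,
                          lof_oe_threshold = 0.3,
                          treat_missing_af_as_rare = TRUE,
                          splice_requires_alert_class = TRUE) {
  stopifnot(is.numeric(af_threshold), length(af_threshold) == 1L,
            af_threshold > 0, af_threshold <= 1)
  structure(list(af_threshold = af_threshold, af_sources = af_sources,
                 lof_pli_threshold = lof_pli_threshold,
                 lof_oe_threshold = lof_oe_threshold,
                 treat_missing_af_as_rare = treat_missing_af_as_rare,
                 splice_requires_alert_class = splice_requires_alert_class),
            class = "triage_config")
}

#' Classify a protein-level change string
#'
#' Maps HGVS-p style strings (with or without the `p.` prefix and
#' parentheses) to a coarse effect class: frameshift (`fs`), stop gain
#' (`*` / `Ter`) give `protein_truncating`; a single-residue substitution
#' gives `missense` with its parsed position; an in-frame deletion or
#' duplication without frameshift gives `inframe_indel`; `p.?` (the notation
#' for an intronic or splice-site change of unknown protein consequence)
#' gives `unknown_splice`. Unparseable strings fall back to `unknown_splice`
#' with a warning, never an error.
#'
#' @param protein_change Character vector of protein-change strings.
#' @return A tibble with columns `protein_change`, `effect_class`,
#'   `protein_position` (`NA` when not parseable).
#' @export
#' @examples
#' classify_variant_effect(c("p.(Arg423*)", "p.(Gly792Glu)",
#'                           "p.Phe419del", "p.?"))
classify_variant_effect <- function(protein_change) {
  stopifnot(is.character(protein_change), all(nzchar(protein_change) |
                                                is.na(protein_change)))
  aa <- "(?:[A-Z][a-z]{2}|\\*|Ter|X)"
  one <- function(s) {
    if (is.na(s)) return(list(class = "unknown_splice", pos = NA_integer_))
    core <- sub("^p\\.", "", s)
    core <- gsub("[()]", "", core)
    pos <- {
      m <- regmatches(core, regexpr("[0-9]+", core))
      if (length(m)) as.integer(m) else NA_integer_
    }
    if (core == "?") return(list(class = "unknown_splice", pos = NA_integer_))
    if (grepl("fs", core, fixed = TRUE) ||
        grepl(paste0("^", aa, "[0-9]+(\\*|Ter)$"), core, perl = TRUE)) {
      return(list(class = "protein_truncating", pos = pos))
    }
    if (grepl(paste0("^", aa, "[0-9]+(_", aa, "[0-9]+)?(del|dup)$"), core,
              perl = TRUE)) {
      return(list(class = "inframe_indel", pos = pos))
    }
    if (grepl(paste0("^[A-Z][a-z]{2}[0-9]+[A-Z][a-z]{2}$"), core,
              perl = TRUE)) {
      return(list(class = "missense", pos = pos))
    }
    warning("unparseable protein change \"", s,
            "\" treated as unknown consequence", call. = FALSE)
    list(class = "unknown_splice", pos = NA_integer_)
  }
  parsed <- lapply(protein_change, one)
  tibble::tibble(
    protein_change = protein_change,
    effect_class = vapply(parsed, `[[`, "", "class"),
    protein_position = vapply(parsed, `[[`, 1L, "pos")
  )
}

#' Filter rows to rare variants
#'
#' Keeps rows whose maximum over the configured population-frequency
#' sources is strictly below the rarity threshold. Rows missing every
#' frequency field are kept or dropped per
#' `cfg$treat_missing_af_as_rare`.
#'
#' @param rows Harmonized tibble of variant rows.
#' @param cfg A [triage_config()].
#' @return Filtered tibble.
#' @export
filter_rare <- function(rows, cfg = triage_config()) {
  stopifnot(inherits(cfg, "triage_config"))
  missing_src <- setdiff(cfg$af_sources, names(rows))
  if (length(missing_src)) {
    stop("unknown allele-frequency source column(s): ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  if (!nrow(rows)) return(rows)
  afm <- as.matrix(rows[cfg$af_sources])
  all_missing <- apply(afm, 1L, function(v) all(is.na(v)))
  maxaf <- suppressWarnings(apply(afm, 1L, max, na.rm = TRUE))
  keep <- ifelse(all_missing, cfg$treat_missing_af_as_rare,
                 maxaf < cfg$af_threshold)
  rows[keep, , drop = FALSE]
}

segregation_vocab <- function() {
  c("de_novo", "maternally_inherited", "paternally_inherited", "biparental",
    "not_maternal", "not_paternal", "unknown")
}

#' Parse segregation status tokens
#'
#' Maps the free-text vocabulary of family-segregation reports
#' (case-insensitive) onto the closed status set: "De novo",
#' "Maternally/Paternally inherited" (including "Probable paternal
#' inheritance"), "Paternally and maternally inherited" (biparental, i.e.
#' compound heterozygous or homozygous), "Not maternally/paternally
#' inherited" (one parent excluded), and "ND" or blank for unknown.
#'
#' @param x Character vector of segregation descriptions.
#' @return Character vector over the closed vocabulary.
#' @export
parse_segregation <- function(x) {
  s <- tolower(trimws(as.character(x)))
  s <- gsub("_", " ", s, fixed = TRUE) # accept token form ("de_novo")
  out <- rep("unknown", length(s))
  out[grepl("de *novo", s)] <- "de_novo"
  bip <- grepl("maternal", s) & grepl("paternal", s) & !grepl("not ", s)
  out[bip] <- "biparental"
  mat <- grepl("maternal", s) & !bip
  pat <- grepl("paternal", s) & !bip
  out[mat & !grepl("not ", s)] <- "maternally_inherited"
  out[pat & !grepl("not ", s)] <- "paternally_inherited"
  out[mat & grepl("not ", s)] <- "not_maternal"
  out[pat & grepl("not ", s)] <- "not_paternal"
  out[is.na(x) | s %in% c("", "nd", "na", "unknown", ".")] <- "unknown"
  bad <- !out %in% segregation_vocab()
  if (any(bad)) out[bad] <- "unknown"
  out
}

#' Read a segregation file
#'
#' Tab-separated `sample_id` to status description, parsed with
#' [parse_segregation()].
#'
#' @param path Segregation TSV (columns `sample_id`, `segregation`).
#' @return Named character vector: sample_id -> status token.
#' @export
read_segregation_file <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  stats::setNames(parse_segregation(tab$segregation), tab$sample_id)
}

inherited_statuses <- function() {
  c("maternally_inherited", "paternally_inherited", "biparental")
}

# TRUE when a segregation status can be reconciled with an inheritance mode
segregation_compatible <- function(status, mode) {
  if (status == "unknown") return(TRUE)
  switch(mode,
    de_novo_dominant = status %in% c("de_novo", "not_maternal",
                                     "not_paternal"),
    autosomal_dominant_inherited = TRUE,
    autosomal_recessive = status == "biparental",
    x_linked = status %in% c("de_novo", "maternally_inherited",
                             "not_paternal"),
    FALSE)
}

class_gate <- function(effect_class, protein_position, alert, cfg) {
  reasons <- character()
  cls <- alert$classes
  if (effect_class == "protein_truncating" && "protein_truncating" %in% cls) {
    reasons <- c(reasons, "class:protein_truncating")
  }
  if (effect_class %in% c("missense", "inframe_indel")) {
    if ("missense_any" %in% cls) {
      reasons <- c(reasons, "class:missense_any")
    }
    if ("missense_in_domain" %in% cls && !is.na(protein_position) &&
        any(vapply(alert$domains,
                   function(d) protein_position >= d[1] &&
                     protein_position <= d[2], TRUE))) {
      reasons <- c(reasons, "class:missense_in_domain")
    }
  }
  if (effect_class == "unknown_splice") {
    if ("splice" %in% cls) {
      reasons <- c(reasons, "class:splice")
    } else if (!cfg$splice_requires_alert_class) {
      reasons <- c(reasons, "class:splice_lenient")
    }
  }
  reasons
}

#' Match rare query hits against an alert
#'
#' Turns rare-filtered rows for an alert's gene into candidate variants by
#' requiring (i) that the variant's effect class is among the classes the
#' source manuscript reported (with in-domain missense additionally
#' requiring the protein position to fall inside an alert domain interval,
#' and unknown-consequence variants requiring a reported splice class), and
#' (ii) that the observed family segregation is compatible with a reported
#' inheritance mode, or is unknown. Under a de-novo-only alert, variants
#' inherited from an asymptomatic parent are still emitted but flagged
#' `inherited-from-asymptomatic-parent`: they form the
#' unknown-significance stratum rather than being silently dropped. Under a
#' recessive alert, two rows of the same sample with opposite parental
#' origins are paired as a compound heterozygote (phase from stated
#' segregation only) and both emitted with reason `recessive-biparental`.
#'
#' The rarity filter is (re-)applied internally so no emitted candidate can
#' bypass it.
#'
#' @param rows Harmonized rows restricted to `alert$gene`.
#' @param alert A `gene_alert` (or one-row alert tibble).
#' @param segregations Named vector sample_id -> status token (from
#'   [read_segregation_file()] or [parse_segregation()]). When the rows
#'   carry a per-variant `segregation` column it takes precedence, which is
#'   required to phase the two arms of a compound heterozygote.
#' @param cfg A [triage_config()].
#' @return A candidate tibble: the input columns plus `effect_class`,
#'   `protein_position`, `segregation`, `match_reasons`, `flags`,
#'   `lof_intolerant`, `criteria`, `classification`, `rationale`.
#' @export
match_candidates <- function(rows, alert, segregations = character(),
                             cfg = triage_config()) {
  alert <- as_gene_alert_any(alert)
  if (!length(alert$classes)) {
    stop("alert has no reported variant classes", call. = FALSE)
  }
  rows <- filter_rare(rows, cfg)
  if (!nrow(rows)) return(candidate_skeleton(rows))
  eff <- classify_variant_effect(rows$PROTEIN)
  # segregation is a property of (variant, sample): a per-row `segregation`
  # column (as in diagnostic report tables) takes precedence over the
  # sample-level map, which cannot distinguish the two arms of a compound het
  seg <- if ("segregation" %in% names(rows)) {
    parse_segregation(rows$segregation)
  } else {
    unname(segregations[rows$sample_id])
  }
  seg[is.na(seg)] <- "unknown"
  n <- nrow(rows)
  reasons <- vector("list", n)
  flags <- vector("list", n)

  # compound-het pairing: same sample, opposite stated parental origins
  comp_het <- rep(FALSE, n)
  if ("autosomal_recessive" %in% alert$inheritance) {
    for (sm in unique(rows$sample_id)) {
      idx <- which(rows$sample_id == sm)
      has_mat <- any(seg[idx] == "maternally_inherited")
      has_pat <- any(seg[idx] == "paternally_inherited")
      if (has_mat && has_pat) {
        comp_het[idx[seg[idx] %in% c("maternally_inherited",
                                     "paternally_inherited")]] <- TRUE
      }
    }
  }

  for (i in seq_len(n)) {
    r_class <- class_gate(eff$effect_class[i], eff$protein_position[i],
                          alert, cfg)
    if (!length(r_class)) next
    r_inh <- character()
    for (mode in alert$inheritance) {
      ok <- segregation_compatible(seg[i], mode)
      if (mode == "autosomal_recessive" && comp_het[i]) {
        ok <- TRUE
        r_inh <- c(r_inh, "recessive-biparental")
      } else if (ok) {
        r_inh <- c(r_inh,
                   if (seg[i] == "unknown") "segregation:unknown"
                   else paste0("inheritance:", mode))
        if (mode == "autosomal_recessive" && seg[i] == "biparental") {
          r_inh <- c(r_inh, "recessive-biparental")
        }
      }
    }
    fl <- character()
    if (!length(r_inh)) {
      # de-novo-only alerts retain inherited hits, flagged, as the VUS stratum
      denovo_only <- identical(alert$inheritance, "de_novo_dominant")
      if (denovo_only && seg[i] %in% inherited_statuses()) {
        r_inh <- "inherited-under-denovo-alert"
        fl <- c(fl, "inherited-from-asymptomatic-parent")
      } else {
        next
      }
    }
    reasons[[i]] <- unique(c(r_class, r_inh))
    flags[[i]] <- fl
  }
  keep <- lengths(reasons) > 0L
  out <- rows[keep, , drop = FALSE]
  out$effect_class <- eff$effect_class[keep]
  out$protein_position <- eff$protein_position[keep]
  out$segregation <- seg[keep]
  out$match_reasons <- vapply(reasons[keep], paste, "", collapse = ",")
  out$flags <- vapply(flags[keep], paste, "", collapse = ",")
  pli <- if ("PLI" %in% names(out)) out$PLI else NA_real_
  oe <- if ("OE" %in% names(out)) out$OE else NA_real_
  out$lof_intolerant <- out$effect_class == "protein_truncating" &
    ((!is.na(pli) & pli > cfg$lof_pli_threshold) |
       (!is.na(oe) & oe < cfg$lof_oe_threshold))
  out$criteria <- ""
  out$classification <- NA_character_
  out$rationale <- NA_character_
  out
}

as_gene_alert_any <- function(alert) {
  if (inherits(alert, "gene_alert")) alert else as_gene_alert(alert)
}

candidate_skeleton <- function(rows) {
  rows$effect_class <- character(nrow(rows))
  rows$protein_position <- integer(nrow(rows))
  rows$segregation <- character(nrow(rows))
  rows$match_reasons <- character(nrow(rows))
  rows$flags <- character(nrow(rows))
  rows$lof_intolerant <- logical(nrow(rows))
  rows$criteria <- character(nrow(rows))
  rows$classification <- character(nrow(rows))
  rows$rationale <- character(nrow(rows))
  rows
}
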