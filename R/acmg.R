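#' ACMG-AMP criterion codes and strengths
#'
#' The evidence codes of the ACMG-AMP sequence-variant interpretation
#' standard, with their default strength levels. Strength is a pure
#' function of the code: no laboratory-specific strength overrides are
#' applied.
#'
#' @return A tibble with columns `code`, `side` (`pathogenic`/`benign`) and
#'   `strength`.
#' @export
acmg_codes <- function() {
  tibble::tibble(
    code = c("PVS1",
             paste0("PS", 1:4),
             paste0("PM", 1:6),
             paste0("PP", 1:5),
             "BA1",
             paste0("BS", 1:4),
             paste0("BP", 1:7)),
    side = c(rep("pathogenic", 16L), rep("benign", 12L)),
    strength = c("very_strong",
                 rep("strong", 4L),
                 rep("moderate", 6L),
                 rep("supporting", 5L),
                 "stand_alone_benign",
                 rep("strong_benign", 4L),
                 rep("supporting_benign", 7L))
  )
}

criterion_strength <- function(codes) {
  tab <- acmg_codes()
  idx <- match(codes, tab$code)
  if (anyNA(idx)) {
    stop("unknown ACMG-AMP code: ",
         paste(codes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(tab$strength[idx], codes)
}

split_codes <- function(x) {
  if (length(x) == 1L && grepl(",", x, fixed = TRUE)) {
    x <- strsplit(x, ",", fixed = TRUE)[[1]]
  }
  x <- trimws(x)
  unique(x[nzchar(x) & !is.na(x)])
}

#' Combine ACMG-AMP criteria into a five-tier classification
#'
#' Implements the combining rules of the ACMG-AMP standard, unmodified:
#' pathogenic and likely-pathogenic rules are evaluated first, then the
#' benign rules. If a pathogenic-side rule and a benign-side rule are
#' simultaneously satisfied the call is a variant of unknown significance
#' with rationale `"conflicting"`; if no rule fires, a VUS with rationale
#' `"insufficient"`. The mapping is deterministic and total over code sets.
#'
#' Pathogenic: PVS1 with (one PS, two PM, one PM + one PP, or two PP);
#' two PS; or one PS with (three PM, two PM + two PP, or one PM + four PP).
#' Likely pathogenic: PVS1 + one PM; one PS + one or two PM; one PS + two
#' PP; three PM; two PM + two PP; or one PM + four PP.
#' Benign: BA1 alone, or two BS. Likely benign: one BS + one BP, or two BP.
#'
#' @param codes Character vector of codes, or a single comma-separated
#'   string such as `"PM1,PM2,PP5"`. May be empty.
#' @return A list with `value` (one of `pathogenic`, `likely_pathogenic`,
#'   `VUS`, `likely_benign`, `benign`) and `rationale` (the satisfied rule
#'   identifier, or `"conflicting"` / `"insufficient"`).
#' @export
#' @examples
#' combine_criteria(c("PM1", "PM2", "PM5", "PP2"))$value
combine_criteria <- function(codes) {
  codes <- split_codes(codes)
  if (length(codes)) criterion_strength(codes) # validates tokens
  n <- function(strength) sum(criterion_strength(codes) == strength)
  pvs <- if (length(codes)) n("very_strong") else 0L
  ps <- if (length(codes)) n("strong") else 0L
  pm <- if (length(codes)) n("moderate") else 0L
  pp <- if (length(codes)) n("supporting") else 0L
  ba <- if (length(codes)) n("stand_alone_benign") else 0L
  bs <- if (length(codes)) n("strong_benign") else 0L
  bp <- if (length(codes)) n("supporting_benign") else 0L

  path_rule <- if (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp == 1) ||
                                pp >= 2)) {
    "pathogenic:PVS1+support"
  } else if (ps >= 2) {
    "pathogenic:2PS"
  } else if (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) ||
                         (pm == 1 && pp >= 4))) {
    "pathogenic:PS+PM/PP"
  } else if (pvs >= 1 && pm == 1) {
    "likely_pathogenic:PVS1+PM"
  } else if (ps == 1 && pm >= 1 && pm <= 2) {
    "likely_pathogenic:PS+1-2PM"
  } else if (ps == 1 && pp >= 2) {
    "likely_pathogenic:PS+2PP"
  } else if (pm >= 3) {
    "likely_pathogenic:3PM"
  } else if (pm == 2 && pp >= 2) {
    "likely_pathogenic:2PM+2PP"
  } else if (pm == 1 && pp >= 4) {
    "likely_pathogenic:PM+4PP"
  } else {
    NULL
  }

  benign_rule <- if (ba >= 1) {
    "benign:BA1"
  } else if (bs >= 2) {
    "benign:2BS"
  } else if (bs == 1 && bp >= 1) {
    "likely_benign:BS+BP"
  } else if (bp >= 2) {
    "likely_benign:2BP"
  } else {
    NULL
  }

  if (!is.null(path_rule) && !is.null(benign_rule)) {
    return(list(value = "VUS", rationale = "conflicting"))
  }
  if (!is.null(path_rule)) {
    return(list(value = sub(":.*$", "", path_rule), rationale = path_rule))
  }
  if (!is.null(benign_rule)) {
    return(list(value = sub(":.*$", "", benign_rule), rationale = benign_rule))
  }
  list(value = "VUS", rationale = "insufficient")
}

#' Classify comma-separated criteria strings
#'
#' Vectorized convenience wrapper around [combine_criteria()] returning the
#' short class labels used in candidate reports.
#'
#' @param x Character vector of comma-separated code lists.
#' @return Character vector over `P`, `LP`, `VUS`, `LB`, `B`.
#' @export
classify_criteria <- function(x) {
  vapply(x, function(s) {
    switch(combine_criteria(s)$value,
           pathogenic = "P", likely_pathogenic = "LP", VUS = "VUS",
           likely_benign = "LB", benign = "B")
  }, "", USE.NAMES = FALSE)
}

#' Apply segregation-driven reclassification to candidates
#'
#' Encodes the two segregation consequences of family testing under a
#' literature alert. (i) Downgrade: when the alert reports a de-novo-only
#' mechanism and the candidate was inherited from an asymptomatic parent --
#' a situation the source manuscript did not describe -- any provisional
#' pathogenic or likely-pathogenic call is downgraded to a VUS with
#' rationale `"inherited-unreported"`. (ii) Upgrade support: a confirmed de
#' novo occurrence under a de-novo alert adds PS2 (trio-confirmed paternity
#' and maternity) before recombination; without trio confirmation no code is
#' added. Candidates with unknown segregation are flagged
#' `segregation-pending` and left unchanged. The operation is idempotent,
#' and every reclassification is recorded in the `reclassified` column as
#' `"before->after"`.
#'
#' @param candidates Candidate tibble from [match_candidates()], with
#'   `criteria` (comma-separated codes) and optionally `classification`
#'   already populated.
#' @param alert The driving `gene_alert` (or one-row alert tibble).
#' @param trio_confirmed Logical: de novo status confirmed on a trio.
#' @return The candidate tibble with `classification`, `rationale`, `flags`
#'   and `reclassified` updated.
#' @export
apply_segregation_evidence <- function(candidates, alert,
                                       trio_confirmed = FALSE) {
  alert <- as_gene_alert_any(alert)
  if (!nrow(candidates)) {
    candidates$reclassified <- character(0)
    return(candidates)
  }
  if (!"reclassified" %in% names(candidates)) {
    candidates$reclassified <- NA_character_
  }
  denovo_only <- identical(alert$inheritance, "de_novo_dominant")
  for (i in seq_len(nrow(candidates))) {
    codes <- split_codes(candidates$criteria[i])
    seg <- candidates$segregation[i]
    if (trio_confirmed && seg == "de_novo" &&
        "de_novo_dominant" %in% alert$inheritance) {
      codes <- unique(c(codes, "PS2"))
    }
    cl <- combine_criteria(codes)
    before <- candidates$classification[i]
    value <- cl$value
    rationale <- cl$rationale
    if (denovo_only && seg %in% inherited_statuses() &&
        value %in% c("pathogenic", "likely_pathogenic")) {
      value <- "VUS"
      rationale <- "inherited-unreported"
    }
    if (seg == "unknown") {
      fl <- split_codes(candidates$flags[i])
      candidates$flags[i] <- paste(unique(c(fl, "segregation-pending")),
                                   collapse = ",")
    }
    if (!is.na(before) && !identical(before, value)) {
      candidates$reclassified[i] <- paste0(before, "->", value)
    }
    candidates$criteria[i] <- paste(codes, collapse = ",")
    candidates$classification[i] <- value
    candidates$rationale[i] <- rationale
  }
  candidates
}
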