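#' Packaged candidate-variant table
#'
#' A transcription of the 56 candidate variants reported by the diagnostic
#' exome reanalysis programme the package models: gene, delay to the
#' diagnostic report (months; `NA` where not determined), family
#' segregation as reported, genomic position (HGVS-g style, hg19), protein
#' change, per-block patient count, final classification mark (P, LP, VUS
#' or LB), and -- where populated -- the retrospectively assigned ACMG-AMP
#' criteria with their class label. The `individual_ids` column is a
#' curated reading of how the per-block patient counts distribute over rows
#' (biallelic pairs share one individual; affected sibs share both rows of
#' a pair); it reproduces the programme's 53 distinct flagged individuals
#' and 21 individuals with a causative variant.
#'
#' @param parse_positions Add `chrom`, `pos`, `end`, `ref`, `alt` columns
#'   parsed from `genomic_position`.
#' @return A tibble with 56 rows.
#' @export
candidate_fixture <- function(parse_positions = FALSE) {
  path <- system.file("extdata", "candidate_variants.tsv",
                      package = "litquery", mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = ".",
                           quote = "")
  tab <- tibble::as_tibble(tab)
  tab$delay_months <- suppressWarnings(as.numeric(tab$delay_months))
  tab$n_patients <- suppressWarnings(as.integer(tab$n_patients))
  if (parse_positions) {
    tab <- dplyr::bind_cols(tab, parse_genomic_position(tab$genomic_position))
  }
  tab
}

#' Replay retrospective ACMG-AMP criteria cells
#'
#' For every fixture row whose retrospective-criteria cell is populated,
#' recombines the listed codes with [combine_criteria()] and compares the
#' result with the printed class label of that cell.
#'
#' @param fixture Tibble from [candidate_fixture()].
#' @return A tibble with columns `gene`, `protein_change`, `retro_codes`,
#'   `expected` (printed label), `computed`, `agree`.
#' @export
replay_retrospective_criteria <- function(fixture = candidate_fixture()) {
  has <- !is.na(fixture$retro_codes) & nzchar(fixture$retro_codes)
  sub <- fixture[has, ]
  computed <- classify_criteria(sub$retro_codes)
  tibble::tibble(gene = sub$gene, protein_change = sub$protein_change,
                 retro_codes = sub$retro_codes,
                 expected = sub$retro_label, computed = computed,
                 agree = computed == sub$retro_label)
}
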