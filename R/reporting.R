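#' Round half away from zero
#'
#' Diagnostic-yield percentages are conventionally rounded half-up (2.5 ->
#' 3), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort summary constants
#'
#' Reference counts for the exome cohort the query engine serves: total
#' exomes, probands versus relatives, the developmental-disorder /
#' intellectual-disability (DD/ID) proband subset, and its diagnosed and
#' undiagnosed partition. Defaults are the counts of the reanalysis
#' programme the packaged example data comes from. Invariants are checked:
#' diagnosed + undiagnosed must equal the DD/ID probands, and probands +
#' relatives the total exomes.
#'
#' @param total_exomes,probands,dd_id_probands,diagnosed_probands,undiagnosed_probands,relatives
#'   Integer counts.
#' @return A list of class `cohort_summary`.
#' @export
cohort_summary <- function(total_exomes = 5459L, probands = 4170L,
                           dd_id_probands = 3771L,
                           diagnosed_probands = 896L,
                           undiagnosed_probands = 2875L,
                           relatives = 1289L) {
  if (diagnosed_probands + undiagnosed_probands != dd_id_probands) {
    stop("diagnosed + undiagnosed must equal DD/ID probands", call. = FALSE)
  }
  if (probands + relatives != total_exomes) {
    stop("probands + relatives must equal total exomes", call. = FALSE)
  }
  structure(list(total_exomes = total_exomes, probands = probands,
                 dd_id_probands = dd_id_probands,
                 diagnosed_probands = diagnosed_probands,
                 undiagnosed_probands = undiagnosed_probands,
                 relatives = relatives),
            class = "cohort_summary")
}

#' Reported monitoring tallies
#'
#' Outcome tallies of the 18-month monitoring programme the packaged
#' example data comes from, used as inputs to [cohort_yields()]: genes
#' monitored, genes positive in daily queries, genes with a causal
#' diagnosis, genes with unknown-significance candidates, and the
#' individual-level tallies (flagged, causative, causative-or-VUS).
#'
#' @return A named list of integer counts.
#' @export
monitoring_summary <- function() {
  list(genes_monitored = 128L, daily_positive_genes = 25L,
       causal_genes = 19L, vus_genes = 19L,
       flagged_individuals = 53L, causative_individuals = 21L,
       causative_or_vus_individuals = 44L)
}

#' Per-mode query line metrics and fold reduction
#'
#' Tallies, per query mode, the number of genes queried and the total lines
#' emitted, with the mean lines per gene truncated toward zero (integer
#' division, matching how such per-gene means are conventionally printed).
#' The fold reduction between the basic and scripted query is the rounded
#' ratio of the two means.
#'
#' @param results List of `query_result` objects (both modes).
#' @return A list with a `modes` tibble (mode, genes, total_lines,
#'   mean_lines_per_gene) and `fold_reduction` (integer, `NA` unless both
#'   modes are present).
#' @export
query_metrics <- function(results) {
  stopifnot(length(results) > 0)
  modes <- vapply(results, `[[`, "", "mode")
  lines <- as.integer(vapply(results, function(r) as.numeric(r$line_count),
                             1))
  tab <- tibble::tibble(mode = modes, lines = lines)
  agg <- dplyr::summarise(dplyr::group_by(tab, mode),
                          genes = dplyr::n(),
                          total_lines = sum(lines), .groups = "drop")
  if (any(agg$genes == 0L)) stop("mode with zero genes", call. = FALSE)
  agg$mean_lines_per_gene <- mean_lines_per_gene(agg$total_lines, agg$genes)
  fold <- NA_integer_
  if (all(c("v1", "v2") %in% agg$mode)) {
    m1 <- agg$mean_lines_per_gene[agg$mode == "v1"]
    m2 <- agg$mean_lines_per_gene[agg$mode == "v2"]
    if (m2 == 0) stop("v2 mean is zero; fold reduction undefined",
                      call. = FALSE)
    fold <- as.integer(round_half_up(m1 / m2))
  }
  list(modes = agg[order(agg$mode), ], fold_reduction = fold)
}

#' @rdname query_metrics
#' @param total_lines,genes Printed totals for one mode.
#' @return `mean_lines_per_gene()`: integer mean, truncated toward zero.
#' @export
mean_lines_per_gene <- function(total_lines, genes) {
  if (any(genes <= 0)) stop("mean lines per gene undefined for zero genes",
                            call. = FALSE)
  as.integer(total_lines %/% genes)
}

candidate_class_column <- function(candidates) {
  cl <- candidates$classification
  # long-form labels from the combiner map onto report labels
  map <- c(pathogenic = "P", likely_pathogenic = "LP", VUS = "VUS",
           likely_benign = "LB", benign = "B")
  ifelse(cl %in% names(map), unname(map[cl]), cl)
}

#' Summarize classified candidates
#'
#' Counts variants by classification tier, distinct genes and distinct
#' affected individuals, and -- given the number of genes queried -- the
#' positive/negative query tally (a positive query is a gene with at least
#' one surviving candidate; a negative query is one without). Class counts
#' always sum to the number of candidates, and positive plus negative genes
#' to the queried genes. The summary is invariant under row order.
#'
#' @param candidates Candidate tibble with a `classification` column; the
#'   individual tally uses `individual_ids` (semicolon-separated) when
#'   present, else `sample_id`.
#' @param queried_genes Optional number of genes queried.
#' @return A list: `n_variants`, `n_genes`, `n_individuals`, `class_counts`
#'   (named over P, LP, VUS, LB, B), `individuals_causative` (carrying at
#'   least one P/LP), `positive_genes`, `negative_genes`.
#' @export
classification_summary <- function(candidates, queried_genes = NULL) {
  if (!"gene" %in% names(candidates) && "GENE" %in% names(candidates)) {
    candidates$gene <- candidates$GENE
  }
  cl <- candidate_class_column(candidates)
  tiers <- c("P", "LP", "VUS", "LB", "B")
  counts <- vapply(tiers, function(k) sum(cl == k, na.rm = TRUE), 1L)
  inds <- if ("individual_ids" %in% names(candidates)) {
    strsplit(candidates$individual_ids, ";", fixed = TRUE)
  } else if ("sample_id" %in% names(candidates)) {
    as.list(candidates$sample_id)
  } else {
    as.list(seq_len(nrow(candidates)))
  }
  all_inds <- unique(unlist(inds))
  causative <- unique(unlist(inds[cl %in% c("P", "LP")]))
  pos <- length(unique(candidates$gene))
  out <- list(n_variants = nrow(candidates),
              n_genes = pos,
              n_individuals = length(all_inds),
              class_counts = counts,
              individuals_causative = length(causative))
  if (!is.null(queried_genes)) {
    out$positive_genes <- pos
    out$negative_genes <- queried_genes - pos
  }
  out
}

#' Diagnostic-yield percentages
#'
#' Pure functions of integer counts, emitted at the precision at which such
#' yields are reported: cohort-level yields to one decimal, per-gene and
#' within-flagged fractions as stated. All rounding is half-up.
#'
#' @param causal_diagnoses Individuals with a new causal diagnosis.
#' @param flagged_individuals Individuals flagged with any candidate.
#' @param causative_or_vus Individuals with a causative or
#'   unknown-significance candidate.
#' @param causal_genes Genes yielding a causal diagnosis.
#' @param positive_genes Genes with a positive daily query.
#' @param queried_genes Genes queried overall.
#' @param cohort A [cohort_summary()].
#' @return Named list of percentages: `causal_yield_undiagnosed_pct`
#'   (causal diagnoses over undiagnosed DD/ID probands, 1 decimal),
#'   `flagged_proband_pct` (flagged over DD/ID probands, 1 decimal),
#'   `causative_among_flagged_pct` (1 decimal),
#'   `causative_or_vus_among_flagged_pct` (integer),
#'   `causal_gene_pct` and `positive_gene_pct` (integer).
#' @export
cohort_yields <- function(causal_diagnoses, flagged_individuals,
                          causative_or_vus, causal_genes, positive_genes,
                          queried_genes, cohort = cohort_summary()) {
  denoms <- c(cohort$undiagnosed_probands, cohort$dd_id_probands,
              flagged_individuals, queried_genes)
  if (any(denoms == 0)) stop("zero denominator in yield computation",
                             call. = FALSE)
  list(
    causal_yield_undiagnosed_pct =
      round_half_up(100 * causal_diagnoses / cohort$undiagnosed_probands, 1),
    flagged_proband_pct =
      round_half_up(100 * flagged_individuals / cohort$dd_id_probands, 1),
    causative_among_flagged_pct =
      round_half_up(100 * causal_diagnoses / flagged_individuals, 1),
    causative_or_vus_among_flagged_pct =
      round_half_up(100 * causative_or_vus / flagged_individuals, 0),
    causal_gene_pct = round_half_up(100 * causal_genes / queried_genes, 0),
    positive_gene_pct = round_half_up(100 * positive_genes / queried_genes, 0)
  )
}

#' Alert-to-report delay statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and maximum
#' of the delays between a positive query and delivery of the diagnostic
#' report. Unknown delays (`NA`, from "ND" cells) are excluded and counted.
#' With a single known delay the standard deviation is reported as `NA`
#' (undefined), the documented convention here.
#'
#' @param delays Numeric vector of delays (months); `NA` for unknown.
#' @return List: `n`, `excluded`, `mean`, `sd`, `min`, `max`.
#' @export
delay_stats <- function(delays) {
  known <- delays[!is.na(delays)]
  if (!length(known)) stop("all delays unknown; statistics undefined",
                           call. = FALSE)
  if (any(known < 0)) stop("delays must be non-negative", call. = FALSE)
  list(n = length(known), excluded = sum(is.na(delays)),
       mean = mean(known),
       sd = if (length(known) > 1L) stats::sd(known) else NA_real_,
       min = min(known), max = max(known))
}

fmt_num <- function(x, digits = 1) {
  formatC(x, format = "f", digits = digits)
}

#' Render a deterministic diagnostic report
#'
#' Produces the candidate table and the metric/yield/delay summary as plain
#' text lines: stable candidate ordering (gene, then position) and fixed
#' number formatting, so two runs on identical inputs are byte-identical.
#'
#' @param candidates Candidate tibble (fixture or pipeline output).
#' @param metrics Optional [query_metrics()] output.
#' @param yields Optional [cohort_yields()] output.
#' @param delays Optional [delay_stats()] output.
#' @return Character vector of report lines.
#' @export
render_report <- function(candidates, metrics = NULL, yields = NULL,
                          delays = NULL) {
  # accept pipeline naming (GENE/PROTEIN/CHROM...) as well as report naming
  if (!"gene" %in% names(candidates) && "GENE" %in% names(candidates)) {
    candidates$gene <- candidates$GENE
  }
  if (!"protein_change" %in% names(candidates) &&
      "PROTEIN" %in% names(candidates)) {
    candidates$protein_change <- candidates$PROTEIN
  }
  if (!"genomic_position" %in% names(candidates) &&
      all(c("CHROM", "POS") %in% names(candidates))) {
    candidates$genomic_position <- paste0(candidates$CHROM, ":",
                                          candidates$POS)
  }
  lines <- c("# Candidate variant report", "")
  summ <- classification_summary(candidates)
  lines <- c(lines,
             paste0("variants: ", summ$n_variants,
                    "  genes: ", summ$n_genes,
                    "  individuals: ", summ$n_individuals),
             paste0("classes: ",
                    paste(names(summ$class_counts), summ$class_counts,
                          sep = "=", collapse = " ")),
             "")
  cols <- intersect(c("gene", "delay_months", "segregation",
                      "genomic_position", "protein_change", "classification",
                      "criteria", "retro_codes"),
                    names(candidates))
  ord <- do.call(order, c(unname(as.list(candidates[intersect(
    c("gene", "genomic_position", "protein_change"), names(candidates))])),
    list(method = "radix")))
  tab <- candidates[ord, cols, drop = FALSE]
  lines <- c(lines, paste(cols, collapse = "\t"))
  if (nrow(tab)) {
    body <- do.call(paste, c(lapply(tab, function(v) {
      v <- as.character(v)
      v[is.na(v)] <- "."
      v
    }), sep = "\t"))
    lines <- c(lines, body)
  }
  if (!is.null(metrics)) {
    lines <- c(lines, "", "# Query metrics")
    for (i in seq_len(nrow(metrics$modes))) {
      m <- metrics$modes[i, ]
      lines <- c(lines, paste0(m$mode, ": genes=", m$genes, " lines=",
                               m$total_lines, " mean_lines_per_gene=",
                               m$mean_lines_per_gene))
    }
    if (!is.na(metrics$fold_reduction)) {
      lines <- c(lines, paste0("fold_reduction=", metrics$fold_reduction))
    }
  }
  if (!is.null(yields)) {
    lines <- c(lines, "", "# Diagnostic yields",
               vapply(names(yields), function(k) {
                 paste0(k, "=", fmt_num(yields[[k]],
                                        if (grepl("pct$", k) &&
                                            yields[[k]] %% 1 != 0) 1 else
                                          ifelse(yields[[k]] %% 1 == 0, 0, 1)))
               }, ""))
  }
  if (!is.null(delays)) {
    lines <- c(lines, "", "# Delay to diagnostic report (months)",
               paste0("n=", delays$n, " excluded=", delays$excluded,
                      " mean=", fmt_num(delays$mean, 1),
                      " sd=", if (is.na(delays$sd)) "NA" else
                        fmt_num(delays$sd, 1),
                      " min=", fmt_num(delays$min, 1),
                      " max=", fmt_num(delays$max, 1)))
  }
  lines
}
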