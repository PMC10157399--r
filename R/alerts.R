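#' Closed vocabularies for gene alerts
#'
#' Association categories distinguish a gene newly tied to a human disorder,
#' an update to the phenotype of a known gene-disease pair, and a known
#' disease gene implicated in a distinct, second disorder. The OMIM status is
#' a snapshot recorded when the alert was curated (newly published genes
#' typically lag their OMIM-morbid annotation; no live lookup is performed).
#'
#' @return Character vector of allowed tokens.
#' @export
alert_categories <- function() {
  c("novel_disorder", "phenotype_update", "distinct_disorder_known_gene")
}

#' @rdname alert_categories
#' @export
omim_statuses <- function() c("morbid", "non_morbid", "absent")

#' @rdname alert_categories
#' @export
inheritance_modes <- function() {
  c("de_novo_dominant", "autosomal_dominant_inherited", "autosomal_recessive",
    "x_linked")
}

#' @rdname alert_categories
#' @export
variant_classes <- function() {
  c("protein_truncating", "missense_in_domain", "missense_any", "splice")
}

#' Construct a single gene alert
#'
#' A gene alert is one literature-monitoring record: the published
#' gene-disease association that drives a targeted query. It carries the
#' inheritance mode(s) and variant class(es) reported by the source
#' manuscript, against which query hits are triaged, and optionally the
#' protein-domain intervals (1-based amino-acid coordinates) required for
#' in-domain missense matching.
#'
#' @param gene Gene symbol (non-empty).
#' @param association_category One of [alert_categories()].
#' @param inheritance Subset of [inheritance_modes()] (at least one).
#' @param classes Subset of [variant_classes()] (at least one).
#' @param publication_date Calendar date string.
#' @param omim_status One of [omim_statuses()].
#' @param domains Optional list of `c(start, end)` amino-acid intervals.
#' @param source_ref Free-text citation of the source manuscript.
#' @return An object of class `gene_alert`.
#' @export
gene_alert <- function(gene, association_category = "novel_disorder",
                       inheritance = "de_novo_dominant",
                       classes = "protein_truncating",
                       publication_date = NA_character_,
                       omim_status = "non_morbid",
                       domains = list(), source_ref = NA_character_) {
  if (!is.character(gene) || length(gene) != 1L || !nzchar(gene)) {
    stop("alert gene must be a non-empty symbol", call. = FALSE)
  }
  check_vocab(association_category, alert_categories(), "association category")
  check_vocab(omim_status, omim_statuses(), "OMIM status")
  if (!length(inheritance)) stop("alert needs at least one inheritance mode",
                                 call. = FALSE)
  check_vocab(inheritance, inheritance_modes(), "inheritance mode")
  if (!length(classes)) stop("alert needs at least one variant class",
                             call. = FALSE)
  check_vocab(classes, variant_classes(), "variant class")
  for (d in domains) {
    if (length(d) != 2L || anyNA(d) || d[1] > d[2] || d[1] < 1) {
      stop("domain intervals must be 1-based (start, end) with start <= end",
           call. = FALSE)
    }
  }
  structure(list(gene = gene, association_category = association_category,
                 inheritance = inheritance, classes = classes,
                 publication_date = publication_date,
                 omim_status = omim_status, domains = domains,
                 source_ref = source_ref),
            class = "gene_alert")
}

check_vocab <- function(x, vocab, what) {
  bad <- setdiff(x, vocab)
  if (length(bad)) {
    stop("unknown ", what, ": ", paste(bad, collapse = ", "),
         " (allowed: ", paste(vocab, collapse = ", "), ")", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.gene_alert <- function(x, ...) {
  cat("<gene_alert> ", x$gene, " [", x$association_category, "] ",
      paste(x$inheritance, collapse = "+"), "; ",
      paste(x$classes, collapse = "+"), "\n", sep = "")
  invisible(x)
}

alert_tsv_columns <- function() {
  c("gene", "publication_date", "association_category", "omim_status",
    "inheritance_modes", "variant_classes", "domains", "source_ref")
}

#' Read a gene-alert file
#'
#' Alert files are tab-separated, one record per line, with a header. The
#' `inheritance_modes` and `variant_classes` cells are comma-separated
#' tokens from the closed vocabularies; `domains` is a JSON array of
#' `[start, end]` amino-acid intervals or `"."` when absent. Every record is
#' validated; an unknown token or empty gene names the offending record.
#'
#' @param path Alert TSV file.
#' @return A tibble with one validated row per alert and a `domains`
#'   list-column.
#' @export
read_alert_file <- function(path) {
  if (!file.exists(path)) stop("no such alert file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, quote = "")
  tab <- tibble::as_tibble(tab)
  if (!nrow(tab)) {
    tab <- tab[alert_tsv_columns()]
    tab$domains <- list()
    return(tab)
  }
  missing <- setdiff(alert_tsv_columns(), names(tab))
  if (length(missing)) {
    stop("alert file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[alert_tsv_columns()]
  doms <- lapply(seq_len(nrow(tab)), function(i) {
    cell <- tab$domains[[i]]
    if (is.na(cell) || cell %in% c(".", "")) return(list())
    parsed <- tryCatch(jsonlite::fromJSON(cell, simplifyMatrix = TRUE),
                       error = function(e) {
                         stop("record ", i, " (", tab$gene[[i]],
                              "): unparseable domains cell", call. = FALSE)
                       })
    if (is.matrix(parsed)) {
      lapply(seq_len(nrow(parsed)), function(r) parsed[r, ])
    } else if (length(parsed)) {
      list(unlist(parsed))
    } else {
      list()
    }
  })
  tab$domains <- doms
  for (i in seq_len(nrow(tab))) {
    rec <- tab[i, ]
    ok <- tryCatch({
      as_gene_alert(rec)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop("invalid alert record ", i, " (gene \"", rec$gene, "\"): ",
           conditionMessage(ok), call. = FALSE)
    }
  }
  if (anyDuplicated(tab[c("gene", "source_ref")])) {
    stop("duplicate (gene, source_ref) alert records", call. = FALSE)
  }
  tab
}

#' Convert one alert-table row to a `gene_alert`
#'
#' @param rec One-row tibble from [read_alert_file()].
#' @return A `gene_alert`.
#' @export
as_gene_alert <- function(rec) {
  if (inherits(rec, "gene_alert")) return(rec)
  stopifnot(is.data.frame(rec), nrow(rec) == 1L)
  split_tokens <- function(x) {
    toks <- strsplit(x, ",", fixed = TRUE)[[1]]
    trimws(toks[nzchar(trimws(toks))])
  }
  gene_alert(
    gene = rec$gene,
    association_category = rec$association_category,
    inheritance = split_tokens(rec$inheritance_modes),
    classes = split_tokens(rec$variant_classes),
    publication_date = rec$publication_date,
    omim_status = rec$omim_status,
    domains = if (is.list(rec$domains)) rec$domains[[1]] else list(),
    source_ref = rec$source_ref
  )
}

#' Write a gene-alert file
#'
#' Inverse of [read_alert_file()]: `read_alert_file(write_alert_file(x, p))`
#' reproduces `x`.
#'
#' @param alerts Alert tibble.
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_alert_file <- function(alerts, path) {
  out <- alerts[setdiff(alert_tsv_columns(), "domains")]
  out$domains <- vapply(alerts$domains, function(d) {
    if (!length(d)) return(".")
    as.character(jsonlite::toJSON(lapply(d, as.integer)))
  }, "")
  out <- out[alert_tsv_columns()]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con)
  }
  invisible(path)
}

#' Tally alerts by association category
#'
#' @param alerts Alert tibble.
#' @return Named integer vector over [alert_categories()], plus
#'   `non_morbid_novel` (novel-disorder alerts whose gene was not yet
#'   OMIM-morbid when curated) and `absent_novel` (gene absent from OMIM
#'   entirely).
#' @export
alert_summary <- function(alerts) {
  counts <- vapply(alert_categories(),
                   function(k) sum(alerts$association_category == k), 1L)
  novel <- alerts$association_category == "novel_disorder"
  c(counts,
    non_morbid_novel = sum(novel & alerts$omim_status == "non_morbid"),
    absent_novel = sum(novel & alerts$omim_status == "absent"),
    total = nrow(alerts))
}

#' Packaged literature-monitoring alert set
#'
#' A 128-record alert set modelling 18 months of daily literature
#' monitoring of a developmental-disorder cohort: 100 novel gene-disease
#' associations (37 of whose genes were not yet OMIM-morbid and one absent
#' from OMIM), 9 known disease genes implicated in a distinct disorder, and
#' 19 phenotype updates. The 36 genes that yielded candidate variants in the
#' companion candidate-variant fixture appear under their real symbols with
#' curated inheritance and variant-class profiles; the remaining 92 records
#' carry synthetic `SYNG...` symbols, and all protein-domain intervals are
#' synthetic.
#'
#' @return Alert tibble, as from [read_alert_file()].
#' @export
monitoring_alerts <- function() {
  read_alert_file(system.file("extdata", "gene_alerts_synthetic.tsv",
                              package = "litquery", mustWork = TRUE))
}
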