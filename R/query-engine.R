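#' Whole-word regular expression for a gene symbol
#'
#' Token characters are `[A-Za-z0-9_-]` and matching is case-sensitive, so a
#' query for `GENE1` never hits `GENE10`, and hyphenated HGNC symbols such as
#' `NKX2-1` are matched as single tokens rather than split at the hyphen.
#'
#' @param gene Gene symbol.
#' @return A perl regular expression string.
#' @keywords internal
word_regex <- function(gene) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", gene)
  paste0("(?<![A-Za-z0-9_-])", esc, "(?![A-Za-z0-9_-])")
}

match_rows_word <- function(rows, gene, full_line) {
  if (!nrow(rows)) return(logical(0))
  rx <- word_regex(gene)
  if (full_line) {
    chr_cols <- names(rows)[vapply(rows, is.character, TRUE)]
    chr_cols <- setdiff(chr_cols, provenance_columns())
    joined <- do.call(paste, c(lapply(rows[chr_cols], function(v) {
      v[is.na(v)] <- "."
      v
    }), sep = "\t"))
    grepl(rx, joined, perl = TRUE)
  } else {
    g <- rows$GENE
    !is.na(g) & grepl(rx, g, perl = TRUE)
  }
}

new_query_result <- function(gene, mode, rows) {
  structure(list(gene = gene, mode = mode, rows = rows,
                 line_count = nrow(rows)),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat("<query_result> ", x$mode, " query for ", x$gene, ": ",
      x$line_count, " line(s)\n", sep = "")
  invisible(x)
}

#' Basic whole-word gene query (v1)
#'
#' Emulates the basic command-line search over a store's analysis files:
#' every line containing the queried symbol as a whole word is emitted,
#' including duplicate lines from repeated analyses of the same sample. By
#' default the match is scoped to the gene-symbol column for precision; with
#' `full_line = TRUE` the whole tab-joined line is searched, the faithful
#' emulation of a plain text grep that also hits annotation fields.
#'
#' @param gene Gene symbol (non-empty).
#' @param store A `variant_store`.
#' @param full_line Search all text fields rather than the gene column.
#' @return A `query_result` (mode `"v1"`); duplicate analysis rows retained.
#' @export
grep_word_v1 <- function(gene, store, full_line = FALSE) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  rows <- read_store_rows(store)
  hit <- match_rows_word(rows, gene, full_line)
  if (!any(hit) && nrow(rows)) {
    warning("symbol ", gene, " not found in any analysis file", call. = FALSE)
  }
  res_rows <- rows[hit, , drop = FALSE]
  res_rows <- res_rows[order(res_rows$sample_id, res_rows$CHROM, res_rows$POS,
                             res_rows$analysis_timestamp, res_rows$source_path,
                             method = "radix"), , drop = FALSE]
  new_query_result(gene, "v1", res_rows)
}

#' Keep only the most recently analyzed row per sample and variant
#'
#' When the same individual has been sequenced or reanalyzed under several
#' pipeline versions, a query returns one line per analysis for each
#' variant. This keeps, for every (sample, chrom, pos, ref, alt), the row
#' whose analysis timestamp is latest; timestamp ties are broken by version
#' tag (descending) then source path. Output order is deterministic
#' (sample, then position).
#'
#' @param rows Tibble of variant rows carrying provenance columns.
#' @return Deduplicated tibble.
#' @export
dedup_latest <- function(rows) {
  if (!nrow(rows)) return(rows)
  if (!"analysis_timestamp" %in% names(rows) ||
      anyNA(rows$analysis_timestamp)) {
    stop("rows lack an analysis timestamp; dedup_latest needs store provenance",
         call. = FALSE)
  }
  ord <- order(rows$sample_id, rows$CHROM, rows$POS, rows$REF, rows$ALT,
               # latest analysis first within each variant group
               -xtfrm(rows$analysis_timestamp), -xtfrm(rows$version_tag),
               rows$source_path, method = "radix")
  rows <- rows[ord, , drop = FALSE]
  key <- paste(rows$sample_id, rows$CHROM, rows$POS, rows$REF, rows$ALT,
               sep = "\r")
  rows[!duplicated(key), , drop = FALSE]
}

#' Harmonize rows onto a master annotation schema
#'
#' Rows originating from files with differing column sets are made
#' rectangular under one master schema: annotation columns the source
#' pipeline did not produce are filled with the missing marker (rendered as
#' the gap token on write), and column order is identical for all rows.
#' A row column absent from the master schema is an error.
#'
#' @param rows Tibble of variant rows.
#' @param master Master [annotation_schema] (must contain the union of the
#'   referenced columns).
#' @return Tibble with exactly the master columns (plus provenance).
#' @export
harmonize_rows <- function(rows, master = schema_v2()) {
  stopifnot(inherits(master, "annotation_schema"))
  extra <- setdiff(names(rows), c(master$columns, provenance_columns()))
  if (length(extra)) {
    stop("column(s) absent from master schema: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(master$columns, names(rows))) {
    rows[[col]] <- if (col %in% numeric_columns()) NA_real_ else NA_character_
  }
  rows[c(master$columns, intersect(provenance_columns(), names(rows)))]
}

#' Deduplicated, harmonized gene query (v2)
#'
#' The scripted query: the whole-word match of [grep_word_v1()] followed by
#' [dedup_latest()] (one row per sample and variant, from the most recent
#' analysis) and [harmonize_rows()] (rectangular output under the master
#' schema, gaps filled with the missing marker). Its line count is therefore
#' never larger than the v1 count for the same gene and store.
#'
#' @inheritParams grep_word_v1
#' @param master Master [annotation_schema] for harmonization.
#' @return A `query_result` (mode `"v2"`).
#' @export
query_gene_v2 <- function(gene, store, master = schema_v2(),
                          full_line = FALSE) {
  v1 <- grep_word_v1(gene, store, full_line = full_line)
  rows <- harmonize_rows(dedup_latest(v1$rows), master)
  rows <- rows[order(rows$sample_id, rows$CHROM, rows$POS, method = "radix"), ,
               drop = FALSE]
  new_query_result(gene, "v2", rows)
}

#' An empty seen-variant ledger
#'
#' The ledger records every (gene, sample, variant) already reported by a
#' query, so that later batch re-queries return only what is new. It is
#' append-only across runs.
#'
#' @return A zero-row ledger tibble.
#' @export
empty_ledger <- function() {
  tibble::tibble(gene = character(), sample_id = character(),
                 chrom = character(), pos = integer(), ref = character(),
                 alt = character(), first_seen = character())
}

#' Read / write a seen-variant ledger
#'
#' Ledgers are stored as JSON lines: one
#' `{gene, sample_id, chrom, pos, ref, alt, first_seen}` record per line.
#'
#' @param path Ledger file.
#' @return `read_ledger()` returns a ledger tibble ([empty_ledger()] when the
#'   file does not exist); `write_ledger()` returns `path` invisibly.
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) return(empty_ledger())
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_ledger())
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- dplyr::bind_rows(recs)
  out$pos <- as.integer(out$pos)
  tibble::as_tibble(out)[names(empty_ledger())]
}

#' @rdname read_ledger
#' @param ledger Ledger tibble.
#' @export
write_ledger <- function(ledger, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(ledger)) {
    for (i in seq_len(nrow(ledger))) {
      writeLines(jsonlite::toJSON(as.list(ledger[i, ]), auto_unbox = TRUE),
                 con)
    }
  }
  invisible(path)
}

ledger_key <- function(gene, sample_id, chrom, pos, ref, alt) {
  paste(gene, sample_id, chrom, pos, ref, alt, sep = "\r")
}

#' End-point batch re-query with delta detection
#'
#' Re-runs the v2 query for every alert gene against the (typically grown)
#' store and returns, per gene, only the (sample, variant) pairs not already
#' recorded in the seen-variant ledger. This recovers hits missed by earlier
#' daily queries, e.g. individuals added to the database after their gene was
#' first searched. The returned ledger is the input ledger extended with all
#' newly returned entries, so cumulative deltas over a growing store equal a
#' single final query.
#'
#' @param genes Character vector of gene symbols, or an alert tibble from
#'   [read_alert_file()] (its `gene` column is used).
#' @param store A `variant_store`.
#' @param ledger A ledger tibble (may be empty).
#' @param master Master schema for harmonization.
#' @param query_date Value recorded as `first_seen` for new entries.
#' @return A list with `results` (named list of `query_result`, rows
#'   restricted to unseen pairs) and `ledger` (updated).
#' @export
requery_endpoint <- function(genes, store, ledger = empty_ledger(),
                             master = schema_v2(), query_date = "endpoint") {
  if (is.data.frame(genes)) genes <- genes$gene
  genes <- unique(genes)
  seen <- ledger_key(ledger$gene, ledger$sample_id, ledger$chrom, ledger$pos,
                     ledger$ref, ledger$alt)
  results <- list()
  new_entries <- list()
  for (g in genes) {
    res <- suppressWarnings(query_gene_v2(g, store, master))
    rows <- res$rows
    if (nrow(rows)) {
      key <- ledger_key(g, rows$sample_id, rows$CHROM, rows$POS, rows$REF,
                        rows$ALT)
      fresh <- !(key %in% seen)
      rows <- rows[fresh, , drop = FALSE]
      if (nrow(rows)) {
        new_entries[[g]] <- tibble::tibble(
          gene = g, sample_id = rows$sample_id, chrom = rows$CHROM,
          pos = rows$POS, ref = rows$REF, alt = rows$ALT,
          first_seen = query_date)
        seen <- c(seen, key[fresh])
      }
    }
    results[[g]] <- new_query_result(g, "v2", rows)
  }
  list(results = results,
       ledger = dplyr::bind_rows(c(list(ledger), unname(new_entries))))
}
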