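#' Parse genomic-position strings into variant keys
#'
#' Accepts HGVS-g style strings as printed in diagnostic reports, e.g.
#' `"chr6:g.31637615T>C"`, `"chr6:g.170594361del"`,
#' `"chr2:g.130914204_130914206del"` or `"chr2:g.160287462dup"`.
#' Substitutions parse ref/alt literally; deletions and duplications become
#' symbolic `DEL`/`DUP` alt tokens with the stated span. Coordinates are
#' 1-based and chromosome labels are preserved as given.
#'
#' @param x Character vector of position strings.
#' @return A tibble with columns `chrom`, `pos`, `end`, `ref`, `alt`.
#' @export
#' @examples
#' parse_genomic_position("chr6:g.31637615T>C")
parse_genomic_position <- function(x) {
  stopifnot(is.character(x))
  out <- lapply(x, function(s) {
    m <- regmatches(s, regexec("^([^:]+):g\\.(\\d+)([ACGT]+)>([ACGT]+)$", s))[[1]]
    if (length(m)) {
      return(list(chrom = m[2], pos = as.integer(m[3]), end = as.integer(m[3]),
                  ref = m[4], alt = m[5]))
    }
    m <- regmatches(s, regexec("^([^:]+):g\\.(\\d+)(?:_(\\d+))?(del|dup)$", s,
                               perl = TRUE))[[1]]
    if (length(m)) {
      pos <- as.integer(m[3])
      end <- if (nzchar(m[4])) as.integer(m[4]) else pos
      return(list(chrom = m[2], pos = pos, end = end,
                  ref = NA_character_, alt = toupper(m[5])))
    }
    stop("cannot parse genomic position: ", s, call. = FALSE)
  })
  tibble::tibble(
    chrom = vapply(out, `[[`, "", "chrom"),
    pos = vapply(out, `[[`, 1L, "pos"),
    end = vapply(out, `[[`, 1L, "end"),
    ref = vapply(out, `[[`, "", "ref"),
    alt = vapply(out, `[[`, "", "alt")
  )
}

parse_af_cells <- function(vals, column, path) {
  suppressWarnings(num <- as.numeric(vals))
  bad <- !is.na(vals) & is.na(num)
  if (any(bad)) {
    warning("non-numeric ", column, " cell(s) in ", path,
            " set to missing: ", paste(unique(vals[bad]), collapse = ", "),
            call. = FALSE)
  }
  num
}

#' Read an annotated variant table
#'
#' Reads one tab-separated analysis file of the store dialect: UTF-8, header
#' row, gap token (`"."` by default) for missing annotation cells. Cells
#' equal to the gap token are returned as `NA`; they are never silently zero.
#' Numeric annotation columns (positions, allele frequencies, scores) are
#' parsed as numbers; a non-numeric allele-frequency cell raises a warning
#' and becomes missing.
#'
#' @param path File to read.
#' @param schema Optional master [annotation_schema]: columns of the schema
#'   absent from the file are appended as all-missing, so tables written by
#'   older pipeline versions can be read under a newer, wider schema.
#' @param header Whether the file carries a header row. Headerless files
#'   require `schema`.
#' @return A tibble with one row per variant line.
#' @export
read_variant_table <- function(path, schema = NULL, header = TRUE) {
  if (!file.exists(path)) stop("no such variant table: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  gap <- if (is.null(schema)) "." else schema$gap_token
  if (header) {
    if (!length(lines)) stop("empty file (missing header): ", path, call. = FALSE)
    cols <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    body <- lines[-1]
    offset <- 1L
  } else {
    if (is.null(schema)) {
      stop("headerless table requires an explicit schema: ", path, call. = FALSE)
    }
    cols <- schema$columns
    body <- lines
    offset <- 0L
  }
  if (length(cols) < 8L || !identical(cols[1:8], core_columns())) {
    stop("malformed store file ", path,
         ": fewer than eight core columns, or core columns not first (line 1)",
         call. = FALSE)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(cols))
  if (length(bad)) {
    stop("malformed store file ", path, ": line ", bad[1] + offset,
         " has ", nf[bad[1]], " columns, expected ", length(cols),
         call. = FALSE)
  }
  cells <- if (length(fields)) {
    matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  } else {
    matrix(character(), nrow = 0, ncol = length(cols))
  }
  tab <- tibble::as_tibble(as.data.frame(cells, stringsAsFactors = FALSE),
                           .name_repair = "minimal")
  names(tab) <- cols
  tab[tab == gap] <- NA
  if (!is.null(schema)) {
    extra <- setdiff(schema$columns, cols)
    for (col in extra) tab[[col]] <- NA_character_
    # master columns first (in schema order), extra file columns preserved after
    tab <- tab[c(schema$columns, setdiff(cols, schema$columns))]
  }
  for (col in intersect(numeric_columns(), names(tab))) {
    tab[[col]] <- if (col %in% af_columns()) {
      parse_af_cells(tab[[col]], col, path)
    } else {
      suppressWarnings(as.numeric(tab[[col]]))
    }
  }
  if ("POS" %in% names(tab)) tab$POS <- as.integer(tab$POS)
  bad_af <- intersect(af_columns(), names(tab))
  for (col in bad_af) {
    v <- tab[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("allele frequency outside [0, 1] in column ", col, " of ", path,
           call. = FALSE)
    }
  }
  tab
}

#' Write an annotated variant table
#'
#' Writes a rectangular tab-separated table under `schema`: header row,
#' missing cells rendered as the schema's gap token. Rows must be
#' expressible in the schema; a row column that is neither in the schema nor
#' a store provenance column is a schema mismatch.
#'
#' @param rows Tibble of variant rows.
#' @param schema An [annotation_schema].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(rows, schema, path) {
  stopifnot(inherits(schema, "annotation_schema"))
  extra <- setdiff(names(rows), c(schema$columns, provenance_columns()))
  if (length(extra)) {
    stop("schema mismatch: row column(s) not in schema: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  out <- lapply(schema$columns, function(col) {
    v <- if (col %in% names(rows)) rows[[col]] else rep(NA, nrow(rows))
    v <- as.character(v)
    v[is.na(v)] <- schema$gap_token
    v
  })
  names(out) <- schema$columns
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(schema$columns, collapse = "\t"), con)
  if (nrow(rows)) {
    writeLines(do.call(paste, c(out, sep = "\t")), con)
  }
  invisible(path)
}

#' Scan a variant store directory
#'
#' A store is a directory of per-sample analysis files plus a JSON manifest
#' (`manifest.json`) listing, for each file, its path (store-relative),
#' `sample_id`, `analysis_timestamp` and pipeline `version_tag`. Analysis
#' timestamps come from the manifest, never from filesystem metadata, so a
#' store scans identically wherever it is copied. The listing is
#' deterministic: sorted by sample then timestamp, independent of filesystem
#' enumeration order. Ties on (sample, timestamp) are broken by version tag
#' (descending) then path; a hard tie is an ambiguity error.
#'
#' @param root Store directory.
#' @param manifest Manifest file name within `root`.
#' @return An object of class `variant_store` with fields `root` and `files`
#'   (a tibble: path, sample_id, analysis_timestamp, version_tag).
#' @export
scan_store <- function(root, manifest = "manifest.json") {
  if (!dir.exists(root)) stop("store root does not exist: ", root, call. = FALSE)
  mpath <- file.path(root, manifest)
  if (!file.exists(mpath)) {
    tsv <- list.files(root, pattern = "\\.tsv$")
    if (length(tsv)) {
      stop("store at ", root, " has analysis files but no manifest (",
           manifest, "); analysis timestamps must come from the manifest",
           call. = FALSE)
    }
    files <- tibble::tibble(path = character(), sample_id = character(),
                            analysis_timestamp = character(),
                            version_tag = character())
    return(structure(list(root = root, files = files), class = "variant_store"))
  }
  man <- jsonlite::fromJSON(mpath, simplifyDataFrame = TRUE)
  files <- tibble::as_tibble(man$files)
  needed <- c("path", "sample_id", "analysis_timestamp", "version_tag")
  if (!all(needed %in% names(files))) {
    stop("manifest must list ", paste(needed, collapse = ", "), call. = FALSE)
  }
  files <- files[needed]
  files[] <- lapply(files, as.character)
  missing <- !file.exists(file.path(root, files$path))
  if (any(missing)) {
    stop("manifest lists missing file(s): ",
         paste(files$path[missing], collapse = ", "), call. = FALSE)
  }
  # same-timestamp entries are ordered by version tag (descending) then path;
  # a full duplicate leaves no tie-break and is an ambiguity error
  key <- paste(files$sample_id, files$analysis_timestamp, files$version_tag,
               files$path)
  if (anyDuplicated(key)) {
    stop("ambiguous store: duplicate (sample, timestamp, version, path) for ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  ord <- order(files$sample_id, files$analysis_timestamp,
               # version tag descending breaks same-timestamp ties
               -xtfrm(files$version_tag), files$path, method = "radix")
  files <- files[ord, ]
  structure(list(root = root, files = files), class = "variant_store")
}

#' @export
print.variant_store <- function(x, ...) {
  cat("<variant_store> ", x$root, ": ", nrow(x$files), " analysis file(s), ",
      length(unique(x$files$sample_id)), " sample(s)\n", sep = "")
  invisible(x)
}

#' Read all rows of a variant store
#'
#' Reads every analysis file of a store, attaching provenance columns
#' (`sample_id`, `analysis_timestamp`, `version_tag`, `source_path`). Files
#' are parsed under their own header so stores mixing pipeline versions with
#' different column sets load as a ragged union (absent annotations are
#' `NA`). Stores mixing "chr"-prefixed and bare chromosome labels are
#' rejected: the store layer performs no coordinate normalization.
#'
#' @param store A `variant_store` from [scan_store()].
#' @return A tibble of annotated variant rows.
#' @export
read_store_rows <- function(store) {
  stopifnot(inherits(store, "variant_store"))
  if (!nrow(store$files)) {
    empty <- read_header_tibble(schema_v2())
    return(empty)
  }
  parts <- lapply(seq_len(nrow(store$files)), function(i) {
    f <- store$files[i, ]
    tab <- read_variant_table(file.path(store$root, f$path))
    tab$sample_id <- f$sample_id
    tab$analysis_timestamp <- f$analysis_timestamp
    tab$version_tag <- f$version_tag
    tab$source_path <- f$path
    tab
  })
  rows <- dplyr::bind_rows(parts)
  pref <- startsWith(rows$CHROM, "chr")
  if (any(pref) && !all(pref)) {
    stop("mixed chromosome label styles in store (both \"chr6\" and \"6\" ",
         "forms present); normalize upstream", call. = FALSE)
  }
  rows
}

read_header_tibble <- function(schema) {
  tab <- tibble::as_tibble(
    stats::setNames(rep(list(character()), length(schema$columns)),
                    schema$columns)
  )
  for (col in intersect(numeric_columns(), names(tab))) {
    tab[[col]] <- numeric()
  }
  tab$POS <- integer()
  tab$sample_id <- character()
  tab$analysis_timestamp <- character()
  tab$version_tag <- character()
  tab$source_path <- character()
  tab
}
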