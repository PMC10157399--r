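#' Core columns of an annotated variant table
#'
#' Every analysis file in a variant store is a tab-separated text table whose
#' first eight columns are the VCF core columns, in VCF order. Pipeline
#' versions differ only in the custom annotation columns that follow.
#'
#' @return Character vector of the eight mandatory column names.
#' @export
core_columns <- function() {
  c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
}

#' Population allele-frequency annotation columns
#'
#' Names of the population-frequency sources carried by the store dialect:
#' ESP, ExAC, and gnomAD exome/genome fractions in `[0, 1]`.
#'
#' @return Character vector of column names.
#' @export
af_columns <- function() {
  c("AF_ESP", "AF_EXAC", "AF_GNOMAD_EXOME", "AF_GNOMAD_GENOME")
}

# annotation columns parsed as numeric; everything else stays character
numeric_columns <- function() {
  c("POS", af_columns(), "INTERNAL_COUNT", "BATCH_COUNT", "GERP", "GRANTHAM",
    "CADD", "MISZ", "PLI", "OE", "OE_LOWER", "OE_UPPER", "CCR")
}

# columns attached by the store layer, not part of any on-disk schema
provenance_columns <- function() {
  c("sample_id", "analysis_timestamp", "version_tag", "source_path")
}

#' Construct an annotation schema
#'
#' An annotation schema records the ordered column set of one pipeline
#' version, a version tag, and the single-character placeholder used for
#' missing annotation cells on disk.
#'
#' @param columns Ordered character vector of column names. The eight core
#'   columns must be present and first.
#' @param version_tag Pipeline version identifier, e.g. `"v1"`.
#' @param gap_token Placeholder for missing cells; defaults to `"."`.
#' @return An object of class `annotation_schema`.
#' @export
annotation_schema <- function(columns, version_tag, gap_token = ".") {
  stopifnot(is.character(columns), length(columns) >= 8L,
            is.character(version_tag), length(version_tag) == 1L,
            is.character(gap_token), nchar(gap_token) == 1L)
  if (!identical(columns[1:8], core_columns())) {
    stop("the eight core columns must be present and first: ",
         paste(core_columns(), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(columns)) {
    stop("duplicate column names in schema: ",
         paste(unique(columns[duplicated(columns)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(columns = columns, version_tag = version_tag,
                 gap_token = gap_token),
            class = "annotation_schema")
}

#' @export
print.annotation_schema <- function(x, ...) {
  cat("<annotation_schema> version ", x$version_tag, ": ",
      length(x$columns), " columns (gap token \"", x$gap_token, "\")\n",
      sep = "")
  invisible(x)
}

v1_annotation_cols <- function() {
  c("GENE", "PROTEIN", af_columns(), "INTERNAL_COUNT", "BATCH_COUNT",
    "POLYPHEN", "GERP", "GRANTHAM", "CADD", "MISZ", "PLI",
    "OMIM_NAME", "OMIM_NUMBER", "OMIM_MODE", "CLINVAR")
}

#' First-generation pipeline schema
#'
#' Core VCF columns plus the original custom annotations: population
#' frequencies and occurrence counts (ESP, ExAC, gnomAD exome/genome, an
#' internal control count and a batch sample count), in-silico scores
#' (Polyphen, GERP, Grantham, CADD, misZ, pLI), OMIM name/number/mode, and
#' the ClinVar classification.
#'
#' @return An [annotation_schema].
#' @export
schema_v1 <- function() {
  annotation_schema(c(core_columns(), v1_annotation_cols()), "v1")
}

#' Second-generation pipeline schema
#'
#' [schema_v1()] extended by the annotations added during database
#' versioning: the loss-of-function observed/expected ratio with its lower
#' and upper bounds, the splicing prediction (SPiP) flag, and the constrained
#' coding region (CCR) percentile.
#'
#' @return An [annotation_schema].
#' @export
schema_v2 <- function() {
  cols <- c(core_columns(), v1_annotation_cols(),
            "OE", "OE_LOWER", "OE_UPPER", "SPIP", "CCR")
  annotation_schema(cols, "v2")
}

#' Schema registered for a pipeline version tag
#'
#' @param version_tag `"v1"` or `"v2"`.
#' @return An [annotation_schema].
#' @export
schema_for_version <- function(version_tag) {
  switch(version_tag,
         v1 = schema_v1(),
         v2 = schema_v2(),
         stop("unknown pipeline version tag: ", version_tag, call. = FALSE))
}
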