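test_that("whole-word queries never match superstring symbols", {
  dir <- withr::local_tempdir()
  set.seed(11)
  rows <- random_rows(20, genes = c("GENE1", "GENE10", "GENE11"))
  store <- build_store(dir, list(
    list(sample = "S1", timestamp = "t1", version = "v2", rows = rows)))
  res <- grep_word_v1("GENE1", store)
  expect_true(all(res$rows$GENE == "GENE1"))
  expect_equal(res$line_count, sum(rows$GENE == "GENE1"))
  # hyphenated symbols are single tokens
  rows2 <- rows
  rows2$GENE <- "NKX2-5"
  dir2 <- withr::local_tempdir()
  store2 <- build_store(dir2, list(
    list(sample = "S1", timestamp = "t1", version = "v2", rows = rows2)))
  expect_equal(suppressWarnings(grep_word_v1("NKX2", store2))$line_count, 0L)
  expect_equal(grep_word_v1("NKX2-5", store2)$line_count, nrow(rows2))
})

test_that("queries over an empty store return zero rows", {
  dir <- withr::local_tempdir()
  store <- scan_store(dir)
  expect_equal(grep_word_v1("GENE1", store)$line_count, 0L)
  expect_equal(query_gene_v2("GENE1", store)$line_count, 0L)
})

test_that("full-line matching agrees with a tokenizer oracle", {
  set.seed(12)
  for (rep in 1:4) {
    dir <- withr::local_tempdir()
    rows <- random_rows(30, genes = c("GENE1", "GENE10", "GENE2", "NKX2-5"))
    # plant the symbol inside an annotation text field on some rows
    hit <- sample(nrow(rows), 5)
    rows$OMIM_NAME[hit] <- paste0("syndrome GENE1 type", 1:5)
    store <- build_store(withr::local_tempdir(), list(
      list(sample = "S1", timestamp = "t1", version = "v2", rows = rows)))
    all_rows <- read_store_rows(store)
    for (gene in c("GENE1", "GENE10", "NKX2-5")) {
      res <- suppressWarnings(grep_word_v1(gene, store, full_line = TRUE))
      expect_equal(res$line_count, sum(oracle_word_hits(all_rows, gene)),
                   info = gene)
    }
  }
})

make_dup_store <- function(dir, n_rows = 6, seed = 13) {
  set.seed(seed)
  rows <- random_rows(n_rows, schema_v1(), genes = "GENE1")
  build_store(dir, list(
    list(sample = "S1", timestamp = "2019-01-01", version = "v1", rows = rows),
    list(sample = "S1", timestamp = "2020-06-01", version = "v2",
         rows = rows[litquery::schema_v1()$columns])))
}

test_that("dedup keeps the most recently analyzed row per sample/variant", {
  store <- make_dup_store(withr::local_tempdir())
  rows <- read_store_rows(store)
  kept <- dedup_latest(rows)
  expect_true(all(kept$analysis_timestamp == "2020-06-01"))
  # counting oracle: one row per distinct (sample, variant)
  expect_equal(nrow(kept),
               nrow(unique(rows[c("sample_id", "CHROM", "POS", "REF",
                                  "ALT")])))
  # idempotence
  expect_equal(dedup_latest(kept), kept)
  # single-analysis input is unchanged as a set
  one <- rows[rows$analysis_timestamp == "2019-01-01", ]
  expect_setequal(paste(dedup_latest(one)$CHROM, dedup_latest(one)$POS),
                  paste(one$CHROM, one$POS))
  # missing timestamps are an error
  bad <- rows
  bad$analysis_timestamp <- NA_character_
  expect_error(dedup_latest(bad), "timestamp")
})

test_that("harmonization fills version gaps and is rectangular", {
  set.seed(14)
  old <- random_rows(5, schema_v1())
  new <- random_rows(5, schema_v2())
  mixed <- dplyr::bind_rows(old, new)
  h <- harmonize_rows(mixed, schema_v2())
  expect_equal(names(h)[seq_along(schema_v2()$columns)], schema_v2()$columns)
  expect_true(all(is.na(h$SPIP[1:5])))
  expect_true(all(is.na(h$CCR[1:5])))
  # rows already on the master schema are unchanged
  expect_equal(h[6:10, schema_v2()$columns], new[schema_v2()$columns])
  # a column outside the master is an error naming it
  bad <- mixed
  bad$ROGUE <- 1
  expect_error(harmonize_rows(bad, schema_v2()), "ROGUE")
})

test_that("scripted queries deduplicate and never exceed the basic count", {
  store <- make_dup_store(withr::local_tempdir())
  v1 <- grep_word_v1("GENE1", store)
  v2 <- query_gene_v2("GENE1", store)
  expect_equal(v1$line_count, 2L * v2$line_count)
  expect_lte(v2$line_count, v1$line_count)
  # v2 rows are a subset of v1 rows modulo duplicate removal
  key <- function(r) paste(r$sample_id, r$CHROM, r$POS, r$REF, r$ALT)
  expect_true(all(key(v2$rows) %in% key(v1$rows)))
  expect_setequal(unique(key(v1$rows)), key(v2$rows))
})

test_that("ledgers round-trip as JSON lines", {
  led <- tibble::tibble(gene = "GENE1", sample_id = "S1", chrom = "chr1",
                        pos = 100L, ref = "A", alt = "T",
                        first_seen = "2020-01-01")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_ledger(led, path)
  expect_equal(read_ledger(path), led)
  expect_equal(read_ledger(tempfile()), empty_ledger())
})

test_that("end-point re-query returns exactly the unseen variants", {
  set.seed(15)
  rows_a <- random_rows(8, genes = "GENE1")
  entries <- list(
    list(sample = "S1", timestamp = "2019-01-01", version = "v2",
         rows = rows_a))
  dir_small <- withr::local_tempdir()
  store_small <- build_store(dir_small, entries)

  first <- requery_endpoint("GENE1", store_small)
  expect_equal(first$results$GENE1$line_count, nrow(rows_a))
  # idempotence: unchanged store yields empty deltas
  second <- requery_endpoint("GENE1", store_small, first$ledger)
  expect_equal(second$results$GENE1$line_count, 0L)
  expect_equal(nrow(second$ledger), nrow(first$ledger))

  # store grown by one new sample: exactly its rows come back
  rows_b <- random_rows(3, genes = "GENE1")
  dir_big <- withr::local_tempdir()
  store_big <- build_store(dir_big, c(entries, list(
    list(sample = "S2", timestamp = "2020-08-01", version = "v2",
         rows = rows_b))))
  third <- requery_endpoint("GENE1", store_big, first$ledger)
  expect_equal(third$results$GENE1$line_count, nrow(rows_b))
  expect_true(all(third$results$GENE1$rows$sample_id == "S2"))
})

test_that("cumulative daily deltas equal one end-point query", {
  set.seed(16)
  genes <- c("GENE1", "GENE2")
  stages <- list()
  entries <- list()
  for (stage in 1:3) {
    entries <- c(entries, list(
      list(sample = paste0("S", stage),
           timestamp = paste0("2020-0", stage, "-01"), version = "v2",
           rows = random_rows(6, genes = genes))))
    stages[[stage]] <- entries
  }
  ledger <- empty_ledger()
  daily_rows <- list()
  for (stage in 1:3) {
    store <- build_store(withr::local_tempdir(), stages[[stage]])
    out <- requery_endpoint(genes, store, ledger)
    ledger <- out$ledger
    daily_rows[[stage]] <- dplyr::bind_rows(
      lapply(out$results, function(r) r$rows))
  }
  final_store <- build_store(withr::local_tempdir(), stages[[3]])
  final <- requery_endpoint(genes, final_store, empty_ledger())
  final_rows <- dplyr::bind_rows(lapply(final$results, function(r) r$rows))
  got <- dplyr::bind_rows(daily_rows)
  key <- function(r) sort(paste(r$sample_id, r$CHROM, r$POS, r$REF, r$ALT))
  expect_equal(key(got), key(final_rows))
})
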