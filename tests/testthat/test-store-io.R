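test_that("genomic position strings parse into variant keys", {
  keys <- parse_genomic_position(c(
    "chr6:g.31637615T>C",
    "chr6:g.170594361del",
    "chr2:g.130914204_130914206del",
    "chr2:g.160287462dup"))
  expect_equal(keys$chrom, c("chr6", "chr6", "chr2", "chr2"))
  expect_equal(keys$pos, c(31637615L, 170594361L, 130914204L, 160287462L))
  expect_equal(keys$end, c(31637615L, 170594361L, 130914206L, 160287462L))
  expect_equal(keys$ref, c("T", NA, NA, NA))
  expect_equal(keys$alt, c("C", "DEL", "DEL", "DUP"))
  expect_error(parse_genomic_position("chr1:31637615T>C"), "cannot parse")
})

test_that("tables read with core columns plus custom annotations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c(core_columns(), "CADD"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t50\tPASS\t.\t23.1",
    "chr1\t200\t.\tG\tC\t60\tPASS\t.\t."), path)
  tab <- read_variant_table(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$CADD, c(23.1, NA))
  expect_equal(tab$POS, c(100L, 200L))
})

test_that("a master schema fills annotation gaps with the missing marker", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- random_rows(4, schema_v1(), miss_rate = 0)
  write_variant_table(rows, schema_v1(), path)
  tab <- read_variant_table(path, schema = schema_v2())
  expect_true(all(c("SPIP", "CCR", "OE") %in% names(tab)))
  expect_true(all(is.na(tab$SPIP)))
  expect_true(all(is.na(tab$CCR)))
})

test_that("malformed files and bad frequency cells are reported", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("CHROM\tPOS\tID\tREF\tALT", "chr1\t1\t.\tA\tT"), path)
  expect_error(read_variant_table(path), "fewer than eight")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c(core_columns(), "AF_GNOMAD_EXOME"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t50\tPASS\t.\t0.001",
    "chr1\t200\t.\tG\tC\t60\tPASS\t."), path2)
  expect_error(read_variant_table(path2), "line 3")

  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c(core_columns(), "AF_GNOMAD_EXOME"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t50\tPASS\t.\tnot_a_number"), path3)
  expect_warning(tab <- read_variant_table(path3), "non-numeric")
  expect_true(is.na(tab$AF_GNOMAD_EXOME))
})

test_that("write then read round-trips rows, schema and missingness", {
  set.seed(101)
  for (schema in list(schema_v1(), schema_v2())) {
    for (rep in 1:3) {
      rows <- random_rows(sample(0:12, 1), schema)
      path <- withr::local_tempfile(fileext = ".tsv")
      write_variant_table(rows, schema, path)
      back <- read_variant_table(path)
      expect_equal(names(back), schema$columns)
      for (col in schema$columns) {
        expect_equal(as.character(back[[col]]), as.character(rows[[col]]),
                     info = paste(schema$version_tag, col))
      }
      # cells missing in memory are the gap token on disk
      lines <- readLines(path)[-1]
      if (nrow(rows)) {
        cells <- do.call(rbind, strsplit(lines, "\t"))
        expect_equal(cells == ".",
                     unname(as.matrix(is.na(rows[schema$columns]) |
                                        rows[schema$columns] == ".")))
      }
    }
  }
})

test_that("writing a row with a column outside the schema is rejected", {
  rows <- random_rows(2, schema_v2())
  rows$NOT_A_COLUMN <- "x"
  expect_error(write_variant_table(rows, schema_v2(), tempfile()),
               "NOT_A_COLUMN")
})

test_that("store scanning is deterministic and manifest-driven", {
  dir <- withr::local_tempdir()
  expect_equal(nrow(scan_store(dir)$files), 0L)

  set.seed(7)
  entries <- list(
    list(sample = "S2", timestamp = "2020-06-01", version = "v2",
         rows = random_rows(3)),
    list(sample = "S1", timestamp = "2019-05-01", version = "v1",
         rows = random_rows(2, schema_v1())),
    list(sample = "S1", timestamp = "2020-06-01", version = "v2",
         rows = random_rows(2))
  )
  dir2 <- withr::local_tempdir()
  store <- build_store(dir2, entries)
  expect_equal(length(unique(store$files$sample_id)), 2L)
  expect_equal(store$files$sample_id, c("S1", "S1", "S2"))
  expect_equal(store$files$analysis_timestamp[1:2],
               c("2019-05-01", "2020-06-01"))

  # permuting the manifest order leaves the listing byte-identical
  dir3 <- withr::local_tempdir()
  store_perm <- build_store(dir3, entries[c(3, 1, 2)])
  expect_equal(store_perm$files[c("sample_id", "analysis_timestamp",
                                  "version_tag")],
               store$files[c("sample_id", "analysis_timestamp",
                             "version_tag")])

  # a timestamp tie resolves by version tag descending; a full duplicate is
  # an ambiguity error
  dir4 <- withr::local_tempdir()
  tie <- list(
    list(sample = "S1", timestamp = "2020-06-01", version = "v1",
         rows = random_rows(1, schema_v1())),
    list(sample = "S1", timestamp = "2020-06-01", version = "v2",
         rows = random_rows(1))
  )
  store_tie <- build_store(dir4, tie)
  expect_equal(store_tie$files$version_tag, c("v2", "v1"))
  man <- jsonlite::fromJSON(file.path(dir4, "manifest.json"),
                            simplifyDataFrame = FALSE)
  man$files <- c(man$files, man$files[1])
  jsonlite::write_json(man, file.path(dir4, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(scan_store(dir4), "ambiguous store")
})

test_that("stores mixing chromosome label styles are rejected", {
  dir <- withr::local_tempdir()
  set.seed(8)
  r1 <- random_rows(2)
  r2 <- random_rows(2)
  r2$CHROM <- sub("^chr", "", r2$CHROM)
  store <- build_store(dir, list(
    list(sample = "S1", timestamp = "t1", version = "v2", rows = r1),
    list(sample = "S2", timestamp = "t1", version = "v2", rows = r2)))
  expect_error(read_store_rows(store), "mixed chromosome label styles")
})
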