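test_that("TSV round-trip preserves counts and lineages", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tiny_table, path)
  back <- read_feature_table(path)
  expect_equal(dim(back), c(2L, 3L))
  expect_equal(back$counts, tiny_table$counts)
  expect_equal(back$taxonomy, tiny_table$taxonomy)
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed tables are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tsA\tsA", "f1\t1\t2"), path)
  expect_error(read_feature_table(path), "duplicate")
  writeLines(c("feature_id\tsA\tsB", "f1\t-1\t2"), path)
  expect_error(read_feature_table(path), "non-negative")
  writeLines(c("feature_id\tsA\tsB", "f1\t1.5\t2"), path)
  expect_error(read_feature_table(path), "integer")
  m <- matrix(1L, 1, 1, dimnames = list("s", "f"))
  expect_error(feature_table(rbind(m, m)), "duplicate sample")
})

test_that("lineage parsing handles partial, empty, and compact dialects", {
  r <- parse_lineage("k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales")
  expect_equal(r[1, "class"], c(class = "Clostridia"))
  expect_equal(r[1, "order"], c(order = "Clostridiales"))
  expect_true(is.na(r[1, "genus"]))
  expect_true(all(is.na(parse_lineage("")[1, ])))
  r2 <- parse_lineage("k__Bacteria;p__;c__")  # no spaces, empty ranks
  expect_equal(r2[1, "kingdom"], c(kingdom = "Bacteria"))
  expect_true(is.na(r2[1, "phylum"]) && is.na(r2[1, "class"]))
  # unprefixed segments are assigned by position
  r3 <- parse_lineage("Bacteria; Proteobacteria")
  expect_equal(unname(r3[1, "phylum"]), "Proteobacteria")
})

test_that("low-depth filter applies the read-count threshold inclusively", {
  m <- matrix(c(7000, 5999, 6000), nrow = 3,
              dimnames = list(c("a", "b", "c"), "f1"))
  ft <- feature_table(m)
  kept <- filter_low_depth(ft, 6000)
  expect_setequal(sample_ids(kept), c("a", "c"))
  expect_equal(feature_ids(kept), "f1")
  expect_equal(filter_low_depth(ft, 0)$counts, ft$counts)
  m2 <- matrix(rep(100, 3), nrow = 3, dimnames = list(c("a", "b", "c"), "f1"))
  expect_error(filter_low_depth(feature_table(m2), 6000), "6000")
})

test_that("BIOM-JSON tables load when biomformat is available", {
  skip_if_not_installed("biomformat")
  path <- withr::local_tempfile(fileext = ".biom")
  json <- jsonlite::toJSON(list(
    id = "t", format = "1.0.0", format_url = "http://biom-format.org",
    type = "OTU table", generated_by = "test", date = "2026-01-01",
    matrix_type = "dense", matrix_element_type = "int", shape = c(2, 2),
    rows = list(list(id = "f1", metadata = NULL),
                list(id = "f2", metadata = NULL)),
    columns = list(list(id = "s1", metadata = NULL),
                   list(id = "s2", metadata = NULL)),
    data = list(c(1, 2), c(3, 4))), auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  ft <- read_feature_table(path, format = "biom-json")
  expect_equal(dim(ft), c(2L, 2L))
  expect_equal(ft$counts["s2", "f2"], 4)
})

test_that("metadata validation enforces pairing constraints", {
  md <- data.frame(sample_id = c("s1", "s2"), patient_id = c("P1", "P1"),
                   tissue = c("tumor", "normal"))
  ok <- validate_metadata(tiny_table, md)
  expect_equal(ok$sample_id, c("s1", "s2"))
  expect_equal(sample_pairs(ok),
               data.frame(patient_id = "P1", tumor = "s1", normal = "s2"))
  md_bad <- data.frame(sample_id = c("s1", "s2"), patient_id = "P1",
                       tissue = "tumor")
  expect_error(validate_metadata(tiny_table, md_bad), "at most one")
})
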