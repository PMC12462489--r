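table1_columns <- c(
  "source name", "characteristics[organism]", "technology type",
  "assay name", "comment[data file]", "comment[fraction identifier]",
  "comment[label]", "comment[cleavage agent details]",
  "comment[instrument]", "comment[modification parameters]",
  "comment[proteomics data acquisition method]", "comment[tool metadata]")

test_that("written SDRF carries every standard column with file-derived cells", {
  d <- experimental_design("run01.raw", "A")
  p <- quant_params("label-free", enzymes = "Trypsin",
                    fixed_mods = "Carbamidomethyl (C)")
  md <- build_metadata_table(d, p)
  doc <- write_sdrf(md, d, p)
  expect_true(all(table1_columns %in% names(doc)))
  expect_identical(doc[["technology type"]],
                   "proteomic profiling by mass spectrometry")
  expect_identical(doc[["assay name"]], "run01")
  expect_identical(doc[["comment[data file]"]], "run01.raw")
  expect_identical(doc[["source name"]], "A")
  # untouched sample properties are autofilled
  expect_identical(doc[["characteristics[organism part]"]],
                   "not available")
  expect_false(any(as.matrix(doc) == ""))
})

test_that("autofill can be disabled, leaving empty cells as issues", {
  d <- experimental_design("run01.raw", "A")
  p <- quant_params("label-free")
  md <- build_metadata_table(d, p)
  doc <- write_sdrf(md, d, p, autofill = FALSE)
  expect_true(any(as.matrix(doc) == ""))
  issues <- validate_sdrf(doc)
  expect_true(any(issues$type == "empty-cell"))
})

test_that("writer output is byte-stable and round-trips through read_sdrf", {
  fx <- generate_design(2, 6, 3)
  md <- generate_sample_metadata(fx$design, fx$params)
  f1 <- withr::local_tempfile(fileext = ".sdrf.tsv")
  f2 <- withr::local_tempfile(fileext = ".sdrf.tsv")
  doc <- write_sdrf(md, fx$design, fx$params, path = f1)
  write_sdrf(md, fx$design, fx$params, path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_sdrf(f1)
  expect_identical(as.data.frame(back), as.data.frame(doc))
})

test_that("read_sdrf rejects malformed files and accepts mixed-case headers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tvalue", "a\t1"), f)
  expect_error(read_sdrf(f), "source name")

  writeLines(character(), f)
  expect_error(read_sdrf(f), "empty")

  writeLines(c("Source Name\tAssay Name", "s1\ta1", "s2"), f)
  expect_error(read_sdrf(f), "ragged")

  writeLines(c("Source Name\tAssay Name", "s1\ta1"), f)
  doc <- read_sdrf(f)
  expect_identical(names(doc), c("source name", "assay name"))

  # trailing empty cells survive the round trip
  writeLines(c("Source Name\tAssay Name\tComment[data file]",
               "s1\ta1\t"), f)
  expect_identical(read_sdrf(f)[["comment[data file]"]], "")
})

test_that("validate_sdrf reports each content problem exactly once", {
  fx <- generate_design(1, 6, 2)
  md <- generate_sample_metadata(fx$design, fx$params)
  doc <- write_sdrf(md, fx$design, fx$params)
  expect_identical(nrow(validate_sdrf(doc)), 0L)

  blanked <- doc
  blanked[["characteristics[organism]"]][3] <- ""
  issues <- validate_sdrf(blanked)
  expect_identical(nrow(issues), 1L)
  expect_identical(issues$type, "empty-cell")
  expect_identical(issues$row, 3L)

  bad_frac <- doc
  bad_frac[["comment[fraction identifier]"]][1] <- "one"
  expect_identical(validate_sdrf(bad_frac)$type, "bad-fraction")

  # rows 1 and 7 carry the same channel (TMT126) in different fractions;
  # pointing row 7 at row 1's file duplicates the (data file, label) pair
  dup <- doc
  dup[["comment[data file]"]][7] <- dup[["comment[data file]"]][1]
  dup[["comment[fraction identifier]"]][7] <-
    dup[["comment[fraction identifier]"]][1]
  issues <- validate_sdrf(dup)
  expect_true("duplicate-relationship" %in% issues$type)

  # brute-force duplicate count agrees with the validator
  key <- paste(dup[["comment[data file]"]], dup[["comment[label]"]])
  expect_identical(sum(issues$type == "duplicate-relationship"),
                   sum(table(key) - 1L))

  shuffled <- doc[, c(1, 7:19, 2:6)]
  class(shuffled) <- class(doc)
  expect_true("column-order" %in% validate_sdrf(shuffled)$type)

  thin <- doc[, 1:3]
  class(thin) <- class(doc)
  expect_true("missing-column" %in% validate_sdrf(thin)$type)
})

test_that("organism inference reads UniProt OS= fields only when unambiguous", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">sp|P00001|A_HUMAN Protein A OS=Homo sapiens OX=9606 GN=A PE=1 SV=1",
    "MKV",
    ">sp|P00002|B_HUMAN Protein B OS=Homo sapiens OX=9606 GN=B PE=1 SV=1",
    "MLA"), f)
  expect_identical(infer_organism_from_fasta(f), "Homo sapiens")

  writeLines(c(">contig_1", "MKV"), f)
  expect_identical(infer_organism_from_fasta(f), NA_character_)

  writeLines(c(
    ">sp|P00001|A_HUMAN Protein A OS=Homo sapiens OX=9606",
    "MKV",
    ">sp|Q00001|A_MOUSE Protein A OS=Mus musculus OX=10090",
    "MLA"), f)
  expect_warning(org <- infer_organism_from_fasta(f), "distinct organisms")
  expect_identical(org, NA_character_)
})

test_that("write_sdrf fills empty organism cells from the FASTA", {
  d <- experimental_design("run01.raw", "A")
  p <- quant_params("label-free")
  md <- build_metadata_table(d, p)
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|X_HUMAN x OS=Homo sapiens OX=9606", "MKV"), f)
  doc <- write_sdrf(md, d, p, fasta = f)
  expect_identical(doc[["characteristics[organism]"]], "Homo sapiens")
})

test_that("metadata tables round-trip through their TSV form", {
  fx <- generate_design(2, 6, 2)
  md <- generate_sample_metadata(fx$design, fx$params)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metadata_table(md, f)
  back <- read_metadata_table(f)
  expect_identical(as.data.frame(back), as.data.frame(md))
})

test_that("write_sdrf rejects metadata/design mismatches", {
  fx <- generate_design(1, 6, 1)
  md <- generate_sample_metadata(fx$design, fx$params)
  other <- generate_design(2, 6, 1)
  expect_error(write_sdrf(md, other$design, other$params),
               "missing from the metadata table")
  md2 <- rbind(md, md[1, ])
  md2$source_name[7] <- "ghost_TMT126"
  attr(md2, "characteristics") <- attr(md, "characteristics")
  class(md2) <- class(md)
  expect_error(write_sdrf(md2, fx$design, fx$params),
               "not in the design")
})
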