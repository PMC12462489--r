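lf_fixture <- function() {
  fx <- generate_design(3, 1, 1)
  fx$metadata <- generate_sample_metadata(fx$design, fx$params)
  fx$doc <- write_sdrf(fx$metadata, fx$design, fx$params)
  fx$table <- generate_protein_groups(fx$design, fx$params, 20, seed = 3)
  fx
}

tmt_fixture <- function(n_fractions = 2) {
  fx <- generate_design(1, 10, n_fractions)
  fx$metadata <- generate_sample_metadata(fx$design, fx$params)
  fx$doc <- write_sdrf(fx$metadata, fx$design, fx$params)
  fx$table <- generate_protein_groups(fx$design, fx$params, 20, seed = 4)
  fx
}

test_that("label-free samples match their LFQ intensity columns", {
  fx <- lf_fixture()
  m <- match_quant_columns(names(fx$table), fx$doc, fx$params)
  expect_identical(unname(m), paste("LFQ intensity", paste0("sample", 1:3)))
  expect_identical(names(m), paste0("sample", 1:3))

  # falls back to plain Intensity columns when LFQ is absent
  tab2 <- fx$table
  names(tab2) <- sub("^LFQ intensity", "Intensity", names(tab2))
  m2 <- match_quant_columns(names(tab2), fx$doc, fx$params)
  expect_identical(unname(m2), paste("Intensity", paste0("sample", 1:3)))
})

test_that("reporter channels match columns in label-scheme order", {
  fx <- tmt_fixture()
  m <- match_quant_columns(names(fx$table), fx$doc, fx$params)
  # brute-force channel-index table: k-th channel -> column index k
  for (k in seq_along(fx$params$label_scheme)) {
    src <- paste0("mixture1_", fx$params$label_scheme[k])
    expect_identical(unname(m[src]),
                     paste("Reporter intensity corrected", k, "mixture1"))
  }
  # 0-based convention shifts every index down by one
  tab0 <- generate_protein_groups(fx$design, fx$params, 5, seed = 1,
                                  index_base = 0L)
  m0 <- match_quant_columns(names(tab0), fx$doc, fx$params, index_base = 0L)
  expect_identical(unname(m0[paste0("mixture1_",
                                    fx$params$label_scheme[1])]),
                   "Reporter intensity corrected 0 mixture1")
})

test_that("experiment names that extend one another do not cross-match", {
  d <- experimental_design(c("a.raw", "ab.raw"), c("A", "AB"))
  p <- quant_params("label-free")
  md <- build_metadata_table(d, p)
  doc <- write_sdrf(md, d, p)
  headers <- c("Protein IDs", "LFQ intensity A", "LFQ intensity AB")
  m <- match_quant_columns(headers, doc, p)
  expect_identical(unname(m["AB"]), "LFQ intensity AB")
  expect_identical(unname(m["A"]), "LFQ intensity A")
})

test_that("matching errors name the offending sources and columns", {
  fx <- lf_fixture()
  headers <- setdiff(names(fx$table), "LFQ intensity sample2")
  expect_error(match_quant_columns(headers, fx$doc, fx$params),
               "no quantitative column found .*sample2")
  dup_headers <- c(names(fx$table), "LFQ intensity sample1")
  expect_error(match_quant_columns(dup_headers, fx$doc, fx$params),
               "appears 2 times")
})

test_that("skip-repetitive keeps exactly the non-constant properties", {
  fx <- tmt_fixture()
  ann_all <- annotate_table(fx$table, fx$doc, fx$params,
                            skip_repetitive = FALSE)
  ann_skip <- annotate_table(fx$table, fx$doc, fx$params,
                             skip_repetitive = TRUE)
  props_all <- rownames(ann_all$annotations)
  props_skip <- rownames(ann_skip$annotations)

  # skip-on rows are a subset of skip-off rows
  expect_true(all(props_skip %in% props_all))
  # every sample property appears when skipping is off
  expect_identical(props_all,
                   c(paste0("characteristics[",
                            default_characteristics(), "]"),
                     "factor value[group]"))
  # brute-force per-property scan of the collapsed sample table
  samples <- collapse_sample_rows(fx$doc)
  varying <- vapply(props_all, function(p) {
    col <- sub("^characteristics\\[(.*)\\]$", "\\1", p)
    v <- if (col == "factor value[group]") samples$group else samples[[col]]
    length(unique(v)) > 1L
  }, logical(1))
  expect_identical(props_skip, props_all[varying])
  # constant + retained = total
  expect_identical(length(props_all),
                   sum(!varying) + length(props_skip))
  # the group factor varies (tumor/normal), organism does not
  expect_true("factor value[group]" %in% props_skip)
  expect_false("characteristics[organism]" %in% props_skip)
})

test_that("annotation is invariant to SDRF row order", {
  fx <- tmt_fixture()
  set.seed(99)
  shuffled <- fx$doc[sample(nrow(fx$doc)), ]
  class(shuffled) <- class(fx$doc)
  a1 <- annotate_table(fx$table, fx$doc, fx$params)
  a2 <- annotate_table(fx$table, shuffled, fx$params)
  expect_identical(a1$annotations[order(rownames(a1$annotations)),
                                  sort(colnames(a1$annotations))],
                   a2$annotations[order(rownames(a2$annotations)),
                                  sort(colnames(a2$annotations))])
})

test_that("annotated tables serialize with annotation rows under the header", {
  fx <- lf_fixture()
  ann <- annotate_table(fx$table, fx$doc, fx$params)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotated_table(ann, f)
  lines <- readLines(f)
  expect_identical(lines[1], paste(names(fx$table), collapse = "\t"))
  n_ann <- nrow(ann$annotations)
  expect_identical(length(lines), 1L + n_ann + nrow(fx$table))
  first_ann <- strsplit(lines[2], "\t")[[1]]
  expect_identical(first_ann[1], rownames(ann$annotations)[1])
  # annotation values sit under the matched columns only
  j <- match(colnames(ann$annotations), names(fx$table))
  expect_identical(first_ann[j], unlist(ann$annotations[1, ],
                                        use.names = FALSE))
  other <- setdiff(seq_along(first_ann), c(1L, j))
  expect_true(all(first_ann[other] == ""))
})
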