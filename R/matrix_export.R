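# Conversion of a quantification table plus its SDRF into the expression
# matrix / sample-annotation pair that downstream differential-expression
# tools (limma, DESeq2, edgeR, ...) take as input. No transformation is
# applied; filtering, normalisation and modelling belong downstream.

#' Convert a quant table and SDRF into an expression bundle
#'
#' Drops rows flagged \code{"+"} in any selected flag column (decoys,
#' contaminants, site-only identifications), extracts the matched
#' intensity columns as a numeric matrix with one column per sample, and
#' builds a sample-annotation table (all SDRF sample properties plus
#' group), one row per sample in matrix column order.
#'
#' @param table data frame from \code{\link{read_quant_table}}.
#' @param doc an \code{sdrf} document.
#' @param params a \code{quant_params} object.
#' @param filters flag columns to filter on; a row is dropped iff any of
#'   them holds \code{"+"}. Default
#'   \code{c("Reverse", "Potential contaminant", "Only identified by
#'   site")}; use \code{character()} to keep everything.
#' @param zero_as_missing replace intensity 0 with \code{NA}? Default
#'   \code{TRUE} (an exact zero means "not quantified" in these tables).
#' @param id_col protein-identifier column, default \code{"Protein IDs"}.
#' @param index_base see \code{\link{match_quant_columns}}.
#' @return An object of class \code{expression_bundle}: \code{matrix}
#'   (proteins x samples, rownames = identifiers, colnames = source
#'   names) and \code{sample_annotation} (data frame, rows in matrix
#'   column order).
#' @export
to_expression_bundle <- function(table, doc, params,
                                 filters = c("Reverse",
                                             "Potential contaminant",
                                             "Only identified by site"),
                                 zero_as_missing = TRUE,
                                 id_col = "Protein IDs",
                                 index_base = 1L) {
  stopifnot(is.data.frame(table))
  if (!id_col %in% names(table))
    stop("identifier column '", id_col, "' not found in the table")
  missing_flags <- setdiff(filters, names(table))
  if (length(missing_flags))
    stop("flag column(s) not found in the table: ",
         paste(missing_flags, collapse = ", "))
  mapping <- match_quant_columns(names(table), doc, params, index_base)
  samples <- collapse_sample_rows(doc)

  keep <- rep(TRUE, nrow(table))
  for (f in filters) keep <- keep & table[[f]] != "+"
  kept <- table[keep, , drop = FALSE]

  mat <- vapply(mapping[samples$source_name], function(col) {
    suppressWarnings(as.numeric(kept[[col]]))
  }, numeric(nrow(kept)))
  mat <- matrix(mat, nrow = nrow(kept),
                dimnames = list(kept[[id_col]], samples$source_name))
  if (zero_as_missing) mat[mat == 0] <- NA_real_

  ann <- data.frame(source_name = samples$source_name,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (ch in attr(samples, "characteristics")) ann[[ch]] <- samples[[ch]]
  ann[["group"]] <- samples[["group"]]

  structure(list(matrix = mat, sample_annotation = ann),
            class = "expression_bundle")
}

#' Write an expression bundle to disk
#'
#' Writes two tab-delimited files: the matrix (first column = protein
#' identifier, remaining columns = source names; missing values empty)
#' and the sample annotation (first column = source name). These two
#' files are the input contract of common differential-expression tools.
#'
#' @param bundle an \code{expression_bundle}.
#' @param matrix_path,annotation_path output paths.
#' @param id_header header of the identifier column in the matrix file.
#' @return Invisibly, \code{c(matrix_path, annotation_path)}.
#' @export
write_expression_bundle <- function(bundle, matrix_path, annotation_path,
                                    id_header = "Protein IDs") {
  stopifnot(inherits(bundle, "expression_bundle"))
  m <- bundle$matrix
  cells <- ifelse(is.na(m), "", as.character(m))
  dim(cells) <- dim(m)
  lines <- c(paste(c(id_header, colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], cells[i, ]), collapse = "\t")
             }, ""))
  con <- file(matrix_path, open = "wb")
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  close(con)

  ann <- bundle$sample_annotation
  alines <- c(paste(names(ann), collapse = "\t"),
              if (nrow(ann))
                do.call(paste, c(lapply(ann, as.character), sep = "\t"))
              else character())
  con <- file(annotation_path, open = "wb")
  writeLines(enc2utf8(alines), con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(c(matrix_path, annotation_path))
}
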