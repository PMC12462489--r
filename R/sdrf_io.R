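# Writing, reading and validating SDRF files.
#
# SDRF is plain tab-delimited UTF-8 text, one header row plus one data row
# per sample-to-data-file relationship. No quoting is used, so cells must
# not contain tabs or newlines; empty cells are forbidden in submitted
# files, which is what the "not available" autofill guarantees. The writer
# is byte-stable: identical inputs give identical file bytes (LF line
# endings, fixed column and attribute order).

# Table-style column layout of a written document:
#   source name | characteristics[...] ... | technology type | assay name |
#   comment[...] ... | factor value[...] ...

#' Default required SDRF columns
#'
#' The column set used by \code{\link{validate_sdrf}} when no template is
#' given: the data-file columns every written document carries plus the
#' default sample characteristics.
#'
#' @return Character vector of lowercase column names.
#' @export
sdrf_default_template <- function() {
  c("source name",
    paste0("characteristics[", default_characteristics(), "]"),
    "technology type", "assay name",
    "comment[data file]", "comment[fraction identifier]", "comment[label]",
    "comment[cleavage agent details]", "comment[instrument]",
    "comment[modification parameters]",
    "comment[proteomics data acquisition method]", "comment[tool metadata]",
    "factor value[group]")
}

#' Write an SDRF document for a design
#'
#' Converts the one-row-per-sample metadata table back to the SDRF layout
#' (one row per sample-to-data-file relationship) and fills every
#' data-file property from the design and the quantification parameters:
#' assay name and data file from the raw-file name (without / with
#' extension), the fraction identifier (1 for unfractionated files),
#' ontology-annotated label, cleavage agent, instrument, modification and
#' acquisition-method cells, the tool-metadata stamp, and the study
#' variable \code{factor value[group]}. \code{technology type} is the
#' constant \code{"proteomic profiling by mass spectrometry"}.
#'
#' Multiple enzymes or modifications produce repeated
#' \code{comment[cleavage agent details]} / \code{comment[modification
#' parameters]} columns, one value per column.
#'
#' @param metadata a \code{sample_metadata} table for the design (see
#'   \code{\link{build_metadata_table}}), with sample properties filled.
#' @param design the \code{exp_design} the table was generated from.
#' @param params a \code{quant_params} object.
#' @param path optional output path; when given the document is also
#'   written to disk (UTF-8, LF, no quoting).
#' @param tool_info free-text tool name and version recorded in
#'   \code{comment[tool metadata]}.
#' @param autofill when \code{TRUE} (default), every empty sample-property
#'   cell is filled with the literal \code{"not available"} so the
#'   document has no missing values and can be submitted as-is.
#' @param fasta optional path to the search FASTA; if its headers use the
#'   UniProt dialect and name a single organism, empty
#'   \code{characteristics[organism]} cells are filled from it.
#' @return An \code{sdrf} object with one row per enumerated
#'   (file, channel) pair.
#' @examples
#' d <- experimental_design("run01.raw", "A")
#' p <- quant_params("label-free", enzymes = "Trypsin")
#' m <- build_metadata_table(d, p)
#' doc <- write_sdrf(m, d, p)
#' doc[["assay name"]]  # "run01"
#' @export
write_sdrf <- function(metadata, design, params, path = NULL,
                       tool_info = paste("sdrfkit",
                                         utils::packageVersion("sdrfkit")),
                       autofill = TRUE, fasta = NULL) {
  stopifnot(inherits(metadata, "sample_metadata"),
            inherits(design, "exp_design"),
            inherits(params, "quant_params"))
  pairs <- enumerate_pairs(design, params)
  unknown <- setdiff(pairs$source_name, metadata$source_name)
  if (length(unknown))
    stop("design enumerates source names missing from the metadata table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  extra <- setdiff(metadata$source_name, pairs$source_name)
  if (length(extra))
    stop("metadata table contains source names not in the design: ",
         paste(utils::head(extra, 5), collapse = ", "))

  chars <- attr(metadata, "characteristics")
  if (!is.null(fasta) && "organism" %in% chars) {
    org <- infer_organism_from_fasta(fasta)
    if (!is.na(org)) {
      empty <- !nzchar(metadata[["organism"]])
      metadata[["organism"]][empty] <- org
    }
  }

  i <- match(pairs$source_name, metadata$source_name)
  n <- nrow(pairs)
  vals <- list()
  nms <- character()
  add <- function(name, value) {
    vals[[length(vals) + 1L]] <<- rep_len(as.character(value), n)
    nms[length(nms) + 1L] <<- name
  }

  add("source name", pairs$source_name)
  for (ch in chars)
    add(paste0("characteristics[", ch, "]"), metadata[[ch]][i])
  add("technology type", "proteomic profiling by mass spectrometry")
  add("assay name", tools::file_path_sans_ext(pairs$file_name))
  add("comment[data file]", pairs$file_name)
  add("comment[fraction identifier]", as.character(pairs$fraction))

  label_cells <- vapply(params$label_scheme,
                        function(ch) format(map_label_term(ch)), "")
  add("comment[label]",
      label_cells[match(pairs$channel, params$label_scheme)])

  if (length(params$enzymes)) {
    for (e in params$enzymes)
      add("comment[cleavage agent details]", format(map_enzyme_term(e)))
  } else {
    add("comment[cleavage agent details]", "")
  }

  instr <- map_instrument_term(params$instrument)
  add("comment[instrument]", if (is.null(instr)) "" else format(instr))

  mods <- c(lapply(params$fixed_mods, map_modification_term, mode = "fixed"),
            lapply(params$variable_mods, map_modification_term,
                   mode = "variable"))
  if (length(mods)) {
    for (m in mods) add("comment[modification parameters]", format(m))
  } else {
    add("comment[modification parameters]", "")
  }

  add("comment[proteomics data acquisition method]",
      format(map_acquisition_term(params$acquisition)))
  add("comment[tool metadata]", tool_info)
  add("factor value[group]", metadata[["group"]][i])

  names(vals) <- paste0("V", seq_along(vals))
  df <- as.data.frame(vals, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- nms
  if (autofill) df[df == ""] <- "not available"
  doc <- new_sdrf(df)
  stopifnot(nrow(doc) == nrow(design) * plex(params))  # sum-of-plex invariant
  if (!is.null(path)) write_sdrf_file(doc, path)
  doc
}

#' Write an SDRF object to disk
#'
#' @param doc an \code{sdrf} object.
#' @param path output path. The file is UTF-8 with LF line endings and no
#'   quoting, so rewriting the same document is byte-identical.
#' @return \code{path}, invisibly.
#' @export
write_sdrf_file <- function(doc, path) {
  stopifnot(inherits(doc, "sdrf"))
  header <- paste(names(doc), collapse = "\t")
  body <- if (nrow(doc)) do.call(paste, c(unname(as.list(doc)), sep = "\t"))
          else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(header, body)), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an SDRF file
#'
#' Cell text and column order are preserved exactly; header names are
#' matched case-insensitively (and stored lowercase). Rows whose cell
#' count differs from the header are rejected.
#'
#' @param path path to a tab-delimited SDRF file.
#' @return An \code{sdrf} object.
#' @export
read_sdrf <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) stop("empty SDRF file: ", path)
  # sentinel keeps trailing empty cells that strsplit would drop
  fields <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
  header <- tolower(fields[[1]])
  if (!"source name" %in% header)
    stop("SDRF file has no 'source name' column: ", path)
  nc <- length(header)
  lens <- lengths(fields[-1])
  if (any(lens != nc))
    stop("ragged SDRF rows (cell count != ", nc, ") at line(s): ",
         paste(utils::head(which(lens != nc) + 1L, 5), collapse = ", "))
  m <- if (length(fields) > 1L) do.call(rbind, fields[-1])
       else matrix(character(), 0, nc)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- header
  new_sdrf(df)
}

#' Validate an SDRF document
#'
#' Content checks that never raise: missing required columns, empty
#' cells, non-numeric fraction identifiers, duplicate
#' (data file, label) relationships, and column-order violations
#' (characteristics before \code{technology type} and \code{assay name},
#' comments after \code{assay name}, factor values last).
#'
#' @param doc an \code{sdrf} object.
#' @param required character vector of required column names; defaults to
#'   \code{\link{sdrf_default_template}}.
#' @return A data frame of issues with columns \code{type}, \code{column},
#'   \code{row}, \code{message}; zero rows when the document is clean.
#' @export
validate_sdrf <- function(doc, required = sdrf_default_template()) {
  stopifnot(inherits(doc, "sdrf"))
  issues <- list()
  push <- function(type, column, row, message)
    issues[[length(issues) + 1L]] <<-
      data.frame(type = type, column = column, row = row, message = message,
                 stringsAsFactors = FALSE)

  nm <- names(doc)
  for (miss in setdiff(tolower(required), nm))
    push("missing-column", miss, NA_integer_,
         paste0("required column '", miss, "' is missing"))

  for (j in seq_along(nm)) {
    empty <- which(!nzchar(doc[[j]]))
    for (r in empty)
      push("empty-cell", nm[j], r,
           paste0("empty cell in '", nm[j], "' row ", r))
  }

  fi <- which(nm == "comment[fraction identifier]")
  for (j in fi) {
    bad <- which(!grepl("^[0-9]+$", doc[[j]]))
    for (r in bad)
      push("bad-fraction", nm[j], r,
           paste0("non-numeric fraction identifier '", doc[[j]][r],
                  "' in row ", r))
  }

  if (all(c("comment[data file]", "comment[label]") %in% nm)) {
    key <- paste(doc[["comment[data file]"]], doc[["comment[label]"]],
                 sep = "\r")
    dup <- which(duplicated(key))
    for (r in dup)
      push("duplicate-relationship", "comment[data file]", r,
           paste0("rows share (data file, label): ",
                  gsub("\r", " / ", key[r])))
  }

  ord_issue <- function(message)
    push("column-order", NA_character_, NA_integer_, message)
  if (nm[1] != "source name")
    ord_issue("first column must be 'source name'")
  char_idx <- grep("^characteristics\\[", nm)
  fv_idx <- grep("^factor value\\[", nm)
  cm_idx <- grep("^comment\\[", nm)
  tt <- match("technology type", nm)
  an <- match("assay name", nm)
  if (length(char_idx) && !is.na(tt) && any(char_idx > tt))
    ord_issue("characteristics columns must precede 'technology type'")
  if (length(char_idx) && !is.na(an) && any(char_idx > an))
    ord_issue("characteristics columns must precede 'assay name'")
  if (length(cm_idx) && !is.na(an) && any(cm_idx < an))
    ord_issue("comment columns must follow 'assay name'")
  if (length(fv_idx)) {
    others <- setdiff(seq_along(nm), fv_idx)
    if (length(others) && min(fv_idx) < max(others))
      ord_issue("factor value columns must come last")
  }

  if (length(issues)) do.call(rbind, issues)
  else data.frame(type = character(), column = character(),
                  row = integer(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Infer the sample organism from a UniProt FASTA
#'
#' Scans the FASTA headers for the UniProt \code{OS=} field. If every
#' entry names the same organism it is returned; headers without
#' \code{OS=} (non-UniProt databases) yield \code{NA}, as do FASTA files
#' mixing several organisms (with a warning).
#'
#' @param fasta path to a protein FASTA file.
#' @return The organism name, or \code{NA_character_}.
#' @export
infer_organism_from_fasta <- function(fasta) {
  idx <- Biostrings::fasta.index(fasta)
  desc <- idx$desc
  m <- regmatches(desc, regexpr("OS=.*?(?=\\s+[A-Z]{2}=|$)", desc,
                                perl = TRUE))
  org <- unique(sub("^OS=", "", m))
  org <- org[nzchar(org)]
  if (length(org) == 0L) return(NA_character_)
  if (length(org) > 1L) {
    warning("FASTA names ", length(org),
            " distinct organisms; cannot infer one", call. = FALSE)
    return(NA_character_)
  }
  org
}

#' Write a metadata-table template or filled table as TSV
#'
#' @param metadata a \code{sample_metadata} table.
#' @param path output path (tab-delimited, UTF-8, LF).
#' @return \code{path}, invisibly.
#' @export
write_metadata_table <- function(metadata, path) {
  stopifnot(inherits(metadata, "sample_metadata"))
  header <- paste(c("source name", attr(metadata, "characteristics"),
                    "group"), collapse = "\t")
  body <- if (nrow(metadata))
    do.call(paste, c(unname(as.list(metadata)), sep = "\t"))
  else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(header, body)), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a (possibly user-filled) metadata table TSV
#'
#' @param path path to a tab-delimited metadata table with a
#'   \code{source name} column (case-insensitive), characteristic columns
#'   and an optional \code{group} column.
#' @return A \code{sample_metadata} table.
#' @export
read_metadata_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  df[is.na(df)] <- ""
  nm <- tolower(names(df))
  i_src <- match(c("source name", "source_name"), nm)
  i_src <- i_src[!is.na(i_src)][1]
  if (is.na(i_src)) stop("metadata table has no 'source name' column")
  i_grp <- match("group", nm)
  char_idx <- setdiff(seq_along(nm), c(i_src, i_grp))
  out <- new_sample_metadata(df[[i_src]], nm[char_idx])
  for (k in char_idx) out[[nm[k]]] <- df[[k]]
  if (!is.na(i_grp)) out[["group"]] <- df[[i_grp]]
  out
}
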