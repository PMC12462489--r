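# Matching SDRF source names to the quantitative columns of a
# protein-groups table, and attaching sample properties above those
# columns as annotation rows (the layout Perseus uses).

# channel name and experiment recovered from one collapsed SDRF sample
sdrf_sample_index <- function(doc, params) {
  src <- unique(doc[["source name"]])
  multiplexed <- plex(params) > 1L
  if (!multiplexed)
    return(data.frame(source_name = src, experiment = src,
                      channel = NA_character_, k = NA_integer_,
                      stringsAsFactors = FALSE))
  if (!"comment[label]" %in% names(doc))
    stop("multiplexed matching needs a 'comment[label]' column in the SDRF")
  first <- match(src, doc[["source name"]])
  label_cell <- doc[["comment[label]"]][first]
  channel <- sub("^NT=([^;]*).*$", "\\1", label_cell)
  k <- match(channel, params$label_scheme)
  if (anyNA(k))
    stop("SDRF labels not present in the label scheme: ",
         paste(unique(channel[is.na(k)]), collapse = ", "))
  experiment <- substr(src, 1L, nchar(src) - nchar(channel) - 1L)
  bad <- src != paste(experiment, channel, sep = "_")
  if (any(bad))
    stop("source name(s) do not end in '_<label>': ",
         paste(src[bad], collapse = ", "))
  data.frame(source_name = src, experiment = experiment, channel = channel,
             k = k, stringsAsFactors = FALSE)
}

#' Match SDRF samples to quantitative table columns
#'
#' Label-free samples match \code{"LFQ intensity <experiment>"} (falling
#' back to \code{"Intensity <experiment>"}); multiplexed samples match
#' \code{"Reporter intensity corrected <k> <experiment>"} (falling back to
#' \code{"Reporter intensity <k> <experiment>"}), where \code{k} is the
#' position of the sample's channel in the label scheme, counted from
#' \code{index_base}. Matching is by full column name, so an experiment
#' named \code{"A"} never claims the columns of an experiment named
#' \code{"AB"}; the longest experiment name wins by construction.
#'
#' @param headers column names of the quantitative table.
#' @param doc an \code{sdrf} document.
#' @param params a \code{quant_params} object.
#' @param index_base 1 (default) if the first channel appears as
#'   \code{"Reporter intensity corrected 1 ..."}, 0 for the 0-based
#'   convention used by some search-engine versions.
#' @return Named character vector mapping source name to column header, a
#'   bijection over the matched samples, in SDRF sample order.
#' @export
match_quant_columns <- function(headers, doc, params, index_base = 1L) {
  stopifnot(is.character(headers), length(headers) > 0L,
            inherits(doc, "sdrf"), inherits(params, "quant_params"),
            index_base %in% c(0L, 1L))
  samples <- sdrf_sample_index(doc, params)
  multiplexed <- plex(params) > 1L
  pick <- function(cands) {
    for (cand in cands) {
      hit <- which(headers == cand)
      if (length(hit) > 1L)
        stop("column '", cand, "' appears ", length(hit),
             " times in the table header")
      if (length(hit) == 1L) return(headers[hit])
    }
    NA_character_
  }
  matched <- vapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    cands <- if (multiplexed) {
      kk <- s$k - 1L + as.integer(index_base)
      c(paste("Reporter intensity corrected", kk, s$experiment),
        paste("Reporter intensity", kk, s$experiment))
    } else {
      c(paste("LFQ intensity", s$experiment),
        paste("Intensity", s$experiment))
    }
    pick(cands)
  }, "")
  if (anyNA(matched))
    stop("no quantitative column found for source(s): ",
         paste(samples$source_name[is.na(matched)], collapse = ", "))
  if (anyDuplicated(matched)) {
    dup <- unique(matched[duplicated(matched)])
    stop("column(s) claimed by more than one source: ",
         paste(dup, collapse = ", "))
  }
  stats::setNames(matched, samples$source_name)
}

#' Annotate a quantitative table with SDRF sample properties
#'
#' Attaches one annotation row per sample property to the matched
#' intensity columns, the way Perseus annotates column metadata. With
#' \code{skip_repetitive} on (the default), properties whose values are
#' identical across all matched samples are dropped, keeping only the
#' properties that actually distinguish samples.
#'
#' @param table data frame read from a protein-groups-style TSV
#'   (\code{check.names = FALSE}).
#' @param doc an \code{sdrf} document; its fraction rows must agree on all
#'   sample properties.
#' @param params a \code{quant_params} object.
#' @param skip_repetitive drop properties constant across all samples?
#' @param index_base see \code{\link{match_quant_columns}}.
#' @return An object of class \code{annotated_table}: a list with
#'   \code{main} (the unchanged table), \code{annotations} (a data frame,
#'   one row per retained property, one column per matched intensity
#'   column) and \code{mapping} (source name to column header).
#' @export
annotate_table <- function(table, doc, params, skip_repetitive = TRUE,
                           index_base = 1L) {
  stopifnot(is.data.frame(table))
  mapping <- match_quant_columns(names(table), doc, params, index_base)
  samples <- collapse_sample_rows(doc)
  props <- c(paste0("characteristics[", attr(samples, "characteristics"),
                    "]"),
             "factor value[group]")
  values <- rbind(t(samples[, attr(samples, "characteristics"),
                            drop = FALSE]),
                  "factor value[group]" = samples[["group"]])
  rownames(values) <- props
  colnames(values) <- mapping[samples$source_name]
  if (skip_repetitive) {
    keep <- apply(values, 1L, function(v) length(unique(v)) > 1L)
    values <- values[keep, , drop = FALSE]
  }
  structure(list(main = table,
                 annotations = as.data.frame(values,
                                             stringsAsFactors = FALSE),
                 mapping = mapping),
            class = "annotated_table")
}

#' Write an annotated table as TSV
#'
#' Serialises the Perseus-style layout in plain text: the header row,
#' then one annotation row per property (its name in the first column,
#' values under the matched intensity columns, other cells empty), then
#' the data rows.
#'
#' @param x an \code{annotated_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotated_table <- function(x, path) {
  stopifnot(inherits(x, "annotated_table"))
  main <- x$main
  nm <- names(main)
  ann_lines <- vapply(rownames(x$annotations), function(p) {
    row <- rep("", length(nm))
    row[1] <- p
    j <- match(colnames(x$annotations), nm)
    row[j] <- unlist(x$annotations[p, ])
    paste(row, collapse = "\t")
  }, "")
  body <- if (nrow(main))
    do.call(paste, c(lapply(main, as.character), sep = "\t"))
  else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(paste(nm, collapse = "\t"), ann_lines, body)),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a protein-groups-style TSV
#'
#' Thin reader that keeps column names verbatim and all cells as text;
#' flag columns (\code{Reverse}, \code{Potential contaminant}, ...) use
#' \code{"+"} marks.
#'
#' @param path path to a tab-delimited table with a header row.
#' @return A data frame with \code{check.names = FALSE}.
#' @export
read_quant_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  df[is.na(df)] <- ""
  df
}
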