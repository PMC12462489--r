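# Layout conversion between the compact one-row-per-sample metadata table
# and the one-row-per-(sample, data file) SDRF layout: multiplexed label
# channels expand into extra sample rows, fractionated raw files collapse
# into one sample row.

#' Build the SDRF source name for a sample
#'
#' In a label-free design the experiment name identifies the sample and is
#' used unchanged. In a multiplexed design several samples share one raw
#' file, so the source name combines the experiment with the label channel,
#' joined by an underscore.
#'
#' @param experiment experiment name (non-empty).
#' @param label channel name, or \code{NULL} for label-free designs.
#' @return The source name, a character scalar.
#' @examples
#' make_source_name("A")                    # "A"
#' make_source_name("mixture1", "TMT126")   # "mixture1_TMT126"
#' @export
make_source_name <- function(experiment, label = NULL) {
  if (length(experiment) != 1L || is.na(experiment) ||
      !nzchar(trimws(experiment)))
    stop("'experiment' must be a single non-empty string")
  if (is.null(label) || identical(label, "label free sample"))
    return(experiment)
  if (!nzchar(trimws(label)))
    stop("'label' must be non-empty when given")
  paste(experiment, label, sep = "_")
}

# distinct experiments in design order of first appearance
design_experiments <- function(design) unique(design$experiment)

#' Build the one-row-per-sample metadata table for a design
#'
#' Expands multiplexed channels (one row per experiment x channel) and
#' collapses fractions (all raw files of one experiment share its sample
#' rows), so users fill exactly one row per sample. All sample properties
#' start empty. Row order is design experiment order, then label-scheme
#' order.
#'
#' @param design an \code{exp_design} (see
#'   \code{\link{experimental_design}}).
#' @param params a \code{quant_params} object.
#' @param characteristics sample properties to include as columns;
#'   defaults to \code{\link{default_characteristics}}.
#' @return A \code{sample_metadata} data frame with one row per sample:
#'   \code{#experiments * plex} rows (which reduces to one row per
#'   experiment for label-free designs).
#' @examples
#' d <- experimental_design(sprintf("f%02d.raw", 1:20),
#'                          rep("mixture1", 20), 1:20)
#' p <- quant_params("reporter-ion", label_scheme = paste0("TMT", 126:135))
#' nrow(build_metadata_table(d, p))  # 10
#' @export
build_metadata_table <- function(design, params,
                                 characteristics = default_characteristics()) {
  stopifnot(inherits(design, "exp_design"), inherits(params, "quant_params"))
  exps <- design_experiments(design)
  multiplexed <- plex(params) > 1L
  src <- unlist(lapply(exps, function(e) {
    if (multiplexed)
      vapply(params$label_scheme, function(l) make_source_name(e, l), "")
    else make_source_name(e)
  }), use.names = FALSE)
  new_sample_metadata(src, characteristics)
}

#' Enumerate every sample-to-data-file relationship of a design
#'
#' Each acquired file carries \code{plex} samples, so the SDRF needs one
#' row per (file, channel) pair. Pairs are ordered by design file order,
#' then label-scheme order.
#'
#' @inheritParams build_metadata_table
#' @return A data frame with columns \code{source_name}, \code{file_path},
#'   \code{file_name}, \code{experiment}, \code{fraction} (absent fractions
#'   reported as 1) and \code{channel}; \code{nrow = nrow(design) * plex}.
#' @export
enumerate_pairs <- function(design, params) {
  stopifnot(inherits(design, "exp_design"), inherits(params, "quant_params"))
  k <- plex(params)
  n <- nrow(design)
  idx <- rep(seq_len(n), each = k)
  channel <- rep(params$label_scheme, times = n)
  multiplexed <- k > 1L
  src <- vapply(seq_along(idx), function(i) {
    make_source_name(design$experiment[idx[i]],
                     if (multiplexed) channel[i] else NULL)
  }, "")
  frac <- design$fraction[idx]
  frac[is.na(frac)] <- 1L  # SDRF forbids empty cells
  data.frame(source_name = src,
             file_path = design$file_path[idx],
             file_name = design$file_name[idx],
             experiment = design$experiment[idx],
             fraction = frac,
             channel = channel,
             stringsAsFactors = FALSE)
}

# columns of an SDRF that describe the sample rather than the data file
sample_property_columns <- function(doc) {
  nm <- names(doc)
  nm[grepl("^characteristics\\[", nm) | grepl("^factor value\\[", nm)]
}

#' Collapse an SDRF back to its one-row-per-sample table
#'
#' The inverse of the layout expansion: rows sharing a source name (the
#' fractions of one sample) are merged into a single record. All sample
#' properties must agree across the rows of one source; a conflict is an
#' error naming the property and the source.
#'
#' @param doc an \code{sdrf} document.
#' @return A \code{sample_metadata} data frame, one row per distinct
#'   source name, in first-appearance order. Characteristic columns keep
#'   their bare (unbracketed) names; the \code{group} column holds
#'   \code{factor value[group]} when present.
#' @export
collapse_sample_rows <- function(doc) {
  stopifnot(inherits(doc, "sdrf"))
  src <- doc[["source name"]]
  sources <- unique(src)
  prop_cols <- sample_property_columns(doc)
  first <- match(sources, src)
  for (p in prop_cols) {
    vals <- doc[[p]]
    agree <- vapply(sources, function(s) {
      v <- vals[src == s]
      all(v == v[1])
    }, logical(1))
    if (!all(agree))
      stop("conflicting values of '", p, "' across fractions of source(s): ",
           paste(sources[!agree], collapse = ", "))
  }
  chars <- sub("^characteristics\\[(.*)\\]$", "\\1",
               grep("^characteristics\\[", prop_cols, value = TRUE))
  out <- new_sample_metadata(sources, tolower(chars))
  for (ch in chars)
    out[[tolower(ch)]] <- doc[[paste0("characteristics[", ch, "]")]][first]
  if ("factor value[group]" %in% prop_cols)
    out[["group"]] <- doc[["factor value[group]"]][first]
  out
}
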