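#' sdrfkit: SDRF-Proteomics metadata for quantitative proteomics
#'
#' Build one-row-per-sample metadata tables from an experimental design,
#' write and validate SDRF (Sample and Data Relationship Format) files,
#' annotate protein-group tables with sample properties, and export
#' expression matrices with sample annotation for downstream
#' differential-expression tools.
#'
#' @keywords internal
"_PACKAGE"

#' Construct an experimental design
#'
#' An experimental design lists the acquired raw files together with the
#' experiment (sample or multiplexed mixture) each file belongs to and,
#' for fractionated samples, the fraction identifier. It mirrors the
#' tab-separated experimental-design template used by common search
#' engines (columns \code{File}, \code{Experiment}, \code{Fraction}).
#'
#' @param file character vector of raw-file paths (or bare names).
#' @param experiment character vector of experiment names, one per file;
#'   non-empty.
#' @param fraction integer vector of fraction identifiers or \code{NULL} /
#'   \code{NA} for unfractionated files. Within one experiment fractions
#'   must either all be given or all be absent.
#' @return A data frame of class \code{exp_design} with columns
#'   \code{file_path}, \code{file_name}, \code{experiment},
#'   \code{fraction}.
#' @examples
#' experimental_design(c("a1.raw", "a2.raw"), c("A", "A"), c(1, 2))
#' @export
experimental_design <- function(file, experiment, fraction = NULL) {
  file <- as.character(file)
  experiment <- as.character(experiment)
  if (length(file) == 0L) stop("design must contain at least one file")
  if (length(experiment) != length(file))
    stop("'experiment' must have one entry per file")
  if (any(is.na(experiment)) || any(!nzchar(trimws(experiment))))
    stop("every file needs a non-empty experiment name")
  if (is.null(fraction)) {
    fraction <- rep(NA_integer_, length(file))
  } else {
    if (length(fraction) != length(file))
      stop("'fraction' must have one entry per file")
    fraction <- suppressWarnings(as.integer(fraction))
  }
  if (any(!is.na(fraction) & fraction < 1L))
    stop("fraction identifiers must be positive integers")

  file_name <- basename(file)
  if (anyDuplicated(file_name))
    stop("duplicate file names in design: ",
         paste(unique(file_name[duplicated(file_name)]), collapse = ", "))

  # fractions must be all-present or all-absent per experiment
  by_exp <- split(fraction, experiment)
  mixed <- vapply(by_exp, function(f) any(is.na(f)) && any(!is.na(f)), logical(1))
  if (any(mixed))
    stop("experiments with partially assigned fractions: ",
         paste(names(by_exp)[mixed], collapse = ", "))

  key <- paste(experiment, fraction, sep = "\r")
  has_frac <- !is.na(fraction)
  if (anyDuplicated(key[has_frac]))
    stop("duplicate (experiment, fraction) pairs in design")

  out <- data.frame(file_path = file, file_name = file_name,
                    experiment = experiment, fraction = fraction,
                    stringsAsFactors = FALSE)
  class(out) <- c("exp_design", "data.frame")
  out
}

#' Read an experimental-design TSV
#'
#' Reads a tab-separated design file with header columns \code{File},
#' \code{Experiment} and optionally \code{Fraction} (case-insensitive).
#'
#' @param path path to the design TSV.
#' @return An \code{exp_design} data frame, see
#'   \code{\link{experimental_design}}.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  nm <- tolower(names(df))
  i_file <- match("file", nm)
  i_exp <- match("experiment", nm)
  if (is.na(i_file) || is.na(i_exp))
    stop("design file must have 'File' and 'Experiment' columns")
  i_frac <- match("fraction", nm)
  frac <- if (is.na(i_frac)) NULL else {
    f <- df[[i_frac]]
    f[!nzchar(trimws(f))] <- NA
    f
  }
  experimental_design(df[[i_file]], df[[i_exp]], frac)
}

#' Construct group-specific quantification parameters
#'
#' Holds the quantification settings that determine how samples relate to
#' raw files and which data-file properties an SDRF records: the label
#' scheme (channel names for multiplexed designs), enzymes, fixed and
#' variable modifications, the instrument and the acquisition mode.
#'
#' @param quant_type one of \code{"label-free"}, \code{"reporter-ion"},
#'   \code{"metabolic-label"}.
#' @param label_scheme ordered character vector of channel names. For
#'   label-free designs this must be the singleton
#'   \code{"label free sample"} (the default when omitted); the number of
#'   channels (the plex) must be > 1 otherwise.
#' @param enzymes character vector of cleavage-agent names.
#' @param fixed_mods,variable_mods character vectors of modifications in
#'   \code{"Name (specificity)"} form, e.g. \code{"Oxidation (M)"}.
#' @param instrument instrument name (free text, mapped to the PSI-MS
#'   vocabulary when writing an SDRF).
#' @param acquisition \code{"DDA"} or \code{"DIA"}.
#' @return An object of class \code{quant_params}.
#' @examples
#' quant_params("label-free", enzymes = "Trypsin",
#'              fixed_mods = "Carbamidomethyl (C)")
#' @export
quant_params <- function(quant_type = c("label-free", "reporter-ion",
                                        "metabolic-label"),
                         label_scheme = NULL,
                         enzymes = character(),
                         fixed_mods = character(),
                         variable_mods = character(),
                         instrument = "",
                         acquisition = c("DDA", "DIA")) {
  quant_type <- match.arg(quant_type)
  acquisition <- match.arg(acquisition)
  if (is.null(label_scheme)) {
    if (quant_type != "label-free")
      stop("'label_scheme' is required for multiplexed designs")
    label_scheme <- "label free sample"
  }
  label_scheme <- as.character(label_scheme)
  if (anyDuplicated(label_scheme))
    stop("channel names must be unique within the label scheme")
  plex <- length(label_scheme)
  if (plex < 1L) stop("label scheme must contain at least one channel")
  if ((plex == 1L) != (quant_type == "label-free"))
    stop("plex must be 1 exactly for label-free designs (got plex = ",
         plex, " with quant_type = '", quant_type, "')")
  structure(list(quant_type = quant_type,
                 label_scheme = label_scheme,
                 enzymes = as.character(enzymes),
                 fixed_mods = as.character(fixed_mods),
                 variable_mods = as.character(variable_mods),
                 instrument = as.character(instrument)[1],
                 acquisition = acquisition),
            class = "quant_params")
}

#' @export
print.quant_params <- function(x, ...) {
  cat("Quantification parameters (", x$quant_type, ", ", x$acquisition,
      ")\n", sep = "")
  cat("  plex:", plex(x), "| channels:",
      paste(x$label_scheme, collapse = ", "), "\n")
  if (length(x$enzymes)) cat("  enzymes:", paste(x$enzymes, collapse = ", "), "\n")
  if (length(x$fixed_mods))
    cat("  fixed mods:", paste(x$fixed_mods, collapse = ", "), "\n")
  if (length(x$variable_mods))
    cat("  variable mods:", paste(x$variable_mods, collapse = ", "), "\n")
  if (nzchar(x$instrument)) cat("  instrument:", x$instrument, "\n")
  invisible(x)
}

#' Number of label channels
#'
#' @param params a \code{quant_params} object.
#' @return Integer plex (1 for label-free designs).
#' @export
plex <- function(params) {
  stopifnot(inherits(params, "quant_params"))
  length(params$label_scheme)
}

#' Read quantification parameters from a YAML config
#'
#' Expected keys: \code{quant_type}, \code{label_scheme}, \code{enzymes},
#' \code{fixed_mods}, \code{variable_mods}, \code{instrument},
#' \code{acquisition}.
#'
#' @param path path to a YAML file.
#' @return A \code{quant_params} object.
#' @export
read_quant_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  quant_params(quant_type = cfg$quant_type %||% "label-free",
               label_scheme = cfg$label_scheme,
               enzymes = cfg$enzymes %||% character(),
               fixed_mods = cfg$fixed_mods %||% character(),
               variable_mods = cfg$variable_mods %||% character(),
               instrument = cfg$instrument %||% "",
               acquisition = cfg$acquisition %||% "DDA")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default required sample characteristics
#'
#' The sample properties every metadata table carries by default; the set
#' follows the SDRF-Proteomics default template and can be extended per
#' call (e.g. with \code{"ancestry category"}, \code{"age"}, \code{"sex"},
#' \code{"individual"} for human studies).
#'
#' @return Character vector of lowercase characteristic names.
#' @export
default_characteristics <- function() {
  c("organism", "organism part", "disease", "cell type",
    "biological replicate")
}

# internal constructor for the one-row-per-sample table
new_sample_metadata <- function(source_name, characteristics, group = NULL) {
  stopifnot(!anyDuplicated(source_name), all(nzchar(source_name)))
  if (any(characteristics != tolower(characteristics)))
    stop("characteristic names must be lowercase")
  out <- data.frame(source_name = source_name, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (ch in characteristics) out[[ch]] <- rep("", length(source_name))
  out[["group"]] <- group %||% rep("", length(source_name))
  attr(out, "characteristics") <- characteristics
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat("Sample metadata table:", nrow(x), "samples,",
      length(attr(x, "characteristics")), "characteristics\n")
  print.data.frame(x, ...)
  invisible(x)
}

# internal constructor checking SDRF structural invariants that hold for
# any document (content checks live in validate_sdrf)
new_sdrf <- function(df) {
  stopifnot(is.data.frame(df))
  if (ncol(df) == 0L || tolower(names(df)[1]) != "source name")
    stop("first SDRF column must be 'source name'")
  bad <- vapply(df, function(col) any(grepl("[\t\n\r]", col)), logical(1))
  if (any(bad))
    stop("cells may not contain tab or newline characters (columns: ",
         paste(names(df)[bad], collapse = ", "), ")")
  names(df) <- tolower(names(df))
  class(df) <- c("sdrf", "data.frame")
  df
}

#' @export
print.sdrf <- function(x, ...) {
  cat("SDRF document:", nrow(x), "sample-to-data-file relationships,",
      ncol(x), "columns\n")
  cat("  columns:", paste(utils::head(names(x), 8), collapse = " | "),
      if (ncol(x) > 8) "| ..." else "", "\n")
  invisible(x)
}

#' @export
print.annotated_table <- function(x, ...) {
  cat("Annotated quantification table:", nrow(x$main), "rows,",
      ncol(x$main), "columns;", nrow(x$annotations),
      "annotation rows over", ncol(x$annotations), "matched columns\n")
  invisible(x)
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat("Expression bundle:", nrow(x$matrix), "features x",
      ncol(x$matrix), "samples\n")
  cat("  sample annotation columns:",
      paste(names(x$sample_annotation), collapse = ", "), "\n")
  invisible(x)
}
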