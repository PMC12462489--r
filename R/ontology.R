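# Offline controlled-vocabulary lookups and ontology-term cells.
#
# SDRF annotates data-file properties with controlled-vocabulary terms
# rendered as semicolon-joined KEY=value pairs, e.g.
#   NT=Oxidation;MT=Variable;TA=M;AC=UNIMOD:35
# The lookups (label reagents, PSI-MS cleavage agents, Unimod
# modifications, PSI-MS instruments, acquisition methods) are packaged TSV
# resources keyed by lowercase name; unknown names degrade to an NT-only
# term plus a warning rather than failing.

#' Construct an ontology term
#'
#' @param name term name (the \code{NT} attribute).
#' @param accession CURIE accession like \code{"MS:1001251"} or
#'   \code{"UNIMOD:35"}, or \code{NULL} when unknown.
#' @param ... further SDRF attributes by key, e.g. \code{MT = "Variable"},
#'   \code{TA = "M"}, \code{PP = "Protein N-term"}, \code{CS = "..."}.
#' @return An object of class \code{ontology_term}.
#' @export
ontology_term <- function(name, accession = NULL, ...) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  attrs <- c(...)
  structure(list(name = name,
                 accession = if (!is.null(accession) && nzchar(accession))
                   accession else NULL,
                 attrs = attrs),
            class = "ontology_term")
}

# fixed attribute order so that identical inputs give identical bytes
.term_attr_order <- c("MT", "PP", "TA", "CS")

#' Render an ontology term as an SDRF cell
#'
#' @param x an \code{ontology_term}.
#' @param ... ignored.
#' @return The cell text, beginning with \code{NT=} and ending with
#'   \code{AC=} when an accession is known; attribute order is NT, MT, PP,
#'   TA, CS, AC.
#' @export
format.ontology_term <- function(x, ...) {
  parts <- paste0("NT=", x$name)
  for (k in .term_attr_order)
    if (k %in% names(x$attrs))
      parts <- c(parts, paste0(k, "=", x$attrs[[k]]))
  if (!is.null(x$accession))
    parts <- c(parts, paste0("AC=", x$accession))
  paste(parts, collapse = ";")
}

#' @export
print.ontology_term <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# cache the packaged lookup tables per session
.lookup_env <- new.env(parent = emptyenv())

read_lookup <- function(which) {
  if (!is.null(.lookup_env[[which]])) return(.lookup_env[[which]])
  path <- system.file("extdata", paste0(which, ".tsv"), package = "sdrfkit",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  tab[is.na(tab)] <- ""
  rownames(tab) <- tolower(tab$name)
  .lookup_env[[which]] <- tab
  tab
}

lookup_row <- function(which, name) {
  tab <- read_lookup(which)
  i <- match(tolower(name), rownames(tab))
  if (is.na(i)) NULL else tab[i, , drop = FALSE]
}

#' Map a label channel to its ontology term
#'
#' Known reagent channels (TMT, iTRAQ, SILAC states, label-free) get the
#' accession recorded in the packaged label vocabulary; unknown channels
#' pass through as an NT-only term with a warning.
#'
#' @param channel channel name, e.g. \code{"TMT126"}; label-free designs
#'   use \code{"label free sample"}.
#' @return An \code{ontology_term}.
#' @examples
#' format(map_label_term("TMT126"))
#' @export
map_label_term <- function(channel) {
  stopifnot(is.character(channel), length(channel) == 1L, nzchar(channel))
  row <- lookup_row("labels", channel)
  if (is.null(row)) {
    warning("unknown label channel '", channel,
            "': no accession recorded", call. = FALSE)
    return(ontology_term(channel))
  }
  ontology_term(row$name, row$accession)
}

#' Map a cleavage agent (enzyme) to its ontology term
#'
#' Known agents get their PSI-MS accession and, where recorded, a
#' \code{CS} attribute holding the cleavage-site regular expression.
#'
#' @param name enzyme name, e.g. \code{"Trypsin"} or \code{"Trypsin/P"}.
#' @return An \code{ontology_term}.
#' @export
map_enzyme_term <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  row <- lookup_row("cleavage_agents", name)
  if (is.null(row)) {
    warning("unknown cleavage agent '", name,
            "': no accession recorded", call. = FALSE)
    return(ontology_term(name))
  }
  if (nzchar(row$cleavage_site))
    ontology_term(row$name, row$accession, CS = row$cleavage_site)
  else
    ontology_term(row$name, row$accession)
}

# "Oxidation (M)" -> name + specificity; bare "Oxidation" is allowed
parse_modification <- function(mod) {
  m <- regmatches(mod, regexec("^\\s*([^()]+?)\\s*(?:\\(([^()]+)\\))?\\s*$",
                               mod))[[1]]
  if (length(m) == 0L || !nzchar(m[2]))
    stop("cannot parse modification '", mod,
         "': expected \"Name\" or \"Name (specificity)\"")
  list(name = m[2], spec = if (nzchar(m[3])) m[3] else NULL)
}

.positional_specs <- c("Protein N-term", "Protein C-term",
                       "Any N-term", "Any C-term", "N-term", "C-term")

#' Map a modification to its ontology term
#'
#' Parses the search-engine notation \code{"Name (specificity)"}. The
#' \code{MT} attribute records whether the modification was searched as
#' fixed or variable; residue specificities become \code{TA} (comma-joined
#' for multi-residue sites like \code{"STY"}), positional specificities
#' like \code{"Protein N-term"} become \code{PP}. Accessions come from the
#' packaged Unimod vocabulary.
#'
#' @param mod modification string, e.g. \code{"Oxidation (M)"}.
#' @param mode \code{"fixed"} or \code{"variable"}.
#' @return An \code{ontology_term}.
#' @examples
#' format(map_modification_term("Oxidation (M)", "variable"))
#' @export
map_modification_term <- function(mod, mode = c("variable", "fixed")) {
  mode <- match.arg(mode)
  p <- parse_modification(mod)
  attrs <- c(MT = if (mode == "fixed") "Fixed" else "Variable")
  if (!is.null(p$spec)) {
    if (p$spec %in% .positional_specs) {
      attrs <- c(attrs, PP = p$spec)
    } else if (grepl("^[A-Z]+$", p$spec)) {
      attrs <- c(attrs, TA = paste(strsplit(p$spec, "")[[1]], collapse = ","))
    } else {
      stop("cannot parse modification specificity '", p$spec, "' in '",
           mod, "'")
    }
  }
  row <- lookup_row("modifications", p$name)
  if (is.null(row)) {
    warning("unknown modification '", p$name,
            "': no accession recorded", call. = FALSE)
    return(do.call(ontology_term, c(list(p$name, NULL), as.list(attrs))))
  }
  do.call(ontology_term, c(list(row$name, row$accession), as.list(attrs)))
}

#' Map the acquisition mode to its ontology term
#'
#' @param mode \code{"DDA"} (data-dependent acquisition) or \code{"DIA"}
#'   (data-independent acquisition).
#' @return An \code{ontology_term}.
#' @export
map_acquisition_term <- function(mode = c("DDA", "DIA")) {
  mode <- match.arg(mode)
  name <- switch(mode,
                 DDA = "data-dependent acquisition",
                 DIA = "data-independent acquisition")
  row <- lookup_row("acquisition_methods", name)
  ontology_term(row$name, row$accession)
}

#' Map an instrument name to its ontology term
#'
#' @param name instrument name, e.g. \code{"Q Exactive HF-X"}.
#' @return An \code{ontology_term}; unknown instruments pass through
#'   NT-only with a warning.
#' @export
map_instrument_term <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(name)) return(NULL)
  row <- lookup_row("instruments", name)
  if (is.null(row)) {
    warning("unknown instrument '", name,
            "': no accession recorded", call. = FALSE)
    return(ontology_term(name))
  }
  ontology_term(row$name, row$accession)
}
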