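# Seeded generators for synthetic designs, filled sample tables and
# protein-groups tables. They exist so every workflow (template -> SDRF ->
# annotation -> export) can be exercised end to end without real
# instrument data, and they are deterministic per seed.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# canonical reagent channel names for common plexes
label_scheme_for <- function(plex) {
  if (plex == 1L) return("label free sample")
  tmt10 <- c("TMT126", "TMT127N", "TMT127C", "TMT128N", "TMT128C",
             "TMT129N", "TMT129C", "TMT130N", "TMT130C", "TMT131")
  switch(as.character(plex),
         "2" = c("SILAC light", "SILAC heavy"),
         "3" = c("SILAC light", "SILAC medium", "SILAC heavy"),
         "4" = paste0("iTRAQ", 114:117),
         "6" = paste0("TMT", 126:131),
         "8" = paste0("iTRAQ", c(113:119, 121)),
         "10" = tmt10,
         "11" = c(tmt10, "TMT131C"),
         paste0("channel", seq_len(plex)))
}

#' Generate a synthetic experimental design with parameters
#'
#' Produces \code{n_experiments * n_fractions} raw files named
#' \code{"<experiment>_fr<k>.raw"} and a matching \code{quant_params}:
#' label-free for \code{plex = 1}, a reporter-ion scheme with canonical
#' channel names (TMT/iTRAQ where the plex has one) otherwise. With
#' \code{n_fractions = 1} the fraction column is left absent, as in an
#' unfractionated design. Deterministic for a given seed.
#'
#' @param n_experiments number of experiments (multiplexed mixtures or
#'   label-free samples).
#' @param plex number of label channels per file (1 = label-free).
#' @param n_fractions fractions per experiment.
#' @param seed integer seed.
#' @return A list with elements \code{design} (an \code{exp_design}) and
#'   \code{params} (a \code{quant_params}).
#' @examples
#' fx <- generate_design(1, plex = 10, n_fractions = 20)
#' nrow(fx$design)  # 20
#' @export
generate_design <- function(n_experiments, plex, n_fractions = 1L,
                            seed = 1L) {
  stopifnot(n_experiments >= 1L, plex >= 1L, n_fractions >= 1L)
  exps <- if (plex > 1L) paste0("mixture", seq_len(n_experiments))
          else paste0("sample", seq_len(n_experiments))
  experiment <- rep(exps, each = n_fractions)
  frac <- rep(seq_len(n_fractions), times = n_experiments)
  files <- sprintf("%s_fr%02d.raw", experiment, frac)
  design <- experimental_design(files, experiment,
                                if (n_fractions > 1L) frac else NULL)
  params <- quant_params(
    quant_type = if (plex == 1L) "label-free" else "reporter-ion",
    label_scheme = if (plex == 1L) NULL else label_scheme_for(plex),
    enzymes = "Trypsin",
    fixed_mods = "Carbamidomethyl (C)",
    variable_mods = c("Oxidation (M)", "Acetyl (Protein N-term)"),
    instrument = "Q Exactive HF-X",
    acquisition = "DDA")
  list(design = design, params = params)
}

# deterministic tumor/normal alternation shared by the metadata and the
# protein-groups generators
sample_groups_for <- function(design, params) {
  n <- length(design_experiments(design)) * plex(params)
  rep(c("tumor", "normal"), length.out = n)
}

#' Generate a filled sample-metadata table for a design
#'
#' Builds the one-row-per-sample table and fills it with plausible values:
#' a single organism, constant tissue/disease/cell-type, per-sample
#' biological replicates, and a \code{group} column alternating
#' \code{"tumor"} / \code{"normal"}.
#'
#' @param design an \code{exp_design}.
#' @param params a \code{quant_params}.
#' @param organism organism written into every row.
#' @return A filled \code{sample_metadata} table.
#' @export
generate_sample_metadata <- function(design, params,
                                     organism = "Homo sapiens") {
  md <- build_metadata_table(design, params)
  n <- nrow(md)
  md[["organism"]] <- organism
  md[["organism part"]] <- "liver"
  md[["disease"]] <- "hepatocellular carcinoma"
  md[["cell type"]] <- "not applicable"
  md[["biological replicate"]] <- as.character(seq_len(n))
  md[["group"]] <- sample_groups_for(design, params)
  md
}

#' Generate a synthetic protein-groups table for a design
#'
#' Column names follow the matcher's contract (\code{"LFQ intensity
#' <experiment>"} for label-free designs, \code{"Reporter intensity
#' corrected <k> <experiment>"} otherwise), plus \code{"Protein IDs"} and
#' the flag columns \code{Reverse}, \code{Potential contaminant} and
#' \code{Only identified by site}. Intensities are drawn lognormal
#' (mean 20, sd 1 on the log2 scale) with \code{group_effect} added on the
#' log2 scale to the tumor samples of the first fifth of proteins, so
#' group structure is visible downstream; a stated fraction of rows is
#' flagged as decoy or contaminant. Deterministic per seed.
#'
#' @param design an \code{exp_design}.
#' @param params a \code{quant_params}.
#' @param n_proteins number of protein rows.
#' @param seed integer seed.
#' @param flagged_fraction fraction of rows flagged \code{Reverse} and
#'   (independently) \code{Potential contaminant}.
#' @param group_effect log2 intensity shift for tumor samples on affected
#'   proteins.
#' @param index_base reporter-column index base, see
#'   \code{\link{match_quant_columns}}.
#' @return A data frame (\code{check.names = FALSE}) with all cells as
#'   text, like \code{\link{read_quant_table}} returns.
#' @export
generate_protein_groups <- function(design, params, n_proteins = 100L,
                                    seed = 1L, flagged_fraction = 0.1,
                                    group_effect = 1, index_base = 1L) {
  exps <- design_experiments(design)
  k <- plex(params)
  multiplexed <- k > 1L
  cols <- unlist(lapply(exps, function(e) {
    if (multiplexed)
      paste("Reporter intensity corrected",
            seq_len(k) - 1L + as.integer(index_base), e)
    else paste("LFQ intensity", e)
  }))
  groups <- sample_groups_for(design, params)

  with_seed(seed, {
    n_sample <- length(cols)
    log2_int <- matrix(stats::rnorm(n_proteins * n_sample, mean = 20, sd = 1),
                       nrow = n_proteins)
    affected <- seq_len(max(1L, floor(n_proteins / 5)))
    tumor_cols <- which(groups == "tumor")
    log2_int[affected, tumor_cols] <-
      log2_int[affected, tumor_cols] + group_effect
    intensities <- round(2^log2_int, 2)

    n_flag <- floor(flagged_fraction * n_proteins)
    rev_rows <- sample.int(n_proteins, n_flag)
    con_rows <- sample.int(n_proteins, n_flag)
  })

  tab <- data.frame("Protein IDs" = sprintf("PROT%04d", seq_len(n_proteins)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(cols)) tab[[cols[j]]] <- as.character(intensities[, j])
  flag <- function(rows) {
    v <- rep("", n_proteins); v[rows] <- "+"; v
  }
  tab[["Reverse"]] <- flag(rev_rows)
  tab[["Potential contaminant"]] <- flag(con_rows)
  tab[["Only identified by site"]] <- flag(integer())
  tab
}
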