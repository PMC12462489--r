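# sdrfkit

Metadata handling is a persistent pain point in mass-spectrometry
proteomics. Quantification tables name their intensity columns after raw
files and experiments, not after the biological samples behind them, and
the community standard for sample metadata — SDRF-Proteomics (Sample and
Data Relationship Format) — asks for one row per *sample-to-data-file
relationship*. For multiplexed experiments (several labelled samples per
acquired file) and fractionated experiments (several files per sample)
that layout forces large amounts of repetitive manual entry, which is a
major reason so few public datasets ship an SDRF at all.

`sdrfkit` is an R toolkit for both directions of that problem:

* **Design → SDRF.** From an experimental-design table (`File`,
  `Experiment`, `Fraction`) and the quantification parameters (label
  scheme, enzymes, modifications, instrument, acquisition mode) it builds
  a *compact one-row-per-sample* metadata table: label channels are
  expanded into rows, fractions are collapsed into one. A TMT 10-plex
  measured in 20 fractions needs a 10-row table from the user, and the
  package writes the full 200-row SDRF (10 samples × 20 files), filling
  every data-file property automatically — assay name and data file from
  the file name, fraction identifiers, and ontology-annotated cells
  (`NT=Trypsin;CS=(?<=[KR])(?!P);AC=MS:1001251`) from packaged PSI-MS and
  Unimod vocabulary lookups. Empty sample properties can be autofilled
  with the literal `not available`, so the file validates with no missing
  values and can be submitted to a repository as-is.

* **SDRF → analysis.** Given an SDRF (from this package or any other
  tool) and a protein-groups-style table, it matches each sample's source
  name to its intensity column (`LFQ intensity <experiment>` for
  label-free, `Reporter intensity corrected <k> <experiment>` for
  reporter-ion designs), attaches sample properties as Perseus-style
  annotation rows (optionally skipping properties identical across all
  samples), and exports an expression matrix plus sample-annotation table
  — the two-file input contract of limma, DESeq2 and edgeR.

The key identity throughout: a sample's **source name** equals its
experiment name, suffixed with `_<label>` for multiplexed designs, so
`mixture1_TMT126` is the first channel of mixture 1.

## Worked example

```r
library(sdrfkit)

# one TMT 10-plex mixture, fractionated into 20 raw files
fx <- generate_design(n_experiments = 1, plex = 10, n_fractions = 20)
md <- build_metadata_table(fx$design, fx$params)
nrow(md)
#> [1] 10

# fill the 10 sample rows (here with the synthetic generator) and write
filled <- generate_sample_metadata(fx$design, fx$params)
doc <- write_sdrf(filled, fx$design, fx$params, path = "out.sdrf.tsv")
doc
#> SDRF document: 200 sample-to-data-file relationships, 19 columns
#>   columns: source name | characteristics[organism] | ...
nrow(validate_sdrf(doc))
#> [1] 0

# annotate a protein-groups table and export for limma/DESeq2/edgeR
tab <- generate_protein_groups(fx$design, fx$params,
                               n_proteins = 100, seed = 1)
ann <- annotate_table(tab, doc, fx$params, skip_repetitive = TRUE)
rownames(ann$annotations)
#> [1] "characteristics[biological replicate]" "factor value[group]"

to_expression_bundle(tab, doc, fx$params)
#> Expression bundle: 81 features x 10 samples
#>   sample annotation columns: source_name, organism, organism part, ...
```

The 10-row table is all a user fills in; the 200 SDRF rows, the ontology
cells and the column layout are derived. With skip-repetitive annotation
only the properties that differ between samples survive (here the
replicate number and the tumor/normal group — organism, tissue, disease
and cell type are identical across samples and would annotate nothing).
The 81 × 10 matrix is what remains of 100 proteins after dropping rows
flagged as decoys (`Reverse`) or contaminants, with zero intensities
recorded as missing.

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/sdrfkit.R template     --design design.tsv --params params.yaml --out template.tsv
Rscript inst/cli/sdrfkit.R write-sdrf   --design design.tsv --params params.yaml \
                                        --metadata filled.tsv --out out.sdrf.tsv
Rscript inst/cli/sdrfkit.R validate     --sdrf out.sdrf.tsv
Rscript inst/cli/sdrfkit.R annotate     --table proteinGroups.txt --sdrf out.sdrf.tsv \
                                        --params params.yaml --out annotated.tsv
Rscript inst/cli/sdrfkit.R export-matrix --table proteinGroups.txt --sdrf out.sdrf.tsv \
                                        --params params.yaml \
                                        --matrix-out matrix.tsv --annotation-out samples.tsv
Rscript inst/cli/sdrfkit.R fixtures     --experiments 1 --plex 10 --fractions 4 \
                                        --seed 3 --proteins 100 --out-dir fixtures/
```

`validate` exits non-zero when issues are found. `--reporter-index-base
{0,1}` selects the reporter-column numbering convention.

## Tests

```sh
Rscript -e 'devtools::test()'
```

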