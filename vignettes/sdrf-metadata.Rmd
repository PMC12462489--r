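---
title: "SDRF metadata for multiplexed and fractionated proteomics: how sdrfkit works"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SDRF metadata for multiplexed and fractionated proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrfkit)
```

## The sample-to-file relationship model

SDRF-Proteomics describes a study as a bipartite relation between
*samples* and *acquired data files*, one table row per relationship.
Two experimental practices make that relation non-trivial:

* **Multiplexing** (TMT, iTRAQ, SILAC): several chemically labelled
  samples share one acquired file. One file therefore contributes
  `plex` rows, where plex is the number of label channels.
* **Fractionation**: one sample is split across several acquired files
  to increase depth. One sample therefore appears once per fraction.

For a design with files $f_1 \dots f_n$ each carrying $k$ channels, the
SDRF has exactly $\sum_i k = n \cdot k$ rows, while the set of distinct
samples has $|E| \cdot k$ members for $|E|$ distinct experiments. This
is the core arithmetic of the package and it is asserted on every
construction: the canonical example of one TMT 10-plex mixture measured
in 20 fractions gives a 10-row sample table and a 200-row SDRF.

The unique sample identifier (the SDRF *source name*) is the experiment
name, suffixed with `_<channel>` when multiplexed. The underscore
separator is the package's choice; the convention in the field is only
"experiment combined with label", and an underscore keeps identifiers
free of whitespace. `make_source_name()` implements it,
`collapse_sample_rows()` inverts the expansion, and the round trip
(expand, write, collapse) is tested as an identity over randomized
designs.

Within the expanded table, row order is deterministic: experiments in
design order, then channels in label-scheme order; relationship rows are
file-major, then channel. Nothing in SDRF mandates an order, but a fixed
one makes the writer byte-stable, which in turn makes outputs diffable
and cacheable.

## What the writer fills and from where

The user fills only sample properties (organism, organism part, disease,
cell type, biological replicate by default, plus a free-form `group`
study variable that becomes `factor value[group]`). Everything else
derives from the design and the quantification parameters:

| column | source |
|---|---|
| `source name` | experiment (+ label) |
| `technology type` | constant `proteomic profiling by mass spectrometry` |
| `assay name` / `comment[data file]` | file name without / with extension |
| `comment[fraction identifier]` | design fraction, `1` if unfractionated |
| `comment[label]` | label scheme, per channel |
| `comment[cleavage agent details]` | enzymes, one repeated column each |
| `comment[modification parameters]` | fixed then variable modifications, one column each |
| `comment[instrument]` | instrument name |
| `comment[proteomics data acquisition method]` | DDA or DIA |
| `comment[tool metadata]` | this package's name and version |

Ontology cells are rendered as `KEY=value` pairs in the fixed order NT,
MT, PP, TA, CS, AC — another byte-stability choice, since no ordering is
prescribed. Accessions come from packaged offline lookup tables built
from the public controlled vocabularies (PSI-MS for labels, cleavage
agents and instruments; Unimod for modifications; the NCIT
acquisition-method terms used by the SDRF-Proteomics templates). An
unknown name degrades to an `NT=`-only term with a warning rather than
an error: the cell stays valid SDRF, and refusing to write a file over
an unrecognised reagent would help nobody. Modification specificities
parse the common search-engine notation: `"Oxidation (M)"` gives
`TA=M`, `"Phospho (STY)"` gives `TA=S,T,Y`, and positional sites such as
`"Acetyl (Protein N-term)"` give `PP=` instead of `TA=`.

Organism can be inferred from the search database when its FASTA headers
follow the UniProt dialect: the `OS=` field is extracted from every
header and used only if a single organism is named; mixtures yield a
warning and leave the cell to the user.

With `autofill = TRUE` every remaining empty cell becomes the literal
`not available` (lowercase, exactly), so the written file has no missing
values — empty cells are the most common reason SDRF submissions fail
validation. `validate_sdrf()` checks the same contract from the reading
side (required columns, empty cells, numeric fraction identifiers,
duplicate file/label relationships, column-group order) and returns an
issue table instead of raising, so a validator run can report everything
at once.

## Annotation and export

`match_quant_columns()` connects SDRF samples to table columns by *exact*
column-name equality: `LFQ intensity <experiment>` (falling back to
`Intensity <experiment>`) for label-free data, and
`Reporter intensity corrected <k> <experiment>` for reporter-ion data,
where `k` is the channel's position in the label scheme. Exact equality
sidesteps prefix ambiguity — an experiment named `A` can never claim the
columns of an experiment named `AB` — and makes the matching a checked
bijection: a sample with no column, or a column claimed twice, is an
error naming the offenders. Because the reporter-column numbering
convention has differed between search-engine versions, `index_base`
selects whether the first channel is column `1` (default) or `0`.

`annotate_table()` attaches one annotation row per sample property above
the matched columns, the layout Perseus uses. With skip-repetitive on
(default), a property is kept only if its values differ between samples:
a single-organism study gains nothing from ten identical `organism`
annotations, whereas the tumor/normal `group` is exactly what downstream
statistics needs. `to_expression_bundle()` produces the numeric matrix
(rows filtered on the `+`-flag columns `Reverse`,
`Potential contaminant`, `Only identified by site`, each individually
switchable) and the per-sample annotation table; zero intensities become
`NA` by default because an exact zero in these tables means "not
quantified", not "measured as zero". No log-transform or normalisation
is applied — those belong to the downstream tool.

## The synthetic generators

`generate_design()` emulates the layouts the package must handle:
`n_experiments × n_fractions` raw files with canonical channel names for
the common plexes (TMT 6/10/11, iTRAQ 4/8, SILAC 2/3), trypsin
digestion, carbamidomethyl/oxidation/N-terminal-acetyl modifications and
a DDA Orbitrap setup. `generate_protein_groups()` draws intensities
lognormal with mean 20 and standard deviation 1 on the log2 scale —
typical of reporter-ion protein intensities — adds a +1 log2 group
effect to the tumor samples of the first fifth of proteins so that group
structure is non-trivial, and flags 10% of rows as decoys and, independently,
10% as contaminants. All randomness sits behind one seed and the global
RNG stream is restored afterwards.

What the generators do *not* emulate: missing values and their
intensity-dependence, correlated fractions, batch effects, shared
peptides, or realistic protein identifiers. Passing tests therefore
demonstrate the metadata plumbing — layout arithmetic, format contracts,
matching, filtering — not statistical behaviour on real data.
Problem sizes in the test suite stay small (designs up to 3 experiments
× 11 channels × 4 fractions, tables of tens of proteins, 200 randomized
designs for the row-count property), which exercises every code path in
seconds.

## Numerical and degenerate-input choices

* A design with no `Fraction` column is treated as unfractionated and
  written with fraction identifier `1`, because SDRF forbids empty
  cells.
* Mixed designs (some experiments fractionated, some not) are allowed;
  collapse is per-experiment. Partially fractionated experiments are
  rejected at construction.
* Cells containing tabs or newlines are rejected when a document is
  built — SDRF is unquoted TSV, so such cells cannot be represented.
* Files are written UTF-8 with LF endings and read back cell-for-cell
  identically; headers are compared case-insensitively and stored
  lowercase.
* An empty enzyme or modification list still emits its column (empty,
  or `not available` under autofill) so the standard column set is
  always present.

## Known limitations

* One parameter set per run: designs mixing label schemes across
  experiments are out of scope.
* Ontology lookups are offline snapshots of the public vocabularies;
  terms added upstream later resolve as NT-only until the tables are
  refreshed.
* Only protein-level tables are exercised; peptide/evidence tables use
  the same mechanism but are not covered by tests.
* Vendor raw files are never read; the instrument is a configuration
  field.
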