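# shared generators for property-style tests: a randomized design/params
# pair plus a filled metadata table, drawn from the layouts the package
# supports (label-free and common reporter-ion plexes, with and without
# fractionation)

random_case <- function(seed) {
  set.seed(seed)
  n_exp <- sample(1:3, 1)
  plex_k <- sample(c(1L, 6L, 10L, 11L), 1)
  n_frac <- sample(1:4, 1)
  fx <- generate_design(n_exp, plex_k, n_frac, seed)
  fx$metadata <- generate_sample_metadata(fx$design, fx$params)
  fx
}

# brute-force count of (experiment x channel) combinations, kept separate
# from the layout code it checks
expected_sample_count <- function(design, params) {
  length(unique(design$experiment)) * length(params$label_scheme)
}
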