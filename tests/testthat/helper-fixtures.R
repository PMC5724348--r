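# Expensive fixtures shared between test files, built once per run.

.fixture_env <- new.env(parent = emptyenv())

# 500 kb pair at p = 0.5 (the reference operating point), k = 90
fixture_spectrum_500kb <- function(seed) {
  key <- paste0("spec500_", seed)
  if (is.null(.fixture_env[[key]])) {
    pair <- simulate_pair(L = 5e5, p = 0.5, seed = seed)
    .fixture_env[[key]] <- match_spectrum(pair$s1, pair$s2, k = 90)
  }
  .fixture_env[[key]]
}

fixture_seeds_500kb <- 101:105
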