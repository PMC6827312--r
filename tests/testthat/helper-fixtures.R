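# Shared fixtures, built once per test run and cached. The heavy pieces
# (all-vs-all alignment of the five-family set, its HMM library) are reused
# across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

five_family <- function() cached("five_family", {
  synth_preset("five_families_small", seed = 1)
})

five_family_hits <- function() cached("five_family_hits", {
  all_vs_all(five_family()$records)
})

five_family_scan <- function() cached("five_family_scan", {
  threshold_scan(five_family_hits(), five_family()$records$id)
})

five_family_delineation <- function() cached("five_family_delineation", {
  part <- partition_at(five_family_scan(), 1e-55)
  suppressMessages(delineate(part, five_family()$records))
})

five_family_library <- function() cached("five_family_library", {
  build_hmm_library(five_family()$records,
                    five_family_delineation()$membership)
})

singletons <- function() cached("singletons", {
  synth_preset("singletons_divergent", seed = 1)
})

fragments_bundle <- function() cached("fragments_bundle", {
  synth_preset("two_families_with_fragments", seed = 1)
})
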