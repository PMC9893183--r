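# One shared fixture bundle and build per test run; generation is
# deterministic, so sharing it across test files only saves time.
.shared <- new.env(parent = emptyenv())

shared_spec <- function() fixture_spec(rng_seed = 42)

shared_bundle_dir <- function() {
  if (is.null(.shared$dir)) {
    dir <- file.path(tempdir(), "kgcraft-shared-bundle")
    make_mock_resources(shared_spec(), dir)
    .shared$dir <- dir
  }
  .shared$dir
}

shared_build <- function() {
  if (is.null(.shared$built)) {
    .shared$built <- build_kg_from_bundle(shared_bundle_dir())
  }
  .shared$built
}

shared_truth <- function() {
  jsonlite::read_json(
    file.path(shared_bundle_dir(), "planted_truth.json"),
    simplifyVector = TRUE
  )
}
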