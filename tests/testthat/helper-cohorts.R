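# Memoized synthetic-cohort feature tables: several test files use the
# same seeded cohorts, and extraction is the expensive step.  The cache
# lives for the duration of the test run.

.cohort_cache <- new.env(parent = emptyenv())

cached_features <- function(spec) {
  key <- paste(spec$seed, spec$n_spch, spec$n_lpa, spec$grid_size,
               spec$lpa_easy_fraction, digest_params(spec$spch),
               digest_params(spec$lpa_easy), digest_params(spec$lpa_hard),
               sep = "|")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- cohort_features(spec)
  .cohort_cache[[key]]
}

digest_params <- function(p) paste(unlist(p), collapse = ",")

cached_default_features <- function(seed) cached_features(default_spec(seed))

# the no-signal control: both classes drawn from the SPCH parameters
null_spec <- function(seed) {
  p <- default_spec(seed)
  cohort_spec(spch = p$spch, lpa_easy = p$spch, lpa_hard = p$spch,
              grid_size = 32, seed = seed)
}
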