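# Shared phantom fixtures; full-size pipeline runs are expensive, so test
# files cache them in this environment keyed by (seed, sd).
.fixture_cache <- new.env(parent = emptyenv())

cached_phantom <- function(seed, sd, ...) {
  key <- paste0("ph_", seed, "_", sd, "_",
                paste(deparse(substitute(list(...))), collapse = ""))
  if (!exists(key, envir = .fixture_cache))
    assign(key, phantom_generate(phantom_spec(seed = seed, speckle_sd = sd,
                                              ...)),
           envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

cached_segmentation <- function(seed, sd) {
  key <- paste0("seg_", seed, "_", sd)
  if (!exists(key, envir = .fixture_cache)) {
    ph <- cached_phantom(seed, sd)
    assign(key, segment_rnfl(ph$image), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
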