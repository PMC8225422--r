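# Seeded reference runs shared across test files, computed once per session.

.trace_cache <- new.env(parent = emptyenv())

cached_trace <- function(tag, seed = 1L) {
  key <- paste0(tag, "_", seed)
  if (is.null(.trace_cache[[key]])) {
    .trace_cache[[key]] <- run_simulation(make_fixture(tag, seed)$config)
  }
  .trace_cache[[key]]
}
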