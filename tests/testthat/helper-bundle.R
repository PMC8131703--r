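# The default experiment takes ~20 s, so tests that inspect the bundle share
# one run.
.bundle_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.bundle_cache$bundle)) .bundle_cache$bundle <- run_experiment()
  .bundle_cache$bundle
}
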