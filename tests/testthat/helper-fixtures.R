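# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

## Full-size default locus (500 kb background), as the acceptance checks use
default_locus <- function() {
  if (is.null(.fixtures$default_locus)) {
    .fixtures$default_locus <- build_synthetic_locus(locus_spec(), seed = 42)
  }
  .fixtures$default_locus
}

## Small locus on a 60 kb background for fast protocol tests
small_locus <- function() {
  if (is.null(.fixtures$small_locus)) {
    .fixtures$small_locus <- build_synthetic_locus(
      locus_spec(background_len = 60000), seed = 11)
  }
  .fixtures$small_locus
}
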