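# Lazily built, session-cached default synthetic set and pipeline bundle,
# shared by the end-to-end tests so the (deliberately realistic-scale)
# generation and full run happen once per test session.

.t6_cache <- new.env(parent = emptyenv())

default_set <- function() {
  if (is.null(.t6_cache$set)) {
    dir <- file.path(tempdir(), "t6sscan_default_set")
    cfg <- synth_config(seed = 20220128L)
    .t6_cache$set <- generate_genome_set(cfg, dir)
    .t6_cache$set_dir <- dir
    .t6_cache$truth <- .t6_cache$set$truth
  }
  .t6_cache$set
}

default_bundle <- function() {
  if (is.null(.t6_cache$bundle)) {
    set <- default_set()
    out <- file.path(tempdir(), "t6sscan_default_out")
    cfg <- run_config(.t6_cache$set_dir, out, seed = 20220128L)
    .t6_cache$bundle <- suppressWarnings(suppressMessages(run_all(cfg)))
    .t6_cache$bundle_cfg <- cfg
  }
  .t6_cache$bundle
}
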