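# The end-to-end phantom study is expensive, and several acceptance checks
# read different aspects of the same run; compute it once per test session.
.study_cache <- new.env(parent = emptyenv())

get_study <- function() {
  if (is.null(.study_cache$res))
    .study_cache$res <- run_study(seed = 1, profile = "demo")
  .study_cache$res
}
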