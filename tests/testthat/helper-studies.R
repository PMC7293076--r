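# Desk-scale study runs shared between acceptance checks (the trap study is
# reused by the cross-condition ordering check), computed lazily and cached
# for the duration of the test run.
.study_cache <- new.env(parent = emptyenv())

deskStudy <- function(name, base_seed = 1) {
  key <- paste0(name, "#", base_seed)
  if (is.null(.study_cache[[key]])) {
    proto <- protocolPreset(name, scale = "desk", base_seed = base_seed)
    .study_cache[[key]] <- runStudy(proto)
  }
  .study_cache[[key]]
}
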