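# The desk-scale end-to-end study is expensive (a few minutes), so the
# acceptance tests share one run; the determinism check performs its own
# second run and compares bit-for-bit.

.studyCache <- new.env(parent = emptyenv())

getStudy <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.studyCache[[key]]))
    .studyCache[[key]] <- runCascadeStudy(seed = seed)
  .studyCache[[key]]
}
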