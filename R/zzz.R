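.onLoad <- function(libname, pkgname) {
  # ranger touches Matrix S4 machinery on every call; loading it once here
  # avoids repeated namespace/method-cache work inside tight CV loops.
  requireNamespace("Matrix", quietly = TRUE)
  invisible()
}
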