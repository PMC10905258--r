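.onLoad <- function(libname, pkgname) {
  if (!exists("baseline", envir = .method_registry, inherits = FALSE)) {
    register_method("baseline", baseline_center_scale, provenance = "builtin")
  }
}
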