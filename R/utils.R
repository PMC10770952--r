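# shared internal helpers

# coordinate convention used throughout: (row, col), 1-based in R matrices,
# origin top-left; distances in pixels between pixel centres

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg, class = "retmorph_error")
}

# FNV-1a 32-bit hash of a character scalar or raw vector, as 8 hex digits;
# used to fingerprint run configurations and input files in manifests
fnv1a_hash <- function(x) {
  if (!is.raw(x)) x <- charToRaw(enc2utf8(paste(x, collapse = "\n")))
  .cpp_fnv1a(x)
}

# binary matrix from labelled mask for one vessel class
class_foreground <- function(mask, vessel_class) {
  code <- switch(vessel_class, artery = 1L, vein = 2L,
                 abort(sprintf("unknown vessel class '%s'", vessel_class)))
  (unclass(mask$grid) == code) * 1L
}

vessel_classes <- c("artery", "vein")
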