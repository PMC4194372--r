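#' plastarch: comparative chloroplast genome architecture
#'
#' See the package vignette for the underlying models and conventions.
#'
#' @name plastarch-package
#' @aliases plastarch
#' @importFrom methods new is validObject setValidity slot
#' @importFrom stats runif
#' @importFrom utils read.delim write.table combn packageVersion
"_PACKAGE"
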