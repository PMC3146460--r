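#' @useDynLib phosdelta, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd runif rnorm
#' @importFrom utils head tail
NULL
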