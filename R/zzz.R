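#' @useDynLib altiscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml
NULL
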