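#' @keywords internal
#' @useDynLib fenestra, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
#' @importFrom dplyr where
"_PACKAGE"

#' @export
ggplot2::autoplot
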