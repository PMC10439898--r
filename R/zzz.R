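#' @keywords internal
#' @useDynLib lvquant, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
"_PACKAGE"

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
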