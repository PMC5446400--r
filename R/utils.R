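`%||%` <- function(a, b) if (is.null(a)) b else a

# uL/min -> um^3/s
ULMIN_TO_UM3S <- 1e9 / 60

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @useDynLib dldcluster, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL
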