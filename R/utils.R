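`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' @importFrom stats approxfun quantile rexp runif rpois setNames var
#' @importFrom rlang .data
NULL

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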