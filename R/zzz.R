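#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @import Matrix
#' @importFrom methods as
#' @importFrom rlang abort
NULL
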