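# Generics re-exported so tidy()/glance()/autoplot() work without loading
# broom or ggplot2 explicitly.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
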