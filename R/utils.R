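#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Classed error so callers can distinguish validation failures programmatically.
stop_compactmix <- function(kind, message, ...) {
  rlang::abort(message,
               class = c(paste0("compactmix_", kind), "compactmix_error"),
               ...)
}
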