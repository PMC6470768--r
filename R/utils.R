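`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative standard deviation
#'
#' sd/mean of a numeric vector; `NaN` when the mean is zero.
#' @param x numeric vector.
#' @return scalar RSD.
#' @keywords internal
rsd <- function(x) stats::sd(x) / mean(x)

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop2(msg)
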