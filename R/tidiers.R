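#' Tidy a scenario run into a probe table
#'
#' @param x A `ptt_run`.
#' @param ... Unused.
#' @return Tibble of probe series: probe label, time, temperature rise
#'   and absolute temperature.
#' @export
tidy.ptt_run <- function(x, ...) {
  x$probes
}

#' One-row summary of a scenario run
#'
#' @param x A `ptt_run`.
#' @param ... Unused.
#' @return One-row tibble: scaling factor, nano absorption, absorbed
#'   fraction, peak-voxel statistical uncertainty and maximum
#'   temperature rise.
#' @export
glance.ptt_run <- function(x, ...) {
  x$summary
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
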