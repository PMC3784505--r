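#' Tidy methods for experiment results
#'
#' `tidy()` returns the per-observation table of a result (regression
#' scatter for HTA, binned map for CIA, per-side-sample whisk statistics
#' for SR); `glance()` returns a one-row summary.
#'
#' @param x An `hta_result`, `cia_result` or `sr_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name vibrisim-tidiers
NULL

#' @rdname vibrisim-tidiers
#' @export
tidy.hta_result <- function(x, ...) {
  x$data
}

#' @rdname vibrisim-tidiers
#' @export
glance.hta_result <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         correlation = x$correlation, n = x$n, duration = x$duration)
}

#' @rdname vibrisim-tidiers
#' @export
tidy.cia_result <- function(x, ...) {
  x$map
}

#' @rdname vibrisim-tidiers
#' @export
glance.cia_result <- function(x, ...) {
  bias <- cia_lateral_bias(x)
  tibble(n_near = x$n_near, n_far = x$n_far, n_whisks = x$n_whisks,
         baseline = x$baseline, ipsi = bias$ipsi, contra = bias$contra,
         duration = x$duration)
}

#' @rdname vibrisim-tidiers
#' @export
tidy.sr_result <- function(x, ...) {
  x$samples
}

#' @rdname vibrisim-tidiers
#' @export
glance.sr_result <- function(x, ...) {
  s <- x$summary
  tibble(n_selected = x$n_selected, n_potential = x$n_potential,
         mean_pre = s$mean_spread[s$whisk == "pre"],
         mean_first = s$mean_spread[s$whisk == "first"],
         mean_second = s$mean_spread[s$whisk == "second"])
}
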