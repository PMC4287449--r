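#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a deconvolution fit
#' @param x A `dynachip_deconv` object.
#' @param ... Unused.
#' @return The peak tibble (center, amplitude).
#' @method tidy dynachip_deconv
#' @export
tidy.dynachip_deconv <- function(x, ...) {
  x$peaks
}

#' One-row summary of a deconvolution fit
#' @param x A `dynachip_deconv` object.
#' @param ... Unused.
#' @method glance dynachip_deconv
#' @export
glance.dynachip_deconv <- function(x, ...) {
  tibble::tibble(n_peaks = nrow(x$peaks),
                 rss = sum(x$residuals^2),
                 sigma = stats::sd(x$residuals),
                 n_probes = nrow(x$signal))
}

#' Tidy a position weight matrix
#' @param x A `dynachip_pwm` object.
#' @param ... Unused.
#' @return Long tibble position, base, prob, information.
#' @method tidy dynachip_pwm
#' @export
tidy.dynachip_pwm <- function(x, ...) {
  tibble::as_tibble(t(x$probs)) |>
    dplyr::mutate(position = dplyr::row_number(),
                  information = x$information) |>
    tidyr::pivot_longer(dplyr::all_of(DNA_BASES), names_to = "base",
                        values_to = "prob") |>
    dplyr::select("position", "base", "prob", "information")
}

#' One-row summary of a motif
#' @param x A `dynachip_pwm` object.
#' @param ... Unused.
#' @method glance dynachip_pwm
#' @export
glance.dynachip_pwm <- function(x, ...) {
  tibble::tibble(width = x$width, consensus = x$consensus,
                 information_bits = sum(x$information),
                 n_sites = x$n_sites,
                 palindromicity = palindromicity(x))
}

#' Tidy a growth fit
#' @param x A `dynachip_growth_fit` object.
#' @param ... Unused.
#' @method tidy dynachip_growth_fit
#' @export
tidy.dynachip_growth_fit <- function(x, ...) {
  tibble::tibble(term = "rate", estimate = x$rate)
}

#' One-row summary of a growth fit
#' @param x A `dynachip_growth_fit` object.
#' @param ... Unused.
#' @method glance dynachip_growth_fit
#' @export
glance.dynachip_growth_fit <- function(x, ...) {
  tibble::tibble(rate = x$rate, r2 = x$r2, n = x$n,
                 window_start = x$window[1], window_end = x$window[2],
                 flagged = x$flagged)
}
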