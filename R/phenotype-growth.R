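#' Fit an exponential growth rate from an OD600 curve
#'
#' The logarithmic growth phase is detected as the longest contiguous
#' window of at least `min_points` samples whose straight-line fit of
#' log2(OD) against time reaches R-squared `r2_threshold` with a positive
#' slope (ties broken by higher R-squared, then earlier start). Preferring
#' the longest qualifying window over the single best-R-squared window
#' keeps short, luckily-linear noise stretches from masquerading as the
#' log phase. The rate is the least-squares slope of that window, in
#' doublings per hour. If no window qualifies the rate is undefined.
#'
#' @param curve Tibble with columns time_h (strictly increasing) and od600
#'   (positive).
#' @param min_points Minimum window length (default 5 samples).
#' @param r2_threshold Minimum acceptable R-squared (default 0.95).
#' @param plateau_frac Samples after the OD first exceeds this fraction of
#'   the curve maximum are excluded before window search (stationary-phase
#'   guard; default 0.7).
#' @return A `dynachip_growth_fit`: list with rate (NA if flagged), r2,
#'   window (start/end times), n, flagged, curve.
#' @export
fit_growth_rate <- function(curve, min_points = 5, r2_threshold = 0.95,
                            plateau_frac = 0.7) {
  if (is.unsorted(curve$time_h, strictly = TRUE)) {
    stop_dynachip("time_h must be strictly increasing",
                  "dynachip_input_error")
  }
  if (any(curve$od600 <= 0)) {
    stop_dynachip("od600 must be positive", "dynachip_input_error")
  }
  # exclude the approach to stationary phase: the bend below the plateau
  # still passes a loose linearity check and biases the slope downward
  keep <- which(curve$od600 <= plateau_frac * max(curve$od600))
  if (length(keep) >= min_points) {
    curve_fit <- curve[seq_len(max(keep)), ]
  } else {
    curve_fit <- curve
  }
  t <- curve_fit$time_h
  y <- log2(curve_fit$od600)
  n <- length(t)
  if (n < min_points) {
    stop_dynachip(sprintf("need >= %d points", min_points),
                  "dynachip_input_error")
  }
  best <- list(r2 = -Inf, len = 0L, start = NA_integer_)
  for (len in min_points:n) {
    for (s in seq_len(n - len + 1)) {
      i <- s:(s + len - 1)
      tt <- t[i]; yy <- y[i]
      sst <- sum((yy - mean(yy))^2)
      if (sst < 1e-12) next  # flat segment: no growth to fit
      b <- stats::cov(tt, yy) / stats::var(tt)
      sse <- sst - b^2 * stats::var(tt) * (len - 1)
      r2 <- 1 - sse / sst
      if (b <= 0 || r2 < r2_threshold) next
      better <- len > best$len ||
        (len == best$len &&
           (r2 > best$r2 + 1e-9 ||
              (abs(r2 - best$r2) <= 1e-9 && s < best$start)))
      if (better) {
        best <- list(r2 = r2, len = len, start = s, slope = b)
      }
    }
  }
  flagged <- !is.finite(best$r2)
  structure(list(
    rate = if (flagged) NA_real_ else best$slope,
    r2 = if (is.finite(best$r2)) best$r2 else NA_real_,
    window = if (flagged) c(NA_real_, NA_real_) else
      c(t[best$start], t[best$start + best$len - 1]),
    n = if (flagged) 0L else best$len,
    flagged = flagged, curve = curve),
    class = "dynachip_growth_fit")
}

#' @export
print.dynachip_growth_fit <- function(x, ...) {
  if (x$flagged) {
    cat("<growth fit> no log phase detected\n")
  } else {
    cat(sprintf("<growth fit> rate %.3f doublings/h (R2 %.3f, window %g-%g h, %d pts)\n",
                x$rate, x$r2, x$window[1], x$window[2], x$n))
  }
  invisible(x)
}

#' Fit growth rates for every strain / condition / replicate
#'
#' @param curves Tibble: strain, h2o2_mM, replicate, time_h, od600.
#' @param ... Passed to [fit_growth_rate()].
#' @return Tibble: strain, h2o2_mM, replicate, rate, r2, window_start,
#'   window_end, flagged.
#' @export
fit_growth_rates <- function(curves, ...) {
  curves |>
    dplyr::group_by(.data$strain, .data$h2o2_mM, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_growth_rate(d, ...)
      tibble::tibble(rate = f$rate, r2 = f$r2,
                     window_start = f$window[1], window_end = f$window[2],
                     flagged = f$flagged)
    }) |>
    dplyr::ungroup()
}

#' Stress-to-baseline growth-rate ratio
#'
#' @param rate_stressed,rate_unstressed Rates in doublings/hour.
#' @return `rate_stressed / rate_unstressed`; NA (with a warning) if the
#'   unstressed rate is not positive or either rate is undefined.
#' @export
growth_ratio <- function(rate_stressed, rate_unstressed) {
  out <- rate_stressed / rate_unstressed
  bad <- is.na(rate_stressed) | is.na(rate_unstressed) | rate_unstressed <= 0
  if (any(bad)) {
    rlang::warn("undefined growth ratio (missing or non-positive baseline rate)")
    out[bad] <- NA_real_
  }
  out
}

#' Per-replicate stress ratios for every strain
#'
#' Pairs each stressed replicate with the same strain's matched unstressed
#' replicate (condition `baseline_mM`).
#'
#' @param rates Tibble from [fit_growth_rates()].
#' @param baseline_mM The no-stress condition (default 0).
#' @return Tibble: strain, h2o2_mM, replicate, ratio.
#' @export
growth_ratios <- function(rates, baseline_mM = 0) {
  base <- rates |>
    dplyr::filter(.data$h2o2_mM == baseline_mM) |>
    dplyr::select("strain", "replicate", base_rate = "rate")
  rates |>
    dplyr::filter(.data$h2o2_mM != baseline_mM) |>
    dplyr::inner_join(base, by = c("strain", "replicate")) |>
    dplyr::mutate(ratio = growth_ratio(.data$rate, .data$base_rate)) |>
    dplyr::select("strain", "h2o2_mM", "replicate", "ratio")
}

#' Compare stress-ratio distributions between two strains
#'
#' Two-sample Student's t-test on the replicate growth-ratio lists of a
#' mutant and the parent strain.
#'
#' @param ratios_mutant,ratios_parent Numeric vectors of replicate ratios.
#' @return Tibble n_mutant, n_parent, t, p, mean_mutant, mean_parent; NA
#'   statistics when a group has fewer than 2 usable replicates.
#' @export
compare_strain_ratios <- function(ratios_mutant, ratios_parent) {
  ratios_mutant <- ratios_mutant[!is.na(ratios_mutant)]
  ratios_parent <- ratios_parent[!is.na(ratios_parent)]
  if (length(ratios_mutant) < 2 || length(ratios_parent) < 2) {
    return(tibble::tibble(n_mutant = length(ratios_mutant),
                          n_parent = length(ratios_parent),
                          t = NA_real_, p = NA_real_,
                          mean_mutant = NA_real_, mean_parent = NA_real_))
  }
  if (stats::sd(c(ratios_mutant, ratios_parent)) == 0) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(ratios_mutant, ratios_parent, var.equal = TRUE)
  }
  tibble::tibble(n_mutant = length(ratios_mutant),
                 n_parent = length(ratios_parent),
                 t = unname(tt$statistic), p = tt$p.value,
                 mean_mutant = mean(ratios_mutant),
                 mean_parent = mean(ratios_parent))
}
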