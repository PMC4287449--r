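#' Within-array density-weighted loess normalization
#'
#' Removes the intensity-dependent trend from one array's log2 ratios.
#' A degree-1 loess of the log ratio against a predictor (the rank of the
#' per-probe total intensity when an `intensity` column is present,
#' otherwise genomic probe order) is fitted with observation weights
#' inversely proportional to a kernel-density estimate of the predictor,
#' and the fitted trend is subtracted.
#'
#' @param probes Tibble for a single array (one replicate, one time point)
#'   with columns `coord`, `value` and optionally `intensity`.
#' @param span Loess span in (0, 1].
#' @param density_bins Number of evaluation points of the density estimate.
#' @return The input tibble with `value` replaced by the detrended value.
#' @export
normalize_within_array <- function(probes, span = 0.3, density_bins = 512) {
  if (nrow(probes) < 50) {
    stop_dynachip("within-array normalization needs >= 50 probes",
                  "dynachip_input_error")
  }
  if (span <= 0 || span > 1) {
    stop_dynachip("`span` must lie in (0, 1]", "dynachip_parameter_error")
  }
  y <- probes$value
  if (stats::sd(y) == 0) {
    rlang::warn("all probe values identical; returning all-zero array")
    probes$value <- rep(0, length(y))
    return(probes)
  }
  x <- if ("intensity" %in% names(probes)) {
    rank(probes$intensity, ties.method = "average")
  } else {
    rank(probes$coord, ties.method = "first")
  }
  dens <- stats::density(x, n = density_bins)
  w <- 1 / pmax(stats::approx(dens$x, dens$y, xout = x, rule = 2)$y, 1e-12)
  w <- w / mean(w)
  fit <- stats::loess(y ~ x, weights = w, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  probes$value <- y - stats::predict(fit, newdata = data.frame(x = x))
  probes
}

#' Quantile normalization across arrays
#'
#' Forces every array's value distribution onto the mean of the per-array
#' order statistics (ties receive the mean of their target quantiles), so
#' that after normalization all arrays share an identical sorted value
#' vector while within-array ranks are preserved.
#'
#' @param arrays Long probe tibble with columns `replicon`, `coord`,
#'   `replicate`, `timepoint_min`, `value`; every (replicate, timepoint)
#'   array must cover the identical probe set.
#' @return The tibble with normalized `value`.
#' @export
normalize_across_arrays <- function(arrays) {
  key <- paste(arrays$replicate, arrays$timepoint_min, sep = "@")
  probe <- paste(arrays$replicon, arrays$coord)
  n_per <- table(key)
  if (length(unique(n_per)) != 1) {
    stop_dynachip("arrays do not share an identical probe set",
                  "dynachip_alignment_error")
  }
  wide <- tryCatch(
    matrix(arrays$value[order(key, probe)],
           nrow = n_per[[1]], dimnames = list(NULL, sort(unique(key)))),
    error = function(e) stop_dynachip("arrays do not share an identical probe set",
                                      "dynachip_alignment_error"))
  if (ncol(wide) < 2) {
    stop_dynachip("quantile normalization needs >= 2 arrays",
                  "dynachip_input_error")
  }
  probes_sorted <- sort(unique(probe))
  if (length(probes_sorted) != nrow(wide)) {
    stop_dynachip("arrays do not share an identical probe set",
                  "dynachip_alignment_error")
  }
  norm <- limma::normalizeQuantiles(wide, ties = TRUE)
  idx <- order(key, probe)
  arrays$value[idx] <- as.vector(norm)
  arrays
}

#' Normalize a replicate ChIP-chip array set
#'
#' The two-stage scheme applied array by array: dye-swapped arrays are
#' sign-flipped first, then each array is detrended with
#' [normalize_within_array()], then arrays are quantile-normalized
#' together with [normalize_across_arrays()]. By default the quantile
#' step runs across the replicate arrays of each time point separately:
#' occupancy genuinely differs between time points in a dynamic
#' experiment, and forcing one distribution onto all conditions
#' redistributes enrichment between time points. `quantile_scope =
#' "all"` pools every array instead.
#'
#' @param probes Long probe tibble (`replicon`, `coord`, `replicate`,
#'   `timepoint_min`, `log2ratio`, optional logical `dye_swap`, optional
#'   `intensity`).
#' @param span Loess span passed to [normalize_within_array()].
#' @param quantile_scope `"timepoint"` (default) or `"all"`.
#' @return Tibble with the normalized signal in column `value`.
#' @export
normalize_arrays <- function(probes, span = 0.3,
                             quantile_scope = c("timepoint", "all")) {
  quantile_scope <- match.arg(quantile_scope)
  probes <- dplyr::mutate(probes, value = .data$log2ratio)
  if ("dye_swap" %in% names(probes)) {
    probes <- dplyr::mutate(probes,
                            value = ifelse(.data$dye_swap, -.data$value,
                                           .data$value))
  }
  within <- probes |>
    dplyr::group_by(.data$replicate, .data$timepoint_min) |>
    dplyr::group_modify(~ normalize_within_array(.x, span = span)) |>
    dplyr::ungroup()
  if (quantile_scope == "all") {
    if (dplyr::n_distinct(within$replicate, within$timepoint_min) < 2) {
      return(within)
    }
    return(normalize_across_arrays(within))
  }
  within |>
    dplyr::group_by(.data$timepoint_min) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$replicate) < 2) return(d)
      d$timepoint_min <- key$timepoint_min[1]
      out <- normalize_across_arrays(d)
      out$timepoint_min <- NULL
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(names(within)))
}

#' Average probe replicates within each time point
#'
#' @param arrays Normalized long probe tibble with column `value`.
#' @param time_points Optional time points that must all be present.
#' @return Tibble: replicon, coord, timepoint_min, value (mean), n_replicates.
#' @export
average_replicates <- function(arrays, time_points = NULL) {
  if (!is.null(time_points)) {
    missing_tp <- setdiff(time_points, unique(arrays$timepoint_min))
    if (length(missing_tp)) {
      stop_dynachip(sprintf("missing time point(s): %s",
                            paste(missing_tp, collapse = ", ")),
                    "dynachip_input_error")
    }
  }
  arrays |>
    dplyr::group_by(.data$replicon, .data$coord, .data$timepoint_min) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     value = mean(.data$value), .groups = "drop") |>
    dplyr::select("replicon", "coord", "timepoint_min", "value",
                  "n_replicates")
}
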