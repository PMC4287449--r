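#' Peak-normalized enrichment kernel
#'
#' The parametric point-spread shape of a single binding event on the
#' tiling array. `kernel(0) = 1` for both families; `width` is the scale
#' (for the Gaussian family the standard deviation is `width / 2`; for the
#' triangular family `width` is the half-base) and `support` is the
#' truncation half-width beyond which the kernel is exactly zero.
#'
#' @param family `"gaussian"` or `"triangular"`.
#' @param width Scale parameter in bp.
#' @param support Truncation half-width in bp.
#' @return A `dynachip_kernel` object.
#' @export
peak_kernel <- function(family = c("gaussian", "triangular"), width = 150,
                        support = 3 * width) {
  family <- match.arg(family)
  if (width <= 0) {
    stop_dynachip("kernel `width` must be positive",
                  "dynachip_parameter_error")
  }
  structure(list(family = family, width = width, support = support),
            class = "dynachip_kernel")
}

#' Evaluate a kernel at signed distances
#' @param kernel A [peak_kernel()].
#' @param d Numeric vector of distances in bp.
#' @return Kernel values in \[0, 1\].
#' @export
kernel_eval <- function(kernel, d) {
  v <- switch(kernel$family,
    gaussian = exp(-0.5 * (d / (kernel$width / 2))^2),
    triangular = pmax(0, 1 - abs(d) / kernel$width)
  )
  v[abs(d) > kernel$support] <- 0
  v
}

# Cross-correlation of a residual vector with the kernel at every candidate
# position on a sub-probe grid.  The probe grid must be regular; candidates
# are probe positions shifted by 0 .. (phases-1) thirds of the spacing.
# Returns a list with, per phase: the correlation vector and the kernel
# energy (sum of squared kernel weights).
kernel_xcorr <- function(resid, spacing, kernel, phases) {
  m <- ceiling(kernel$support / spacing)
  lapply(seq_len(phases) - 1L, function(ph) {
    delta <- ph * spacing / phases
    w <- kernel_eval(kernel, (-m:m) * spacing - delta)
    # stats::filter convolves (kernel flipped); reverse for correlation
    cc <- stats::filter(resid, rev(w), sides = 2)
    list(cc = as.matrix(cc), energy = sum(w^2), delta = delta)
  })
}

#' Sparse nonnegative deconvolution of a probe signal
#'
#' Greedy forward selection of peak centers on a sub-probe grid: at each
#' step the candidate position giving the largest residual sum-of-squares
#' reduction (with a nonnegative amplitude) is added, all amplitudes are
#' refitted jointly by nonnegative least squares, and selection stops when
#' the best remaining single-peak amplitude falls below `min_amplitude` or
#' `max_peaks` is reached.
#'
#' @param signal Tibble with columns `coord` (regular grid) and `value`,
#'   one replicon / replicate / time point.
#' @param kernel A [peak_kernel()].
#' @param max_peaks Maximum number of peaks.
#' @param min_amplitude Stop threshold on the incremental peak amplitude
#'   (log2-ratio units).
#' @param grid_factor Candidate positions per probe spacing (default 3,
#'   i.e. a candidate grid at spacing/3).
#' @return A `dynachip_deconv` object: list with `peaks` (tibble center,
#'   amplitude), `fitted`, `residuals`, `signal`, `kernel`.
#' @export
fit_deconvolution <- function(signal, kernel, max_peaks = 30,
                              min_amplitude = 0.5, grid_factor = 3) {
  if (nrow(signal) == 0) {
    stop_dynachip("empty signal", "dynachip_input_error")
  }
  coords <- signal$coord
  y <- signal$value
  spacing <- unique(diff(coords))
  if (length(spacing) != 1) {
    spacing <- round(stats::median(diff(coords)))
    if (any(abs(diff(coords) - spacing) > 1e-6)) {
      stop_dynachip("probe grid must be regular", "dynachip_input_error")
    }
  }
  if (kernel$support < spacing) {
    stop_dynachip("kernel support is narrower than the probe spacing",
                  "dynachip_parameter_error")
  }

  centers <- numeric(0)
  resid <- y
  repeat {
    if (length(centers) >= max_peaks) break
    xc <- kernel_xcorr(resid, spacing, kernel, grid_factor)
    best <- list(amp = -Inf, score = -Inf)
    for (phase in xc) {
      amp <- pmax(phase$cc[, 1], 0) / phase$energy
      amp[is.na(amp)] <- 0
      score <- amp^2 * phase$energy  # RSS reduction of adding this peak
      i <- which.max(score)
      if (length(i) && score[i] > best$score) {
        best <- list(amp = amp[i], score = score[i],
                     center = coords[i] + phase$delta)
      }
    }
    if (!is.finite(best$amp) || best$amp < min_amplitude) break
    if (best$center %in% centers) break
    centers <- c(centers, best$center)
    A <- vapply(centers, function(ctr) kernel_eval(kernel, coords - ctr),
                numeric(length(coords)))
    fit <- pracma::lsqnonneg(A, y)
    resid <- y - as.vector(A %*% fit$x)
    amplitudes <- fit$x
  }

  if (length(centers) == 0) {
    peaks <- tibble::tibble(center = numeric(0), amplitude = numeric(0))
    fitted <- rep(0, length(y))
  } else {
    keep <- amplitudes > 0
    centers <- centers[keep]
    amplitudes <- amplitudes[keep]
    ord <- order(centers)
    peaks <- tibble::tibble(center = centers[ord],
                            amplitude = amplitudes[ord])
    fitted <- y - resid
  }
  structure(list(peaks = peaks, fitted = fitted, residuals = y - fitted,
                 signal = signal, kernel = kernel, spacing = spacing,
                 grid_factor = grid_factor),
            class = "dynachip_deconv")
}

#' Bootstrap significance of deconvolved peaks
#'
#' The null distribution is the maximum nonnegative single-peak amplitude
#' fitted on signals built by resampling the model residuals with
#' replacement onto the probe grid. Each peak's p-value is
#' `(1 + #(null >= amplitude)) / (1 + n_boot)`, so p is add-one bounded
#' away from zero and monotone decreasing in amplitude.
#'
#' @param fit A `dynachip_deconv` object.
#' @param n_boot Number of bootstrap resamples (>= 100 recommended).
#' @param seed Integer seed.
#' @return The peak tibble of `fit` with a `p_value` column; the null
#'   maxima are attached as attribute `"null_max"`.
#' @export
bootstrap_peak_pvalues <- function(fit, n_boot = 500, seed = 1L) {
  stopifnot(inherits(fit, "dynachip_deconv"))
  if (n_boot < 100) {
    rlang::warn("n_boot < 100 gives coarse p-values")
  }
  e <- fit$residuals
  n <- length(e)
  set.seed(as.integer(seed))
  if (stats::sd(e) == 0) {
    null_max <- rep(0, n_boot)
  } else {
    E <- matrix(sample(e, n * n_boot, replace = TRUE), n, n_boot)
    xc <- kernel_xcorr(E, fit$spacing, fit$kernel, fit$grid_factor)
    null_max <- rep(0, n_boot)
    for (phase in xc) {
      cc <- phase$cc
      cc[is.na(cc)] <- 0
      null_max <- pmax(null_max, apply(cc, 2, max) / phase$energy)
    }
    null_max <- pmax(null_max, 0)
  }
  peaks <- fit$peaks
  peaks$p_value <- vapply(peaks$amplitude, function(a) {
    (1 + sum(null_max >= a)) / (1 + n_boot)
  }, numeric(1))
  attr(peaks, "null_max") <- null_max
  peaks
}

#' Call binding peaks across a replicate time course
#'
#' Runs [fit_deconvolution()] and [bootstrap_peak_pvalues()] independently
#' for every (replicon, replicate, time point) array and concatenates the
#' calls. Deterministic: each array's bootstrap seed is derived from `seed`
#' and the array's position in the grouping order.
#'
#' @param arrays Normalized probe tibble (columns replicon, coord,
#'   replicate, timepoint_min, value).
#' @param kernel A [peak_kernel()].
#' @param max_peaks,min_amplitude,grid_factor Passed to
#'   [fit_deconvolution()].
#' @param n_boot Bootstrap resamples per array.
#' @param seed Base seed.
#' @return Tibble of peaks: replicon, center, amplitude, p_value,
#'   timepoint_min, replicate.
#' @export
call_peaks_timecourse <- function(arrays, kernel, max_peaks = 30,
                                  min_amplitude = 0.5, grid_factor = 3,
                                  n_boot = 500, seed = 1L) {
  groups <- arrays |>
    dplyr::distinct(.data$replicon, .data$replicate, .data$timepoint_min) |>
    dplyr::arrange(.data$replicon, .data$replicate, .data$timepoint_min)
  purrr::pmap(cbind(groups, .group = seq_len(nrow(groups))),
              function(replicon, replicate, timepoint_min, .group) {
    sig <- arrays[arrays$replicon == replicon &
                    arrays$replicate == replicate &
                    arrays$timepoint_min == timepoint_min, ] |>
      dplyr::arrange(.data$coord)
    fit <- fit_deconvolution(sig, kernel, max_peaks = max_peaks,
                             min_amplitude = min_amplitude,
                             grid_factor = grid_factor)
    peaks <- bootstrap_peak_pvalues(fit, n_boot = n_boot,
                                    seed = stage_seed(seed, 100L + .group))
    attr(peaks, "null_max") <- NULL
    dplyr::mutate(peaks, replicon = replicon, timepoint_min = timepoint_min,
                  replicate = replicate, .before = 1)
  }) |> purrr::list_rbind()
}
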