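#' Plot dynamic binding clusters
#'
#' Scaled per-gene occupancy trajectories, one facet per cluster, with the
#' cluster mean highlighted (the standard display for dynamic occupancy
#' clusters).
#'
#' @param profiles Long profile tibble (gene_id, timepoint_min, intensity).
#' @param clusters Tibble gene_id, cluster from [cluster_profiles()].
#' @return A ggplot object.
#' @export
plot_binding_clusters <- function(profiles, clusters) {
  scaled <- scale_profiles(profiles) |>
    dplyr::inner_join(clusters, by = "gene_id") |>
    dplyr::filter(!.data$constant)
  means <- scaled |>
    dplyr::group_by(.data$cluster, .data$timepoint_min) |>
    dplyr::summarise(scaled = mean(.data$scaled), .groups = "drop")
  ggplot2::ggplot(scaled, ggplot2::aes(.data$timepoint_min, .data$scaled)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$gene_id),
                       alpha = 0.25, colour = "grey40") +
    ggplot2::geom_line(data = means, linewidth = 1.2, colour = "black") +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time after H2O2 (min)",
                  y = "scaled occupancy") +
    ggplot2::theme_minimal()
}

#' Plot the windowed distance-activity association
#'
#' Negative log10 permutation p-value against the absolute-distance
#' cutoff, with the random-normal reference series dashed.
#'
#' @param assoc Tibble from [distance_activity_association()].
#' @return A ggplot object.
#' @export
plot_distance_activity <- function(assoc) {
  long <- assoc |>
    dplyr::select("cutoff", actual = "neg_log10_p",
                  reference = "neg_log10_p_ref") |>
    tidyr::pivot_longer(-"cutoff", names_to = "series",
                        values_to = "neg_log10_p")
  ggplot2::ggplot(long, ggplot2::aes(.data$cutoff, .data$neg_log10_p,
                                     linetype = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_linetype_manual(values = c(actual = "solid",
                                              reference = "dashed")) +
    ggplot2::labs(x = "|RosR - Tfb distance| cutoff (bp)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Plot growth curves on a log2 OD scale
#'
#' @param curves Tibble strain, h2o2_mM, replicate, time_h, od600.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$time_h, log2(.data$od600),
                               colour = factor(.data$h2o2_mM),
                               group = interaction(.data$h2o2_mM,
                                                   .data$replicate))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~strain) +
    ggplot2::labs(x = "time (h)", y = "log2 OD600",
                  colour = "H2O2 (mM)") +
    ggplot2::theme_minimal()
}

#' Autoplot a deconvolution fit
#'
#' Probe signal, model fit, and called peak centers.
#'
#' @param object A `dynachip_deconv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dynachip_deconv
#' @export
autoplot.dynachip_deconv <- function(object, ...) {
  d <- dplyr::mutate(object$signal, fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(.data$coord, .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::geom_vline(data = object$peaks,
                        ggplot2::aes(xintercept = .data$center),
                        linetype = "dotted") +
    ggplot2::labs(x = "coordinate (bp)", y = "log2 IP/mock") +
    ggplot2::theme_minimal()
}

#' Autoplot a motif as a simple information-scaled logo
#'
#' Letter heights are the per-base share of the column's information
#' content in bits.
#'
#' @param object A `dynachip_pwm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dynachip_pwm
#' @export
autoplot.dynachip_pwm <- function(object, ...) {
  d <- tidy.dynachip_pwm(object) |>
    dplyr::mutate(height = .data$prob * .data$information)
  ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$height,
                                  fill = .data$base)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.1) +
    ggplot2::labs(x = "position", y = "information (bits)",
                  subtitle = object$consensus) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
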