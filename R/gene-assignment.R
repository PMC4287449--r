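#' Assign binding peaks to nearby genes
#'
#' A peak is assigned to every non-redundant gene whose translation-start
#' coordinate lies within `max_dist` bp (inclusive, either side) of the
#' peak center, so one intergenic peak between divergently transcribed
#' genes maps to both.
#'
#' @param peaks Peak tibble (replicon, center, amplitude, p_value,
#'   timepoint_min, replicate).
#' @param annotation Gene tibble with gene_id, replicon, strand,
#'   translation_start.
#' @param max_dist Maximum peak-to-start distance in bp (default 250).
#' @param redundant_genes Character vector of gene ids to exclude.
#' @return Tibble: one row per (peak, gene) assignment, the peak columns
#'   plus gene_id and distance.
#' @export
assign_peaks_to_genes <- function(peaks, annotation, max_dist = 250,
                                  redundant_genes = character()) {
  if (nrow(annotation) == 0) {
    return(dplyr::mutate(peaks[0, ], gene_id = character(0),
                         distance = numeric(0)))
  }
  unknown <- setdiff(unique(peaks$replicon), unique(annotation$replicon))
  if (length(unknown)) {
    stop_dynachip(sprintf("peaks on unknown replicon(s): %s",
                          paste(unknown, collapse = ", ")),
                  "dynachip_input_error")
  }
  ann <- annotation |>
    dplyr::filter(!.data$gene_id %in% redundant_genes) |>
    dplyr::select("gene_id", "replicon", "translation_start")
  peaks |>
    dplyr::inner_join(ann, by = "replicon",
                      relationship = "many-to-many") |>
    dplyr::mutate(distance = abs(.data$center - .data$translation_start)) |>
    dplyr::filter(.data$distance <= max_dist) |>
    dplyr::select(-"translation_start")
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via `X = -2 * sum(log(p))`, referred to
#' the upper tail of a chi-square distribution with `2k` degrees of
#' freedom.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return The combined p-value.
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0) {
    stop_dynachip("no p-values to combine", "dynachip_input_error")
  }
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_dynachip("p-values must lie in [0, 1]", "dynachip_input_error")
  }
  if (any(p_values == 0)) {
    rlang::warn("p-value of 0 clamped to the smallest double")
    p_values <- pmax(p_values, .Machine$double.xmin)
  }
  x <- -2 * sum(log(p_values))
  stats::pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

# single-linkage grouping of 1-d positions: labels runs whose consecutive
# gaps are <= merge_dist
cluster_positions <- function(x, merge_dist) {
  ord <- order(x)
  lab <- cumsum(c(1, diff(x[ord]) > merge_dist))
  lab[order(ord)]
}

#' Build per-gene dynamic binding profiles
#'
#' Combines peak evidence into one occupancy vector per gene: peaks
#' assigned to a gene are grouped into loci (centers within
#' `locus_merge_dist` bp), evidence is combined across replicates within
#' each locus and time point (Fisher's method on p-values, mean amplitude),
#' then across loci of the same gene (Fisher again, amplitudes averaged).
#' Genes are retained only if the composite p-value is below `alpha` at one
#' or more time points; time points failing the threshold are set to zero
#' intensity. Retained genes propagate their profile to other members of
#' the same operon.
#'
#' @param peak_gene_map Output of [assign_peaks_to_genes()].
#' @param time_points The full ordered time grid in minutes.
#' @param alpha Per-time-point significance threshold (default 0.05).
#' @param operons Optional operon tibble (operon_id, gene_id).
#' @param annotation Optional annotation used to attach replicons to operon
#'   members.
#' @param locus_merge_dist Peaks closer than this are one locus (bp).
#' @return Long tibble: gene_id, replicon, source_gene_id, timepoint_min,
#'   intensity, p_value, n_peaks, locus_center.
#' @export
build_binding_profiles <- function(peak_gene_map, time_points, alpha = 0.05,
                                   operons = NULL, annotation = NULL,
                                   locus_merge_dist = 100) {
  if (nrow(peak_gene_map) == 0) {
    return(tibble::tibble(gene_id = character(0), replicon = character(0),
                          source_gene_id = character(0),
                          timepoint_min = numeric(0), intensity = numeric(0),
                          p_value = numeric(0), n_peaks = integer(0),
                          locus_center = numeric(0)))
  }
  bad_tp <- setdiff(unique(peak_gene_map$timepoint_min), time_points)
  if (length(bad_tp)) {
    stop_dynachip(sprintf("peaks at time point(s) %s not in the time grid",
                          paste(bad_tp, collapse = ", ")),
                  "dynachip_input_error")
  }

  per_locus <- peak_gene_map |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(locus = cluster_positions(.data$center,
                                            locus_merge_dist)) |>
    # stage 1: combine replicate evidence within a locus and time point
    dplyr::group_by(.data$gene_id, .data$replicon, .data$locus,
                    .data$timepoint_min) |>
    dplyr::summarise(p_value = fisher_combine(.data$p_value),
                     intensity = mean(.data$amplitude),
                     n_peaks = dplyr::n(),
                     locus_center = mean(.data$center), .groups = "drop")

  per_gene <- per_locus |>
    # stage 2: combine evidence across loci of the same gene
    dplyr::group_by(.data$gene_id, .data$replicon, .data$timepoint_min) |>
    dplyr::summarise(p_value = fisher_combine(.data$p_value),
                     intensity = mean(.data$intensity),
                     n_peaks = sum(.data$n_peaks),
                     locus_center = mean(.data$locus_center),
                     .groups = "drop")

  profiles <- per_gene |>
    tidyr::complete(tidyr::nesting(!!!rlang::syms(c("gene_id", "replicon"))),
                    timepoint_min = time_points,
                    fill = list(p_value = 1, intensity = 0, n_peaks = 0L,
                                locus_center = NA_real_)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(any(.data$p_value < alpha)) |>
    dplyr::ungroup() |>
    dplyr::mutate(intensity = ifelse(.data$p_value < alpha,
                                     .data$intensity, 0)) |>
    dplyr::mutate(source_gene_id = .data$gene_id, .after = "replicon")

  if (!is.null(operons) && nrow(profiles) > 0) {
    retained <- unique(profiles$gene_id)
    op_of <- operons[operons$gene_id %in% retained, ]
    extra <- operons |>
      dplyr::filter(.data$operon_id %in% op_of$operon_id,
                    !.data$gene_id %in% retained)
    if (nrow(extra) > 0) {
      # take each operon's best-evidence retained gene as the source
      source_by_op <- profiles |>
        dplyr::inner_join(op_of, by = "gene_id") |>
        dplyr::group_by(.data$operon_id, .data$gene_id) |>
        dplyr::summarise(best_p = min(.data$p_value), .groups = "drop") |>
        dplyr::group_by(.data$operon_id) |>
        dplyr::slice_min(.data$best_p, n = 1, with_ties = FALSE) |>
        dplyr::ungroup() |>
        dplyr::select("operon_id", source_gene_id = "gene_id")
      propagated <- extra |>
        dplyr::inner_join(source_by_op, by = "operon_id") |>
        dplyr::select("gene_id", "source_gene_id") |>
        dplyr::inner_join(
          profiles |> dplyr::select(-"gene_id") |>
            dplyr::rename(src = "source_gene_id"),
          by = c(source_gene_id = "src"),
          relationship = "many-to-many")
      profiles <- dplyr::bind_rows(profiles, propagated)
    }
  }
  dplyr::arrange(profiles, .data$gene_id, .data$timepoint_min)
}

#' Pivot long binding profiles to a gene x time matrix
#' @param profiles Long profile tibble from [build_binding_profiles()].
#' @param value Column to spread (default intensity).
#' @return Numeric matrix, rownames gene ids, one column per time point.
#' @export
profile_matrix <- function(profiles, value = "intensity") {
  wide <- profiles |>
    dplyr::select("gene_id", "timepoint_min", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "timepoint_min",
                       values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}
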