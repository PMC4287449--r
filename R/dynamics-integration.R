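#' Mean-and-variance scale binding profiles
#'
#' Scales each gene's occupancy vector to mean 0 and standard deviation 1
#' (the form used for display and archetype matching). Constant profiles
#' cannot be scaled: they come back all-zero and flagged.
#'
#' @param profiles Long profile tibble (gene_id, timepoint_min, intensity).
#' @return Long tibble gene_id, timepoint_min, scaled, constant.
#' @export
scale_profiles <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(
      constant = stats::sd(.data$intensity) == 0,
      scaled = if (stats::sd(.data$intensity) == 0) {
        rep(0, dplyr::n())
      } else {
        as.vector(scale(.data$intensity))
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "timepoint_min", "scaled", "constant")
}

#' Spearman rank correlation (GE-ChIP statistic)
#'
#' Rank correlation with average ranks for ties. A constant vector has no
#' rank ordering, so the statistic is undefined and `NA` is returned
#' (callers flag such genes as unclassifiable rather than forcing 0).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Cs in \[-1, 1\], or NA if either vector is constant.
#' @export
spearman_cs <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_dynachip("spearman_cs needs two equal-length vectors of length >= 3",
                  "dynachip_input_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

# scaled archetype templates on an arbitrary time grid
archetype_templates <- function(n_time) {
  t(vapply(1:4, function(a) {
    s <- archetype_shape(a, n_time)
    as.vector(scale(s))
  }, numeric(n_time)))
}

#' Cluster dynamic binding profiles
#'
#' Agglomerative complete-linkage clustering with dissimilarity
#' `1 - Spearman(profile_i, profile_j)`, cut to exactly `k` clusters.
#' Cluster numbers are then matched to the four dynamic archetypes (lost;
#' lost-then-restored; gained; variable) by assigning cluster mean profiles
#' to archetype templates so that total distance is minimized.
#'
#' @param profiles Long profile tibble (gene_id, timepoint_min, intensity).
#'   Constant profiles are excluded (unrankable) with a message.
#' @param k Number of clusters (default 4).
#' @return Tibble gene_id, cluster (archetype-matched), raw_cluster (tree
#'   order).
#' @export
cluster_profiles <- function(profiles, k = 4) {
  m <- profile_matrix(profiles)
  keep <- apply(m, 1, stats::sd) > 0
  if (any(!keep)) {
    rlang::inform(sprintf("%d constant profile(s) excluded from clustering",
                          sum(!keep)))
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < k) {
    stop_dynachip(sprintf("need at least k = %d non-constant profiles", k),
                  "dynachip_input_error")
  }
  cs <- stats::cor(t(m), method = "spearman")
  d <- stats::as.dist(1 - cs)
  hc <- stats::hclust(d, method = "complete")
  raw <- stats::cutree(hc, k = k)

  # match cluster numbers to archetypes: enumerate assignments, minimize
  # total Euclidean distance between scaled cluster means and templates
  templates <- archetype_templates(ncol(m))
  means <- t(vapply(seq_len(k), function(cl) {
    colMeans(m[raw == cl, , drop = FALSE])
  }, numeric(ncol(m))))
  means_scaled <- t(apply(means, 1, function(v) {
    if (stats::sd(v) == 0) rep(0, length(v)) else as.vector(scale(v))
  }))
  if (k == nrow(templates)) {
    perms <- permutations_of(k)
    cost <- vapply(seq_len(nrow(perms)), function(i) {
      sum(vapply(seq_len(k), function(cl) {
        sum((means_scaled[cl, ] - templates[perms[i, cl], ])^2)
      }, numeric(1)))
    }, numeric(1))
    mapping <- perms[which.min(cost), ]
  } else {
    mapping <- seq_len(k)
  }
  tibble::tibble(gene_id = rownames(m), raw_cluster = unname(raw),
                 cluster = unname(mapping[raw]))
}

# all permutations of 1..n (n small)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' GE-ChIP correlation of binding and expression profiles
#'
#' For each gene with both a binding profile and expression data,
#' expression replicates are averaged per time point and the Spearman
#' correlation between the occupancy vector and the expression vector over
#' the shared time grid is computed.
#'
#' @param profiles Long binding-profile tibble (gene_id, timepoint_min,
#'   intensity).
#' @param expression Long expression tibble (gene_id, timepoint_min,
#'   replicate, expression).
#' @return Tibble gene_id, cs (NA for constant profiles), n_time.
#' @export
ge_chip_correlate <- function(profiles, expression) {
  expr_mean <- expression |>
    dplyr::group_by(.data$gene_id, .data$timepoint_min) |>
    dplyr::summarise(expression = mean(.data$expression), .groups = "drop")
  joined <- profiles |>
    dplyr::select("gene_id", "timepoint_min", "intensity") |>
    dplyr::distinct() |>
    dplyr::inner_join(expr_mean, by = c("gene_id", "timepoint_min"))
  missing <- setdiff(unique(profiles$gene_id), unique(joined$gene_id))
  out <- joined |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      cs = spearman_cs(.data$intensity, .data$expression),
      n_time = dplyr::n(), .groups = "drop")
  attr(out, "missing_expression") <- missing
  out
}

#' Call activation / repression from GE-ChIP correlations
#'
#' @param cs_parent Tibble gene_id, cs for the parent genotype.
#' @param cs_knockout Optional tibble gene_id, cs for the knockout.
#' @param thresholds Length-2 numeric `c(activated, repressed)`; a gene is
#'   activated if parent Cs >= the first (inclusive), repressed if <= the
#'   second (inclusive), otherwise unclassified.
#' @param clusters Optional tibble gene_id, cluster to carry along.
#' @return Tibble gene_id, cs_parent, cs_knockout, label, cluster.
#' @export
call_regulation <- function(cs_parent, cs_knockout = NULL,
                            thresholds = c(0.6, -0.6), clusters = NULL) {
  out <- cs_parent |>
    dplyr::rename(cs_parent = "cs") |>
    dplyr::select("gene_id", "cs_parent")
  if (!is.null(cs_knockout)) {
    out <- dplyr::left_join(out,
                            dplyr::select(dplyr::rename(cs_knockout,
                                                        cs_knockout = "cs"),
                                          "gene_id", "cs_knockout"),
                            by = "gene_id")
  } else {
    out$cs_knockout <- NA_real_
  }
  out <- out |>
    dplyr::mutate(label = dplyr::case_when(
      is.na(.data$cs_parent) ~ "unclassified",
      .data$cs_parent >= thresholds[1] ~ "activated",
      .data$cs_parent <= thresholds[2] ~ "repressed",
      TRUE ~ "unclassified"
    ))
  if (!is.null(clusters)) {
    out <- dplyr::left_join(out,
                            dplyr::select(clusters, "gene_id", "cluster"),
                            by = "gene_id")
  }
  out
}

#' Test the genotype shift of GE-ChIP correlations
#'
#' Student's t-test comparing parent-strain Cs values with knockout-strain
#' Cs values for the genes of one regulation class (correlated/activated
#' or anticorrelated/repressed). Unpaired equal-variance by default; a
#' paired test is available since the gene sets are matched.
#'
#' @param calls Output of [call_regulation()] (needs cs_parent,
#'   cs_knockout, label).
#' @param side `"correlated"` (activated genes) or `"anticorrelated"`
#'   (repressed genes).
#' @param paired Use a paired t-test.
#' @return Tibble side, n, t, p, mean_parent, mean_knockout; a side with
#'   fewer than 2 complete gene pairs is reported with NA statistics.
#' @export
compare_genotype_correlations <- function(calls,
                                          side = c("correlated",
                                                   "anticorrelated"),
                                          paired = FALSE) {
  side <- match.arg(side)
  lab <- if (side == "correlated") "activated" else "repressed"
  sub <- calls |>
    dplyr::filter(.data$label == lab, !is.na(.data$cs_parent),
                  !is.na(.data$cs_knockout))
  if (nrow(sub) < 2) {
    return(tibble::tibble(side = side, n = nrow(sub), t = NA_real_,
                          p = NA_real_, mean_parent = NA_real_,
                          mean_knockout = NA_real_))
  }
  if (stats::sd(c(sub$cs_parent, sub$cs_knockout)) == 0) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(sub$cs_parent, sub$cs_knockout, paired = paired,
                        var.equal = !paired)
  }
  tibble::tibble(side = side, n = nrow(sub),
                 t = unname(tt$statistic), p = tt$p.value,
                 mean_parent = mean(sub$cs_parent),
                 mean_knockout = mean(sub$cs_knockout))
}
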