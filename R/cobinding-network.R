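#' Signed distance between a sequence-specific and a general-factor site
#'
#' Negative means the sequence-specific (RosR) site lies upstream of the
#' Tfb site with respect to the gene's orientation: on the + strand
#' `rosr - tfb`, on the - strand `tfb - rosr`.
#'
#' @param rosr_center,tfb_center Site centers in bp (vectorized).
#' @param gene_strand `"+"` or `"-"` (vectorized).
#' @return Signed distance in bp.
#' @export
signed_distance <- function(rosr_center, tfb_center, gene_strand) {
  if (!all(gene_strand %in% c("+", "-"))) {
    stop_dynachip("strand must be '+' or '-'", "dynachip_input_error")
  }
  ifelse(gene_strand == "+", rosr_center - tfb_center,
         tfb_center - rosr_center)
}

#' Detect co-binding of a sequence-specific factor with Tfb paralogs
#'
#' Returns every (RosR site, Tfb site, gene) triple such that both sites
#' lie within `max_gene_dist` bp of the gene's translation start and the
#' two sites lie within `max_pair_dist` bp of each other.
#'
#' @param rosr_sites Tibble: replicon, center (one row per RosR locus).
#' @param tfb_sites Tibble: tfb_name, replicon, center.
#' @param annotation Gene tibble (gene_id, replicon, strand,
#'   translation_start).
#' @param max_gene_dist,max_pair_dist Distance criteria in bp (default 250).
#' @return Pair tibble: gene_id, strand, rosr_center, tfb_name, tfb_center,
#'   signed_distance.
#' @export
detect_cobinding <- function(rosr_sites, tfb_sites, annotation,
                             max_gene_dist = 250, max_pair_dist = 250) {
  ann <- dplyr::select(annotation, "gene_id", "replicon", "strand",
                       "translation_start")
  near_genes <- function(sites) {
    sites |>
      dplyr::inner_join(ann, by = "replicon",
                        relationship = "many-to-many") |>
      dplyr::filter(abs(.data$center - .data$translation_start) <=
                      max_gene_dist)
  }
  rosr <- near_genes(dplyr::select(rosr_sites, "replicon", "center")) |>
    dplyr::rename(rosr_center = "center")
  tfb <- near_genes(dplyr::select(tfb_sites, "tfb_name", "replicon",
                                  "center")) |>
    dplyr::rename(tfb_center = "center") |>
    dplyr::select("gene_id", "tfb_name", "tfb_center")
  rosr |>
    dplyr::inner_join(tfb, by = "gene_id", relationship = "many-to-many") |>
    dplyr::filter(abs(.data$rosr_center - .data$tfb_center) <=
                    max_pair_dist) |>
    dplyr::mutate(signed_distance = signed_distance(.data$rosr_center,
                                                    .data$tfb_center,
                                                    .data$strand)) |>
    dplyr::select("gene_id", "replicon", "strand", "rosr_center",
                  "tfb_name", "tfb_center", "signed_distance")
}

#' Tfb combination sets and combination-size histogram
#'
#' @param pairs Pair tibble from [detect_cobinding()].
#' @return List with `combinations` (gene_id, tfb_set, n_tfb; one row per
#'   co-bound gene, each Tfb name counted once) and `histogram`
#'   (n_tfb, n_genes).
#' @export
cobinding_combinations <- function(pairs) {
  combos <- pairs |>
    dplyr::distinct(.data$gene_id, .data$tfb_name) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      tfb_set = paste(sort(.data$tfb_name), collapse = "+"),
      n_tfb = dplyr::n_distinct(.data$tfb_name), .groups = "drop")
  hist <- combos |>
    dplyr::count(.data$n_tfb, name = "n_genes")
  list(combinations = combos, histogram = hist)
}

#' Sliding-window distance-activity association with a resampling null
#'
#' For each absolute-distance cutoff on a `step`-bp grid, selects the pairs
#' whose |signed distance| falls within the `window_width`-bp window ending
#' at that cutoff and computes the Spearman correlation between signed
#' distance and regulatory activity (the gene's GE-ChIP Cs). Significance
#' is an empirical permutation p-value: activities are permuted among the
#' selected pairs `n_resample` times and
#' `p = (1 + #(|Cs_perm| >= |Cs|)) / (1 + n_resample)`. A reference series
#' replaces the actual activities with draws from a normal distribution
#' with the same mean, standard deviation and count.
#'
#' @param pairs Pair tibble with columns signed_distance and activity.
#' @param window_width Window width in bp (default 50).
#' @param step Cutoff grid step in bp (default 5).
#' @param max_cutoff Largest cutoff in bp (default 250).
#' @param n_resample Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return Tibble: cutoff, n_pairs, cs, p, neg_log10_p, cs_ref, p_ref,
#'   neg_log10_p_ref, null_mean, null_sd. Windows with fewer than 3 pairs
#'   or degenerate activities have NA statistics.
#' @export
distance_activity_association <- function(pairs, window_width = 50, step = 5,
                                          max_cutoff = 250,
                                          n_resample = 10000, seed = 1L) {
  if (nrow(pairs) < 3) {
    stop_dynachip("need at least 3 pairs", "dynachip_input_error")
  }
  set.seed(as.integer(seed))
  cutoffs <- seq(step, max_cutoff, by = step)
  purrr::map(cutoffs, function(cutoff) {
    lo <- cutoff - window_width
    sel <- pairs[abs(pairs$signed_distance) <= cutoff &
                   abs(pairs$signed_distance) > lo, ]
    base <- tibble::tibble(cutoff = cutoff, n_pairs = nrow(sel),
                           cs = NA_real_, p = NA_real_,
                           neg_log10_p = NA_real_, cs_ref = NA_real_,
                           p_ref = NA_real_, neg_log10_p_ref = NA_real_,
                           null_mean = NA_real_, null_sd = NA_real_)
    n <- nrow(sel)
    if (n < 3 || stats::sd(sel$activity) == 0 ||
        stats::sd(sel$signed_distance) == 0) {
      return(base)
    }
    rd <- rank(sel$signed_distance)
    ra <- rank(sel$activity)
    cs <- stats::cor(rd, ra)
    perm <- vapply(seq_len(n_resample), function(i) sample(ra),
                   numeric(n))
    cs_perm <- as.vector(stats::cor(rd, perm))
    p <- (1 + sum(abs(cs_perm) >= abs(cs) - 1e-12)) / (1 + n_resample)
    # reference: synthetic activities ~ N(mean, sd) of the actual ones
    a_ref <- stats::rnorm(n, mean(sel$activity), stats::sd(sel$activity))
    cs_ref <- stats::cor(rd, rank(a_ref))
    perm_ref <- as.vector(stats::cor(rd, apply(perm, 2, sample)))
    p_ref <- (1 + sum(abs(perm_ref) >= abs(cs_ref) - 1e-12)) /
      (1 + n_resample)
    base |>
      dplyr::mutate(cs = .env$cs, p = .env$p,
                    neg_log10_p = -log10(.env$p),
                    cs_ref = .env$cs_ref, p_ref = .env$p_ref,
                    neg_log10_p_ref = -log10(.env$p_ref),
                    null_mean = mean(cs_perm), null_sd = stats::sd(cs_perm))
  }) |> purrr::list_rbind()
}

#' Global distance-activity association
#'
#' Spearman correlation between signed distance and activity over all
#' pairs, with the same permutation p-value as the windowed analysis.
#'
#' @inheritParams distance_activity_association
#' @return Tibble n_pairs, cs, p.
#' @export
distance_activity_global <- function(pairs, n_resample = 10000, seed = 1L) {
  if (nrow(pairs) < 3) {
    stop_dynachip("need at least 3 pairs", "dynachip_input_error")
  }
  set.seed(as.integer(seed))
  rd <- rank(pairs$signed_distance)
  ra <- rank(pairs$activity)
  cs <- stats::cor(rd, ra)
  perm <- vapply(seq_len(n_resample), function(i) sample(ra),
                 numeric(length(ra)))
  cs_perm <- as.vector(stats::cor(rd, perm))
  p <- (1 + sum(abs(cs_perm) >= abs(cs) - 1e-12)) / (1 + n_resample)
  tibble::tibble(n_pairs = nrow(pairs), cs = cs, p = p)
}

#' Upper-tail hypergeometric test
#'
#' `P(X >= overlap)` for `X ~ Hypergeometric(universe, set_a, set_b)`: the
#' probability of seeing at least the observed overlap when `set_b` items
#' are drawn from a universe containing `set_a` marked items.
#'
#' @param overlap Observed overlap count.
#' @param set_a,set_b Sizes of the two sets.
#' @param universe Universe size.
#' @return The p-value.
#' @export
hypergeom_test <- function(overlap, set_a, set_b, universe) {
  if (overlap > min(set_a, set_b) || max(set_a, set_b) > universe ||
      any(c(overlap, set_a, set_b, universe) < 0)) {
    stop_dynachip("inconsistent hypergeometric counts",
                  "dynachip_input_error")
  }
  stats::phyper(overlap - 1, set_a, universe - set_a, set_b,
                lower.tail = FALSE)
}

#' Functional-category enrichment of a gene set
#'
#' Hypergeometric overrepresentation of each category among `gene_set`
#' against the genome-wide background. Genes absent from the category table
#' are pooled into an "Unknown function" bucket.
#'
#' @param gene_set Character vector of gene ids.
#' @param category_table Tibble gene_id, category.
#' @param universe Character vector of all annotated gene ids.
#' @param adjust Add a Benjamini-Hochberg adjusted column.
#' @return Tibble: category, count, size, expect, p (unadjusted) and
#'   optionally p_adj.
#' @export
category_enrichment <- function(gene_set, category_table, universe,
                                adjust = TRUE) {
  cat_tbl <- tibble::tibble(gene_id = universe) |>
    dplyr::left_join(category_table, by = "gene_id") |>
    dplyr::mutate(category = dplyr::coalesce(.data$category,
                                             "Unknown function"))
  gene_set <- intersect(gene_set, universe)
  n_set <- length(gene_set)
  n_uni <- length(universe)
  out <- cat_tbl |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(size = dplyr::n(),
                     count = sum(.data$gene_id %in% gene_set),
                     .groups = "drop") |>
    dplyr::mutate(
      expect = n_set * .data$size / n_uni,
      p = purrr::map2_dbl(.data$count, .data$size,
                          ~ hypergeom_test(.x, .y, n_set, n_uni))
    ) |>
    dplyr::arrange(.data$p)
  if (adjust) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
  }
  out
}

#' Overlap of an observed regulon with a predicted network
#'
#' @param observed,predicted Character vectors of target gene ids.
#' @param universe Character vector of all genes.
#' @return Tibble: n_observed, n_predicted, overlap, fraction (of observed
#'   targets that were predicted), p (hypergeometric upper tail). An empty
#'   observed set yields NA fraction.
#' @export
network_overlap <- function(observed, predicted, universe) {
  observed <- unique(intersect(observed, universe))
  predicted <- unique(intersect(predicted, universe))
  ov <- length(intersect(observed, predicted))
  frac <- if (length(observed) == 0) NA_real_ else ov / length(observed)
  p <- if (length(observed) == 0 || length(predicted) == 0) {
    NA_real_
  } else {
    hypergeom_test(ov, length(observed), length(predicted),
                   length(universe))
  }
  tibble::tibble(n_observed = length(observed),
                 n_predicted = length(predicted), overlap = ov,
                 fraction = frac, p = p)
}
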