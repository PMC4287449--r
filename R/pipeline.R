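default_pipeline_params <- function() {
  list(alpha = 0.05, cs_thresholds = c(0.6, -0.6), flank = 250,
       max_dist = 250, k = 4, window_width = 50, step = 5,
       n_resample = 10000, n_boot = 300, min_amplitude = 0.5,
       motif_width = 20, n_motifs = 1, locus_merge_dist = 100,
       match_dist = 100)
}

#' Run the full dynamic-binding analysis pipeline
#'
#' Executes the stages in order: simulate (synthetic mode) or load (real
#' mode) inputs, normalize probe signals, call peaks per replicate and
#' time point, map peaks to genes and build occupancy profiles, cluster
#' dynamics and integrate with expression, discover the cis-regulatory
#' motif, analyse co-binding geometry, test functional enrichment and
#' network overlap, and score growth phenotypes. In synthetic mode a
#' truth-recovery report is appended. All randomness derives from
#' `config$seed`, so a rerun with the same configuration reproduces every
#' output.
#'
#' @param config A [synthetic_config()].
#' @param mode `"synthetic"` (generate inputs with planted truth) or
#'   `"real"` (supply `inputs`).
#' @param params Named list overriding the stage defaults (alpha,
#'   cs_thresholds, flank, max_dist, k, window_width, step, n_resample,
#'   n_boot, min_amplitude, motif_width, n_motifs, locus_merge_dist,
#'   match_dist).
#' @param inputs Real mode only: named list of tibbles (probes,
#'   annotation, sequence, operons, expression_parent,
#'   expression_knockout, tfb_sites, categories, predicted_targets,
#'   growth). Missing optional elements skip the dependent stages with a
#'   message.
#' @param out_dir Optional directory; when given, every stage table is
#'   written as TSV (plus FASTA/GFF3 and a JSON manifest).
#' @param quiet Suppress stage messages.
#' @return A `dynachip_run` list of stage outputs.
#' @export
run_pipeline <- function(config, mode = c("synthetic", "real"),
                         params = list(), inputs = list(), out_dir = NULL,
                         quiet = FALSE) {
  mode <- match.arg(mode)
  p <- utils::modifyList(default_pipeline_params(), params)
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))
  t_start <- Sys.time()

  if (mode == "synthetic") {
    say("stage simulate: generating genome, truth and raw data")
    genome <- generate_genome(config)
    truth <- plant_dynamics(config, genome)
    planted <- plant_motifs(truth, genome$sequence, config)
    truth <- planted$truth
    genome$sequence <- planted$sequence
    tfb_sites <- plant_tfb_sites(truth, config)
    probes <- simulate_chip_signal(truth, config)
    expression_parent <- simulate_expression(truth, config, "parent")
    expression_knockout <- simulate_expression(truth, config, "knockout")
    growth <- simulate_growth(config)
    categories <- dplyr::select(genome$annotation, "gene_id", "category")
    predicted_targets <- synthetic_predicted_network(truth,
                                                     genome$annotation,
                                                     seed = config$seed)
  } else {
    genome <- list(annotation = inputs$annotation,
                   sequence = inputs$sequence, operons = inputs$operons)
    truth <- NULL
    tfb_sites <- inputs$tfb_sites
    probes <- inputs$probes
    expression_parent <- inputs$expression_parent
    expression_knockout <- inputs$expression_knockout
    growth <- inputs$growth
    categories <- inputs$categories
    predicted_targets <- inputs$predicted_targets
    if (is.null(probes) || is.null(genome$annotation)) {
      stop_dynachip("real mode needs at least `probes` and `annotation`",
                    "dynachip_stage_error")
    }
  }
  kernel <- peak_kernel("gaussian", width = config$kernel_width)
  time_points <- sort(unique(probes$timepoint_min))

  say("stage normalize: %d probe measurements", nrow(probes))
  normalized <- normalize_arrays(probes)

  say("stage callpeaks: deconvolution per replicate and time point")
  peaks <- call_peaks_timecourse(normalized, kernel,
                                 min_amplitude = p$min_amplitude,
                                 n_boot = p$n_boot,
                                 seed = stage_seed(config$seed, 301L))
  say("stage callpeaks: %d raw peaks", nrow(peaks))

  say("stage genemap: assigning peaks and building profiles")
  peak_gene_map <- assign_peaks_to_genes(peaks, genome$annotation,
                                         max_dist = p$max_dist)
  profiles <- build_binding_profiles(peak_gene_map, time_points,
                                     alpha = p$alpha,
                                     operons = genome$operons,
                                     locus_merge_dist = p$locus_merge_dist)
  say("stage genemap: %d genes retained",
      dplyr::n_distinct(profiles$gene_id))

  clusters <- NULL; calls <- NULL; genotype_tests <- NULL
  cs_parent <- NULL; cs_knockout <- NULL
  if (dplyr::n_distinct(profiles$gene_id) >= p$k) {
    say("stage integrate: clustering dynamics")
    clusters <- cluster_profiles(profiles, k = p$k)
    if (!is.null(expression_parent)) {
      cs_parent <- ge_chip_correlate(profiles, expression_parent)
      cs_knockout <- if (!is.null(expression_knockout)) {
        ge_chip_correlate(profiles, expression_knockout)
      }
      calls <- call_regulation(cs_parent, cs_knockout,
                               thresholds = p$cs_thresholds,
                               clusters = clusters)
      if (!is.null(cs_knockout)) {
        genotype_tests <- dplyr::bind_rows(
          compare_genotype_correlations(calls, "correlated"),
          compare_genotype_correlations(calls, "anticorrelated"))
      }
    } else {
      say("stage integrate: no expression matrix; binding-only outputs")
    }
  } else {
    say("stage integrate: too few profiles; skipped")
  }

  loci <- profiles |>
    dplyr::filter(!is.na(.data$locus_center)) |>
    dplyr::distinct(.data$replicon, center = .data$locus_center) |>
    dplyr::group_by(.data$replicon) |>
    dplyr::mutate(locus = cluster_positions(.data$center,
                                            p$locus_merge_dist)) |>
    dplyr::group_by(.data$replicon, .data$locus) |>
    dplyr::summarise(center = round(mean(.data$center)),
                     .groups = "drop") |>
    dplyr::select("replicon", "center")
  motifs <- NULL; motif_sig <- NULL; occurrences <- NULL; windows <- NULL
  if (!is.null(genome$sequence) && nrow(loci) >= 5) {
    say("stage motif: %d loci searched", nrow(loci))
    windows <- extract_search_windows(loci, genome$sequence,
                                      flank = p$flank)
    motifs <- discover_motif(windows, width = p$motif_width,
                             n_motifs = p$n_motifs)
    if (length(motifs)) {
      motif_sig <- motif_significance(motifs[[1]], windows,
                                      seed = stage_seed(config$seed, 401L))
      threshold <- 0.6 * max_pwm_score(motifs[[1]])
      occurrences <- scan_genome(motifs[[1]], genome$sequence,
                                 genome$annotation,
                                 score_threshold = threshold)
    }
  } else {
    say("stage motif: skipped (no sequence or too few loci)")
  }

  pairs <- NULL; assoc <- NULL; assoc_global <- NULL
  combinations <- NULL
  if (!is.null(tfb_sites) && nrow(loci) > 0 && !is.null(calls)) {
    say("stage cobind: %d Tfb sites", nrow(tfb_sites))
    pairs <- detect_cobinding(loci, tfb_sites, genome$annotation,
                              max_gene_dist = p$max_dist,
                              max_pair_dist = p$max_dist) |>
      dplyr::inner_join(dplyr::select(calls, "gene_id",
                                      activity = "cs_parent"),
                        by = "gene_id") |>
      dplyr::filter(!is.na(.data$activity))
    if (nrow(pairs) >= 3) {
      combinations <- cobinding_combinations(pairs)
      assoc <- distance_activity_association(
        pairs, window_width = p$window_width, step = p$step,
        n_resample = p$n_resample, seed = stage_seed(config$seed, 501L))
      assoc_global <- distance_activity_global(
        pairs, n_resample = p$n_resample,
        seed = stage_seed(config$seed, 503L))
    }
  } else {
    say("stage cobind: skipped (missing Tfb sites or regulation calls)")
  }

  enrichment <- NULL; overlap <- NULL
  if (!is.null(categories) && nrow(profiles) > 0) {
    say("stage enrich: arCOG-style categories")
    bound_genes <- unique(profiles$gene_id)
    enrichment <- category_enrichment(bound_genes, categories,
                                      genome$annotation$gene_id)
    if (!is.null(predicted_targets)) {
      overlap <- network_overlap(bound_genes, predicted_targets,
                                 genome$annotation$gene_id)
    }
  }

  growth_rates <- NULL; growth_ratio_tbl <- NULL; growth_tests <- NULL
  if (!is.null(growth)) {
    say("stage growth: fitting rates")
    growth_rates <- fit_growth_rates(growth)
    growth_ratio_tbl <- growth_ratios(growth_rates)
    strains <- unique(growth_ratio_tbl$strain)
    if (all(c("parent", "mutant") %in% strains)) {
      growth_tests <- growth_ratio_tbl |>
        dplyr::filter(.data$strain %in% c("parent", "mutant")) |>
        dplyr::group_by(.data$h2o2_mM) |>
        dplyr::group_modify(function(d, key) {
          compare_strain_ratios(d$ratio[d$strain == "mutant"],
                                d$ratio[d$strain == "parent"])
        }) |>
        dplyr::ungroup()
    }
  }

  results <- structure(list(
    config = config, params = p, mode = mode, truth = truth,
    genome = genome, tfb_sites = tfb_sites, probes = probes,
    normalized = normalized, peaks = peaks,
    peak_gene_map = peak_gene_map, profiles = profiles,
    clusters = clusters, cs_parent = cs_parent,
    cs_knockout = cs_knockout, calls = calls,
    genotype_tests = genotype_tests, windows = windows, motifs = motifs,
    motif_sig = motif_sig, occurrences = occurrences, pairs = pairs,
    combinations = combinations, assoc = assoc,
    assoc_global = assoc_global, enrichment = enrichment,
    overlap = overlap, growth = growth, growth_rates = growth_rates,
    growth_ratios = growth_ratio_tbl, growth_tests = growth_tests),
    class = "dynachip_run")

  if (mode == "synthetic") {
    results$report <- truth_report(results, truth)
  }
  results$manifest <- run_manifest(results)
  say("pipeline complete in %.1f s",
      as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  if (!is.null(out_dir)) {
    write_run(results, out_dir)
  }
  results
}

max_pwm_score <- function(pwm) {
  sum(log2(apply(pwm$probs, 2, max) /
             pwm$background[apply(pwm$probs, 2, which.max)]))
}

#' Synthetic predicted-network target set
#'
#' Emulates an externally inferred regulatory network prediction: a subset
#' of the true targets (default 30 percent) diluted with random
#' non-target genes, used to exercise the network-overlap test.
#'
#' @param truth Truth tibble.
#' @param annotation Annotation tibble.
#' @param recall_fraction Fraction of true targets included.
#' @param n_noise Number of random non-target genes added.
#' @param seed Integer seed.
#' @return Character vector of predicted target gene ids.
#' @export
synthetic_predicted_network <- function(truth, annotation,
                                        recall_fraction = 0.3,
                                        n_noise = 30, seed = 1L) {
  set.seed(stage_seed(seed, 83L))
  hits <- sample(truth$gene_id,
                 round(recall_fraction * nrow(truth)))
  pool <- setdiff(annotation$gene_id, truth$gene_id)
  c(hits, sample(pool, min(n_noise, length(pool))))
}

#' Truth-recovery report for a synthetic run
#'
#' Compares every recoverable quantity of a pipeline run against the
#' planted truth: peak recall/precision and center error (site-time
#' points at detectable amplitude, at least 4 noise sd), gene recovery,
#' cluster purity against archetypes, regulation-call recall, motif
#' consensus recovery and significance, distance-activity effect
#' detection, and growth-rate errors.
#'
#' @param results A `dynachip_run`.
#' @param truth The truth tibble of the same run.
#' @return Tibble metric, value.
#' @export
truth_report <- function(results, truth) {
  config <- results$config
  p <- results$params
  tps <- config$time_points
  amp <- truth_amplitudes(truth, tps)
  metrics <- list()

  # --- peak recovery ---------------------------------------------------
  sig_peaks <- results$peaks |>
    dplyr::filter(.data$p_value < p$alpha)
  detect_floor <- 4 * config$noise_sd
  site_tp <- tidyr::crossing(site = seq_len(nrow(truth)),
                             tp_idx = seq_along(tps)) |>
    dplyr::mutate(amp = amp[cbind(.data$site, .data$tp_idx)],
                  timepoint_min = tps[.data$tp_idx],
                  center = truth$center[.data$site],
                  replicon = truth$replicon[.data$site]) |>
    dplyr::filter(.data$amp >= detect_floor)
  if (nrow(site_tp) > 0 && nrow(sig_peaks) > 0) {
    match_err <- purrr::pmap_dbl(
      site_tp[, c("replicon", "timepoint_min", "center")],
      function(replicon, timepoint_min, center) {
        cand <- sig_peaks[sig_peaks$replicon == replicon &
                            sig_peaks$timepoint_min == timepoint_min, ]
        if (nrow(cand) == 0) return(NA_real_)
        min(abs(cand$center - center))
      })
    recalled <- !is.na(match_err) & match_err <= p$match_dist
    metrics$peak_recall <- mean(recalled)
    metrics$peak_center_error_median_bp <-
      stats::median(match_err[recalled])
    # precision over deduplicated significant calls
    truth_at <- function(replicon, timepoint_min, center) {
      i <- truth$replicon == replicon
      j <- match(timepoint_min, tps)
      any(i & amp[, j] > 0 & abs(truth$center - center) <= p$match_dist)
    }
    dedup <- sig_peaks |>
      dplyr::mutate(bin = round(.data$center / p$match_dist)) |>
      dplyr::distinct(.data$replicon, .data$timepoint_min, .data$bin,
                      .keep_all = TRUE)
    metrics$peak_precision <- mean(purrr::pmap_lgl(
      dedup[, c("replicon", "timepoint_min", "center")], truth_at))
  }

  # --- gene recovery ---------------------------------------------------
  retained <- unique(results$profiles$source_gene_id)
  metrics$gene_recall <- mean(truth$gene_id %in% retained)

  # --- clusters --------------------------------------------------------
  if (!is.null(results$clusters)) {
    joined <- results$clusters |>
      dplyr::inner_join(truth[, c("gene_id", "archetype")], by = "gene_id")
    if (nrow(joined) > 0) {
      purity <- joined |>
        dplyr::count(.data$raw_cluster, .data$archetype) |>
        dplyr::group_by(.data$raw_cluster) |>
        dplyr::summarise(best = max(.data$n), total = sum(.data$n),
                         .groups = "drop")
      metrics$cluster_purity <- sum(purity$best) / sum(purity$total)
    }
  }

  # --- regulation calls ------------------------------------------------
  if (!is.null(results$calls)) {
    reg <- results$calls |>
      dplyr::inner_join(truth[, c("gene_id", "sign")], by = "gene_id") |>
      dplyr::filter(!is.na(.data$cs_parent))
    if (nrow(reg) > 0) {
      expected <- ifelse(reg$sign > 0, "activated", "repressed")
      metrics$regulation_recall <- mean(reg$label == expected)
      metrics$mean_abs_cs_parent <- mean(abs(reg$cs_parent))
      if (!all(is.na(reg$cs_knockout))) {
        metrics$mean_abs_cs_knockout <-
          mean(abs(reg$cs_knockout), na.rm = TRUE)
      }
    }
  }

  # --- motif -----------------------------------------------------------
  if (!is.null(results$motifs) && length(results$motifs)) {
    cons <- results$motifs[[1]]$consensus
    metrics$motif_consensus_match <-
      consensus_match(cons, config$motif_consensus)
    if (!is.null(results$motif_sig)) {
      metrics$motif_wilcoxon_p <- results$motif_sig$p
    }
    if (!is.null(results$occurrences) &&
        nrow(results$occurrences) > 0) {
      near <- results$occurrences |>
        dplyr::filter(.data$gene_id %in% truth$gene_id)
      if (nrow(near) > 0) {
        metrics$motif_mean_abs_dist_bp <- mean(abs(near$dist_to_start))
      }
    }
  }

  # --- co-binding geometry --------------------------------------------
  if (!is.null(results$assoc_global)) {
    metrics$distance_activity_cs <- results$assoc_global$cs
    metrics$distance_activity_p <- results$assoc_global$p
  }
  if (!is.null(results$assoc)) {
    ok <- !is.na(results$assoc$neg_log10_p)
    if (any(ok)) {
      nlp <- results$assoc$neg_log10_p[ok]
      attained <- results$assoc$cutoff[ok][nlp >= max(nlp) - 1e-9]
      # the empirical p floors over a plateau of saturated windows; report
      # the plateau midpoint
      metrics$distance_peak_cutoff_bp <- stats::median(attained)
    }
  }
  if (!is.null(results$pairs) && nrow(results$pairs) > 0) {
    bins <- table(floor(abs(results$pairs$signed_distance) / 10))
    metrics$tfb_distance_mode_bp <-
      10 * as.numeric(names(bins)[which.max(bins)]) + 5
  }

  # --- growth ----------------------------------------------------------
  if (!is.null(results$growth_rates)) {
    planted <- attr(results$growth, "rates")
    if (!is.null(planted)) {
      err <- results$growth_rates |>
        dplyr::inner_join(planted, by = c("strain", "h2o2_mM")) |>
        dplyr::filter(!.data$flagged) |>
        dplyr::mutate(rel_err = abs(.data$rate.x - .data$rate.y) /
                        .data$rate.y)
      metrics$growth_rate_max_rel_error <- max(err$rel_err)
    }
  }

  tibble::tibble(metric = names(metrics),
                 value = unlist(metrics, use.names = FALSE))
}

# fraction of constrained (non-n) consensus positions of the generator
# motif matched by the discovered consensus, best over strand
consensus_match <- function(found, generator) {
  gen <- strsplit(toupper(generator), "")[[1]]
  keep <- gen %in% DNA_BASES
  score_one <- function(s) {
    f <- strsplit(toupper(s), "")[[1]]
    if (length(f) != length(gen)) return(0)
    mean(f[keep] == gen[keep])
  }
  max(score_one(found), score_one(reverse_complement(toupper(found))))
}

run_manifest <- function(results) {
  counts <- list(
    probes = nrow(results$probes %||% tibble::tibble()),
    peaks = nrow(results$peaks %||% tibble::tibble()),
    genes_retained = dplyr::n_distinct(results$profiles$gene_id),
    pairs = nrow(results$pairs %||% tibble::tibble()))
  list(package = "dynachip",
       version = as.character(utils::packageVersion("dynachip")),
       mode = results$mode,
       seed = results$config$seed,
       param_hash = rlang::hash(list(results$config, results$params)),
       counts = counts)
}

#' @export
print.dynachip_run <- function(x, ...) {
  cat("<dynachip pipeline run>", x$mode, "mode, seed", x$config$seed, "\n")
  cat("  peaks:", nrow(x$peaks), " genes retained:",
      dplyr::n_distinct(x$profiles$gene_id), "\n")
  if (!is.null(x$report)) {
    cat("  truth recovery:\n")
    for (i in seq_len(nrow(x$report))) {
      cat(sprintf("    %-32s %.4g\n", x$report$metric[i],
                  x$report$value[i]))
    }
  }
  invisible(x)
}

#' Write every table of a pipeline run to a directory
#'
#' @param results A `dynachip_run`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x) && is.data.frame(x) && nrow(x) >= 0) {
      readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  w(results$probes, "probes")
  w(results$normalized, "normalized")
  w(results$peaks, "peaks")
  w(results$profiles, "profiles")
  w(results$clusters, "clusters")
  w(results$calls, "regulation_calls")
  w(results$genotype_tests, "genotype_tests")
  w(results$pairs, "cobinding_pairs")
  w(results$assoc, "distance_activity")
  w(results$enrichment, "enrichment")
  w(results$overlap, "network_overlap")
  w(results$growth_rates, "growth_rates")
  w(results$growth_ratios, "growth_ratios")
  w(results$growth_tests, "growth_tests")
  w(results$report, "truth_report")
  if (!is.null(results$truth)) w(results$truth, "truth")
  if (!is.null(results$genome$annotation)) {
    write_annotation_gff3(results$genome$annotation,
                          file.path(out_dir, "annotation.gff3"))
  }
  if (!is.null(results$genome$sequence)) {
    write_sequence_fasta(results$genome$sequence,
                         file.path(out_dir, "genome.fasta"))
  }
  if (!is.null(results$motifs) && length(results$motifs)) {
    write_pwm_meme(results$motifs[[1]], file.path(out_dir, "motif.meme"))
  }
  jsonlite::write_json(results$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
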