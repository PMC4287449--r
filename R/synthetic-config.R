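#' Configuration for the synthetic ChIP-chip study generator
#'
#' Bundles every tunable of the synthetic-data module into a validated list.
#' The defaults emulate the design of a dynamic ChIP-chip experiment in a
#' halophilic archaeon under peroxide stress: a genome tiled every 30 bp in
#' triplicate, four sampling times (0, 10, 20, 60 min after H2O2 addition),
#' binding sites planted in promoters following four dynamic archetypes
#' (lost; lost-then-restored; gained; variable), expression coupled to
#' occupancy in the parent genotype and decoupled in the regulator knockout,
#' a 20-bp imperfect palindrome implanted upstream of a fraction of target
#' genes, and general-factor (Tfb) sites at controlled signed distances.
#'
#' @param genome_length Length in bp of each replicon.
#' @param n_replicons Number of replicons.
#' @param probe_spacing Tiling distance between probe centers, bp.
#' @param n_probe_replicates On-array probe replicates per position.
#' @param time_points Sampling times in minutes, strictly increasing.
#' @param n_bio_replicates Biological replicates per condition.
#' @param n_genes Number of genes per replicon.
#' @param n_planted_sites Number of planted binding sites (across replicons).
#' @param cluster_mix Length-4 fractions of sites assigned to dynamic
#'   archetypes 1-4; must sum to 1. The default reflects the relative sizes
#'   of the four occupancy clusters seen in dynamic peroxide-stress binding
#'   data (roughly 35/36/11/18 percent).
#' @param kernel_width Width (bp) of the enrichment kernel used to shape the
#'   simulated IP signal around each planted center.
#' @param noise_sd Additive Gaussian noise on probe log2 ratios.
#' @param amplitude_range Range from which each site's base log2 enrichment
#'   amplitude is drawn uniformly.
#' @param coupling_noise_sd Gaussian noise on expression values.
#' @param expression_effect Scale applied to the standardized occupancy
#'   profile when generating coupled (parent) expression.
#' @param motif_implant_fraction Fraction of planted sites whose promoter
#'   receives a motif implant.
#' @param motif_consensus Consensus of the generator motif; lower-case or
#'   "N"/"n" positions are unconstrained.
#' @param motif_concentration Probability mass on the consensus base at
#'   constrained motif positions (remainder split evenly).
#' @param motif_offset Distance in bp from the implant midpoint to the gene
#'   translation start (upstream).
#' @param tfb_names Names of the general-factor paralogs to plant.
#' @param tfb_distance_mode,tfb_distance_sd Mode and spread (bp) of the
#'   absolute RosR-to-Tfb distance distribution.
#' @param min_site_spacing Minimum distance between planted site centers, bp.
#' @param gc_content Genome G+C fraction (the organism emulated is GC-rich).
#' @param seed Integer seed controlling all generator randomness.
#' @return A `dynachip_config` list.
#' @export
synthetic_config <- function(genome_length = 150000,
                             n_replicons = 1,
                             probe_spacing = 30,
                             n_probe_replicates = 3,
                             time_points = c(0, 10, 20, 60),
                             n_bio_replicates = 3,
                             n_genes = 100,
                             n_planted_sites = 40,
                             cluster_mix = c(88, 90, 29, 45) / 252,
                             kernel_width = 150,
                             noise_sd = 0.5,
                             amplitude_range = c(1.5, 2.5),
                             coupling_noise_sd = 0.1,
                             expression_effect = 1,
                             motif_implant_fraction = 2 / 3,
                             motif_consensus = "TCGNCGACGAGNTCGNCGAC",
                             motif_concentration = 0.9,
                             motif_offset = 18,
                             tfb_names = c("TfbA", "TfbB", "TfbD", "TfbF", "TfbG"),
                             tfb_distance_mode = 70,
                             tfb_distance_sd = 15,
                             min_site_spacing = 2 * kernel_width,
                             gc_content = 0.67,
                             seed = 1L) {
  config <- list(
    genome_length = genome_length, n_replicons = n_replicons,
    probe_spacing = probe_spacing, n_probe_replicates = n_probe_replicates,
    time_points = time_points, n_bio_replicates = n_bio_replicates,
    n_genes = n_genes, n_planted_sites = n_planted_sites,
    cluster_mix = cluster_mix, kernel_width = kernel_width,
    noise_sd = noise_sd, amplitude_range = amplitude_range,
    coupling_noise_sd = coupling_noise_sd,
    expression_effect = expression_effect,
    motif_implant_fraction = motif_implant_fraction,
    motif_consensus = motif_consensus,
    motif_concentration = motif_concentration,
    motif_offset = motif_offset,
    tfb_names = tfb_names,
    tfb_distance_mode = tfb_distance_mode,
    tfb_distance_sd = tfb_distance_sd,
    min_site_spacing = min_site_spacing,
    gc_content = gc_content,
    seed = as.integer(seed)
  )
  class(config) <- "dynachip_config"
  validate_config(config)
  config
}

validate_config <- function(config) {
  stopifnot(inherits(config, "dynachip_config"))
  if (config$probe_spacing <= 0) {
    stop_dynachip("`probe_spacing` must be positive", "dynachip_config_error")
  }
  if (length(config$cluster_mix) != 4 ||
      any(config$cluster_mix < 0) ||
      abs(sum(config$cluster_mix) - 1) > 1e-8) {
    stop_dynachip("`cluster_mix` must be 4 nonnegative fractions summing to 1",
                  "dynachip_config_error")
  }
  if (is.unsorted(config$time_points, strictly = TRUE)) {
    stop_dynachip("`time_points` must be strictly increasing",
                  "dynachip_config_error")
  }
  counts <- c(config$n_replicons, config$n_probe_replicates,
              config$n_bio_replicates)
  if (any(counts < 1)) {
    stop_dynachip("replicon and replicate counts must be >= 1",
                  "dynachip_config_error")
  }
  if (config$n_genes < 0 || config$n_planted_sites < 0) {
    stop_dynachip("gene and site counts must be nonnegative",
                  "dynachip_config_error")
  }
  if (config$motif_implant_fraction < 0 || config$motif_implant_fraction > 1) {
    stop_dynachip("`motif_implant_fraction` must lie in [0, 1]",
                  "dynachip_config_error")
  }
  if (config$noise_sd < 0 || config$coupling_noise_sd < 0) {
    stop_dynachip("noise standard deviations must be nonnegative",
                  "dynachip_config_error")
  }
  invisible(config)
}

#' @export
print.dynachip_config <- function(x, ...) {
  cat("<dynachip synthetic study config>\n")
  cat("  genome:", x$n_replicons, "replicon(s) x", x$genome_length, "bp,",
      x$n_genes, "genes\n")
  cat("  probes: every", x$probe_spacing, "bp x", x$n_probe_replicates,
      "probe reps x", x$n_bio_replicates, "bio reps\n")
  cat("  time points (min):", paste(x$time_points, collapse = ", "), "\n")
  cat("  planted sites:", x$n_planted_sites,
      sprintf("(mix %s)", paste(round(x$cluster_mix, 2), collapse = "/")), "\n")
  cat("  noise_sd:", x$noise_sd, " kernel_width:", x$kernel_width,
      " seed:", x$seed, "\n")
  invisible(x)
}
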