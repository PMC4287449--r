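#' Generate a synthetic genome: annotation, sequence, operon table
#'
#' Lays out non-overlapping genes on each replicon, draws a random
#' GC-biased nucleotide sequence, and groups runs of co-oriented adjacent
#' genes into operons. Coordinates are 0-based half-open internally; the
#' translation start is the coordinate of the first base of the start codon
#' (`start` on the + strand, `end - 1` on the - strand).
#'
#' @param config A [synthetic_config()] object.
#' @return A list with elements `annotation` (tibble: gene_id, replicon,
#'   start, end, strand, translation_start, category), `sequence` (named
#'   character vector, one string per replicon) and `operons` (tibble:
#'   operon_id, gene_id).
#' @export
generate_genome <- function(config) {
  validate_config(config)
  set.seed(stage_seed(config$seed, 11L))
  replicons <- sprintf("repl%02d", seq_len(config$n_replicons))

  bases <- c("A", "C", "G", "T")
  base_probs <- c((1 - config$gc_content) / 2, config$gc_content / 2,
                  config$gc_content / 2, (1 - config$gc_content) / 2)
  sequence <- vapply(replicons, function(r) {
    paste(sample(bases, config$genome_length, replace = TRUE,
                 prob = base_probs), collapse = "")
  }, character(1))

  # split genes across replicons as evenly as possible
  genes_per <- diff(round(seq(0, config$n_genes, length.out =
                                config$n_replicons + 1)))
  ann <- purrr::map2(replicons, genes_per, function(repl, n_genes) {
    if (n_genes == 0) return(NULL)
    lens <- sample(600:1200, n_genes, replace = TRUE)
    min_gap <- 150
    edge <- 400  # keep promoters clear of replicon ends
    needed <- sum(lens) + (n_genes + 1) * min_gap + 2 * edge
    if (needed > config$genome_length) {
      stop_dynachip(sprintf(
        "genome_length %d too small for %d genes (needs >= %d bp)",
        config$genome_length, n_genes, needed), "dynachip_sizing_error")
    }
    slack <- config$genome_length - needed
    extra <- if (slack > 0) {
      stats::rmultinom(1, slack, rep(1, n_genes + 1))[, 1]
    } else rep(0, n_genes + 1)
    gaps <- min_gap + extra
    starts <- edge + cumsum(gaps[seq_len(n_genes)]) +
      cumsum(c(0, lens[-n_genes]))
    tibble::tibble(
      replicon = repl,
      start = starts,
      end = starts + lens,
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
  }) |> purrr::list_rbind()
  if (nrow(ann) == 0) {
    ann <- tibble::tibble(replicon = character(0), start = integer(0),
                          end = integer(0), strand = character(0))
  }

  ann <- ann |>
    dplyr::mutate(
      gene_id = sprintf("SYNG%04d", dplyr::row_number()),
      translation_start = ifelse(.data$strand == "+", .data$start,
                                 .data$end - 1),
      category = sample(sprintf("arCOG-%s",
                                c("J", "K", "L", "D", "O", "M", "P", "T",
                                  "C", "G", "E", "F", "H", "I", "R", "S")),
                        dplyr::n(), replace = TRUE)
    ) |>
    dplyr::select("gene_id", "replicon", "start", "end", "strand",
                  "translation_start", "category")

  # operons: runs of adjacent co-oriented genes with a short intergenic gap
  operons <- ann |>
    dplyr::group_by(.data$replicon) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      gap = .data$start - dplyr::lag(as.numeric(.data$end),
                                     default = -Inf),
      new_unit = .data$gap > 300 |
        .data$strand != dplyr::lag(.data$strand, default = "") |
        stats::runif(dplyr::n()) < 0.35,
      unit = cumsum(.data$new_unit)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(operon_id = sprintf("OP%04d",
                                      as.integer(factor(paste(.data$replicon,
                                                              .data$unit))))) |>
    dplyr::select("operon_id", "gene_id")

  list(annotation = ann, sequence = sequence, operons = operons)
}

# archetype shapes over the time grid; amplitudes are multiples of the
# site's base amplitude.  1: bound then lost; 2: lost then restored;
# 3: gained under stress; 4: variable (oscillating) occupancy.
archetype_shape <- function(archetype, n_time) {
  shape <- switch(archetype,
    `1` = c(1, rep(0, n_time - 1)),
    `2` = c(1, rep(0, n_time - 2), 1),
    `3` = c(0, seq(0.7, 1, length.out = n_time - 1)),
    `4` = rep_len(c(0.9, 0.15, 1, 0.1), n_time)
  )
  shape
}

#' Plant binding sites with dynamic occupancy archetypes
#'
#' Selects promoter-proximal positions (within 250 bp of a translation
#' start, mutually separated by at least `min_site_spacing`), assigns each
#' site one of four dynamic archetypes according to `cluster_mix`, draws a
#' per-time-point amplitude vector from the archetype shape, and assigns a
#' regulation sign (+1 activated, -1 repressed).
#'
#' @param config A [synthetic_config()] object.
#' @param genome Output of [generate_genome()].
#' @return A truth tibble with one row per planted site: site_id, replicon,
#'   center, gene_id, strand, translation_start, archetype, sign and one
#'   `amp_<t>` column per time point.
#' @export
plant_dynamics <- function(config, genome) {
  validate_config(config)
  ann <- genome$annotation
  if (nrow(ann) == 0) {
    stop_dynachip("annotation is empty", "dynachip_input_error")
  }
  set.seed(stage_seed(config$seed, 23L))
  n_sites <- config$n_planted_sites
  tps <- config$time_points

  # greedy selection of genes whose starts are mutually well separated
  cand <- ann[sample.int(nrow(ann)), ]
  chosen <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ts <- cand$translation_start[i]
    same <- cand$replicon[chosen] == cand$replicon[i]
    if (!any(same & abs(cand$translation_start[chosen] - ts) <
               config$min_site_spacing)) {
      chosen <- c(chosen, i)
    }
    if (length(chosen) == n_sites) break
  }
  if (length(chosen) < n_sites) {
    stop_dynachip(sprintf(
      "could not place %d sites >= %d bp apart; enlarge the genome or reduce sites",
      n_sites, config$min_site_spacing), "dynachip_sizing_error")
  }
  sites <- cand[chosen, ]

  # archetype counts: floor of the mix, remainders to largest fractions
  raw <- config$cluster_mix * n_sites
  counts <- floor(raw)
  rem <- n_sites - sum(counts)
  if (rem > 0) {
    top_up <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top_up] <- counts[top_up] + 1
  }
  archetypes <- sample(rep(1:4, times = counts))

  offset <- pmin(pmax(round(stats::rnorm(n_sites, 0, 80)), -250), 250)
  base_amp <- stats::runif(n_sites, config$amplitude_range[1],
                           config$amplitude_range[2])

  amp <- t(vapply(seq_len(n_sites), function(i) {
    shape <- archetype_shape(archetypes[i], length(tps))
    jitter <- stats::runif(length(tps), 0.9, 1.1)
    a <- base_amp[i] * shape * ifelse(shape > 0, jitter, 1)
    pmax(a, 0)
  }, numeric(length(tps))))
  colnames(amp) <- sprintf("amp_%d", tps)

  truth <- tibble::tibble(
    site_id = sprintf("SITE%03d", seq_len(n_sites)),
    replicon = sites$replicon,
    center = sites$translation_start + offset,
    gene_id = sites$gene_id,
    strand = sites$strand,
    translation_start = sites$translation_start,
    archetype = archetypes,
    sign = sample(c(1, -1), n_sites, replace = TRUE)
  )
  dplyr::bind_cols(truth, tibble::as_tibble(amp))
}

truth_amplitudes <- function(truth, time_points) {
  as.matrix(truth[, sprintf("amp_%d", time_points)])
}

#' Simulate tiled ChIP-chip probe signals from planted sites
#'
#' Each probe's expected log2 IP/mock ratio is the sum over planted sites of
#' the site amplitude at that time point times a peak-normalized enrichment
#' kernel evaluated at the probe-to-center distance. Independent Gaussian
#' noise of sd `noise_sd` is added per probe, per replicate, per time point.
#'
#' @param truth Truth tibble from [plant_dynamics()].
#' @param config A [synthetic_config()] object.
#' @param kernel Optional [peak_kernel()]; defaults to a Gaussian kernel of
#'   width `config$kernel_width`.
#' @return Probe tibble: replicon, coord, replicate, timepoint_min,
#'   log2ratio. Replicates are labelled `b<bio>.p<probe>`.
#' @export
simulate_chip_signal <- function(truth, config, kernel = NULL) {
  validate_config(config)
  kernel <- kernel %||% peak_kernel("gaussian", width = config$kernel_width)
  set.seed(stage_seed(config$seed, 37L))
  tps <- config$time_points
  amp <- truth_amplitudes(truth, tps)
  replicons <- sprintf("repl%02d", seq_len(config$n_replicons))
  rep_ids <- as.vector(outer(seq_len(config$n_probe_replicates),
                             seq_len(config$n_bio_replicates),
                             function(p, b) sprintf("b%d.p%d", b, p)))

  purrr::map(replicons, function(repl) {
    coords <- seq(0, config$genome_length - 1, by = config$probe_spacing)
    expected <- matrix(0, length(coords), length(tps))
    idx <- which(truth$replicon == repl)
    for (i in idx) {
      k <- kernel_eval(kernel, coords - truth$center[i])
      nz <- which(k > 0)
      if (length(nz)) {
        expected[nz, ] <- expected[nz, ] + outer(k[nz], amp[i, ])
      }
    }
    grid <- tidyr::crossing(replicate = rep_ids, timepoint_min = tps) |>
      dplyr::arrange(.data$replicate, .data$timepoint_min)
    purrr::pmap(grid, function(replicate, timepoint_min) {
      mu <- expected[, match(timepoint_min, tps)]
      tibble::tibble(
        replicon = repl, coord = coords, replicate = replicate,
        timepoint_min = timepoint_min,
        log2ratio = mu + stats::rnorm(length(mu), 0, config$noise_sd)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Simulate an expression time course coupled (or not) to occupancy
#'
#' In the parent genotype each target gene's expression profile is a
#' monotone transform of its occupancy profile, multiplied by the planted
#' regulation sign (so activated genes track occupancy and repressed genes
#' mirror it), plus Gaussian noise. In the regulator knockout, expression is
#' independent of occupancy: pure noise about the gene's baseline. Genes not
#' in `genes` beyond the planted targets likewise receive baseline noise.
#'
#' @param truth Truth tibble from [plant_dynamics()].
#' @param config A [synthetic_config()] object.
#' @param genotype `"parent"` or `"knockout"`.
#' @param genes Optional character vector of gene ids to simulate; defaults
#'   to the planted target genes.
#' @return Long expression tibble: gene_id, timepoint_min, replicate,
#'   expression.
#' @export
simulate_expression <- function(truth, config, genotype = c("parent", "knockout"),
                                genes = NULL) {
  validate_config(config)
  genotype <- tryCatch(match.arg(genotype),
                       error = function(e) stop_dynachip(
                         "genotype must be 'parent' or 'knockout'",
                         "dynachip_input_error"))
  set.seed(stage_seed(config$seed, if (genotype == "parent") 41L else 43L))
  tps <- config$time_points
  genes <- genes %||% truth$gene_id
  amp <- truth_amplitudes(truth, tps)

  base <- matrix(0, length(genes), length(tps),
                 dimnames = list(genes, sprintf("%d", tps)))
  if (genotype == "parent") {
    hit <- match(truth$gene_id, genes)
    for (i in which(!is.na(hit))) {
      a <- amp[i, ]
      if (stats::sd(a) > 0) {
        z <- (a - mean(a)) / stats::sd(a)
        base[hit[i], ] <- truth$sign[i] * config$expression_effect * z
      }
    }
  }

  tidyr::crossing(gene_id = genes, timepoint_min = tps,
                  replicate = seq_len(config$n_bio_replicates)) |>
    dplyr::mutate(
      expression = base[cbind(match(.data$gene_id, genes),
                              match(.data$timepoint_min, tps))] +
        stats::rnorm(dplyr::n(), 0, config$coupling_noise_sd)
    )
}

#' Position weight matrix of the generator motif
#'
#' Builds the PWM from which motif implants are sampled: constrained
#' positions put `concentration` probability on the consensus base (the
#' remainder split evenly over the other three); `N`/`n` positions are
#' uniform.
#'
#' @param consensus Consensus string over A, C, G, T, N.
#' @param concentration Probability on the consensus base.
#' @return A 4 x width probability matrix with rownames A, C, G, T.
#' @export
generator_pwm <- function(consensus, concentration = 0.9) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  w <- length(letters)
  pwm <- matrix(0.25, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(w)) {
    if (letters[j] %in% rownames(pwm)) {
      pwm[, j] <- (1 - concentration) / 3
      pwm[letters[j], j] <- concentration
    }
  }
  pwm
}

#' Implant cis-regulatory motif instances upstream of target genes
#'
#' A fraction of planted sites receive a motif instance sampled from the
#' generator PWM, written into the genome so that the implant midpoint lies
#' `motif_offset` bp upstream of the gene's translation start (on the gene's
#' strand; minus-strand implants are reverse-complemented before insertion).
#'
#' @param truth Truth tibble from [plant_dynamics()].
#' @param sequence Named character vector of replicon sequences.
#' @param config A [synthetic_config()] object.
#' @return A list with `sequence` (modified), and `truth` with added columns
#'   motif_implanted, motif_start (0-based), motif_seq (implanted strand
#'   sequence as it appears in gene orientation).
#' @export
plant_motifs <- function(truth, sequence, config) {
  validate_config(config)
  set.seed(stage_seed(config$seed, 53L))
  pwm <- generator_pwm(config$motif_consensus, config$motif_concentration)
  w <- ncol(pwm)
  n_implant <- round(config$motif_implant_fraction * nrow(truth))
  implant_idx <- sort(sample.int(nrow(truth), n_implant))

  truth$motif_implanted <- FALSE
  truth$motif_start <- NA_integer_
  truth$motif_seq <- NA_character_

  for (i in implant_idx) {
    instance <- paste(apply(pwm, 2, function(p) {
      sample(rownames(pwm), 1, prob = p)
    }), collapse = "")
    ts <- truth$translation_start[i]
    if (truth$strand[i] == "+") {
      midpoint <- ts - config$motif_offset
      start <- midpoint - floor(w / 2)
      inserted <- instance
    } else {
      midpoint <- ts + config$motif_offset
      start <- midpoint - floor(w / 2)
      inserted <- reverse_complement(instance)
    }
    repl_len <- nchar(sequence[[truth$replicon[i]]])
    if (start < 0 || start + w > repl_len) {
      stop_dynachip(sprintf("motif implant for %s overruns replicon bounds",
                            truth$gene_id[i]), "dynachip_placement_error")
    }
    substr(sequence[[truth$replicon[i]]], start + 1, start + w) <- inserted
    truth$motif_implanted[i] <- TRUE
    truth$motif_start[i] <- start
    truth$motif_seq[i] <- instance
  }
  list(sequence = sequence, truth = truth)
}

#' Plant general-factor (Tfb) binding sites at signed distances
#'
#' Each planted site receives one to three Tfb sites. The absolute
#' RosR-to-Tfb distance is drawn around `tfb_distance_mode`; the sign of the
#' distance encodes the planted regulation: activated genes get the
#' sequence-specific site upstream of the Tfb site (negative signed
#' distance, gene-strand convention), repressed genes the opposite.
#'
#' @param truth Truth tibble from [plant_dynamics()].
#' @param config A [synthetic_config()] object.
#' @return Tibble of Tfb sites: tfb_name, replicon, center, gene_id,
#'   true_signed_distance.
#' @export
plant_tfb_sites <- function(truth, config) {
  validate_config(config)
  set.seed(stage_seed(config$seed, 61L))
  purrr::pmap(truth[, c("site_id", "replicon", "center", "gene_id", "strand",
                        "translation_start", "sign")],
              function(site_id, replicon, center, gene_id, strand,
                       translation_start, sign) {
    n_tfb <- sample(1:3, 1, prob = c(0.55, 0.3, 0.15))
    names <- sample(config$tfb_names, n_tfb)
    # cap |d| so the Tfb site stays within 250 bp of the gene start
    cap <- max(20, 250 - abs(center - translation_start))
    d_abs <- pmin(pmax(round(stats::rnorm(n_tfb, config$tfb_distance_mode,
                                          config$tfb_distance_sd)), 10), cap)
    signed <- if (sign > 0) -d_abs else d_abs
    # signed = rosr - tfb on + strand, tfb - rosr on - strand
    tfb_center <- if (strand == "+") center - signed else center + signed
    tibble::tibble(tfb_name = names, replicon = replicon, center = tfb_center,
                   gene_id = gene_id, true_signed_distance = signed)
  }) |> purrr::list_rbind()
}

#' Simulate optical-density growth curves
#'
#' OD600 follows `OD0 * 2^(rate * t)` during log phase, plateauing at
#' `od_max`, with optional multiplicative log-normal noise, sampled every
#' `sampling_h` hours.
#'
#' @param config A [synthetic_config()] object (supplies replicate count and
#'   seed).
#' @param rates Tibble with columns strain, h2o2_mM, rate (doublings/hour).
#'   Defaults to a parent strain and a stress-sensitive mutant at 0, 5 and
#'   6 mM peroxide.
#' @param od0 Starting OD600.
#' @param od_max Plateau OD600.
#' @param duration_h,sampling_h Time span and sampling interval in hours.
#' @param noise_cv Multiplicative noise coefficient of variation (0 = none).
#' @return Tibble: strain, h2o2_mM, replicate, time_h, od600; planted rates
#'   attached as attribute `"rates"`.
#' @export
simulate_growth <- function(config, rates = NULL, od0 = 0.1, od_max = 1.2,
                            duration_h = 24, sampling_h = 0.5,
                            noise_cv = 0.05) {
  validate_config(config)
  if (od0 <= 0) {
    stop_dynachip("`od0` must be positive", "dynachip_input_error")
  }
  rates <- rates %||% tibble::tribble(
    ~strain,   ~h2o2_mM, ~rate,
    "parent",  0,        0.30,
    "parent",  5,        0.24,
    "parent",  6,        0.20,
    "mutant",  0,        0.30,
    "mutant",  5,        0.15,
    "mutant",  6,        0.10
  )
  set.seed(stage_seed(config$seed, 71L))
  times <- seq(0, duration_h, by = sampling_h)
  out <- tidyr::crossing(rates,
                         replicate = seq_len(config$n_bio_replicates)) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      strain = .data$strain, h2o2_mM = .data$h2o2_mM,
      replicate = .data$replicate, time_h = times,
      od600 = pmin(od0 * 2^(.data$rate * times), od_max) *
        exp(stats::rnorm(length(times), 0, noise_cv))
    )
  attr(out, "rates") <- rates
  out
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
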