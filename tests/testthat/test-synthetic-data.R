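test_that("config validation rejects malformed studies", {
  expect_s3_class(synthetic_config(), "dynachip_config")
  expect_error(synthetic_config(probe_spacing = 0), class = "dynachip_config_error")
  expect_error(synthetic_config(cluster_mix = c(0.5, 0.5, 0.2, 0)),
               class = "dynachip_config_error")
  expect_error(synthetic_config(time_points = c(0, 10, 10, 60)),
               class = "dynachip_config_error")
  expect_error(synthetic_config(motif_implant_fraction = 1.5),
               class = "dynachip_config_error")
})

test_that("generated genomes have disjoint genes and are deterministic", {
  cfg <- synthetic_config(n_genes = 50, genome_length = 100000, seed = 3)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$annotation), 50)
  expect_equal(nchar(g1$sequence[[1]]), 100000)
  # interval sweep: sorted genes must not overlap
  ann <- dplyr::arrange(g1$annotation, start)
  expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))
  # strands sane, translation starts at the right end
  expect_true(all(ann$strand %in% c("+", "-")))
  expect_equal(ann$translation_start,
               ifelse(ann$strand == "+", ann$start, ann$end - 1))

  empty <- generate_genome(synthetic_config(n_genes = 0,
                                            genome_length = 100000,
                                            seed = 3))
  expect_equal(nrow(empty$annotation), 0)
  expect_equal(nchar(empty$sequence[[1]]), 100000)

  expect_error(generate_genome(synthetic_config(n_genes = 200,
                                                genome_length = 30000)),
               class = "dynachip_sizing_error")
})

test_that("planted dynamics follow the archetype shapes and the mix", {
  cfg <- small_config(n_planted_sites = 12)
  g <- generate_genome(cfg)
  truth <- plant_dynamics(cfg, g)
  expect_equal(nrow(truth), 12)
  # archetype counts match the mix within rounding
  counts <- table(factor(truth$archetype, levels = 1:4))
  expect_true(all(abs(counts - cfg$cluster_mix * 12) <= 1))
  # sites sit near their gene's translation start and apart from each other
  expect_true(all(abs(truth$center - truth$translation_start) <= 250))
  d <- outer(truth$center, truth$center, function(a, b) abs(a - b))
  diag(d) <- Inf
  expect_true(all(d >= cfg$min_site_spacing))

  amp <- as.matrix(truth[, paste0("amp_", cfg$time_points)])
  a1 <- amp[truth$archetype == 1, , drop = FALSE]
  expect_true(all(a1[, 1] > 0) && all(a1[, -1] == 0))
  a2 <- amp[truth$archetype == 2, , drop = FALSE]
  expect_true(all(a2[, 1] > 0) && all(a2[, 4] > 0) &&
                all(a2[, 2:3] == 0))
  a3 <- amp[truth$archetype == 3, , drop = FALSE]
  expect_true(all(a3[, 1] == 0) && all(a3[, -1] > 0))
  expect_true(all(amp >= 0))
  expect_true(all(truth$sign %in% c(-1, 1)))

  pure <- plant_dynamics(synthetic_config(cluster_mix = c(1, 0, 0, 0),
                                          n_planted_sites = 8, seed = 5),
                         generate_genome(synthetic_config(seed = 5)))
  expect_true(all(pure$archetype == 1))
})

test_that("simulated probe signal is kernel-shaped with linear amplitudes", {
  cfg <- small_config(noise_sd = 0)
  g <- generate_genome(cfg)
  truth <- plant_dynamics(cfg, g)
  kernel <- peak_kernel("gaussian", width = cfg$kernel_width)
  probes <- simulate_chip_signal(truth, cfg, kernel)
  one <- dplyr::filter(probes, replicate == "b1.p1", timepoint_min == 0)
  # noiseless signal at each probe equals the kernel superposition
  active <- dplyr::filter(truth, amp_0 > 0)
  expected <- rowSums(vapply(seq_len(nrow(active)), function(i) {
    active$amp_0[i] * kernel_eval(kernel, one$coord - active$center[i])
  }, numeric(nrow(one))))
  expect_equal(one$log2ratio, expected, tolerance = 1e-12)

  # doubling amplitudes doubles the noiseless signal exactly
  truth2 <- truth
  for (cc in paste0("amp_", cfg$time_points)) truth2[[cc]] <- 2 * truth2[[cc]]
  probes2 <- simulate_chip_signal(truth2, cfg, kernel)
  expect_equal(probes2$log2ratio, 2 * probes$log2ratio, tolerance = 1e-12)

  # replicate structure
  expect_equal(dplyr::n_distinct(probes$replicate),
               cfg$n_probe_replicates * cfg$n_bio_replicates)
})

test_that("replicate mean at the center probe approaches amplitude x kernel(0)", {
  cfg <- synthetic_config(genome_length = 30000, n_genes = 10,
                          n_planted_sites = 2, n_probe_replicates = 10,
                          n_bio_replicates = 10, noise_sd = 0.5, seed = 17)
  g <- generate_genome(cfg)
  truth <- plant_dynamics(cfg, g)
  probes <- simulate_chip_signal(truth, cfg)
  site <- truth[truth$amp_0 > 0, ][1, ]
  near <- dplyr::filter(probes, timepoint_min == 0,
                        abs(coord - site$center) ==
                          min(abs(coord - site$center)))
  kernel <- peak_kernel("gaussian", width = cfg$kernel_width)
  mu <- site$amp_0 * kernel_eval(kernel, near$coord[1] - site$center)
  se <- cfg$noise_sd / sqrt(nrow(near))
  expect_lt(abs(mean(near$log2ratio) - mu), 3 * se)
})

test_that("expression coupling is monotone in the parent and absent in the knockout", {
  cfg <- small_config(coupling_noise_sd = 0)
  g <- generate_genome(cfg)
  truth <- plant_dynamics(cfg, g)
  expr <- simulate_expression(truth, cfg, "parent")
  mean_expr <- expr |>
    dplyr::group_by(gene_id, timepoint_min) |>
    dplyr::summarise(expression = mean(expression), .groups = "drop")
  for (i in seq_len(nrow(truth))) {
    e <- mean_expr$expression[mean_expr$gene_id == truth$gene_id[i]]
    a <- as.numeric(truth[i, paste0("amp_", cfg$time_points)])
    expect_equal(spearman_cs(e, a) * truth$sign[i], 1)
  }
  expect_error(simulate_expression(truth, cfg, "wildtype"),
               class = "dynachip_input_error")

  # knockout |Cs| sits at the 4-point null, far below the coupled parent
  cfg2 <- synthetic_config(genome_length = 1500000, n_genes = 1200,
                           n_planted_sites = 400, min_site_spacing = 100,
                           seed = 23)
  g2 <- generate_genome(cfg2)
  truth2 <- plant_dynamics(cfg2, g2)
  ko <- simulate_expression(truth2, cfg2, "knockout")
  mean_ko <- ko |>
    dplyr::group_by(gene_id, timepoint_min) |>
    dplyr::summarise(expression = mean(expression), .groups = "drop")
  amp <- as.matrix(truth2[, paste0("amp_", cfg2$time_points)])
  cs <- vapply(seq_len(nrow(truth2)), function(i) {
    e <- mean_ko$expression[mean_ko$gene_id == truth2$gene_id[i]]
    spearman_cs(amp[i, ], e)
  }, numeric(1))
  # Monte-Carlo null for mean |Spearman| at 4 points with the same tie
  # structure: permute the expression ranks
  set.seed(1)
  null_mean <- mean(replicate(2000, {
    i <- sample(nrow(truth2), 1)
    abs(spearman_cs(amp[i, ], sample(4)))
  }))
  expect_lt(abs(mean(abs(cs), na.rm = TRUE) - null_mean), 0.08)
  # and decisively below the noiseless coupled value of 1
  expect_lt(mean(abs(cs), na.rm = TRUE), 0.65)
})

test_that("motif implants land 18 bp upstream with the configured content", {
  cfg <- small_config(motif_implant_fraction = 1, motif_concentration = 1)
  g <- generate_genome(cfg)
  truth <- plant_dynamics(cfg, g)
  pm <- plant_motifs(truth, g$sequence, cfg)
  expect_true(all(pm$truth$motif_implanted))
  w <- nchar(cfg$motif_consensus)
  for (i in seq_len(nrow(pm$truth))) {
    row <- pm$truth[i, ]
    written <- substr(pm$sequence[[row$replicon]], row$motif_start + 1,
                      row$motif_start + w)
    oriented <- if (row$strand == "+") written else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(written)))
    # zero-entropy generator: equals the consensus away from the n wildcards
    gen <- strsplit(cfg$motif_consensus, "")[[1]]
    found <- strsplit(oriented, "")[[1]]
    expect_identical(found[gen != "N"], gen[gen != "N"])
    # midpoint 18 bp upstream of the translation start
    midpoint <- row$motif_start + w / 2
    offset <- if (row$strand == "+") row$translation_start - midpoint else
      midpoint - row$translation_start
    expect_equal(offset, cfg$motif_offset, tolerance = 1)
  }

  none <- plant_motifs(truth, g$sequence,
                       small_config(motif_implant_fraction = 0))
  expect_identical(none$sequence, g$sequence)
  expect_false(any(none$truth$motif_implanted))
})

test_that("Tfb sites follow the sign convention and distance mode", {
  truth <- tibble::tibble(site_id = c("a", "b"), replicon = "r",
                          center = c(1000, 1000), gene_id = c("g1", "g2"),
                          strand = "+", translation_start = c(1000, 1000),
                          sign = c(1, -1))
  cfg <- synthetic_config(seed = 2)
  tfb <- plant_tfb_sites(truth, cfg)
  act <- tfb[tfb$gene_id == "g1", ]
  rep_ <- tfb[tfb$gene_id == "g2", ]
  # activated: RosR upstream of Tfb (negative signed distance, Tfb downstream)
  expect_true(all(act$true_signed_distance < 0))
  expect_true(all(act$center > 1000))
  expect_true(all(rep_$true_signed_distance > 0))
  expect_true(all(rep_$center < 1000))

  # |distance| mode near the configured 70 bp over many sites
  cfg2 <- synthetic_config(genome_length = 2000000, n_genes = 800,
                           n_planted_sites = 500, min_site_spacing = 100,
                           seed = 31)
  g2 <- generate_genome(cfg2)
  truth2 <- plant_dynamics(cfg2, g2)
  tfb2 <- plant_tfb_sites(truth2, cfg2)
  h <- hist(abs(tfb2$true_signed_distance), breaks = seq(0, 250, 10),
            plot = FALSE)
  peak_bin <- h$mids[which.max(h$counts)]
  expect_gte(peak_bin, 65)
  expect_lte(peak_bin, 75)
})

test_that("growth curves follow the closed form and plateau", {
  cfg <- synthetic_config(n_bio_replicates = 2, seed = 9)
  rates <- tibble::tibble(strain = "s", h2o2_mM = 0, rate = 1)
  curves <- simulate_growth(cfg, rates, od0 = 0.1, od_max = 10,
                            duration_h = 4, noise_cv = 0)
  one <- dplyr::filter(curves, replicate == 1)
  expect_equal(one$od600[one$time_h == 2], 0.4)
  expect_equal(one$od600, pmin(0.1 * 2^one$time_h, 10))

  flat <- simulate_growth(cfg, tibble::tibble(strain = "s", h2o2_mM = 0,
                                              rate = 0),
                          noise_cv = 0)
  expect_true(all(flat$od600 == flat$od600[1]))
  expect_error(simulate_growth(cfg, rates, od0 = -1),
               class = "dynachip_input_error")
})
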