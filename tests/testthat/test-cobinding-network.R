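test_that("signed distance follows the strand convention", {
  expect_equal(signed_distance(100, 150, "+"), -50)
  expect_equal(signed_distance(150, 100, "-"), -50)
  expect_equal(signed_distance(1000, 1000, "+"), 0)
  # antisymmetric under strand flip with positions swapped
  for (i in 1:10) {
    a <- i * 37; b <- i * 53
    expect_equal(signed_distance(a, b, "+"), signed_distance(b, a, "-"))
  }
  expect_error(signed_distance(1, 2, "x"), class = "dynachip_input_error")
})

test_that("co-binding detection applies both 250 bp criteria", {
  ann <- tibble::tibble(gene_id = "g1", replicon = "r", strand = "+",
                        translation_start = 1100)
  rosr <- tibble::tibble(replicon = "r", center = 1000)
  tfb_ok <- tibble::tibble(tfb_name = "TfbG", replicon = "r", center = 1200)
  pairs <- detect_cobinding(rosr, tfb_ok, ann)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$signed_distance, -200)

  # pair distance 300 fails criterion (b) even though both are near a gene
  ann2 <- tibble::tibble(gene_id = "g1", replicon = "r", strand = "+",
                         translation_start = 1150)
  tfb_far <- tibble::tibble(tfb_name = "TfbG", replicon = "r",
                            center = 1300)
  expect_equal(nrow(detect_cobinding(rosr, tfb_far, ann2)), 0)

  # combination sets count each Tfb once per gene
  tfb_multi <- tibble::tibble(
    tfb_name = c("TfbB", "TfbG", "TfbG"), replicon = "r",
    center = c(1150, 1200, 1210))
  pairs2 <- detect_cobinding(rosr, tfb_multi, ann)
  combos <- cobinding_combinations(pairs2)
  expect_equal(combos$combinations$n_tfb, 2)
  expect_equal(combos$combinations$tfb_set, "TfbB+TfbG")
  expect_equal(sum(combos$histogram$n_genes),
               nrow(combos$combinations))
})

test_that("distance-activity association recovers the planted geometry", {
  cfg <- synthetic_config(genome_length = 2000000, n_genes = 800,
                          n_planted_sites = 500, min_site_spacing = 100,
                          seed = 31)
  g <- generate_genome(cfg)
  truth <- plant_dynamics(cfg, g)
  tfb <- plant_tfb_sites(truth, cfg)
  pairs <- tfb |>
    dplyr::inner_join(truth[, c("gene_id", "sign")], by = "gene_id") |>
    dplyr::mutate(signed_distance = true_signed_distance,
                  activity = sign * 0.9 + rnorm(dplyr::n(), 0, 0.1))
  glob <- distance_activity_global(pairs, n_resample = 2000, seed = 1)
  expect_lt(glob$cs, 0)
  expect_lt(glob$p, 0.001)

  assoc <- distance_activity_association(pairs, n_resample = 500, seed = 1)
  ok <- !is.na(assoc$neg_log10_p)
  # the permutation p saturates over a plateau of well-populated windows;
  # the series must attain its maximum at the planted 70 bp mode
  attained <- assoc$cutoff[ok][
    assoc$neg_log10_p[ok] >= max(assoc$neg_log10_p[ok]) - 1e-9]
  expect_true(any(attained >= 65 & attained <= 75))
  # sparse windows far left of the mode cannot even reach the floor
  expect_false(any(attained <= 15))
  # the reference series is computed wherever the actual one is
  expect_true(all(!is.na(assoc$neg_log10_p_ref[ok])))

  # degenerate window: identical activities give NA statistics
  flat <- pairs[1:5, ]
  flat$activity <- 1
  flat$signed_distance <- c(-10, -20, -30, -40, -50)
  out <- distance_activity_association(flat, n_resample = 100, seed = 1)
  expect_true(all(is.na(out$cs)))

  expect_error(distance_activity_association(pairs[1:2, ]),
               class = "dynachip_input_error")
})

test_that("the windowed permutation test is level under the null", {
  set.seed(77)
  alpha <- 0.05
  hits <- 0; total <- 0
  for (rep_i in 1:8) {
    pairs <- tibble::tibble(
      signed_distance = sample(c(-1, 1), 120, replace = TRUE) *
        sample(10:250, 120, replace = TRUE),
      activity = rnorm(120))
    assoc <- distance_activity_association(pairs, n_resample = 400,
                                           seed = rep_i)
    ok <- !is.na(assoc$p)
    hits <- hits + sum(assoc$p[ok] < alpha)
    total <- total + sum(ok)
  }
  se <- sqrt(alpha * (1 - alpha) / total)
  expect_lte(hits / total, alpha + 3 * se)
})

test_that("hypergeometric helpers match enumeration oracles", {
  expect_equal(hypergeom_test(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_test(3, 4, 5, 10), oracle_hypergeom(3, 4, 5, 10),
               tolerance = 1e-12)
  expect_equal(hypergeom_test(5, 5, 5, 5), 1)
  p0 <- hypergeom_test(0, 4, 5, 10)
  expect_true(p0 > 0 && p0 <= 1)
  expect_error(hypergeom_test(6, 4, 5, 10), class = "dynachip_input_error")

  # category enrichment: a set drawn wholly from one category
  universe <- sprintf("g%03d", 1:100)
  cats <- tibble::tibble(gene_id = universe,
                         category = rep(c("stress", "translation",
                                          "transport", "other"), each = 25))
  enr <- category_enrichment(universe[1:10], cats, universe)
  expect_equal(enr$category[1], "stress")
  expect_equal(enr$count[enr$category == "stress"], 10)
  expect_equal(enr$expect[enr$category == "stress"], 10 * 25 / 100)
  expect_equal(enr$p[enr$category == "stress"],
               oracle_hypergeom(10, 25, 10, 100), tolerance = 1e-12)
  # genes missing from the table fall into the unknown bucket
  cats2 <- cats[1:50, ]
  enr2 <- category_enrichment(universe[1:10], cats2, universe)
  expect_true("Unknown function" %in% enr2$category)

  # expect formula example
  enr3 <- category_enrichment(sprintf("x%d", 1:100),
                              tibble::tibble(gene_id = sprintf("x%d", 1:10),
                                             category = "K"),
                              c(sprintf("x%d", 1:100),
                                sprintf("y%d", 1:900)))
  expect_equal(enr3$expect[enr3$category == "K"], 100 * 10 / 1000)
})

test_that("network overlap reports fraction and hypergeometric p", {
  universe <- sprintf("g%d", 1:200)
  obs <- universe[1:20]
  pred <- universe[c(1:6, 50:73)]
  out <- network_overlap(obs, pred, universe)
  expect_equal(out$overlap, 6)
  expect_equal(out$fraction, 6 / 20)
  expect_equal(out$p, oracle_hypergeom(6, 20, 30, 200), tolerance = 1e-12)
  expect_equal(network_overlap(obs, obs, universe)$fraction, 1)
  expect_equal(network_overlap(obs, universe[100:120],
                               universe)$fraction, 0)
  expect_true(is.na(network_overlap(character(0), pred,
                                    universe)$fraction))
})
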