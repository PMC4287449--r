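long_profiles <- function(mat, tps = c(0, 10, 20, 60)) {
  tibble::tibble(
    gene_id = rep(rownames(mat), each = ncol(mat)),
    timepoint_min = rep(tps, nrow(mat)),
    intensity = as.vector(t(mat)))
}

test_that("the GE-ChIP Spearman statistic matches the rank formula", {
  expect_equal(spearman_cs(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_cs(1:4, 4:1), -1)
  expect_equal(spearman_cs(1:4, c(1, 2, 4, 3)), 0.8)
  expect_equal(spearman_cs(c(2, 0, 0, 2), c(5, 1, 1, 5)), 1)
  expect_true(is.na(spearman_cs(c(1, 1, 1, 1), 1:4)))
  expect_error(spearman_cs(1:3, 1:4), class = "dynachip_input_error")

  # exhaustively over all 24 permutations of 4 distinct values the
  # statistic matches the brute-force formula and fills the 0.2 lattice
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  vals <- apply(perms, 1, function(p) {
    cs <- spearman_cs(1:4, p)
    expect_equal(cs, oracle_spearman(1:4, p), tolerance = 1e-12)
    cs
  })
  expect_setequal(round(sort(unique(vals)), 10),
                  round(seq(-1, 1, by = 0.2), 10))
})

test_that("profile scaling standardizes and flags constants", {
  m <- rbind(g1 = c(2, 0, 0, 2), g2 = c(1, 1, 1, 1))
  s <- scale_profiles(long_profiles(m))
  g1 <- s$scaled[s$gene_id == "g1"]
  expect_equal(mean(g1), 0, tolerance = 1e-9)
  expect_equal(sd(g1), 1, tolerance = 1e-9)
  expect_true(all(s$scaled[s$gene_id == "g2"] == 0))
  expect_true(all(s$constant[s$gene_id == "g2"]))
})

test_that("complete-linkage clustering matches the exhaustive oracle", {
  # four archetype profiles x 10 exact copies: pure clusters
  tps <- c(0, 10, 20, 60)
  arch <- rbind(c(2, 0, 0, 0), c(2, 0, 0, 2), c(0, 1.4, 1.7, 2),
                c(1.8, 0.3, 2, 0.2))
  m <- arch[rep(1:4, each = 10), ]
  rownames(m) <- sprintf("g%02d", 1:40)
  cl <- cluster_profiles(long_profiles(m), k = 4)
  truth <- rep(1:4, each = 10)
  purity <- sum(vapply(split(truth, cl$cluster), function(x)
    max(table(x)), numeric(1))) / 40
  expect_equal(purity, 1)
  # archetype matching: cluster numbers recover the archetype order
  expect_equal(cl$cluster, truth)

  # n = 5: agreement with the exhaustive merge oracle
  set.seed(42)
  for (rep_i in 1:5) {
    m5 <- matrix(rnorm(20), 5, dimnames = list(sprintf("g%d", 1:5), NULL))
    d <- 1 - cor(t(m5), method = "spearman")
    oracle <- oracle_complete_linkage(d, 2)
    cl5 <- cluster_profiles(long_profiles(m5), k = 2)
    expect_true(same_partition(cl5$raw_cluster[match(sprintf("g%d", 1:5),
                                                     cl5$gene_id)],
                               oracle))
  }

  # identical profiles merge first, at height zero
  m2 <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1),
              d = c(2, 1, 4, 3), e = c(3, 4, 1, 2))
  cl2 <- cluster_profiles(long_profiles(m2), k = 4)
  expect_equal(cl2$cluster[cl2$gene_id == "a"],
               cl2$cluster[cl2$gene_id == "b"])

  expect_error(cluster_profiles(long_profiles(m2[1:3, ]), k = 4),
               class = "dynachip_input_error")
})

test_that("clustering and correlations are rank-invariant to scaling", {
  set.seed(7)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("g%d", 1:10), NULL))
  prof <- long_profiles(m)
  scaled <- scale_profiles(prof) |>
    dplyr::rename(intensity = scaled)
  cl_raw <- cluster_profiles(prof, k = 3)
  cl_scaled <- cluster_profiles(scaled, k = 3)
  expect_true(same_partition(cl_raw$raw_cluster, cl_scaled$raw_cluster))
})

test_that("binding-expression correlation joins genes and genotypes", {
  prof <- long_profiles(rbind(gA = c(2, 0, 0, 2)))
  expr <- tibble::tibble(gene_id = "gA", timepoint_min = c(0, 10, 20, 60),
                         replicate = 1, expression = c(5, 1, 1, 5))
  cs <- ge_chip_correlate(prof, expr)
  expect_equal(cs$cs, 1)
  # replicates are averaged before correlating
  expr2 <- dplyr::bind_rows(expr,
                            dplyr::mutate(expr, replicate = 2,
                                          expression = expression + 0.4))
  expect_equal(ge_chip_correlate(prof, expr2)$cs, 1)
  # genes without expression are flagged
  prof2 <- long_profiles(rbind(gA = c(2, 0, 0, 2), gB = c(1, 2, 3, 4)))
  cs2 <- ge_chip_correlate(prof2, expr)
  expect_equal(attr(cs2, "missing_expression"), "gB")
})

test_that("regulation calls use inclusive +/-0.6 thresholds", {
  cs_p <- tibble::tibble(gene_id = c("a", "b", "c", "d", "e"),
                         cs = c(0.6, -0.6, 0.4, 0.95, NA))
  calls <- call_regulation(cs_p)
  expect_equal(calls$label, c("activated", "repressed", "unclassified",
                              "activated", "unclassified"))
})

test_that("genotype comparison detects decoupling of the knockout", {
  # identical distributions: t = 0, p = 1
  calls <- tibble::tibble(gene_id = sprintf("g%d", 1:5),
                          cs_parent = c(0.7, 0.8, 0.9, 0.75, 0.85),
                          cs_knockout = c(0.7, 0.8, 0.9, 0.75, 0.85),
                          label = "activated")
  same <- compare_genotype_correlations(calls, "correlated")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # planted decoupling: parent ~ 0.9, knockout ~ 0 (n = 50) rejects hard
  set.seed(13)
  calls2 <- tibble::tibble(
    gene_id = sprintf("g%d", 1:50),
    cs_parent = pmin(rnorm(50, 0.9, 0.05), 1),
    cs_knockout = pmax(pmin(rnorm(50, 0, 0.2), 1), -1),
    label = "activated")
  strong <- compare_genotype_correlations(calls2, "correlated")
  expect_lt(strong$p, 1e-6)

  # degenerate group size is reported as not testable
  one <- calls2[1, ]
  nt <- compare_genotype_correlations(one, "correlated")
  expect_true(is.na(nt$p))
  expect_equal(nt$n, 1)
  # empty side likewise
  none <- compare_genotype_correlations(calls2, "anticorrelated")
  expect_true(is.na(none$p))
})
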