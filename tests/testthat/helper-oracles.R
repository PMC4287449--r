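# Independent oracles used by the tests.  These deliberately re-derive
# results by brute force or closed form, without touching the package's
# implementation paths.

# Fisher combination via the closed-form chi-square survival function
# written out directly (for k = 2: exp(-x/2) * (1 + x/2)).
oracle_fisher2 <- function(p1, p2) {
  x <- -2 * (log(p1) + log(p2))
  exp(-x / 2) * (1 + x / 2)
}

# Spearman via the textbook rank formula on average ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exhaustive greedy complete-linkage agglomeration for a small
# dissimilarity matrix; ties broken by the lowest member indices.
# Returns the cluster labels at k clusters.
oracle_complete_linkage <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1] - 1e-12) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    clusters[[j]] <- NULL
  }
  labels <- integer(n)
  for (c in seq_along(clusters)) labels[clusters[[c]]] <- c
  labels
}

# Upper-tail hypergeometric probability by direct enumeration with
# binomial coefficients.
oracle_hypergeom <- function(overlap, set_a, set_b, universe) {
  ks <- overlap:min(set_a, set_b)
  sum(choose(set_a, ks) * choose(universe - set_a, set_b - ks)) /
    choose(universe, set_b)
}

# Quantile normalization as the mean of order statistics, ties receiving
# the mean of their target quantiles.
oracle_quantile_normalize <- function(mat) {
  target <- rowMeans(apply(mat, 2, sort))
  apply(mat, 2, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_len(length(target)), target, xout = r)$y
  })
}

# Best width-w gapless alignment (one site per sequence, forward strand)
# by exhaustive enumeration, maximizing summed information content.
oracle_best_alignment <- function(seqs, w) {
  starts <- lapply(seqs, function(s) seq_len(nchar(s) - w + 1))
  grid <- expand.grid(starts)
  best <- list(score = -Inf)
  for (g in seq_len(nrow(grid))) {
    words <- vapply(seq_along(seqs), function(i) {
      substr(seqs[i], grid[g, i], grid[g, i] + w - 1)
    }, character(1))
    mat <- do.call(rbind, strsplit(words, ""))
    score <- sum(apply(mat, 2, function(col) {
      p <- table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)
      2 + sum(ifelse(p > 0, p * log2(p), 0))
    }))
    if (score > best$score) {
      best <- list(score = score, words = words)
    }
  }
  mat <- do.call(rbind, strsplit(best$words, ""))
  consensus <- apply(mat, 2, function(col) {
    names(which.max(table(col)))
  })
  list(score = best$score, consensus = paste(consensus, collapse = ""))
}

# Partition agreement up to relabelling.
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# A zero-entropy PWM built from a consensus, for scanning/significance
# tests that need a known motif.
new_pwm_for_test <- function(consensus, bg = rep(0.25, 4)) {
  probs <- generator_pwm(consensus, concentration = 0.97)
  names(bg) <- c("A", "C", "G", "T")
  structure(list(probs = probs, background = bg, consensus = consensus,
                 information = rep(1, ncol(probs)), width = ncol(probs),
                 n_sites = 1, loglik = 0, gamma = 0.01),
            class = "dynachip_pwm")
}

# A small synthetic study shared by several tests.
small_config <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 60000, n_genes = 40, n_planted_sites = 12,
         n_bio_replicates = 1, n_probe_replicates = 2, seed = 7),
    list(...))
  do.call(synthetic_config, args)
}
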