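test_that("search windows are centered, clipped and strand-complete", {
  sequence <- c(chr = paste(rep("ACGT", 2500), collapse = ""))
  loci <- tibble::tibble(replicon = "chr", center = c(5000, 100, 9900))
  w <- extract_search_windows(loci, sequence, flank = 250)
  expect_equal(w$start, c(4750, 0, 9650))
  expect_equal(w$end, c(5251, 351, 10000))
  expect_equal(nchar(w$seq), w$end - w$start)
  expect_equal(nchar(w$seq[1]), 501)
  expect_error(extract_search_windows(
    tibble::tibble(replicon = "chr", center = 10001), sequence),
    class = "dynachip_input_error")
})

test_that("the tiny planted word matches the exhaustive alignment oracle", {
  seqs <- c("ACGTGGCCAAT", "GGACGTCCTTA", "TTGACGTAGG", "CCTACGTAGA",
            "AGGACGTTCC")
  found <- discover_motif(seqs, width = 4)
  oracle <- oracle_best_alignment(seqs, 4)
  expect_equal(found[[1]]$consensus, oracle$consensus)
  expect_equal(found[[1]]$consensus, "ACGT")
})

test_that("planted palindrome implants are recovered from synthetic promoters", {
  cfg <- synthetic_config(n_planted_sites = 60, n_genes = 100,
                          genome_length = 150000,
                          motif_implant_fraction = 40 / 60,
                          motif_concentration = 1, seed = 11)
  g <- generate_genome(cfg)
  truth <- plant_dynamics(cfg, g)
  pm <- plant_motifs(truth, g$sequence, cfg)
  loci <- dplyr::distinct(pm$truth[, c("replicon", "center")])
  windows <- extract_search_windows(loci, pm$sequence, flank = 250)
  motifs <- discover_motif(windows, width = 20)
  top <- motifs[[1]]

  # EM objective is non-decreasing across iterations
  expect_true(all(diff(top$loglik) >= -1e-9))

  # consensus equals the generator at every constrained position
  gen <- strsplit(cfg$motif_consensus, "")[[1]]
  match_frac <- max(
    mean(strsplit(top$consensus, "")[[1]][gen != "N"] == gen[gen != "N"]),
    mean(strsplit(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(toupper(top$consensus)))), "")[[1]][gen != "N"] ==
        gen[gen != "N"]))
  expect_equal(match_frac, 1)

  # windows of i.i.d. bases carry less information than the planted case
  set.seed(2)
  random_w <- vapply(seq_len(40), function(i) {
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
          collapse = "")
  }, character(1))
  rand <- discover_motif(random_w, width = 20)
  expect_lt(sum(rand[[1]]$information), sum(top$information))

  # shuffled-sequence Wilcoxon significance of the planted motif
  sig <- motif_significance(top, windows, seed = 5)
  expect_lt(sig$p, 0.01)
})

test_that("discovery is symmetric under reverse-complementing the input", {
  cfg <- synthetic_config(n_planted_sites = 30, n_genes = 60,
                          genome_length = 100000,
                          motif_implant_fraction = 1,
                          motif_concentration = 1, seed = 19)
  g <- generate_genome(cfg)
  truth <- plant_dynamics(cfg, g)
  pm <- plant_motifs(truth, g$sequence, cfg)
  loci <- dplyr::distinct(pm$truth[, c("replicon", "center")])
  windows <- extract_search_windows(loci, pm$sequence, flank = 100)
  fwd <- discover_motif(windows, width = 20)[[1]]
  rc_seqs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(windows$seq)))
  rev <- discover_motif(rc_seqs, width = 20)[[1]]
  expect_equal(sum(fwd$information) * fwd$n_sites,
               sum(rev$information) * rev$n_sites, tolerance = 0.05)
})

test_that("motif significance has exact behavior in degenerate cases", {
  pwm <- new_pwm_for_test("CCGG")
  # single-base sequences are invariant under shuffling: all diffs 0, p = 1
  mono <- rep(paste(rep("A", 30), collapse = ""), 6)
  expect_equal(motif_significance(pwm, mono, seed = 1)$p, 1)

  # eight all-positive paired differences give the exact tail 1 / 2^8
  set.seed(3)
  strong <- vapply(seq_len(8), function(i) {
    paste0("CCGGCCGGCCGG", paste(sample(c("A", "T"), 24, replace = TRUE),
                                 collapse = ""))
  }, character(1))
  res <- motif_significance(pwm, strong, seed = 4)
  expect_equal(res$p, 1 / 2^8, tolerance = 1e-12)

  expect_error(motif_significance(pwm, strong, n_shuffles = 0),
               class = "dynachip_input_error")
})

test_that("genome scanning reports occurrences with signed gene distances", {
  pwm <- new_pwm_for_test("ACGCGT")
  arms <- paste(rep("A", 100), collapse = "")
  # plant at positions 100..105 (0-based), gene start at 123 on + strand
  sequence <- c(chr = paste0(arms, "ACGCGT", paste(rep("A", 94),
                                                   collapse = "")))
  ann <- tibble::tibble(gene_id = "g1", replicon = "chr", strand = "+",
                        translation_start = 123)
  hits <- scan_genome(pwm, sequence, ann, score_threshold = 5)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$start, 100)
  expect_equal(plus$gene_id, "g1")
  expect_equal(plus$dist_to_start, 100 + 3 - 123)  # 20 bp upstream -> -20
  # the planted word is its own reverse complement: the minus strand hit
  # has the same midpoint
  minus <- hits[hits$strand == "-", ]
  expect_equal(minus$midpoint, plus$midpoint)

  # threshold -Inf returns every position on both strands
  all_hits <- scan_genome(pwm, sequence, score_threshold = -Inf)
  expect_equal(nrow(all_hits), unname(2 * (nchar(sequence) - 6 + 1)))
})

test_that("palindromicity counts complementary mirrored positions", {
  expect_equal(palindromicity("ACGT"), 1)
  expect_equal(palindromicity("AAAA"), 0)
  # direct position-by-position oracle for the imperfect palindrome
  s <- "TCGNCGACGAGNTCGNCGAC"
  letters <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  w <- length(letters)
  oracle <- mean(vapply(seq_len(w), function(i) {
    a <- letters[i]; b <- letters[w - i + 1]
    a == "N" || b == "N" || comp[a] == b
  }, logical(1)))
  expect_equal(palindromicity(s), oracle)
  expect_lt(palindromicity(s), 1)
  # a perfectly palindromic PWM scores 1
  pwm <- new_pwm_for_test("ACGCGT")
  expect_equal(palindromicity(pwm), 1, tolerance = 1e-9)
})
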