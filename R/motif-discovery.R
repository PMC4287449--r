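DNA_BASES <- c("A", "C", "G", "T")

# encode a sequence string as integer codes 1..4 (NA for anything else)
encode_dna <- function(x) {
  match(strsplit(toupper(x), "")[[1]], DNA_BASES)
}

# reverse-complement of a code vector
rc_codes <- function(codes) {
  rev(5L - codes)
}

#' Extract search windows around binding loci
#'
#' Windows of `2 * flank + 1` bp centered on each locus, clipped at the
#' replicon ends. Both strands are searched downstream, so only the forward
#' sequence is stored.
#'
#' @param loci Tibble with columns replicon, center (0-based bp).
#' @param sequence Named character vector of replicon sequences.
#' @param flank Flank size in bp (default 250).
#' @return Tibble: locus_id, replicon, center, start, end (0-based
#'   half-open), seq.
#' @export
extract_search_windows <- function(loci, sequence, flank = 250) {
  lens <- nchar(sequence)
  if (any(loci$center < 0 | loci$center >= lens[loci$replicon])) {
    stop_dynachip("locus outside its replicon", "dynachip_input_error")
  }
  loci |>
    dplyr::mutate(
      locus_id = sprintf("locus%03d", dplyr::row_number()),
      start = pmax(0, .data$center - flank),
      end = pmin(unname(lens[.data$replicon]), .data$center + flank + 1),
      seq = unname(substr(sequence[.data$replicon], .data$start + 1,
                          .data$end))
    ) |>
    dplyr::select("locus_id", "replicon", "center", "start", "end", "seq")
}

# stack every width-w subsequence of every window (both strands) into an
# integer matrix; meta records (window, offset, strand) per row
stack_sites <- function(seqs, width) {
  seqs <- unname(seqs)
  pieces <- purrr::map(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    codes <- encode_dna(s)
    L <- length(codes)
    if (L < width) return(NULL)
    idx <- outer(seq_len(L - width + 1) - 1L, seq_len(width), "+")
    fwd <- matrix(codes[idx], nrow(idx), width)
    rev <- matrix(rc_codes(codes)[idx], nrow(idx), width)
    m <- rbind(fwd, rev)
    offs <- seq_len(L - width + 1) - 1L
    meta <- tibble::tibble(
      window = i,
      offset = rep(offs, 2),
      strand = rep(c("+", "-"), each = nrow(idx)),
      # start of the site on the forward strand, so overlaps between the
      # two orientations of the same stretch can be recognized
      fwd_start = c(offs, L - offs - width))
    ok <- stats::complete.cases(m)
    m <- m[ok, , drop = FALSE]
    meta <- meta[ok, ]
    # content key: deterministic tie-breaking that does not depend on
    # window orientation or row order
    meta$rowkey <- as.vector((m - 1) %*% 4^(seq_len(width) - 1))
    list(m = m, meta = meta)
  })
  pieces <- purrr::compact(pieces)
  list(m = do.call(rbind, purrr::map(pieces, "m")),
       meta = purrr::list_rbind(purrr::map(pieces, "meta")))
}

# log-likelihood ratio of each stacked site under theta vs background
site_llr <- function(m, theta, log_bg) {
  w <- ncol(m)
  lt <- log(theta)
  acc <- numeric(nrow(m))
  for (j in seq_len(w)) {
    acc <- acc + lt[cbind(m[, j], j)] - log_bg[m[, j]]
  }
  acc
}

# one evaluation of the ANR mixture log-likelihood (up to the constant
# background term, which is shared by all candidate models)
anr_loglik <- function(llr, gamma) {
  sum(log((1 - gamma) + gamma * exp(pmin(llr, 700))))
}

# suppress overlapping site responsibilities: within each (window, strand)
# only the local-maximum z within a motif width survives.  This keeps the
# any-number-of-repeats model from blending phase-shifted alignments of
# internally repetitive (palindromic) motifs.
suppress_overlaps <- function(z, offsets, rowkeys, groups, width) {
  zm <- z
  for (idx in groups) {
    zz <- z[idx]
    off <- offsets[idx]
    # ties (saturated responsibilities) break on the site's own sequence
    # content, which is invariant to window orientation and row order
    ord <- order(-zz, rowkeys[idx], off)
    taken <- logical(length(idx))
    suppressed <- logical(length(idx))
    for (i in ord) {
      if (suppressed[i]) next
      taken[i] <- TRUE
      suppressed[abs(off - off[i]) < width & !taken] <- TRUE
    }
    zm[idx][!taken] <- 0
  }
  zm
}

# ANR expectation-maximization with overlap suppression, from a fixed
# start.  The mixture log-likelihood is evaluated each iteration and the
# run stops (at the previous parameters) as soon as it fails to improve,
# so the recorded trace is non-decreasing.
em_anr <- function(m, bg, theta0, gamma0, meta, max_iter = 100, tol = 1e-6,
                   pseudo = 0.25) {
  log_bg <- log(bg)
  theta <- theta0
  gamma <- gamma0
  groups <- split(seq_len(nrow(meta)), meta$window)
  ll_trace <- numeric(0)
  state <- NULL
  for (iter in seq_len(max_iter)) {
    llr <- site_llr(m, theta, log_bg)
    odds <- gamma / (1 - gamma) * exp(pmin(llr, 700))
    z <- suppress_overlaps(odds / (1 + odds), meta$fwd_start, meta$rowkey,
                           groups, ncol(m))
    ll <- anr_loglik(llr, gamma)
    if (iter > 1 && ll < ll_trace[iter - 1]) break  # objective dipped: stop
    ll_trace <- c(ll_trace, ll)
    state <- list(theta = theta, gamma = gamma, z = z)
    if (iter > 1 && ll - ll_trace[iter - 1] < tol) break
    # M-step on the suppressed responsibilities
    for (j in seq_len(ncol(m))) {
      counts <- vapply(1:4, function(a) sum(z[m[, j] == a]), numeric(1))
      counts <- counts + pseudo * bg * 4
      theta[, j] <- counts / sum(counts)
    }
    gamma <- min(max(mean(z), 1e-6), 0.5)
  }
  c(state, list(loglik = ll_trace))
}

# total information content in bits relative to the background model
pwm_ic_bg <- function(theta, bg) {
  sum(apply(theta, 2, function(p) sum(ifelse(p > 0, p * log2(p / bg), 0))))
}

# MEME-style column shifting: realign the claimed sites by a small global
# offset and keep the phase with the highest background-relative
# information, which resolves the alignment ambiguity of internally
# repetitive motifs
refine_shift <- function(fit, m, meta, bg, max_shift = 5, pseudo = 0.25) {
  sites <- which(fit$z > 0.5)
  if (length(sites) < 2) return(fit)
  key_all <- paste(meta$window, meta$offset, meta$strand)
  zz <- fit$z[sites]
  best <- list(score = -Inf, shift = 0L)
  for (s in -max_shift:max_shift) {
    rows <- match(paste(meta$window[sites], meta$offset[sites] + s,
                        meta$strand[sites]), key_all)
    ok <- !is.na(rows)
    if (sum(ok) < 2) next
    mm <- m[rows[ok], , drop = FALSE]
    zk <- zz[ok]
    theta <- fit$theta
    for (j in seq_len(ncol(m))) {
      counts <- vapply(1:4, function(a) sum(zk[mm[, j] == a]), numeric(1))
      counts <- counts + pseudo * bg * 4
      theta[, j] <- counts / sum(counts)
    }
    score <- pwm_ic_bg(theta, bg) * sum(zk)
    if (score > best$score + 1e-9 ||
        (score > best$score - 1e-9 && abs(s) < abs(best$shift))) {
      best <- list(score = score, shift = s, theta = theta)
    }
  }
  if (best$shift == 0L || is.null(best$theta)) return(fit)
  # one E-step under the refined matrix for responsibilities and gamma
  llr <- site_llr(m, best$theta, log(bg))
  odds <- fit$gamma / (1 - fit$gamma) * exp(pmin(llr, 700))
  groups <- split(seq_len(nrow(meta)), meta$window)
  z <- suppress_overlaps(odds / (1 + odds), meta$fwd_start, meta$rowkey,
                         groups, ncol(m))
  list(theta = best$theta, gamma = min(max(mean(z), 1e-6), 0.5), z = z,
       loglik = fit$loglik)
}

pwm_consensus <- function(theta) {
  paste(vapply(seq_len(ncol(theta)), function(j) {
    a <- which.max(theta[, j])
    if (theta[a, j] < 0.5) "n" else DNA_BASES[a]
  }, character(1)), collapse = "")
}

pwm_information <- function(theta) {
  # bits per column relative to a uniform background
  apply(theta, 2, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0)))
}

new_pwm <- function(theta, bg, n_sites, loglik, gamma) {
  rownames(theta) <- DNA_BASES
  structure(list(probs = theta, background = bg,
                 consensus = pwm_consensus(theta),
                 information = pwm_information(theta),
                 width = ncol(theta), n_sites = n_sites,
                 loglik = loglik, gamma = gamma),
            class = "dynachip_pwm")
}

#' @export
print.dynachip_pwm <- function(x, ...) {
  cat("<dynachip PWM>", x$width, "bp, consensus", x$consensus, "\n")
  cat("  information:", round(sum(x$information), 1), "bits total;",
      "expected sites:", round(x$n_sites, 1), "\n")
  invisible(x)
}

# count exact k-mers (both strands) across encoded windows; returns a
# tibble kmer_id, codes (list), count, enrichment over background
seed_kmers <- function(codes_list, k, bg) {
  pow <- 4^(seq_len(k) - 1)
  ids <- purrr::map(codes_list, function(codes) {
    out <- integer(0)
    for (cc in list(codes, rc_codes(codes))) {
      L <- length(cc)
      if (L < k) next
      idx <- outer(seq_len(L - k + 1) - 1L, seq_len(k), "+")
      mm <- matrix(cc[idx], nrow(idx), k)
      ok <- stats::complete.cases(mm)
      out <- c(out, as.integer((mm[ok, , drop = FALSE] - 1L) %*% pow))
    }
    out
  })
  all_ids <- unlist(ids)
  tab <- table(all_ids)
  kmer_id <- as.integer(names(tab))
  decode <- function(id) {
    (id %/% pow) %% 4 + 1
  }
  codes <- lapply(kmer_id, decode)
  expected <- length(all_ids) *
    vapply(codes, function(cd) prod(bg[cd]), numeric(1))
  count <- as.integer(tab)
  # Poisson surprise, not a ratio: guards against rare words that appear
  # once or twice by chance in a skewed-composition background
  surprise <- -stats::ppois(count - 1L, expected, lower.tail = FALSE,
                            log.p = TRUE)
  tibble::tibble(kmer_id = kmer_id, codes = codes, count = count,
                 expected = expected, surprise = surprise)
}

#' De novo motif discovery by any-number-of-repeats EM
#'
#' Fits a two-component (motif / background) mixture over every
#' fixed-width subsequence of the input windows on both strands, with an
#' any-number-of-occurrences prior on sites. Starts are seeded from
#' enumerated high-frequency words (background-corrected k-mer counts),
#' each tried at every offset within the motif window; the best starts by
#' one-step likelihood are run to convergence and motifs are ranked by
#' total information content times expected site count. Additional motifs
#' are found after masking the sites claimed by earlier ones. The whole
#' procedure is deterministic.
#'
#' @param windows Tibble from [extract_search_windows()] (or a character
#'   vector of sequences).
#' @param width Motif width in bp (<= 20 by convention here).
#' @param n_motifs Number of motifs to report.
#' @param n_seeds Seed words tried per motif.
#' @param n_starts EM runs per motif (best starts kept).
#' @param max_iter EM iteration cap.
#' @return A list of `dynachip_pwm` objects, ranked.
#' @export
discover_motif <- function(windows, width = 20, n_motifs = 1, n_seeds = 8,
                           n_starts = 3, max_iter = 100) {
  seqs <- if (is.data.frame(windows)) windows$seq else windows
  if (length(seqs) < 5) {
    stop_dynachip("motif discovery needs >= 5 windows",
                  "dynachip_input_error")
  }
  short <- nchar(seqs) < width
  if (any(short)) {
    rlang::warn(sprintf("%d window(s) shorter than the motif width skipped",
                        sum(short)))
    seqs <- seqs[!short]
  }
  codes_list <- lapply(seqs, encode_dna)
  all_codes <- unlist(codes_list)
  all_codes <- c(all_codes, 5L - all_codes)  # strand-symmetric background
  bg <- as.vector(table(factor(all_codes, levels = 1:4)))
  bg <- pmax(bg, 1) / sum(pmax(bg, 1))
  names(bg) <- DNA_BASES

  stacked <- stack_sites(seqs, width)
  m <- stacked$m
  if (is.null(m) || nrow(m) == 0) {
    stop_dynachip("no scorable positions at this motif width",
                  "dynachip_input_error")
  }

  k <- min(7L, width)
  motifs <- list()
  active <- rep(TRUE, nrow(m))
  for (mi in seq_len(n_motifs)) {
    m_act <- m[active, , drop = FALSE]
    meta_act <- stacked$meta[active, ]
    if (nrow(m_act) < 10) break
    # seed words: count on the original windows for the first motif, on the
    # still-active subsequences afterwards
    seed_src <- if (mi == 1) codes_list else
      lapply(seq_len(nrow(m_act)), function(i) m_act[i, ])
    seeds <- seed_kmers(seed_src, k, bg)
    seeds <- seeds[order(-(seeds$count >= 2), -seeds$surprise,
                         seeds$kmer_id), ]
    seeds <- utils::head(seeds, n_seeds)

    gamma0 <- min(0.25, length(seqs) / nrow(m_act))
    log_bg <- log(bg)
    starts <- list()
    for (si in seq_len(nrow(seeds))) {
      for (off in 0:(width - k)) {
        theta0 <- matrix(bg, 4, width)
        for (j in seq_len(k)) {
          theta0[, off + j] <- 0.18 / 3
          theta0[seeds$codes[[si]][j], off + j] <- 0.82
        }
        llr <- site_llr(m_act, theta0, log_bg)
        starts[[length(starts) + 1]] <-
          list(theta0 = theta0, ll = anr_loglik(llr, gamma0))
      }
    }
    if (!length(starts)) break
    lls <- vapply(starts, function(s) s$ll, numeric(1))
    top <- order(-lls)[seq_len(min(n_starts, length(starts)))]
    fits <- lapply(starts[top], function(s) {
      em_anr(m_act, bg, s$theta0, gamma0, meta_act, max_iter = max_iter)
    })
    # choose among converged runs by mixture likelihood (background term is
    # common to all candidates on the same data)
    obj <- vapply(fits, function(f) utils::tail(f$loglik, 1), numeric(1))
    best <- fits[[which.max(obj)]]
    best <- refine_shift(best, m_act, meta_act, bg)
    motifs[[mi]] <- new_pwm(best$theta, bg, n_sites = sum(best$z),
                            loglik = best$loglik, gamma = best$gamma)
    # mask rows claimed by this motif before searching for the next
    claimed <- rep(FALSE, nrow(m))
    claimed[which(active)[best$z > 0.5]] <- TRUE
    active <- active & !claimed
  }
  if (!length(motifs)) {
    rlang::warn("no motif could be fitted (degenerate input)")
  }
  motifs
}

# best log-odds score of a PWM anywhere in one sequence (both strands)
best_window_score <- function(pwm, codes) {
  lo <- log2(pwm$probs / pwm$background)
  w <- pwm$width
  best <- -Inf
  for (cc in list(codes, rc_codes(codes))) {
    L <- length(cc)
    if (L < w) next
    s <- numeric(L - w + 1)
    for (j in seq_len(w)) {
      v <- lo[cbind(cc[seq_len(L - w + 1) + j - 1L], j)]
      v[is.na(v)] <- -Inf
      s <- s + v
    }
    if (length(s)) best <- max(best, max(s))
  }
  best
}

#' Wilcoxon signed-rank significance of a motif
#'
#' Compares each window's best motif log-odds score against the best score
#' in a mononucleotide-shuffled copy of the same window (composition
#' preserved per window), with a one-sided paired Wilcoxon signed-rank
#' test (actual greater).
#'
#' @param pwm A `dynachip_pwm`.
#' @param windows Window tibble or character vector of sequences.
#' @param n_shuffles Shuffled copies per window (scores averaged).
#' @param seed Integer seed for the shuffles.
#' @return Tibble p, n, median_actual, median_shuffled.
#' @export
motif_significance <- function(pwm, windows, n_shuffles = 1, seed = 1L) {
  seqs <- if (is.data.frame(windows)) windows$seq else windows
  if (n_shuffles < 1) {
    stop_dynachip("n_shuffles must be >= 1", "dynachip_input_error")
  }
  set.seed(as.integer(seed))
  actual <- vapply(seqs, function(s) best_window_score(pwm, encode_dna(s)),
                   numeric(1), USE.NAMES = FALSE)
  shuffled <- vapply(seqs, function(s) {
    codes <- encode_dna(s)
    mean(vapply(seq_len(n_shuffles), function(i) {
      best_window_score(pwm, sample(codes))
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  keep <- is.finite(actual) & is.finite(shuffled)
  d <- actual[keep] - shuffled[keep]
  d <- d[d != 0]
  if (length(d) == 0) {
    p <- 1
  } else if (length(d) <= 15) {
    # exact signed-rank tail by enumerating all sign assignments (handles
    # tied |differences| that the asymptotic test only approximates)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    w_null <- as.vector(signs %*% r)
    p <- mean(w_null >= w_obs - 1e-9)
  } else {
    p <- stats::wilcox.test(actual[keep], shuffled[keep], paired = TRUE,
                            alternative = "greater")$p.value
  }
  tibble::tibble(p = p, n = sum(keep),
                 median_actual = stats::median(actual[keep]),
                 median_shuffled = stats::median(shuffled[keep]))
}

#' Scan a genome for motif occurrences
#'
#' Scores every position on both strands and reports occurrences whose
#' log-odds score meets `score_threshold`, annotated with the signed
#' distance from the occurrence midpoint to the nearest gene's translation
#' start (negative = upstream with respect to the gene's strand).
#'
#' @param pwm A `dynachip_pwm`.
#' @param sequence Named character vector of replicon sequences.
#' @param annotation Gene tibble (gene_id, replicon, strand,
#'   translation_start); optional.
#' @param score_threshold Minimum log-odds score.
#' @return Tibble: replicon, start (0-based), strand, score, midpoint,
#'   gene_id, dist_to_start; mean absolute distance attached as attribute
#'   `"mean_abs_dist"`.
#' @export
scan_genome <- function(pwm, sequence, annotation = NULL,
                        score_threshold = 0) {
  lo <- log2(pwm$probs / pwm$background)
  w <- pwm$width
  hits <- purrr::imap(as.list(sequence), function(s, repl) {
    codes <- encode_dna(s)
    L <- length(codes)
    if (L < w) return(NULL)
    per_strand <- function(cc, strand) {
      n_pos <- L - w + 1
      sc <- numeric(n_pos)
      for (j in seq_len(w)) {
        v <- lo[cbind(cc[seq_len(n_pos) + j - 1L], j)]
        v[is.na(v)] <- -Inf
        sc <- sc + v
      }
      pos <- which(sc >= score_threshold)
      if (!length(pos)) return(NULL)
      start <- if (strand == "+") pos - 1L else L - (pos - 1L) - w
      tibble::tibble(replicon = repl, start = start, strand = strand,
                     score = sc[pos])
    }
    dplyr::bind_rows(per_strand(codes, "+"),
                     per_strand(rc_codes(codes), "-"))
  }) |> purrr::list_rbind()

  if (nrow(hits) == 0) {
    out <- dplyr::mutate(hits, midpoint = numeric(0),
                         gene_id = character(0), dist_to_start = numeric(0))
    attr(out, "mean_abs_dist") <- NA_real_
    return(out)
  }
  hits <- dplyr::mutate(hits, midpoint = .data$start + w / 2)
  if (!is.null(annotation) && nrow(annotation) > 0) {
    nearest <- purrr::pmap(hits[, c("replicon", "midpoint")],
                           function(replicon, midpoint) {
      ann <- annotation[annotation$replicon == replicon, ]
      if (nrow(ann) == 0) {
        return(tibble::tibble(gene_id = NA_character_,
                              dist_to_start = NA_real_))
      }
      d_raw <- midpoint - ann$translation_start
      d_signed <- ifelse(ann$strand == "+", d_raw, -d_raw)
      i <- which.min(abs(d_raw))
      tibble::tibble(gene_id = ann$gene_id[i], dist_to_start = d_signed[i])
    }) |> purrr::list_rbind()
    hits <- dplyr::bind_cols(hits, nearest)
  } else {
    hits$gene_id <- NA_character_
    hits$dist_to_start <- NA_real_
  }
  attr(hits, "mean_abs_dist") <- mean(abs(hits$dist_to_start), na.rm = TRUE)
  hits
}

#' Palindromicity of a motif or sequence
#'
#' For a string: the fraction of positions whose base complements the base
#' at the mirrored position (`n` is a wildcard and always matches). For a
#' PWM: the mean over positions of the probability mass shared between a
#' column and the complemented mirrored column.
#'
#' @param x A character string or a `dynachip_pwm`.
#' @return A fraction in \[0, 1\].
#' @export
palindromicity <- function(x) {
  if (inherits(x, "dynachip_pwm")) {
    theta <- x$probs
    w <- ncol(theta)
    agree <- vapply(seq_len(w), function(j) {
      q <- rev(theta[, w - j + 1])  # complemented mirrored column
      sum(pmin(theta[, j], q))
    }, numeric(1))
    return(mean(agree))
  }
  s <- strsplit(toupper(x), "")[[1]]
  w <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- vapply(seq_len(w), function(i) {
    a <- s[i]
    b <- s[w - i + 1]
    a == "N" || b == "N" || (!is.na(comp[a]) && comp[a] == b)
  }, logical(1))
  mean(hits)
}
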