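#' Read / write probe tables
#'
#' Plain TSV with columns replicon, coord, replicate, timepoint_min,
#' log2ratio (coordinates 0-based probe centers).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_probe_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_probe_tsv
#' @param x Probe tibble.
#' @export
write_probe_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Write an annotation as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 is written 1-based
#' inclusive.
#'
#' @param annotation Annotation tibble (gene_id, replicon, start, end,
#'   strand).
#' @param path Output path.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- GenomicRanges::GRanges(
      seqnames = annotation$replicon,
      ranges = IRanges::IRanges(start = annotation$start + 1,
                                end = annotation$end),
      strand = annotation$strand)
    gr$type <- "gene"
    gr$ID <- annotation$gene_id
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    lines <- sprintf("%s\tdynachip\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     annotation$replicon, annotation$start + 1,
                     annotation$end, annotation$strand, annotation$gene_id)
    writeLines(c("##gff-version 3", lines), path)
  }
  invisible(path)
}

#' Read a GFF3 gene annotation into the internal tibble form
#'
#' @param path GFF3 path.
#' @return Annotation tibble with 0-based half-open coordinates and the
#'   translation_start column derived from strand.
#' @export
read_annotation_gff3 <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    ann <- tibble::tibble(
      gene_id = as.character(gr$ID),
      replicon = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)))
  } else {
    raw <- readr::read_tsv(path, comment = "#", col_names = c(
      "replicon", "source", "type", "start1", "end1", "score", "strand",
      "phase", "attributes"), show_col_types = FALSE)
    ann <- raw |>
      dplyr::filter(.data$type == "gene") |>
      dplyr::mutate(gene_id = sub(".*ID=([^;]+).*", "\\1",
                                  .data$attributes),
                    start = .data$start1 - 1L, end = .data$end1) |>
      dplyr::select("gene_id", "replicon", "start", "end", "strand")
  }
  dplyr::mutate(ann,
                translation_start = ifelse(.data$strand == "+", .data$start,
                                           .data$end - 1))
}

#' Write replicon sequences as FASTA
#' @param sequence Named character vector.
#' @param path Output path.
#' @export
write_sequence_fasta <- function(sequence, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequence), path)
  invisible(path)
}

#' Read replicon sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_sequence_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write peaks as a BED-like TSV
#'
#' 0-based half-open intervals of width equal to the kernel support,
#' centered on the called peak.
#'
#' @param peaks Peak tibble.
#' @param path Output path.
#' @param support Kernel support half-width in bp.
#' @export
write_peaks_bed <- function(peaks, path, support = 450) {
  peaks |>
    dplyr::mutate(start = pmax(0, round(.data$center - support)),
                  end = round(.data$center + support),
                  .before = "center") |>
    readr::write_tsv(path)
  invisible(path)
}

#' Write a PWM in MEME minimal text format
#' @param pwm A `dynachip_pwm`.
#' @param path Output path.
#' @param name Motif name.
#' @export
write_pwm_meme <- function(pwm, path, name = "motif_1") {
  bg <- pwm$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg[1], bg[2], bg[3], bg[4]), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       pwm$width, max(1, round(pwm$n_sites)))), con)
  writeLines(apply(t(pwm$probs), 1, function(p) {
    sprintf(" %.6f %.6f %.6f %.6f", p[1], p[2], p[3], p[4])
  }), con)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [synthetic_config()] plus an
#' optional `pipeline` block of stage parameters (alpha, cs_threshold,
#' flank, max_dist, k, window_width, step, n_resample, n_boot,
#' min_amplitude).
#'
#' @param path YAML path.
#' @return List with elements `config` (a `dynachip_config`) and
#'   `pipeline` (named list of stage parameters).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline <- raw$pipeline %||% list()
  raw$pipeline <- NULL
  known <- names(formals(synthetic_config))
  config <- do.call(synthetic_config, raw[intersect(names(raw), known)])
  list(config = config, pipeline = pipeline)
}
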