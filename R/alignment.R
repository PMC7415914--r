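#' Align a contig to a pseudo-reference (local, both strands)
#'
#' Affine-gap Smith-Waterman local alignment of each contig and of its
#' reverse complement against the pseudo-reference; unaligned contig ends
#' become soft-clips. Scoring defaults copy BWA-MEM (match +1, mismatch -4,
#' gap open 6, gap extend 1), so behaviour is comparable to what a local
#' read aligner reports on the same sequences. The best alignment per strand
#' is reported whenever its score reaches `min_score`; both orientations
#' count equally downstream because contig orientation after assembly is
#' arbitrary.
#'
#' @param contigs Tibble with `id` and `sequence` (see [assemble_reads()]),
#'   or a single character string.
#' @param ref Pseudo-reference list from [build_pseudo_reference()], or a
#'   plain named list with `name` and `sequence`.
#' @param match,mismatch,gap_open,gap_extend Non-negative scoring parameters;
#'   `mismatch`, `gap_open`, `gap_extend` are penalties. A gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param min_score Minimum reported alignment score (default 30).
#' @return Tibble with one row per reported alignment: `contig_id`,
#'   `ref_name`, `ref_start`, `ref_end` (0-based half-open aligned reference
#'   span), `strand` (`"+"`/`"-"`), `cigar` (M/I/D/S over the
#'   reference-forward orientation of the contig, SAM convention), `score`.
#' @export
align_contigs <- function(contigs, ref, match = 1L, mismatch = 4L,
                          gap_open = 6L, gap_extend = 1L, min_score = 30L) {
  if (is.character(contigs)) {
    contigs <- tibble::tibble(id = paste0("contig_", seq_along(contigs)),
                              sequence = contigs)
  }
  stopifnot(mismatch >= 0, gap_open >= 0, gap_extend >= 0, min_score > 0,
            nzchar(ref$sequence))
  rows <- purrr::pmap(list(contigs$id, contigs$sequence), function(id, seq) {
    purrr::map(c("+", "-"), function(strand) {
      q <- if (strand == "+") toupper(seq) else revcomp(seq)
      hit <- .sw_align(q, toupper(ref$sequence), match, mismatch,
                       gap_open, gap_extend)
      if (hit$score < min_score) return(NULL)
      tibble::tibble(
        contig_id = id, ref_name = ref$name,
        ref_start = hit$ref_start, ref_end = hit$ref_end,
        strand = strand, cigar = hit$cigar, score = hit$score)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0) {
    return(tibble::tibble(contig_id = character(), ref_name = character(),
                          ref_start = integer(), ref_end = integer(),
                          strand = character(), cigar = character(),
                          score = integer()))
  }
  dplyr::arrange(out, .data$contig_id, dplyr::desc(.data$score),
                 .data$strand)
}

#' Parse a CIGAR string into operation lengths and codes
#'
#' @param cigar CIGAR string over M/I/D/S.
#' @return Tibble with `op` and `len`.
#' @export
parse_cigar <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDS])")[[1]]
  if (nrow(m) == 0 || sum(nchar(m[, 1])) != nchar(cigar)) {
    stop("malformed CIGAR: '", cigar, "'")
  }
  tibble::tibble(op = m[, 3], len = as.integer(m[, 2]))
}

#' Write contig alignments as SAM
#'
#' Emits a valid SAM with the pseudo-reference as the sole reference
#' sequence, for inspection in a genome browser. POS is 1-based per the SAM
#' spec; minus-strand records carry flag 16 with the sequence stored
#' reverse-complemented (reference-forward), the SAM convention.
#'
#' @param alignments Tibble from [align_contigs()].
#' @param contigs Contig tibble supplying sequences by `id`.
#' @param ref Pseudo-reference list (`name`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(alignments, contigs, ref, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", ref$name, "\tLN:", nchar(ref$sequence)))
  seq_by_id <- stats::setNames(toupper(contigs$sequence), contigs$id)
  body <- purrr::pmap_chr(alignments, function(contig_id, ref_name,
                                               ref_start, ref_end, strand,
                                               cigar, score, ...) {
    seq <- seq_by_id[[contig_id]]
    if (strand == "-") seq <- revcomp(seq)
    paste(contig_id, if (strand == "-") 16L else 0L, ref_name,
          ref_start + 1L, 60L, cigar, "*", 0L, 0L, seq, "*",
          paste0("AS:i:", score), sep = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}
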