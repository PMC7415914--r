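#' Compute the two read-extraction windows around a junction
#'
#' For a back-splice candidate `[start, end)` (`start` = splice acceptor,
#' `end` = splice donor, 0-based half-open) and window size `w`, the
#' acceptor-side window is `[start, start + w)` and the donor-side window is
#' `[end - w, end)`. Both are clamped to the circRNA span and to the contig:
#' sequence beyond the opposite junction coordinate belongs to the next
#' traversal of the circle, so windows never extend past it.
#'
#' @param candidate One-row data frame (or list) with `chrom`, `start`, `end`.
#' @param w Window size in bp (recommended between 1x and 2x the library
#'   insert size; default 300).
#' @param chrom_len Length of the contig `chrom`.
#' @return Tibble with two rows (`side` = `"acceptor"`, `"donor"`) and
#'   columns `chrom`, `start`, `end`.
#' @examples
#' extraction_regions(list(chrom = "chr1", start = 1000, end = 2000), 300, 10000)
#' @export
extraction_regions <- function(candidate, w = 300L, chrom_len) {
  start <- as.integer(candidate$start)
  end <- as.integer(candidate$end)
  w <- as.integer(w)
  stopifnot(w >= 1L, start < end, start >= 0L, end <= chrom_len)
  acc_end <- as.integer(min(start + w, end, chrom_len))
  don_start <- as.integer(max(end - w, start, 0L))
  tibble::tibble(
    side = c("acceptor", "donor"),
    chrom = rep(as.character(candidate$chrom), 2L),
    start = c(start, don_start),
    end = c(acc_end, end))
}

#' Build the junction-spanning pseudo-reference
#'
#' Concatenates the `w` bp of genome sequence ending at the donor coordinate
#' with the `w` bp starting at the acceptor coordinate, so that a read or
#' contig crossing the back-splice junction aligns contiguously across a
#' known offset. Windows are clamped to the circRNA span, so for a circle of
#' length `L < w` each side is the full circle sequence and the junction
#' offset equals `L`.
#'
#' @inheritParams extraction_regions
#' @param fasta_path Genome FASTA (indexed on first use).
#' @return List with `name` (`chrom:start-end`), `sequence`, and
#'   `junction_offset` (donor-side slice length: `sequence[0:offset)` is
#'   donor-side, `sequence[offset:)` is acceptor-side, 0-based).
#' @export
build_pseudo_reference <- function(fasta_path, candidate, w = 300L) {
  clen <- chrom_length(fasta_path, as.character(candidate$chrom))
  regs <- extraction_regions(candidate, w, clen)
  acc <- regs[regs$side == "acceptor", ]
  don <- regs[regs$side == "donor", ]
  don_seq <- fetch_reference_slice(fasta_path, don$chrom, don$start, don$end)
  acc_seq <- fetch_reference_slice(fasta_path, acc$chrom, acc$start, acc$end)
  list(
    name = paste0(candidate$chrom, ":", candidate$start, "-", candidate$end),
    sequence = paste0(don_seq, acc_seq),
    junction_offset = nchar(don_seq))
}

#' Write pseudo-references as FASTA
#'
#' @param refs A pseudo-reference (list) or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pseudo_reference <- function(refs, path) {
  if (!is.null(refs$sequence)) refs <- list(refs)
  seqs <- stats::setNames(purrr::map_chr(refs, "sequence"),
                          purrr::map_chr(refs, "name"))
  write_fasta(seqs, path)
}
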