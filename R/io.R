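#' Fetch a slice of an indexed genome FASTA
#'
#' Random access into a (faidx-indexed) FASTA file. Coordinates are 0-based
#' half-open, the convention used throughout the package; the slice of
#' `[start, end)` always has length `end - start`.
#'
#' @param fasta_path Path to a FASTA file. A `.fai` index is created on first
#'   use if missing.
#' @param chrom Sequence name.
#' @param start,end 0-based half-open interval; `0 <= start < end` and `end`
#'   must not exceed the contig length (no clamping here — callers clamp).
#' @return Uppercase nucleotide string of length `end - start`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' fetch_reference_slice(fa, "chr1", 0, 4)
#' @export
fetch_reference_slice <- function(fasta_path, chrom, start, end) {
  stopifnot(length(chrom) == 1, length(start) == 1, length(end) == 1)
  if (!(start >= 0 && start < end)) {
    stop("invalid region: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  fa <- open_fasta(fasta_path)
  info <- Rsamtools::seqinfo(fa)
  if (!chrom %in% GenomeInfoDb::seqnames(info)) {
    stop("unknown sequence '", chrom, "' in ", fasta_path)
  }
  clen <- GenomeInfoDb::seqlengths(info)[[chrom]]
  if (end > clen) {
    stop("region [", start, ", ", end, ") extends past end of '", chrom,
         "' (length ", clen, ")")
  }
  rng <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  toupper(as.character(Rsamtools::scanFa(fa, rng)[[1L]]))
}

# open FaFile handles are cached per path: batch validation touches the
# same genome hundreds of times and reopening dominates runtime otherwise
.fa_cache <- new.env(parent = emptyenv())

open_fasta <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  key <- normalizePath(fasta_path)
  hit <- .fa_cache[[key]]
  if (!is.null(hit) && Rsamtools::isOpen(hit)) return(hit)
  fai <- paste0(fasta_path, ".fai")
  if (!file.exists(fai)) Rsamtools::indexFa(fasta_path)
  fa <- Rsamtools::FaFile(fasta_path)
  open(fa)
  .fa_cache[[key]] <- fa
  fa
}

chrom_length <- function(fasta_path, chrom) {
  fa <- open_fasta(fasta_path)
  info <- Rsamtools::seqinfo(fa)
  if (!chrom %in% GenomeInfoDb::seqnames(info)) {
    stop("unknown sequence '", chrom, "' in ", fasta_path)
  }
  unname(GenomeInfoDb::seqlengths(info)[[chrom]])
}

#' Prepare an alignment file for region queries
#'
#' Plain SAM input is converted to a sorted, indexed BAM in a scratch
#' directory; BAM input is indexed in place if no index exists. The returned
#' path is suitable for repeated [extract_reads()] calls.
#'
#' @param path Path to a `.sam` or `.bam` file of reads aligned to the genome.
#' @return Path to a coordinate-sorted, indexed BAM.
#' @export
prepare_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    return(Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE))
  }
  bai <- paste0(path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", path))) {
    ok <- tryCatch({
      Rsamtools::indexBam(path)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      stop("BAM index missing and indexing failed for ", path,
           "; is the file coordinate-sorted? Sort with samtools sort ",
           "or pass a SAM file, which is converted automatically.")
    }
  }
  path
}

#' Extract reads overlapping genomic regions
#'
#' Fetches every primary alignment record whose aligned reference span
#' overlaps any of the given regions by at least one base. The full read
#' sequence is returned, including soft-clipped bases (clipped bases do not
#' extend the span used for the overlap test). Secondary, supplementary and
#' unmapped records are excluded; duplicate hits of the same record across
#' regions are removed, so the result has set semantics over the region list.
#'
#' @param path SAM or BAM file (see [prepare_alignments()]).
#' @param regions Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param min_mapq Minimum mapping quality; default 0 keeps multi-mapped reads.
#' @return Tibble with one row per read: `name`, `sequence`, `quality`
#'   (NA when absent), `mate` (`"first"`, `"second"` or `"unpaired"`).
#' @export
extract_reads <- function(path, regions, min_mapq = 0L) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)))
  empty <- tibble::tibble(name = character(), sequence = character(),
                          quality = character(), mate = character())
  if (nrow(regions) == 0) return(empty)
  bam <- prepare_alignments(path)
  which <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("qname", "flag", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE),
    mapqFilter = as.integer(min_mapq))
  hits <- Rsamtools::scanBam(bam, param = param)
  recs <- purrr::map(hits, function(h) {
    tibble::tibble(
      name = h$qname,
      sequence = as.character(h$seq),
      quality = as.character(h$qual),
      flag = h$flag)
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) return(empty)
  out$quality[out$quality == "*" | !nzchar(out$quality)] <- NA_character_
  out$mate <- dplyr::case_when(
    bitwAnd(out$flag, 1L) == 0L ~ "unpaired",
    bitwAnd(out$flag, 64L) != 0L ~ "first",
    bitwAnd(out$flag, 128L) != 0L ~ "second",
    TRUE ~ "unpaired")
  out |>
    dplyr::distinct(.data$name, .data$mate, .keep_all = TRUE) |>
    dplyr::arrange(.data$name, .data$mate) |>
    dplyr::select("name", "sequence", "quality", "mate")
}

#' Write reads as FASTQ
#'
#' Reads lacking quality strings get a constant placeholder quality (`"I"`,
#' Phred 40) so the file remains parseable by standard FASTQ readers.
#'
#' @param reads Data frame with `name`, `sequence` and optionally `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("name", "sequence") %in% names(reads)))
  qual <- if ("quality" %in% names(reads)) reads$quality else
    rep(NA_character_, nrow(reads))
  qual <- ifelse(is.na(qual),
                 strrep("I", nchar(reads$sequence)), qual)
  stopifnot(all(nchar(qual) == nchar(reads$sequence)))
  lines <- if (nrow(reads) == 0) character(0) else
    as.vector(rbind(paste0("@", reads$name), reads$sequence,
                    rep("+", nrow(reads)), qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path.
#' @return Tibble with `name`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  empty <- tibble::tibble(name = character(), sequence = character(),
                          quality = character())
  if (file.size(path) == 0) return(empty)
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  tibble::tibble(
    name = names(seqs) %||% character(),
    sequence = unname(as.character(seqs)),
    quality = unname(as.character(S4Vectors::mcols(seqs)$qualities)))
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs))
  if (length(seqs) > 0 && is.null(names(seqs))) {
    stop("sequences must be named")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector (uppercase).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' Read junction candidates from a BED-like file
#'
#' Tab-separated `chrom  start  end  [id]`, 0-based half-open, `#` comments.
#' Missing ids default to `chrom:start-end`.
#'
#' @param path Candidate file.
#' @param one_based Set `TRUE` if the file uses 1-based inclusive starts;
#'   starts are shifted down by one on input.
#' @return Tibble with `chrom`, `start`, `end`, `id`.
#' @export
read_candidates <- function(path, one_based = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), id = character()))
  }
  parts <- stringr::str_split(lines, "\t")
  bad <- which(purrr::map_int(parts, length) < 3)
  if (length(bad) > 0) {
    stop("malformed candidate line ", bad[1], ": '", lines[bad[1]],
         "' (need chrom<TAB>start<TAB>end[<TAB>id])")
  }
  tbl <- tibble::tibble(
    chrom = purrr::map_chr(parts, 1),
    start = suppressWarnings(as.integer(purrr::map_chr(parts, 2))),
    end = suppressWarnings(as.integer(purrr::map_chr(parts, 3))),
    id = purrr::map_chr(parts, function(p) if (length(p) >= 4) p[4] else NA))
  if (anyNA(tbl$start) || anyNA(tbl$end)) {
    bad <- which(is.na(tbl$start) | is.na(tbl$end))[1]
    stop("malformed candidate line ", bad, ": non-numeric coordinates")
  }
  if (one_based) tbl$start <- tbl$start - 1L
  if (any(tbl$start >= tbl$end)) {
    bad <- which(tbl$start >= tbl$end)[1]
    stop("candidate line ", bad, ": start (", tbl$start[bad],
         ") must be < end (", tbl$end[bad], ")")
  }
  tbl$id <- ifelse(is.na(tbl$id),
                   paste0(tbl$chrom, ":", tbl$start, "-", tbl$end), tbl$id)
  tbl
}

#' Parse an inline junction coordinate
#'
#' @param coord String `chrom:start-end` (0-based half-open).
#' @return One-row candidate tibble.
#' @export
parse_coordinate <- function(coord) {
  m <- stringr::str_match(coord, "^([^:]+):(\\d+)-(\\d+)$")
  if (is.na(m[1, 1])) {
    stop("malformed coordinate '", coord, "' (expected chrom:start-end)")
  }
  start <- as.integer(m[1, 3]); end <- as.integer(m[1, 4])
  if (start >= end) stop("coordinate '", coord, "': start must be < end")
  tibble::tibble(chrom = m[1, 2], start = start, end = end, id = coord)
}

#' Write a validation report as TSV
#'
#' @param report Tibble as returned by [validate_junctions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}
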