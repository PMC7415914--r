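#' The four junction-overlap stringency levels
#'
#' A contig alignment verifies a junction at a level when it covers at least
#' `per_side_bp` aligned bases on each side of the back-splice point: high
#' stringency 30 bp (60 bp total), medium 20 bp, low 10 bp, very low 5 bp.
#'
#' @return Tibble with `label` (HS/MS/LS/VLS) and `per_side_bp`.
#' @export
stringency_levels <- function() {
  tibble::tibble(label = c("HS", "MS", "LS", "VLS"),
                 per_side_bp = c(30L, 20L, 10L, 5L))
}

#' Aligned bases on each side of the back-splice point
#'
#' Replays an alignment's CIGAR against the pseudo-reference and counts, on
#' each side of the junction offset, the reference positions aligned to
#' query bases (M operations). Deleted reference positions (D) advance the
#' reference but contribute to neither side; inserted (I) and soft-clipped
#' (S) bases consume only query and never count. This is the strict reading
#' of "minimum length of alignment on both sides": only bases actually
#' aligned across the junction count.
#'
#' @param ref_start 0-based reference start of the alignment.
#' @param cigar CIGAR string (M/I/D/S).
#' @param junction_offset 0-based index of the back-splice point in the
#'   pseudo-reference.
#' @return Named numeric vector `c(left = ..., right = ...)`: aligned bases
#'   in `[0, junction_offset)` and `[junction_offset, len)` respectively.
#' @examples
#' junction_overlap(270, "70M", 300)  # 30 left, 40 right
#' @export
junction_overlap <- function(ref_start, cigar, junction_offset) {
  ops <- parse_cigar(cigar)
  pos <- as.integer(ref_start)
  junction_offset <- as.integer(junction_offset)
  left <- 0L; right <- 0L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op == "M") {
      left <- left + max(0L, min(pos + len, junction_offset) - pos)
      right <- right + max(0L, pos + len - max(pos, junction_offset))
      pos <- pos + len
    } else if (op == "D") {
      pos <- pos + len
    }
  }
  c(left = left, right = right)
}

#' Evaluate contig alignments against the stringency levels
#'
#' A level passes when ANY single alignment record has at least
#' `per_side_bp` aligned bases on BOTH sides of the junction (records are
#' never combined: each must individually span the back-splice point).
#'
#' @param alignments Tibble from [align_contigs()].
#' @param junction_offset Back-splice offset in the pseudo-reference.
#' @param levels Stringency table, default [stringency_levels()].
#' @return List: `verdicts` (named logical, one per level),
#'   `supporting` (named list of qualifying contig ids per level),
#'   `best_left`, `best_right` (overlap pair of the record maximising the
#'   smaller side), `overlaps` (per-record left/right tibble).
#' @export
evaluate_alignments <- function(alignments, junction_offset,
                                levels = stringency_levels()) {
  if (nrow(alignments) == 0) {
    return(list(
      verdicts = stats::setNames(rep(FALSE, nrow(levels)), levels$label),
      supporting = stats::setNames(rep(list(character()), nrow(levels)),
                                   levels$label),
      best_left = 0L, best_right = 0L,
      overlaps = tibble::tibble(contig_id = character(), left = integer(),
                                right = integer())))
  }
  ov <- purrr::pmap(alignments, function(ref_start, cigar, ...) {
    junction_overlap(ref_start, cigar, junction_offset)
  })
  overlaps <- tibble::tibble(
    contig_id = alignments$contig_id,
    left = purrr::map_int(ov, function(x) as.integer(x[["left"]])),
    right = purrr::map_int(ov, function(x) as.integer(x[["right"]])))
  verdicts <- logical(nrow(levels))
  supporting <- vector("list", nrow(levels))
  for (i in seq_len(nrow(levels))) {
    t <- levels$per_side_bp[i]
    ok <- overlaps$left >= t & overlaps$right >= t
    verdicts[i] <- any(ok)
    supporting[[i]] <- unique(overlaps$contig_id[ok])
  }
  names(verdicts) <- names(supporting) <- levels$label
  minside <- pmin(overlaps$left, overlaps$right)
  best <- which(minside == max(minside))
  best <- best[which.max(overlaps$left[best] + overlaps$right[best])]
  list(verdicts = verdicts, supporting = supporting,
       best_left = overlaps$left[best], best_right = overlaps$right[best],
       overlaps = overlaps)
}

#' Validate one back-splice junction candidate end to end
#'
#' Runs the three phases for a single candidate: (1) extract reads from the
#' window on either side of the junction and assemble them into contigs;
#' (2) build the junction-spanning pseudo-reference from the genome;
#' (3) align the contigs to the pseudo-reference and test the junction
#' overlap at each stringency level. Deterministic end to end.
#'
#' @param aln_path SAM/BAM of reads aligned to the genome (a prepared BAM
#'   path from [prepare_alignments()] avoids re-conversion in batch runs).
#' @param fasta_path Genome FASTA.
#' @param candidate One-row data frame or list with `chrom`, `start`, `end`
#'   and optionally `id` (0-based half-open; start = splice acceptor,
#'   end = splice donor).
#' @param w Window size in bp (default 300; recommended 1-2x insert size).
#' @param min_mapq Minimum mapping quality for extracted reads.
#' @param min_circ_size Minimum circRNA length accepted (default 50).
#' @param k,min_kmer_count,min_contig_length Assembler parameters
#'   ([assemble_reads()]).
#' @param min_score Minimum contig alignment score ([align_contigs()]).
#' @param levels Stringency table (default all four levels).
#' @param keep_dir If non-NULL, per-candidate intermediates (extracted
#'   FASTQ, contig FASTA, pseudo-reference FASTA, alignment SAM) are written
#'   under this directory.
#' @return One-row tibble: `candidate_id`, `chrom`, `start`, `end`, `w`,
#'   `n_reads_extracted`, `n_contigs`, `best_left_overlap`,
#'   `best_right_overlap`, `pass_HS`, `pass_MS`, `pass_LS`, `pass_VLS`,
#'   `failure_stage` (`none`, `no_reads`, `no_contigs`, `no_alignment` or
#'   `no_junction_overlap`), `supporting_contigs_VLS` (comma-separated).
#' @export
validate_candidate <- function(aln_path, fasta_path, candidate, w = 300L,
                               min_mapq = 0L, min_circ_size = 50L,
                               k = 31L, min_kmer_count = 2L,
                               min_contig_length = 100L, min_score = 30L,
                               levels = stringency_levels(),
                               keep_dir = NULL) {
  id <- candidate$id %||%
    paste0(candidate$chrom, ":", candidate$start, "-", candidate$end)
  if (is.na(id)) id <- paste0(candidate$chrom, ":", candidate$start, "-",
                              candidate$end)
  if (candidate$end - candidate$start < min_circ_size) {
    abort_stage(paste0("candidate ", id, " shorter than minimum circRNA ",
                       "size (", min_circ_size, " bp)"), "candidate")
  }
  clen <- chrom_length(fasta_path, as.character(candidate$chrom))
  if (candidate$end > clen) {
    abort_stage(paste0("candidate ", id, " extends past end of ",
                       candidate$chrom, " (length ", clen, ")"), "candidate")
  }
  regions <- extraction_regions(candidate, w, clen)

  reads <- extract_reads(aln_path, regions, min_mapq = min_mapq)
  if (!is.null(keep_dir)) {
    dir.create(keep_dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(reads, file.path(keep_dir, paste0(id, ".reads.fastq")))
  }
  stageout <- function(stage, n_reads = 0L, n_contigs = 0L, ev = NULL) {
    verdicts <- if (is.null(ev)) {
      stats::setNames(rep(FALSE, nrow(levels)), levels$label)
    } else ev$verdicts
    tibble::tibble(
      candidate_id = id, chrom = as.character(candidate$chrom),
      start = as.integer(candidate$start), end = as.integer(candidate$end),
      w = as.integer(w), n_reads_extracted = n_reads, n_contigs = n_contigs,
      best_left_overlap = if (is.null(ev)) 0L else as.integer(ev$best_left),
      best_right_overlap = if (is.null(ev)) 0L else as.integer(ev$best_right),
      pass_HS = isTRUE(verdicts[["HS"]]),
      pass_MS = isTRUE(verdicts[["MS"]]),
      pass_LS = isTRUE(verdicts[["LS"]]),
      pass_VLS = isTRUE(verdicts[["VLS"]]),
      failure_stage = stage,
      supporting_contigs_VLS = if (is.null(ev)) "" else
        paste(ev$supporting[["VLS"]], collapse = ","))
  }
  if (nrow(reads) == 0) return(stageout("no_reads"))

  contigs <- assemble_reads(reads, k = k, min_kmer_count = min_kmer_count,
                            min_contig_length = min_contig_length)
  if (!is.null(keep_dir) && nrow(contigs) > 0) {
    write_contigs(contigs, file.path(keep_dir, paste0(id, ".contigs.fasta")))
  }
  if (nrow(contigs) == 0) return(stageout("no_contigs", nrow(reads)))

  pseudo <- build_pseudo_reference(fasta_path, candidate, w)
  alns <- align_contigs(contigs, pseudo, min_score = min_score)
  if (!is.null(keep_dir)) {
    write_pseudo_reference(pseudo,
                           file.path(keep_dir, paste0(id, ".pseudoref.fasta")))
    write_alignments_sam(alns, contigs, pseudo,
                         file.path(keep_dir, paste0(id, ".contigs.sam")))
  }
  if (nrow(alns) == 0) {
    return(stageout("no_alignment", nrow(reads), nrow(contigs)))
  }
  ev <- evaluate_alignments(alns, pseudo$junction_offset, levels)
  stage <- if (any(ev$verdicts)) "none" else "no_junction_overlap"
  stageout(stage, nrow(reads), nrow(contigs), ev)
}

#' Validate a table of back-splice junction candidates
#'
#' Tibble-in, tibble-out batch driver over [validate_candidate()]: one row
#' per candidate, input order preserved. SAM input is converted to an
#' indexed BAM once for the whole batch.
#'
#' @param candidates Data frame with `chrom`, `start`, `end` and optionally
#'   `id` (see [read_candidates()]).
#' @param aln_path SAM/BAM of reads aligned to the genome.
#' @param fasta_path Genome FASTA.
#' @inheritParams validate_candidate
#' @param keep_dir If non-NULL, per-candidate intermediates are kept here.
#' @return A `bsj_report` tibble (one row per candidate; columns as in
#'   [validate_candidate()]).
#' @examples
#' \donttest{
#' sim <- simulate_dataset(tempfile(), n_circ = 3, circ_coverage = 20,
#'                         read_length = 150, seed = 1)
#' truth <- dplyr::filter(sim$truth, class == "circRNA")
#' validate_junctions(truth, sim$sam, sim$genome, w = 300)
#' }
#' @export
validate_junctions <- function(candidates, aln_path, fasta_path, w = 300L,
                               min_mapq = 0L, min_circ_size = 50L,
                               k = 31L, min_kmer_count = 2L,
                               min_contig_length = 100L, min_score = 30L,
                               levels = stringency_levels(),
                               keep_dir = NULL) {
  stopifnot(is.data.frame(candidates),
            all(c("chrom", "start", "end") %in% names(candidates)))
  bam <- prepare_alignments(aln_path)
  if (!"id" %in% names(candidates)) candidates$id <- NA_character_
  rows <- purrr::pmap(
    candidates[, c("chrom", "start", "end", "id")],
    function(chrom, start, end, id) {
      validate_candidate(
        bam, fasta_path,
        list(chrom = chrom, start = start, end = end, id = id),
        w = w, min_mapq = min_mapq, min_circ_size = min_circ_size,
        k = k, min_kmer_count = min_kmer_count,
        min_contig_length = min_contig_length, min_score = min_score,
        levels = levels, keep_dir = keep_dir)
    })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bsj_report", class(out))
  attr(out, "w") <- as.integer(w)
  out
}
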