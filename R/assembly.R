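#' Assemble reads into contigs with a deterministic de Bruijn assembler
#'
#' Builds a de Bruijn graph over canonical k-mers (a k-mer and its reverse
#' complement are counted as one, so strand of origin does not matter),
#' drops k-mers seen fewer than `min_kmer_count` times (the only error
#' handling: sequencing errors produce low-multiplicity k-mers), compresses
#' maximal unbranched paths, and emits the compressed paths as contigs.
#' Compression stops at every branch point; no bubble popping is attempted —
#' branch-induced fragmentation can lower sensitivity downstream but never
#' creates chimeric contigs.
#'
#' The result is deterministic: reads are sorted canonically before graph
#' construction and graph traversal order is fixed, so two runs on the same
#' input produce byte-identical contig sets.
#'
#' If the input contains error-free reads tiling a sequence S
#' (`|S| >= min_contig_length`) at every position with k-mer depth
#' `>= min_kmer_count` and S's k-mers are unique in the input, some output
#' contig contains S or its reverse complement as a substring.
#'
#' @param reads Data frame with a `sequence` column, or a character vector
#'   of read sequences. May contain `N`s (k-mers containing non-ACGT bases
#'   are dropped) and reads from either strand.
#' @param k K-mer size (odd, `>= 11`). When reads are shorter than `2k`, k is
#'   reduced to `floor(L/2) + 1` (rounded down to odd) for minimum read
#'   length L, so adjacent read k-mers still overlap.
#' @param min_kmer_count Minimum k-mer multiplicity retained (default 2).
#'   Fewer than `min_kmer_count` input reads yield an empty contig set — the
#'   low-coverage failure mode reported downstream as `no_contigs`.
#' @param min_contig_length Minimum emitted contig length (default 100: the
#'   junction check needs at most 2 x 30 bp around the back-splice point,
#'   and short-read datasets at shallow coverage rarely assemble past 200).
#' @return Tibble with `id`, `sequence` (canonical orientation:
#'   lexicographic min of the unitig and its reverse complement) and
#'   `read_support` (number of input reads sharing at least one retained
#'   k-mer with the contig).
#' @export
assemble_reads <- function(reads, k = 31L, min_kmer_count = 2L,
                           min_contig_length = 100L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  stopifnot(is.character(seqs), min_kmer_count >= 1L)
  empty <- tibble::tibble(id = character(), sequence = character(),
                          read_support = integer())
  seqs <- toupper(seqs[nzchar(seqs)])
  if (length(seqs) < min_kmer_count) return(empty)
  seqs <- sort(seqs)

  k <- as.integer(k)
  lmin <- min(nchar(seqs))
  if (lmin < 2L * k) {
    k <- lmin %/% 2L + 1L
    if (k %% 2L == 0L) k <- k - 1L
    k <- max(k, 11L)
  }
  stopifnot(k %% 2L == 1L, k >= 11L, min_contig_length >= k)
  usable <- seqs[nchar(seqs) >= k]
  if (length(usable) == 0) return(empty)

  read_kmers <- purrr::map(usable, function(s) {
    n <- nchar(s)
    km <- substring(s, 1:(n - k + 1L), k:n)
    canonical(km[grepl("^[ACGT]+$", km)])
  })
  counts <- table(unlist(read_kmers))
  kept <- names(counts)[counts >= min_kmer_count]
  if (length(kept) == 0) return(empty)

  nodes <- sort(unique(c(kept, revcomp(kept))))
  n <- length(nodes)
  suf <- substr(nodes, 2L, k)
  bases <- c("A", "C", "G", "T")
  nxt <- vapply(bases, function(b) match(paste0(suf, b), nodes), integer(n))
  if (n == 1L) nxt <- matrix(nxt, nrow = 1L)
  outdeg <- rowSums(!is.na(nxt))
  indeg <- tabulate(nxt[!is.na(nxt)], nbins = n)
  succ <- integer(n)  # unique successor where outdeg == 1
  has1 <- which(outdeg == 1L)
  if (length(has1) > 0) {
    succ[has1] <- apply(nxt[has1, , drop = FALSE], 1L,
                        function(r) r[!is.na(r)][1L])
  }
  # predecessor out-degree for unitig start detection
  pred_out_ok <- rep(FALSE, n)
  one_in <- which(indeg == 1L)
  if (length(one_in) > 0) {
    pred <- integer(n)
    from <- rep(seq_len(n), 4L)[!is.na(nxt)]
    to <- nxt[!is.na(nxt)]
    pred[to[to %in% one_in]] <- from[to %in% one_in]
    pred_out_ok[one_in] <- outdeg[pred[one_in]] == 1L
  }
  is_start <- indeg != 1L | !pred_out_ok

  visited <- logical(n)
  unitigs <- character(0)
  walk <- function(v) {
    chars <- nodes[v]
    visited[v] <<- TRUE
    cur <- v
    repeat {
      if (outdeg[cur] != 1L) break
      nx <- succ[cur]
      if (is_start[nx] || visited[nx]) break
      visited[nx] <<- TRUE
      chars <- c(chars, substr(nodes[nx], k, k))
      cur <- nx
    }
    paste(chars, collapse = "")
  }
  for (v in which(is_start)) {
    if (!visited[v]) unitigs <- c(unitigs, walk(v))
  }
  for (v in which(!visited)) {  # leftover perfect cycles
    if (!visited[v]) unitigs <- c(unitigs, walk(v))
  }

  contigs <- sort(unique(canonical(unitigs)))
  contigs <- contigs[nchar(contigs) >= min_contig_length]
  if (length(contigs) == 0) return(empty)

  support <- vapply(contigs, function(cs) {
    m <- nchar(cs)
    ck <- canonical(substring(cs, 1:(m - k + 1L), k:m))
    sum(vapply(read_kmers, function(rk) any(rk %in% ck), logical(1)))
  }, integer(1), USE.NAMES = FALSE)

  tibble::tibble(
    id = sprintf("contig_%d", seq_along(contigs)),
    sequence = contigs,
    read_support = support)
}

#' Assemble reads with an external assembler binary
#'
#' Writes the reads to a temporary FASTQ and invokes
#' `command <reads.fastq> <out.fasta>`; the command must write its contigs
#' to the given FASTA path. Intended as an adapter for full-scale assemblers
#' such as Trinity; the built-in [assemble_reads()] is the default and needs
#' no external software.
#'
#' @param reads As for [assemble_reads()].
#' @param command Name or path of the assembler executable.
#' @param args Extra arguments inserted before the FASTQ path.
#' @return Tibble with `id`, `sequence`, `read_support` (NA: external tools
#'   do not report it in FASTA).
#' @export
assemble_external <- function(reads, command, args = character()) {
  if (Sys.which(command) == "" && !file.exists(command)) {
    stop("external assembler '", command, "' not found on PATH; ",
         "use the built-in assembler (assemble_reads) instead")
  }
  if (is.character(reads) && is.null(dim(reads))) {
    reads <- tibble::tibble(name = paste0("read", seq_along(reads)),
                            sequence = reads)
  }
  fq <- tempfile(fileext = ".fastq")
  fa <- tempfile(fileext = ".fasta")
  write_fastq(reads, fq)
  out <- suppressWarnings(
    system2(command, c(args, fq, fa), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop("external assembler '", command, "' exited with status ", status,
         ":\n", paste(out, collapse = "\n"))
  }
  if (!file.exists(fa) || file.size(fa) == 0) {
    return(tibble::tibble(id = character(), sequence = character(),
                          read_support = integer()))
  }
  seqs <- read_fasta(fa)
  tibble::tibble(id = names(seqs), sequence = unname(seqs),
                 read_support = NA_integer_)
}

#' Write contigs as FASTA
#'
#' @param contigs Tibble from [assemble_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  write_fasta(stats::setNames(contigs$sequence, contigs$id), path)
}
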