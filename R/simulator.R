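#' Generate a random genome FASTA
#'
#' Uniform-random A/C/G/T contigs, written with a faidx index; deterministic
#' for a given seed. A stand-in for a real reference at desk scale.
#'
#' @param path Output FASTA path.
#' @param n_chroms Number of contigs (named `chr1`, `chr2`, ...).
#' @param chrom_length Length of each contig (>= 1000).
#' @param seed RNG seed (mandatory: outputs must be reproducible).
#' @return `path`, invisibly.
#' @export
simulate_genome <- function(path, n_chroms = 1L, chrom_length = 1e6,
                            seed) {
  stopifnot(chrom_length >= 1000, n_chroms >= 1)
  set.seed(seed)
  seqs <- vapply(seq_len(n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n_chroms))
  write_fasta(seqs, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

# non-overlapping locus placement with a fixed inter-locus buffer
place_loci <- function(n, locus_lens, chrom_names, chrom_len,
                       buffer = 200L) {
  placed <- list()
  occupied <- stats::setNames(
    rep(list(matrix(numeric(0), ncol = 2)), length(chrom_names)),
    chrom_names)
  for (i in seq_len(n)) {
    len <- locus_lens[i]
    ok <- FALSE
    for (try in 1:2000) {
      chrom <- sample(chrom_names, 1)
      start <- sample.int(chrom_len - len, 1) - 1L
      occ <- occupied[[chrom]]
      clash <- nrow(occ) > 0 &&
        any(start < occ[, 2] + buffer & start + len + buffer > occ[, 1])
      if (!clash) {
        occupied[[chrom]] <- rbind(occ, c(start, start + len))
        placed[[i]] <- tibble::tibble(chrom = chrom, start = start,
                                      end = start + len)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place ", n, " non-overlapping loci; ",
                  "genome too small")
  }
  dplyr::bind_rows(placed)
}

# apply per-base substitution errors to a genome-orientation sequence
mutate_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hits <- which(runif(n) < rate)
  if (length(hits) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (h in hits) {
    chars[h] <- sample(setdiff(c("A", "C", "G", "T"), chars[h]), 1)
  }
  paste(chars, collapse = "")
}

# does a read interval [s, s+rl) on the unrolled circle cross a multiple of
# L with >= 1 base on each side?
crosses_junction <- function(s, rl, L) {
  (s %/% L) < ((s + rl - 1L) %/% L)
}

# truncated-normal fragment length in [read_length, 2 * insert_size]
draw_fraglen <- function(insert_size, insert_sd, read_length) {
  for (i in 1:100) {
    f <- round(rnorm(1, insert_size, insert_sd))
    if (f >= read_length && f <= 2L * insert_size) return(as.integer(f))
  }
  as.integer(insert_size)
}

# SAM placement of one genome-orientation read from a circle:
# junction-crossing reads go to the side holding the majority of their
# bases, remainder soft-clipped (tie -> acceptor side)
place_circle_read <- function(s, rl, L, locus_start) {
  p <- s %% L
  if (!crosses_junction(s, rl, L)) {
    return(list(pos = locus_start + p, cigar = paste0(rl, "M")))
  }
  b1 <- as.integer((s %/% L + 1L) * L - s)  # bases before first wrap (donor)
  after <- rl - b1
  if (b1 > after) {
    list(pos = locus_start + p, cigar = paste0(b1, "M", after, "S"))
  } else {
    matched <- min(after, L)
    trail <- after - matched
    cig <- paste0(b1, "S", matched, "M",
                  if (trail > 0) paste0(trail, "S") else "")
    list(pos = locus_start, cigar = cig)
  }
}

#' Simulate a paired-end circRNA sequencing dataset
#'
#' Places non-overlapping circRNA and linear-transcript loci on a random
#' genome and emits paired-end reads, a genome-placed coordinate-sorted SAM,
#' paired FASTQ files and a truth table. For each circRNA of circular length
#' L, the junction-supporting read-pair count is drawn Poisson(circ_coverage)
#' and fragments are sampled uniformly on the circle with coordinates taken
#' modulo L; a read supports the junction when its sequence crosses the
#' back-splice point by at least one base on each side. Additional
#' non-junction circle pairs and linear-locus pairs are drawn
#' Poisson(linear_coverage) each. In the SAM, fully-intra-segment reads get
#' full-match CIGARs at their genomic position; junction-crossing reads are
#' placed on the side holding the majority of their bases with the remainder
#' soft-clipped (tie: acceptor side) — what a local aligner does with an
#' unannotated back-splice. Fragment length is Normal(insert_size,
#' insert_sd) truncated to `[read_length, 2 * insert_size]`.
#'
#' @param out_dir Output directory (created).
#' @param n_circ Number of circRNA loci.
#' @param circ_coverage Mean junction-supporting reads per circRNA (the
#'   per-circle target is drawn Poisson(circ_coverage)).
#' @param linear_coverage Mean non-junction pairs per circle and mean pairs
#'   per linear locus.
#' @param read_length Read length in bp (50, 100 or 150 in the benchmark
#'   grid; any positive value works).
#' @param insert_size,insert_sd Fragment length mean (default 300) and sd.
#' @param min_circ_size Minimum circle length (default 50); shorter loci are
#'   rejected at placement.
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed RNG seed (mandatory).
#' @param n_chroms,chrom_length Genome shape.
#' @param n_linear Number of circRNA-free linear loci (negative controls).
#' @param circ_len_range Circle length range, sampled uniformly (default
#'   200-1200 bp, typical mature exonic circRNA lengths).
#' @param linear_len_range Linear locus length range (default 500-2000 bp).
#' @return List with paths `genome`, `fastq1`, `fastq2`, `sam`, `truth_path`,
#'   `manifest`, and tibbles `truth` (columns `id`, `chrom`, `start`, `end`,
#'   `circle_length`, `n_supporting`, `class`, `read_ids`) and `reads`.
#' @export
simulate_dataset <- function(out_dir, n_circ = 50L, circ_coverage = 10,
                             linear_coverage = 10, read_length = 150L,
                             insert_size = 300L, insert_sd = 30L,
                             min_circ_size = 50L, error_rate = 0,
                             seed, n_chroms = 1L, chrom_length = 2e6,
                             n_linear = 20L,
                             circ_len_range = c(200L, 1200L),
                             linear_len_range = c(500L, 2000L)) {
  if (missing(seed)) stop("seed is mandatory for reproducible simulation")
  stopifnot(read_length >= 20, insert_size >= read_length,
            circ_len_range[1] >= min_circ_size)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  genome_path <- file.path(out_dir, "genome.fa")
  chrom_names <- paste0("chr", seq_len(n_chroms))
  genome <- vapply(chrom_names, function(nm) {
    paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  write_fasta(genome, genome_path)
  Rsamtools::indexFa(genome_path)

  rl <- as.integer(read_length)
  circ_lens <- if (n_circ > 0) {
    sample(circ_len_range[1]:circ_len_range[2], n_circ, replace = TRUE)
  } else integer(0)
  lin_lens <- if (n_linear > 0) {
    sample(linear_len_range[1]:linear_len_range[2], n_linear, replace = TRUE)
  } else integer(0)
  loci <- place_loci(n_circ + n_linear, c(circ_lens, lin_lens),
                     chrom_names, chrom_length)
  loci$class <- rep(c("circRNA", "linear"), c(n_circ, n_linear))
  loci$id <- c(sprintf("circ_%04d", seq_len(n_circ)),
               sprintf("lin_%04d", seq_len(n_linear)))

  recs <- vector("list", nrow(loci))
  truth_rows <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    L <- locus$end - locus$start
    src <- substr(genome[[locus$chrom]], locus$start + 1L, locus$end)
    circ <- locus$class == "circRNA"
    big <- if (circ) strrep(src, ceiling((2L * insert_size + rl) / L) + 2L)
           else src

    pair_specs <- list()
    if (circ) {
      # target number of junction-supporting READS; supporting pairs are
      # added until the target is met (a pair can contribute 1 or 2)
      n_supp <- rpois(1, circ_coverage)
      got <- 0L
      for (try in seq_len(200L * max(n_supp, 1L))) {
        if (got >= n_supp) break
        u <- sample.int(L, 1) - 1L
        flen <- draw_fraglen(insert_size, insert_sd, rl)
        s2 <- u + flen - rl
        nx <- crosses_junction(u, rl, L) + crosses_junction(s2, rl, L)
        if (nx > 0L) {
          pair_specs[[length(pair_specs) + 1L]] <- c(u, flen)
          got <- got + nx
        }
      }
      n_bg <- rpois(1, linear_coverage)
      got <- 0L
      for (try in seq_len(200L * max(n_bg, 1L))) {
        if (got >= n_bg) break
        u <- sample.int(L, 1) - 1L
        flen <- draw_fraglen(insert_size, insert_sd, rl)
        s2 <- u + flen - rl
        if (!crosses_junction(u, rl, L) && !crosses_junction(s2, rl, L)) {
          pair_specs[[length(pair_specs) + 1L]] <- c(u, flen)
          got <- got + 1L
        }
      }
    } else {
      n_pairs <- rpois(1, linear_coverage)
      for (pp in seq_len(n_pairs)) {
        flen <- min(draw_fraglen(insert_size, insert_sd, rl), L)
        u <- sample.int(max(L - flen, 1L), 1) - 1L
        pair_specs[[length(pair_specs) + 1L]] <- c(u, flen)
      }
    }

    np <- length(pair_specs)
    supp_ids <- character(0)
    qn <- pos <- cig <- sq <- character(2L * np)
    pos <- integer(2L * np)
    for (pp in seq_along(pair_specs)) {
      u <- pair_specs[[pp]][1]; flen <- pair_specs[[pp]][2]
      s2 <- u + flen - rl
      qname <- paste0(locus$id, "_p", pp)
      seq1 <- mutate_bases(substr(big, u + 1L, u + rl), error_rate)
      seq2 <- mutate_bases(substr(big, s2 + 1L, s2 + rl), error_rate)
      if (circ) {
        pl1 <- place_circle_read(u, rl, L, locus$start)
        pl2 <- place_circle_read(s2, rl, L, locus$start)
        if (crosses_junction(u, rl, L)) {
          supp_ids <- c(supp_ids, paste0(qname, "/1"))
        }
        if (crosses_junction(s2, rl, L)) {
          supp_ids <- c(supp_ids, paste0(qname, "/2"))
        }
      } else {
        pl1 <- list(pos = locus$start + u, cigar = paste0(rl, "M"))
        pl2 <- list(pos = locus$start + s2, cigar = paste0(rl, "M"))
      }
      j <- 2L * pp - 1L
      qn[j:(j + 1L)] <- qname
      pos[j] <- pl1$pos; pos[j + 1L] <- pl2$pos
      cig[j] <- pl1$cigar; cig[j + 1L] <- pl2$cigar
      sq[j] <- seq1; sq[j + 1L] <- seq2
    }
    recs[[i]] <- tibble::tibble(
      qname = qn, chrom = locus$chrom, pos = pos, cigar = cig,
      flag = rep(c(99L, 147L), np), seq = sq,
      mate = rep(c(1L, 2L), np))
    truth_rows[[i]] <- tibble::tibble(
      id = locus$id, chrom = locus$chrom, start = locus$start,
      end = locus$end,
      circle_length = if (circ) L else NA_integer_,
      n_supporting = length(supp_ids),
      class = locus$class,
      read_ids = paste(supp_ids, collapse = ","))
  }
  reads <- dplyr::bind_rows(recs)
  truth <- dplyr::bind_rows(truth_rows)

  # FASTQ: read 1 fragment-forward, read 2 reverse-complemented
  fq1 <- file.path(out_dir, "reads_1.fastq")
  fq2 <- file.path(out_dir, "reads_2.fastq")
  r1 <- reads[reads$mate == 1L, ]
  r2 <- reads[reads$mate == 2L, ]
  write_fastq(tibble::tibble(name = paste0(r1$qname, "/1"),
                             sequence = r1$seq), fq1)
  write_fastq(tibble::tibble(name = paste0(r2$qname, "/2"),
                             sequence = revcomp(r2$seq)), fq2)

  sam_path <- file.path(out_dir, "reads.sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", chrom_names, "\tLN:",
                     format(chrom_length, scientific = FALSE)))
  ord <- order(match(reads$chrom, chrom_names), reads$pos, reads$qname,
               reads$mate)
  sorted <- reads[ord, ]
  body <- paste(sorted$qname, sorted$flag, sorted$chrom, sorted$pos + 1L,
                60L, sorted$cigar, "*", 0L, 0L, sorted$seq,
                strrep("I", rl), sep = "\t")
  writeLines(c(header, body), sam_path)

  truth_path <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(truth, truth_path)

  manifest <- file.path(out_dir, "manifest.tsv")
  params <- c(n_circ = n_circ, circ_coverage = circ_coverage,
              linear_coverage = linear_coverage, read_length = rl,
              insert_size = insert_size, insert_sd = insert_sd,
              min_circ_size = min_circ_size, error_rate = error_rate,
              seed = seed, n_chroms = n_chroms,
              chrom_length = chrom_length, n_linear = n_linear)
  writeLines(c("key\tvalue", paste(names(params), params, sep = "\t")),
             manifest)

  list(genome = genome_path, fastq1 = fq1, fastq2 = fq2, sam = sam_path,
       truth_path = truth_path, manifest = manifest, truth = truth,
       reads = reads)
}

#' Select truth-based positive and negative candidate sets
#'
#' Ranks the simulated circRNAs by true junction-supporting read count and
#' returns the top fraction as true positives and the bottom fraction as
#' true negatives (defaults: top 2%, bottom 1%, at least one each). Ties are
#' broken by candidate id so the selection is deterministic.
#'
#' @param truth Truth tibble from [simulate_dataset()] (or read from
#'   `truth.tsv`).
#' @param top_frac Fraction of circRNAs taken as positives (default 0.02).
#' @param bottom_frac Fraction taken as negatives (default 0.01).
#' @return List of tibbles `positives` and `negatives` (truth rows).
#' @export
truth_sets <- function(truth, top_frac = 0.02, bottom_frac = 0.01) {
  circ <- truth[truth$class == "circRNA", ]
  if (nrow(circ) == 0) stop("truth table contains no circRNAs")
  n <- nrow(circ)
  desc_ord <- circ[order(-circ$n_supporting, circ$id), ]
  asc_ord <- circ[order(circ$n_supporting, circ$id), ]
  list(positives = desc_ord[seq_len(ceiling(top_frac * n)), ],
       negatives = asc_ord[seq_len(ceiling(bottom_frac * n)), ])
}
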