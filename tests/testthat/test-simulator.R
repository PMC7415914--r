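test_that("simulation is byte-deterministic for a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  a <- simulate_dataset(d1, n_circ = 5, n_linear = 2, circ_coverage = 8,
                        read_length = 100, seed = 61, chrom_length = 2e5)
  b <- simulate_dataset(d2, n_circ = 5, n_linear = 2, circ_coverage = 8,
                        read_length = 100, seed = 61, chrom_length = 2e5)
  for (f in c("genome", "fastq1", "fastq2", "sam", "truth_path")) {
    expect_identical(readBin(a[[f]], "raw", file.size(a[[f]])),
                     readBin(b[[f]], "raw", file.size(b[[f]])),
                     label = f)
  }
})

test_that("random genomes are GC-balanced and multi-contig aware", {
  fa <- tempfile(fileext = ".fa")
  simulate_genome(fa, n_chroms = 2, chrom_length = 5e5, seed = 62)
  seqs <- read_fasta(fa)
  expect_identical(names(seqs), c("chr1", "chr2"))
  gc <- sum(stringr::str_count(seqs, "[GC]")) / sum(nchar(seqs))
  expect_lt(abs(gc - 0.5), 0.02)

  # determinism at the byte level
  fa2 <- tempfile(fileext = ".fa")
  simulate_genome(fa2, n_chroms = 2, chrom_length = 5e5, seed = 62)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fa2, "raw", file.size(fa2)))
})

test_that("supporting-read counts are calibrated to circ_coverage", {
  sim <- shared_sim("cov10", n_circ = 50, n_linear = 5, circ_coverage = 10,
                    linear_coverage = 10, read_length = 150, seed = 63,
                    chrom_length = 2e6)
  circ <- sim$truth[sim$truth$class == "circRNA", ]
  expect_identical(nrow(circ), 50L)
  m <- mean(circ$n_supporting)
  expect_gte(m, 8); expect_lte(m, 12)
})

test_that("error-free reads are substrings of their rotated source", {
  sim <- shared_sim("cov10", n_circ = 50, n_linear = 5, circ_coverage = 10,
                    linear_coverage = 10, read_length = 150, seed = 63,
                    chrom_length = 2e6)
  genome <- read_fasta(sim$genome)
  fq <- dplyr::bind_rows(read_fastq(sim$fastq1), read_fastq(sim$fastq2))
  locus_of <- stats::setNames(seq_len(nrow(sim$truth)),
                              sim$truth$id)
  src_of <- function(row) {
    s <- substr(genome[[row$chrom]], row$start + 1, row$end)
    if (row$class == "circRNA") strrep(s, ceiling(1000 / nchar(s)) + 1)
    else s
  }
  ids <- sub("_p\\d+/[12]$", "", fq$name)
  for (i in sample(nrow(fq), 200)) {
    row <- sim$truth[locus_of[[ids[i]]], ]
    src <- src_of(row)
    hit <- grepl(fq$sequence[i], src, fixed = TRUE) ||
      grepl(revcomp(fq$sequence[i]), src, fixed = TRUE)
    expect_true(hit, label = fq$name[i])
  }
})

test_that("SAM records are parseable and stay inside their locus", {
  sim <- shared_sim("cov10", n_circ = 50, n_linear = 5, circ_coverage = 10,
                    linear_coverage = 10, read_length = 150, seed = 63,
                    chrom_length = 2e6)
  bam <- Rsamtools::asBam(sim$sam, tempfile(), overwrite = TRUE)
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "pos", "cigar")))[[1]]
  expect_identical(length(rec$qname), nrow(sim$reads))
  ids <- sub("_p\\d+$", "", rec$qname)
  truth <- sim$truth
  idx <- match(ids, truth$id)
  spans <- vapply(rec$cigar, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "D")])
  }, integer(1), USE.NAMES = FALSE)
  expect_true(all(rec$pos - 1L >= truth$start[idx]))
  expect_true(all(rec$pos - 1L + spans <= truth$end[idx]))
})

test_that("truth supporting counts match a brute-force recount", {
  sim <- shared_sim("recount", n_circ = 10, n_linear = 2, circ_coverage = 8,
                    linear_coverage = 6, read_length = 100, seed = 64,
                    chrom_length = 3e5)
  genome <- read_fasta(sim$genome)
  fq <- dplyr::bind_rows(read_fastq(sim$fastq1), read_fastq(sim$fastq2))
  circ <- sim$truth[sim$truth$class == "circRNA", ]
  for (i in seq_len(nrow(circ))) {
    row <- circ[i, ]
    L <- row$end - row$start
    circle <- substr(genome[[row$chrom]], row$start + 1, row$end)
    doubled <- strrep(circle, max(2, ceiling(200 / L) + 1))
    jpoints <- L * seq_len(max(1, nchar(doubled) %/% L) - 1)
    mine <- fq[startsWith(fq$name, paste0(row$id, "_")), ]
    crossing <- vapply(mine$sequence, function(s) {
      for (cand in c(s, revcomp(s))) {
        hits <- stringr::str_locate_all(doubled, stringr::fixed(cand))[[1]]
        for (h in seq_len(nrow(hits))) {
          a <- hits[h, 1] - 1; b <- hits[h, 2]  # 0-based [a, b)
          if (any(jpoints > a & jpoints < b)) return(TRUE)
        }
      }
      FALSE
    }, logical(1), USE.NAMES = FALSE)
    expect_identical(sum(crossing), row$n_supporting, label = row$id)
  }
})

test_that("truth positive/negative selection follows the rank rules", {
  truth <- tibble::tibble(
    id = sprintf("circ_%03d", 1:100), chrom = "chr1",
    start = 1:100 * 10L, end = 1:100 * 10L + 500L,
    circle_length = 500L,
    n_supporting = rep(c(5L, 20L), 50),
    class = "circRNA")
  sets <- truth_sets(truth)
  expect_identical(nrow(sets$positives), 2L)
  expect_identical(nrow(sets$negatives), 1L)
  expect_gte(min(sets$positives$n_supporting),
             max(sets$negatives$n_supporting))

  # all-equal counts: selection falls back to id order, deterministically
  truth$n_supporting <- 7L
  sets <- truth_sets(truth)
  expect_identical(sets$positives$id, c("circ_001", "circ_002"))
  expect_identical(sets$negatives$id, "circ_001")

  # n_circ = 0 is rejected
  expect_error(truth_sets(truth[truth$class == "linear", ]), "no circRNAs")
})
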