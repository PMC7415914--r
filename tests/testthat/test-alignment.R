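make_ref <- function(seq, name = "pseudo") list(name = name, sequence = seq)

test_that("scores match the Biostrings local-alignment oracle", {
  suppressPackageStartupMessages(requireNamespace("Biostrings"))
  set.seed(41)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                                  baseOnly = TRUE)
  for (i in 1:60) {
    q <- rnd_seq(sample(20:200, 1))
    r <- rnd_seq(sample(20:200, 1))
    if (i %% 2 == 0) {  # plant shared homology half the time
      core <- rnd_seq(sample(25:60, 1))
      q <- paste0(substr(q, 1, 20), core, substr(q, 21, 50))
      r <- paste0(substr(r, 1, 15), core, substr(r, 16, 40))
    }
    mine <- backsplicer:::.sw_align(q, r)$score
    oracle <- Biostrings::score(Biostrings::pairwiseAlignment(
      q, r, type = "local", substitutionMatrix = mat,
      gapOpening = 6, gapExtension = 1))
    expect_identical(mine, as.integer(max(oracle, 0)))
  }
})

test_that("exact substring contigs align full-length without clips", {
  set.seed(42)
  ref <- make_ref(rnd_seq(600))
  ctg <- substr(ref$sequence, 251, 350)
  hits <- align_contigs(ctg, ref)
  plus <- hits[hits$strand == "+", ]
  expect_identical(plus$ref_start, 250L)
  expect_identical(plus$ref_end, 350L)
  expect_identical(plus$score, 100L)
  expect_identical(plus$cigar, "100M")
})

test_that("reverse-complement contigs align on the minus strand, same span", {
  set.seed(43)
  ref <- make_ref(rnd_seq(600))
  ctg <- substr(ref$sequence, 251, 350)
  fwd <- align_contigs(ctg, ref)
  rev <- align_contigs(revcomp(ctg), ref)
  f <- fwd[which.max(fwd$score), ]
  r <- rev[which.max(rev$score), ]
  expect_identical(r$ref_start, f$ref_start)
  expect_identical(r$ref_end, f$ref_end)
  expect_identical(r$score, f$score)
  expect_identical(sort(c(f$strand, r$strand)), c("+", "-"))
})

test_that("unaligned contig ends become soft-clips", {
  set.seed(44)
  ref <- make_ref(rnd_seq(600))
  flank <- rnd_seq(20)
  ctg <- paste0(flank, substr(ref$sequence, 251, 350))
  hits <- align_contigs(ctg, ref)
  plus <- hits[hits$strand == "+", ]
  expect_identical(plus$ref_start, 250L)
  expect_identical(plus$ref_end, 350L)
  expect_match(plus$cigar, "^20S")
})

test_that("CIGAR replay reproduces the reported score and spans", {
  set.seed(45)
  for (i in 1:25) {
    ref <- make_ref(rnd_seq(300))
    # mutate a copied slice: substitutions and a small indel
    a <- sample(1:100, 1)
    ctg <- substr(ref$sequence, a, a + 149)
    pos <- sample(20:130, 3)
    for (p in pos) {
      substr(ctg, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (i %% 2 == 0) ctg <- paste0(substr(ctg, 1, 60), substr(ctg, 66, 150))
    hits <- align_contigs(ctg, ref, min_score = 20)
    for (j in seq_len(nrow(hits))) {
      h <- hits[j, ]
      q <- if (h$strand == "+") ctg else revcomp(ctg)
      rp <- replay_score(q, ref$sequence, h$ref_start, h$cigar)
      expect_identical(rp$score, as.numeric(h$score))
      expect_identical(rp$query_consumed, nchar(ctg))
      expect_identical(rp$ref_end, h$ref_end)
    }
  }
})

test_that("contigs below min_score are not reported", {
  set.seed(46)
  ref <- make_ref(rnd_seq(400))
  expect_identical(nrow(align_contigs(rnd_seq(60), ref, min_score = 40)), 0L)
})

test_that("alignment SAM is valid and 1-based", {
  set.seed(47)
  ref <- make_ref(rnd_seq(600), name = "chr9:100-700")
  contigs <- tibble::tibble(
    id = c("c1", "c2"),
    sequence = c(substr(ref$sequence, 251, 350),
                 revcomp(substr(ref$sequence, 101, 220))),
    read_support = c(5L, 4L))
  alns <- align_contigs(contigs, ref)
  sam <- tempfile(fileext = ".sam")
  write_alignments_sam(alns, contigs, ref, sam)

  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  fields <- strsplit(body, "\t")
  pos <- as.integer(vapply(fields, `[[`, "", 4))
  expect_identical(sort(pos), sort(alns$ref_start + 1L))

  flags <- as.integer(vapply(fields, `[[`, "", 2))
  minus <- vapply(fields, `[[`, "", 1) %in%
    alns$contig_id[alns$strand == "-"]
  expect_identical(bitwAnd(flags, 16L) != 0L, minus)
  # minus-strand SEQ is stored reference-forward
  c2 <- fields[[which(vapply(fields, `[[`, "", 1) == "c2")]]
  expect_identical(c2[10], revcomp(contigs$sequence[2]))

  # round trip through an independent SAM parser
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  parsed <- Rsamtools::scanBam(bam)[[1]]
  expect_identical(sort(as.character(parsed$qname)), c("c1", "c2"))
})
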