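test_that("junction overlap counts aligned reference bases per side", {
  expect_identical(junction_overlap(270, "70M", 300),
                   c(left = 30L, right = 40L))
  expect_identical(junction_overlap(0, "250M", 300),
                   c(left = 250L, right = 0L))
  # a deletion spanning the junction advances the reference but counts
  # on neither side
  expect_identical(junction_overlap(280, "15M10D25M", 300),
                   c(left = 15L, right = 25L))
  # insertions and soft clips never count
  expect_identical(junction_overlap(280, "10S20M5I20M10S", 300),
                   c(left = 20L, right = 20L))
})

test_that("verdicts require one record qualifying on both sides", {
  lv <- stringency_levels()
  mk <- function(starts, cigars) {
    tibble::tibble(contig_id = paste0("c", seq_along(starts)),
                   ref_name = "p", ref_start = starts,
                   ref_end = starts, strand = "+", cigar = cigars,
                   score = 1L)
  }
  # one record with 30 left / 40 right passes everything
  ev <- evaluate_alignments(mk(270, "70M"), 300)
  expect_true(all(ev$verdicts))
  expect_identical(ev$supporting$HS, "c1")

  # (10, 400) and (300, 8): LS passes via record 1 only; MS/HS fail
  ev <- evaluate_alignments(mk(c(290, 0), c("410M", "308M")), 300)
  expect_identical(unname(ev$verdicts),
                   c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(ev$supporting$LS, "c1")
  expect_identical(ev$best_left, 10L)
  expect_identical(ev$best_right, 400L)

  # empty alignments: everything fails
  ev <- evaluate_alignments(mk(integer(0), character(0)), 300)
  expect_false(any(ev$verdicts))
})

test_that("verdict monotonicity holds across random alignment sets", {
  set.seed(51)
  for (i in 1:50) {
    n <- sample(1:5, 1)
    starts <- sample(0:590, n, replace = TRUE)
    lens <- sample(20:200, n, replace = TRUE)
    alns <- tibble::tibble(
      contig_id = paste0("c", seq_len(n)), ref_name = "p",
      ref_start = starts, ref_end = starts + lens, strand = "+",
      cigar = paste0(lens, "M"), score = lens)
    v <- evaluate_alignments(alns, 300)$verdicts
    expect_true(all(v[c("HS", "MS", "LS")] <= v[c("MS", "LS", "VLS")]))
  }
})

test_that("a pseudo-reference aligned against itself passes high stringency", {
  set.seed(52)
  fa <- toy_fasta(rnd_seq(3000))
  ps <- build_pseudo_reference(fa, list(chrom = "chr1", start = 500,
                                        end = 2500), w = 300)
  alns <- align_contigs(ps$sequence, ps)
  ev <- evaluate_alignments(alns, ps$junction_offset)
  expect_true(ev$verdicts[["HS"]])
})

test_that("the pipeline validates planted junctions end to end", {
  sim <- shared_sim("cov20", n_circ = 25, n_linear = 8, circ_coverage = 20,
                    linear_coverage = 10, read_length = 150, seed = 101,
                    chrom_length = 1e6)
  circ <- sim$truth[sim$truth$class == "circRNA" & sim$truth$n_supporting > 0, ]
  rep <- validate_junctions(circ[, c("chrom", "start", "end", "id")],
                            sim$sam, sim$genome, w = 300)
  register_report(rep)
  expect_s3_class(rep, "bsj_report")
  expect_identical(rep$candidate_id, circ$id)
  expect_gte(mean(rep$pass_VLS), 0.95)
  expect_true(all(rep$n_reads_extracted[rep$failure_stage == "none"] > 0))
})

test_that("linear-only loci never validate (negative control)", {
  sim <- shared_sim("cov20", n_circ = 25, n_linear = 8, circ_coverage = 20,
                    linear_coverage = 10, read_length = 150, seed = 101,
                    chrom_length = 1e6)
  lin <- sim$truth[sim$truth$class == "linear", ]
  rep <- validate_junctions(lin[, c("chrom", "start", "end", "id")],
                            sim$sam, sim$genome, w = 300)
  register_report(rep)
  expect_false(any(rep$pass_VLS))
  expect_false(any(rep$pass_HS))
})

test_that("a candidate with no reads fails at the extraction stage", {
  set.seed(53)
  fa <- toy_fasta(rnd_seq(5000))
  recs <- data.frame(qname = "r1", flag = 0L, chrom = "chr1", pos0 = 100L,
                     cigar = "100M", seq = rnd_seq(100))
  sam <- toy_sam(recs, c(chr1 = 5000L))
  rep <- validate_candidate(sam, fa, list(chrom = "chr1", start = 3000,
                                          end = 4000))
  expect_identical(rep$failure_stage, "no_reads")
  expect_false(any(unlist(rep[paste0("pass_",
                                     stringency_levels()$label)])))
})

test_that("candidate sanity checks raise staged errors", {
  set.seed(54)
  fa <- toy_fasta(rnd_seq(1000))
  sam <- toy_sam(data.frame(qname = "r", flag = 0L, chrom = "chr1",
                            pos0 = 0L, cigar = "50M", seq = rnd_seq(50)),
                 c(chr1 = 1000L))
  expect_error(validate_candidate(sam, fa, list(chrom = "chr1", start = 10,
                                                end = 30)),
               "minimum circRNA size")
  expect_error(validate_candidate(sam, fa, list(chrom = "chr1", start = 10,
                                                end = 3000)),
               "past end")
})

test_that("keep_dir writes per-candidate intermediates", {
  sim <- shared_sim("cov20", n_circ = 25, n_linear = 8, circ_coverage = 20,
                    linear_coverage = 10, read_length = 150, seed = 101,
                    chrom_length = 1e6)
  circ <- sim$truth[sim$truth$class == "circRNA" &
                      sim$truth$n_supporting > 0, ][1, ]
  keep <- tempfile("keep")
  rep <- validate_junctions(circ[, c("chrom", "start", "end", "id")],
                            sim$sam, sim$genome, keep_dir = keep)
  register_report(rep)
  files <- list.files(keep)
  expect_true(any(grepl("reads\\.fastq$", files)))
  expect_true(any(grepl("contigs\\.fasta$", files)))
  expect_true(any(grepl("pseudoref\\.fasta$", files)))
  expect_true(any(grepl("contigs\\.sam$", files)))
})
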