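# Shared fixtures, all generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

rnd_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# toy single-contig FASTA; returns its path
toy_fasta <- function(seq, name = "chr1", dir = tempfile("fa")) {
  dir.create(dir, showWarnings = FALSE)
  path <- file.path(dir, "toy.fa")
  write_fasta(stats::setNames(seq, name), path)
  path
}

# minimal SAM writer for hand-built records:
# records = data.frame(qname, flag, chrom, pos0, cigar, seq)
toy_sam <- function(records, sq_lens, path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", names(sq_lens), "\tLN:", sq_lens))
  records <- records[order(match(records$chrom, names(sq_lens)),
                           records$pos0), ]
  body <- paste(records$qname, records$flag, records$chrom,
                records$pos0 + 1L, 60L, records$cigar, "*", 0L, 0L,
                records$seq, strrep("I", nchar(records$seq)), sep = "\t")
  writeLines(c(header, body), path)
  path
}

# memoised simulated datasets shared across test files (helpers are sourced
# once per test run, so the cache lives for the whole suite)
.sim_cache <- new.env(parent = emptyenv())
shared_sim <- function(name, ...) {
  if (is.null(.sim_cache[[name]])) {
    .sim_cache[[name]] <- simulate_dataset(
      file.path(tempdir(), paste0("sim_", name)), ...)
  }
  .sim_cache[[name]]
}

# the suite-wide monotonicity ledger: every bsj_report produced anywhere in
# the tests is registered here and checked once at the end of the suite
.report_ledger <- new.env(parent = emptyenv())
.report_ledger$reports <- list()
register_report <- function(report) {
  .report_ledger$reports <- c(.report_ledger$reports, list(report))
  invisible(report)
}

# independent CIGAR replay used to cross-check alignment records: walks the
# CIGAR over the raw sequences and recomputes the affine-gap score
replay_score <- function(query, ref, ref_start, cigar,
                         match = 1, mismatch = 4,
                         gap_open = 6, gap_extend = 1) {
  ops <- parse_cigar(cigar)
  qi <- 0L; ri <- ref_start
  sc <- 0
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op == "S") {
      qi <- qi + len
    } else if (op == "M") {
      qs <- substring(query, qi + 1L, qi + len)
      rs <- substring(ref, ri + 1L, ri + len)
      eq <- sum(strsplit(qs, "")[[1]] == strsplit(rs, "")[[1]])
      sc <- sc + eq * match - (len - eq) * mismatch
      qi <- qi + len; ri <- ri + len
    } else if (op == "I") {
      sc <- sc - gap_open - len * gap_extend
      qi <- qi + len
    } else if (op == "D") {
      sc <- sc - gap_open - len * gap_extend
      ri <- ri + len
    }
  }
  list(score = sc, query_consumed = qi, ref_end = ri)
}
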