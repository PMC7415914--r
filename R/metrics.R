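#' F1 score from precision and sensitivity
#'
#' Harmonic mean `2PS / (P + S)`; returns 0 when both are zero (documented
#' convention so batch summaries never divide by zero).
#'
#' @param precision,sensitivity Fractions in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @examples
#' f1_score(0.8, 0.6)
#' @export
f1_score <- function(precision, sensitivity) {
  stopifnot(precision >= 0, precision <= 1,
            sensitivity >= 0, sensitivity <= 1)
  ifelse(precision + sensitivity == 0, 0,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' Spliced reads per billion mappings (SRPBM)
#'
#' `supporting / total_mapped * 1e9` — the junction-supporting read count
#' normalised by library size, used to compare circRNA expression before
#' and after RNase R enrichment.
#'
#' @param supporting Number of junction-supporting reads.
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return SRPBM value.
#' @examples
#' srpbm(10, 1e9)
#' @export
srpbm <- function(supporting, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  supporting / total_mapped * 1e9
}

#' Is a candidate depleted by RNase R enrichment?
#'
#' RNase R digests linear RNA but spares circles, so a true circRNA's
#' normalised expression should not decrease after treatment. A candidate
#' is depleted only when SRPBM strictly decreases; equality counts as not
#' depleted. (The strict-inequality reading — requiring an increase — is
#' the documented alternative.)
#'
#' @param srpbm_treated SRPBM after RNase R treatment.
#' @param srpbm_untreated SRPBM before treatment.
#' @return Logical: `TRUE` when depleted.
#' @export
is_depleted <- function(srpbm_treated, srpbm_untreated) {
  srpbm_treated < srpbm_untreated
}

#' Summarise a validation run against truth sets
#'
#' Counts true/false positives/negatives at one stringency level: a true
#' positive is a truth-positive candidate passing the level, a false
#' positive a truth-negative candidate passing it. Division-by-zero cases
#' (no positives, no calls) return 0 with a warning rather than erroring.
#'
#' @param report `bsj_report` tibble from [validate_junctions()].
#' @param positives,negatives Character vectors of candidate ids (disjoint).
#' @param level Stringency label: `"HS"`, `"MS"`, `"LS"` or `"VLS"`.
#' @return One-row tibble: `level`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `precision`, `f1`.
#' @export
evaluate_run <- function(report, positives, negatives, level = "LS") {
  stopifnot(level %in% stringency_levels()$label,
            length(intersect(positives, negatives)) == 0)
  col <- paste0("pass_", level)
  passed <- report$candidate_id[report[[col]]]
  tp <- sum(positives %in% passed)
  fn <- length(positives) - tp
  fp <- sum(negatives %in% passed)
  tn <- length(negatives) - fp
  safe_rate <- function(num, den, what) {
    if (den == 0) {
      warning("no ", what, "; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  sens <- safe_rate(tp, tp + fn, "positives")
  prec <- safe_rate(tp, tp + fp, "calls")
  tibble::tibble(level = level, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, precision = prec,
                 f1 = f1_score(prec, sens))
}

#' Benchmark a simulated dataset across stringency levels and window sizes
#'
#' Runs the full validation pipeline over the truth-derived positive and
#' negative candidate sets of a simulated dataset for each requested window
#' size, then summarises sensitivity/precision/F1 at every stringency level —
#' the desk-scale analogue of a sensitivity grid over simulation conditions.
#'
#' @param dataset List from [simulate_dataset()], or a dataset directory
#'   containing `genome.fa`, `reads.sam` and `truth.tsv`.
#' @param w Window sizes to test (default `c(300, 600)`).
#' @param top_frac,bottom_frac Truth-set fractions (see [truth_sets()]).
#' @param ... Passed to [validate_junctions()].
#' @return A `bsj_benchmark` tibble: one row per (window, level) with the
#'   [evaluate_run()] columns.
#' @export
benchmark_dataset <- function(dataset, w = c(300L, 600L),
                              top_frac = 0.02, bottom_frac = 0.01, ...) {
  if (is.character(dataset)) {
    dataset <- list(
      genome = file.path(dataset, "genome.fa"),
      sam = file.path(dataset, "reads.sam"),
      truth = readr::read_tsv(file.path(dataset, "truth.tsv"),
                              show_col_types = FALSE))
  }
  if (!file.exists(dataset$sam)) stop("missing alignment file: ", dataset$sam)
  sets <- truth_sets(dataset$truth, top_frac, bottom_frac)
  cands <- dplyr::bind_rows(sets$positives, sets$negatives)
  grid <- purrr::map(w, function(wi) {
    rep <- validate_junctions(cands[, c("chrom", "start", "end", "id")],
                              dataset$sam, dataset$genome, w = wi, ...)
    lv <- purrr::map(stringency_levels()$label, function(l) {
      evaluate_run(rep, sets$positives$id, sets$negatives$id, l)
    })
    dplyr::mutate(dplyr::bind_rows(lv), w = wi, .before = 1)
  })
  out <- dplyr::bind_rows(grid)
  class(out) <- c("bsj_benchmark", class(out))
  out
}
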