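#' Tidy a validation report into long verdict form
#'
#' @param x A `bsj_report` from [validate_junctions()].
#' @param ... Unused.
#' @return Tibble with one row per candidate x stringency level:
#'   `candidate_id`, `level`, `per_side_bp`, `pass`, plus the per-candidate
#'   diagnostics.
#' @export
tidy.bsj_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("pass_",
                                             stringency_levels()$label)),
                        names_to = "level", names_prefix = "pass_",
                        values_to = "pass") |>
    dplyr::left_join(stringency_levels(), by = c(level = "label")) |>
    dplyr::select("candidate_id", "chrom", "start", "end", "w", "level",
                  "per_side_bp", "pass", "n_reads_extracted", "n_contigs",
                  "best_left_overlap", "best_right_overlap", "failure_stage")
}

#' One-row summary of a validation report
#'
#' @param x A `bsj_report`.
#' @param ... Unused.
#' @return One-row tibble: candidate count, pass counts per level, and the
#'   count of candidates failing at each pipeline stage.
#' @export
glance.bsj_report <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_pass_HS = sum(x$pass_HS), n_pass_MS = sum(x$pass_MS),
    n_pass_LS = sum(x$pass_LS), n_pass_VLS = sum(x$pass_VLS),
    n_no_reads = sum(x$failure_stage == "no_reads"),
    n_no_contigs = sum(x$failure_stage == "no_contigs"),
    n_no_alignment = sum(x$failure_stage == "no_alignment"),
    n_no_junction_overlap = sum(x$failure_stage == "no_junction_overlap"))
}

#' Plot per-candidate junction overlap against the stringency thresholds
#'
#' Scatter of best left vs best right aligned overlap for every candidate,
#' with the four per-side stringency thresholds drawn as reference lines; a
#' candidate passes a level when its best single alignment clears the
#' threshold on both axes.
#'
#' @param object A `bsj_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsj_report <- function(object, ...) {
  thr <- stringency_levels()
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$best_left_overlap,
                               y = .data$best_right_overlap,
                               colour = .data$failure_stage)) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$per_side_bp),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_vline(data = thr,
                        ggplot2::aes(xintercept = .data$per_side_bp),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "best aligned bases left of junction",
                  y = "best aligned bases right of junction",
                  colour = "failure stage")
}

#' Tidy a benchmark grid
#'
#' @param x A `bsj_benchmark` from [benchmark_dataset()].
#' @param ... Unused.
#' @return Long tibble with `w`, `level`, `metric`, `value`.
#' @export
tidy.bsj_benchmark <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("sensitivity", "precision", "f1"),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("w", "level", "metric", "value", "tp", "fp", "tn", "fn")
}

#' One-row summary of a benchmark grid
#'
#' @param x A `bsj_benchmark`.
#' @param ... Unused.
#' @return One-row tibble with the sensitivity range across levels and
#'   windows and the mean F1.
#' @export
glance.bsj_benchmark <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    min_sensitivity = min(x$sensitivity),
    max_sensitivity = max(x$sensitivity),
    mean_f1 = mean(x$f1))
}

#' Plot benchmark sensitivity across stringency levels and windows
#'
#' @param object A `bsj_benchmark`.
#' @param ... Unused.
#' @return A ggplot object: sensitivity per stringency level, one line per
#'   window size.
#' @export
autoplot.bsj_benchmark <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$level <- factor(d$level, levels = stringency_levels()$label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$sensitivity,
                                  group = factor(.data$w),
                                  colour = factor(.data$w))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "overlap stringency", y = "sensitivity",
                  colour = "window (bp)")
}
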