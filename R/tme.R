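#' Trait measurement error
#'
#' TME is the absolute difference between the scale-based and image-based
#' body weight of the same animal on the same occasion; the percentage uses
#' the scale weight as denominator (consistent with MAPE).
#'
#' @param data Data frame with paired scale and image body weights.
#' @param scale_col,image_col Column names of the two measurements.
#' @return `data` with `tme` (kg) and `tme_percent` appended.
#' @examples
#' compute_tme(tibble::tibble(scale_bw = 100, image_bw = 98))
#' @export
compute_tme <- function(data, scale_col = "scale_bw",
                        image_col = "image_bw") {
  miss <- setdiff(c(scale_col, image_col), names(data))
  if (length(miss))
    abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  s <- data[[scale_col]]
  i <- data[[image_col]]
  if (anyNA(s) || anyNA(i))
    abort("unpaired records: NA in scale or image body weight.")
  if (any(s <= 0)) abort("scale body weight must be positive.")
  dplyr::mutate(data, tme = abs(s - i), tme_percent = 100 * abs(s - i) / s)
}

#' Top-k agreement between two GWAS rankings
#'
#' Counts how many of the `k_top` top-ranked markers of the reference scan
#' appear among the `k_ref` top-ranked markers of the other scan, both ranked
#' by `-log10 p` (ties by marker index).
#'
#' @param rank_ref,rank_other `gwas_result` objects (or tibbles with
#'   `marker_id` and `rank`) over the same marker universe.
#' @param k_top Size of the reference top list (default 10).
#' @param k_ref Size of the other scan's top list (default 100).
#' @return Integer count in `[0, k_top]`.
#' @export
topk_agreement <- function(rank_ref, rank_other, k_top = 10, k_ref = 100) {
  if (!setequal(rank_ref$marker_id, rank_other$marker_id))
    abort("marker sets differ between the two rankings.")
  top_ref <- rank_ref$marker_id[order(rank_ref$rank)][seq_len(k_top)]
  top_oth <- rank_other$marker_id[order(rank_other$rank)][seq_len(k_ref)]
  length(intersect(top_ref, top_oth))
}

#' Animals with consistently extreme measurement error
#'
#' Flags animals in the top (or bottom) `quantile` of TME at `min_times` or
#' more time points.
#'
#' @param tme_data Tibble with `animal_id`, `time_point`, `tme` (one method).
#' @param quantile Extremeness cutoff as a fraction (default decile, 0.1).
#' @param min_times Minimum number of qualifying time points (default 2).
#' @return Tibble `animal_id`, `group` (`"high"`/`"low"`), `n_time_points`.
#' @export
tme_consistency <- function(tme_data, quantile = 0.1, min_times = 2) {
  ranked <- tme_data |>
    dplyr::group_by(.data$time_point) |>
    dplyr::mutate(
      hi = .data$tme >= stats::quantile(.data$tme, 1 - quantile,
                                        type = 1),
      lo = .data$tme <= stats::quantile(.data$tme, quantile, type = 1)
    ) |>
    dplyr::ungroup()
  counts <- ranked |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(n_high = sum(.data$hi), n_low = sum(.data$lo))
  dplyr::bind_rows(
    counts |> dplyr::filter(.data$n_high >= min_times) |>
      dplyr::transmute(.data$animal_id, group = "high",
                       n_time_points = .data$n_high),
    counts |> dplyr::filter(.data$n_low >= min_times) |>
      dplyr::transmute(.data$animal_id, group = "low",
                       n_time_points = .data$n_low)
  )
}

#' Assemble the TME comparison report
#'
#' Gathers the stage outputs into the four-table report: prediction fit
#' metrics per method and time point; the heritability triple (scale BW,
#' image BW, TME) per method and time point; top-k agreement and TME-overlap
#' counts; and the per-animal TME table with the consistently-extreme listing.
#' Missing stages leave their table `NULL` and are named in `$gaps`.
#'
#' @param fit_metrics Tibble from the regression stage (or `NULL`).
#' @param heritability Tibble of h2 estimates (or `NULL`).
#' @param agreement Tibble of agreement counts (or `NULL`).
#' @param tme Per-animal TME tibble (or `NULL`).
#' @param consistency_quantile Cutoff passed to [tme_consistency()].
#' @param render_validation Optional rendered-subset comparison tibble.
#' @return Object of class `tme_report`.
#' @export
assemble_tme_report <- function(fit_metrics = NULL, heritability = NULL,
                                agreement = NULL, tme = NULL,
                                consistency_quantile = 0.1,
                                render_validation = NULL) {
  consistency <- NULL
  if (!is.null(tme) && length(unique(tme$time_point)) >= 2) {
    consistency <- tme |>
      dplyr::group_by(.data$method) |>
      dplyr::group_modify(~ tme_consistency(.x, consistency_quantile)) |>
      dplyr::ungroup()
  }
  tables <- list(fit_metrics = fit_metrics, heritability = heritability,
                 agreement = agreement, tme = tme,
                 consistency = consistency,
                 render_validation = render_validation)
  gaps <- names(tables)[vapply(tables, is.null, logical(1))]
  gaps <- setdiff(gaps, c("consistency", "render_validation"))
  structure(c(tables, list(gaps = gaps)), class = "tme_report")
}

#' @export
print.tme_report <- function(x, ...) {
  cat("<tme_report>\n")
  if (!is.null(x$fit_metrics)) {
    cat("  fit metrics (held-out):\n")
    held <- dplyr::filter(x$fit_metrics, .data$split == "test")
    for (i in seq_len(nrow(held)))
      cat(sprintf("    %s %s: R2 = %.2f, MAPE = %.2f%%\n",
                  held$time_point[i], held$method[i], held$r2[i],
                  held$mape[i]))
  }
  if (!is.null(x$heritability)) {
    cat("  heritability (h2 [SE]):\n")
    for (i in seq_len(nrow(x$heritability)))
      cat(sprintf("    %s %s %s: %.2f (%.2f)\n",
                  x$heritability$time_point[i], x$heritability$method[i],
                  x$heritability$trait[i], x$heritability$h2[i],
                  x$heritability$se_h2[i]))
  }
  if (!is.null(x$agreement)) {
    cat("  GWAS top-k:\n")
    for (i in seq_len(nrow(x$agreement)))
      cat(sprintf("    %s %s: agreement %d/%d, TME overlap %d/%d\n",
                  x$agreement$time_point[i], x$agreement$method[i],
                  x$agreement$agreement[i], x$agreement$k_top[i],
                  x$agreement$tme_overlap[i], x$agreement$k_top[i]))
  }
  if (length(x$gaps))
    cat("  missing stages:", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

#' Box plot of TME percentages by method and time point
#'
#' @param object A `tme_report` with a `tme` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tme_report <- function(object, ...) {
  if (is.null(object$tme)) abort("report has no per-animal TME table.")
  ggplot2::ggplot(object$tme,
                  ggplot2::aes(x = .data$time_point, y = .data$tme_percent,
                               fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "time point", y = "trait measurement error (%)",
                  fill = "method") +
    ggplot2::theme_minimal()
}

#' TME trajectories of consistently extreme animals
#'
#' Line plot of TME over time points for the animals flagged by
#' [tme_consistency()].
#'
#' @param report A `tme_report` with `tme` and `consistency` tables.
#' @param method Method whose TME is drawn (default first).
#' @return A ggplot.
#' @export
plot_tme_trajectories <- function(report, method = NULL) {
  if (is.null(report$consistency))
    abort("report has no consistency table (needs >= 2 time points).")
  if (is.null(method)) method <- report$tme$method[1]
  keep <- dplyr::filter(report$consistency, .data$method == !!method)
  df <- report$tme |>
    dplyr::filter(.data$method == !!method,
                  .data$animal_id %in% keep$animal_id) |>
    dplyr::left_join(dplyr::select(keep, "animal_id", "group"),
                     by = "animal_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_point, y = .data$tme,
                                   group = .data$animal_id,
                                   colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time point", y = "TME (kg)", colour = "TME group") +
    ggplot2::theme_minimal()
}
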