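# Reporting: shifted-MI regulon profiles (plot data and ggplot2 views)
# and human-readable run summaries. Pure views over conditional records —
# no statistic is recomputed here.

#' Shifted-MI profile of a regulon under one modulator
#'
#' Targets are ranked by `mi_original` descending (strongest TF-target
#' interactions first, ties broken by gene id); `mi_scaled` is
#' `mi_original` scaled to \[0, 1\] by the regulon maximum, and
#' `mi_shift_scaled = mi_scaled * (1 + dmi)` is the shifted value, so a
#' positive modulator lifts points above the profile and a negative one
#' pushes them below. Raw nats are preserved alongside the scaled values.
#'
#' @param regulon Regulon tibble for one TF.
#' @param records Conditional records covering the regulon (one modulator).
#' @return A tibble of class `mindy_shift_profile`: `rank`, `target`,
#'   `mi_original`, `mi_scaled`, `dmi`, `mi_shift`, `mi_shift_scaled`,
#'   `modulated`.
#' @export
shift_profile <- function(regulon, records) {
  stopifnot(nrow(records) > 0)
  missing <- setdiff(regulon$target, records$target)
  if (length(missing) > 0) {
    stop("records do not cover the regulon: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  prof <- records |>
    dplyr::filter(.data$target %in% regulon$target) |>
    dplyr::arrange(dplyr::desc(.data$mi_original), .data$target) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      mi_scaled = .data$mi_original / max(.data$mi_original),
      mi_shift_scaled = .data$mi_scaled * (1 + .data$dmi)
    ) |>
    dplyr::select("rank", "target", "tf", "modulator", "mi_original",
                  "mi_scaled", "dmi", "mi_shift", "mi_shift_scaled",
                  "modulated")
  class(prof) <- c("mindy_shift_profile", class(prof))
  prof
}

#' Plot a shifted-MI profile
#'
#' Grey points: scaled MI of every TF-target interaction across all
#' samples, ranked from strongest to weakest. Green points: the shifted
#' value for targets with a significant MI change between modulator
#' strata.
#'
#' @param object A `mindy_shift_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mindy_shift_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mi_scaled),
                        colour = "grey55", size = 1.6) +
    ggplot2::geom_point(
      data = dplyr::filter(object, .data$modulated),
      ggplot2::aes(y = .data$mi_shift_scaled),
      colour = "forestgreen", size = 2
    ) +
    ggplot2::labs(
      x = "target rank (MI descending)", y = "scaled MI",
      title = sprintf("%s regulon | modulator %s",
                      object$tf[1], object$modulator[1])
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mindy_shift_profile
#' @param profile A `mindy_shift_profile`.
#' @export
plot_shift_profile <- function(profile, ...) autoplot(profile, ...)

#' Shift profile of the top modulator of a fit
#'
#' @param object A `mindy_fit`.
#' @param ... Unused.
#' @return A ggplot (the profile of the most significant (TF, modulator)
#'   pair).
#' @export
autoplot.mindy_fit <- function(object, ...) {
  sig <- object$significant
  if (nrow(sig) == 0L) stop("no significant modulator to plot", call. = FALSE)
  top <- sig[order(sig$p_adj), ][1, ]
  recs <- dplyr::filter(object$records, .data$tf == top$tf,
                        .data$modulator == top$modulator)
  reg <- dplyr::filter(object$regulons, .data$tf == top$tf)
  autoplot(shift_profile(reg, recs))
}

#' Write a run summary and plot-ready profile tables
#'
#' Writes a markdown summary (per-TF counts of positive and negative
#' modulators and in-modulator calls) and, for every significant (TF,
#' modulator) pair, a profile TSV under `dir/profiles/`.
#'
#' @param fit A `mindy_fit`.
#' @param dir Output directory (created if needed).
#' @return Path of the summary file, invisibly.
#' @export
render_summary <- function(fit, dir) {
  stopifnot(inherits(fit, "mindy_fit"))
  dir.create(file.path(dir, "profiles"), showWarnings = FALSE, recursive = TRUE)
  sig <- fit$significant
  lines <- c("# Modulator inference summary", "",
             sprintf("- TFs analysed: %d", dplyr::n_distinct(fit$regulons$tf)),
             sprintf("- Candidates tested: %d",
                     dplyr::n_distinct(fit$summaries$modulator)),
             sprintf("- Significant modulators (adjusted p < %g): %d",
                     fit$config$alpha_adj, nrow(sig)),
             sprintf("- In-modulator calls: %d", nrow(fit$in_modulators)), "")
  if (nrow(sig) == 0L) {
    lines <- c(lines, "No significant modulators.", "")
  } else {
    counts <- sig |>
      dplyr::count(.data$tf, .data$sign) |>
      tidyr::pivot_wider(names_from = "sign", values_from = "n",
                         values_fill = 0L)
    lines <- c(lines, "## Per-TF counts", "",
               paste(utils::capture.output(print(as.data.frame(counts))),
                     collapse = "\n"), "")
    for (i in seq_len(nrow(sig))) {
      recs <- dplyr::filter(fit$records, .data$tf == sig$tf[i],
                            .data$modulator == sig$modulator[i])
      reg <- dplyr::filter(fit$regulons, .data$tf == sig$tf[i])
      prof <- shift_profile(reg, recs)
      write_results_table(
        prof, file.path(dir, "profiles",
                        sprintf("profile_%s_%s.tsv", sig$tf[i], sig$modulator[i])))
    }
  }
  path <- file.path(dir, "summary.md")
  writeLines(lines, path)
  invisible(path)
}
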