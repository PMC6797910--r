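report_columns <- c("site_index", "max_pp", "best_cutoff", "best_scenario_id",
                    "n_transitions", "threshold_upper", "threshold_lower",
                    "call")
report_calls <- c("adaptive", "non_adaptive", "unresolved", "below_threshold",
                  "skipped_gaps")

#' Write a site report to TSV
#'
#' Writes the canonical per-site columns (`site_index`, `max_pp`,
#' `best_cutoff`, `best_scenario_id`, `n_transitions`, `threshold_upper`,
#' `threshold_lower`, `call`), floats at six significant digits, missing
#' numeric fields empty.
#'
#' @param report A `pcoc_report` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(report, path) {
  missing <- setdiff(report_columns, names(report))
  if (length(missing))
    stop("report lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(report$call), report_calls)
  if (length(bad))
    stop("unknown call value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out <- report[, report_columns]
  for (col in c("max_pp", "best_cutoff", "threshold_upper", "threshold_lower"))
    out[[col]] <- signif(out[[col]], 6)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a site report written by [write_site_report()]
#'
#' @param path Path to the TSV.
#' @return A `pcoc_report` tibble with the canonical columns.
#' @export
read_site_report <- function(path) {
  tb <- readr::read_tsv(path, na = "", col_types = readr::cols(
    site_index = readr::col_integer(),
    max_pp = readr::col_double(),
    best_cutoff = readr::col_double(),
    best_scenario_id = readr::col_character(),
    n_transitions = readr::col_integer(),
    threshold_upper = readr::col_double(),
    threshold_lower = readr::col_double(),
    call = readr::col_character()
  ))
  class(tb) <- c("pcoc_report", class(tb))
  tb
}

#' @export
print.pcoc_report <- function(x, ...) {
  cat(sprintf("<pcoc_report> %d site(s)\n", nrow(x)))
  NextMethod()
}

#' Tidy a site report
#'
#' @param x A `pcoc_report`.
#' @param ... Unused.
#' @return A plain tibble of the canonical report columns.
#' @export
tidy.pcoc_report <- function(x, ...) {
  tibble::as_tibble(x[, intersect(report_columns, names(x))])
}

#' One-row summary of a site report
#'
#' @param x A `pcoc_report`.
#' @param ... Unused.
#' @return A tibble with site counts per call class and the median PP among
#'   scored sites.
#' @export
glance.pcoc_report <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x),
    n_adaptive = sum(x$call == "adaptive"),
    n_non_adaptive = sum(x$call == "non_adaptive"),
    n_unresolved = sum(x$call == "unresolved"),
    n_below_threshold = sum(x$call == "below_threshold"),
    n_skipped_gaps = sum(x$call == "skipped_gaps"),
    median_pp = median(x$max_pp, na.rm = TRUE)
  )
}

#' Manhattan-style plot of a site report
#'
#' Per-site maximum posterior probability with bootstrap threshold bands:
#' PP at or above the upper band supports a convergently adaptive site, PP
#' at or below the lower band a non-adaptive one.
#'
#' @param report A `pcoc_report`.
#' @return A ggplot object.
#' @export
plot_site_report <- function(report) {
  scored <- dplyr::filter(report, !is.na(.data$max_pp))
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$site_index)) +
    ggplot2::geom_linerange(
      data = dplyr::filter(scored, !is.na(.data$threshold_upper)),
      ggplot2::aes(ymin = .data$threshold_upper, ymax = 1),
      color = "darkgreen", alpha = 0.25, linewidth = 1.5) +
    ggplot2::geom_linerange(
      data = dplyr::filter(scored, !is.na(.data$threshold_lower)),
      ggplot2::aes(ymin = 0, ymax = .data$threshold_lower),
      color = "firebrick", alpha = 0.25, linewidth = 1.5) +
    ggplot2::geom_point(ggplot2::aes(y = .data$max_pp, color = .data$call),
                        shape = 18, size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "alignment site", y = "max PCOC posterior probability",
                  color = "call") +
    ggplot2::theme_minimal()
}
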