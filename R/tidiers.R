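#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a position frequency matrix into long form
#'
#' @param x A `position_freq` object.
#' @param ... Unused.
#' @return A tibble with columns `position`, `base`, `freq`.
#' @method tidy position_freq
#' @export
tidy.position_freq <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), "position", "A", "C", "G", "T"),
    cols = c("A", "C", "G", "T"), names_to = "base", values_to = "freq"
  )
}

#' One-row summary of a position frequency matrix
#'
#' @param x A `position_freq` object.
#' @param theta Conservation threshold used for `n_conserved` (default 0.95).
#' @param ... Unused.
#' @method glance position_freq
#' @export
glance.position_freq <- function(x, theta = 0.95, ...) {
  tibble::tibble(
    length = nrow(x),
    n_sequences = attr(x, "n_sequences"),
    mode = attr(x, "mode"),
    n_conserved = sum(x$max_freq >= theta),
    mean_max_freq = mean(x$max_freq)
  )
}

#' Per-position conservation plot
#'
#' Maximum base frequency along the region with a dotted red line at the
#' conservation threshold, mirroring the figures this analysis produces.
#'
#' @param object A `position_freq` object.
#' @param theta Threshold line (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot position_freq
#' @export
autoplot.position_freq <- function(object, theta = 0.95, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$max_freq)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$max_freq >= theta), size = 2) +
    ggplot2::geom_hline(yintercept = theta, linetype = "dotted", colour = "red") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue", `FALSE` = "orange"),
                                 name = sprintf(">= %g", theta)) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(v) 100 * v) +
    ggplot2::labs(x = "position in contig", y = "max base frequency (%)") +
    ggplot2::theme_minimal()
}

#' Tidy an NR table with ranks and cumulative coverage
#'
#' @param x An `nr_table`.
#' @param ... Unused.
#' @method tidy nr_table
#' @export
tidy.nr_table <- function(x, ...) {
  total <- attr(x, "total_fragments")
  dplyr::mutate(tibble::as_tibble(x),
    rank = dplyr::row_number(),
    cum_fraction = cumsum(.data$abundance) / total
  )
}

#' One-row summary of an NR reduction
#'
#' @param x An `nr_table`.
#' @param fraction Coverage fraction for `nr_needed` (default 0.95).
#' @param ... Unused.
#' @method glance nr_table
#' @export
glance.nr_table <- function(x, fraction = 0.95, ...) {
  total <- attr(x, "total_fragments")
  tibble::tibble(
    n_fragments = total,
    n_nr = nrow(x),
    reduction_percent = reduction_percent(total, nrow(x)),
    nr_needed = nr_needed(x, fraction),
    coverage_fraction = fraction
  )
}

#' Tidy a scan result (drops the positions list-column)
#'
#' @param x A `scan_result`.
#' @param ... Unused.
#' @method tidy scan_result
#' @export
tidy.scan_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$hit_positions <- NULL
  out
}

#' Summary of a database scan
#'
#' @param x A `scan_result`.
#' @param ... Unused.
#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x),
    n_contigs = length(unique(x$contig_name)),
    n_records = attr(x, "n_records"),
    max_percent = max(x$percent),
    min_percent = min(x$percent)
  )
}

#' Window-frequency profile plot for a database scan
#'
#' @param object A `scan_result`.
#' @param ... Unused.
#' @return A ggplot object: percent of records hit per window index,
#'   facetted by contig.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, ...) {
  ggplot2::ggplot(tidy.scan_result(object),
                  ggplot2::aes(x = .data$index, y = .data$percent)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~contig_name) +
    ggplot2::labs(x = "window index (0-based)", y = "records hit (%)") +
    ggplot2::theme_minimal()
}

#' Duplicate-reaction curve across window sizes
#'
#' @param object A `specificity_curve`.
#' @param ... Unused.
#' @return A ggplot object with the selected k highlighted.
#' @method autoplot specificity_curve
#' @export
autoplot.specificity_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$k, y = .data$duplicate_count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = "k-mer size", y = "records with duplicate matches") +
    ggplot2::theme_minimal()
}

#' Outcome summary of a fragment recovery
#'
#' @param x A `fragment_set`.
#' @param ... Unused.
#' @method glance fragment_set
#' @export
glance.fragment_set <- function(x, ...) {
  tibble::tibble(
    contig_name = attr(x, "contig_name"),
    n_records = nrow(x),
    n_recovered = attr(x, "n_recovered"),
    n_truncated = attr(x, "n_truncated"),
    n_unmatched = attr(x, "n_unmatched"),
    n_duplicate = sum(x$duplicate)
  )
}
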