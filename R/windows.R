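#' Enumerate k-mer windows of primer contigs
#'
#' Slides a window of length `k` along each contig: a contig of length L
#' yields L - k + 1 windows (none when L < k). Window indices are 0-based,
#' so index i covers contig positions i+1 .. i+k. Each window carries its
#' isoform multiplicity, the number of unambiguous k-mers it denotes.
#'
#' @param contigs A data frame with columns `name` and `sequence` (IUPAC),
#'   e.g. from [reference_contigs()].
#' @param k Window length in nucleotides (default 12).
#' @return A tibble with columns `contig_name`, `index` (0-based),
#'   `sequence`, `iso_count`, one row per window in contig order.
#' @examples
#' enumerate_windows(reference_contigs()[1, ], k = 12)
#' @export
enumerate_windows <- function(contigs, k = 12L) {
  stopifnot(is.data.frame(contigs), all(c("name", "sequence") %in% names(contigs)))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be a positive integer", call. = FALSE)
  purrr::map2_dfr(contigs$name, contigs$sequence, function(nm, seq) {
    .validate_iupac(seq)
    L <- nchar(seq)
    if (L < k) {
      return(tibble::tibble(contig_name = character(), index = integer(),
                            sequence = character(), iso_count = double()))
    }
    starts <- seq_len(L - k + 1L)
    win <- substring(seq, starts, starts + k - 1L)
    tibble::tibble(
      contig_name = nm,
      index = starts - 1L,
      sequence = win,
      iso_count = purrr::map_dbl(win, sequence_multiplicity)
    )
  })
}

#' Summarise contigs by length, degeneracy and k-mer content
#'
#' Produces the per-contig summary table: length, number of degenerate
#' bases, number of k-mer windows (length - k + 1) and total number of
#' isoform k-mers (sum of per-window multiplicities). With `total = TRUE` a
#' "Total" row of column sums is appended.
#'
#' @inheritParams enumerate_windows
#' @param total Append a Total row (default TRUE).
#' @return A tibble with columns `name`, `length`, `degenerate_bases`,
#'   `n_kmers`, `n_iso_kmers`.
#' @examples
#' contig_summary(reference_contigs())
#' @export
contig_summary <- function(contigs, k = 12L, total = TRUE) {
  windows <- enumerate_windows(contigs, k)
  per_contig <- tibble::tibble(
    name = as.character(contigs$name),
    length = nchar(contigs$sequence),
    degenerate_bases = purrr::map_int(contigs$sequence, degeneracy_count)
  )
  win_sum <- dplyr::summarise(
    dplyr::group_by(windows, name = .data$contig_name),
    n_kmers = dplyr::n(),
    n_iso_kmers = sum(.data$iso_count),
    .groups = "drop"
  )
  out <- dplyr::left_join(per_contig, win_sum, by = "name")
  out <- dplyr::mutate(out,
    n_kmers = dplyr::coalesce(as.integer(.data$n_kmers), 0L),
    n_iso_kmers = dplyr::coalesce(.data$n_iso_kmers, 0)
  )
  if (total) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      name = "Total",
      length = sum(out$length),
      degenerate_bases = sum(out$degenerate_bases),
      n_kmers = sum(out$n_kmers),
      n_iso_kmers = sum(out$n_iso_kmers)
    ))
  }
  out
}
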