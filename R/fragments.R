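#' Choose the anchor window for a contig
#'
#' The anchor is the k-mer window with the highest database frequency
#' (`seq_hits`); ties are broken deterministically by the smallest window
#' index. Flank widths follow from the window position: `left_flank`
#' nucleotides are needed before the match and `right_flank` after it to
#' rebuild a fragment of full contig length.
#'
#' @param scan_result A [scan_database()] result filtered to one contig.
#' @return A one-row tibble of class `anchor_spec`: `contig_name`, `index`,
#'   `sequence`, `k`, `left_flank`, `right_flank`, `contig_length`,
#'   `seq_hits`.
#' @export
select_anchor <- function(scan_result) {
  stopifnot(is.data.frame(scan_result))
  if (!nrow(scan_result)) stop("empty scan result", call. = FALSE)
  if (length(unique(scan_result$contig_name)) != 1L) {
    stop("`scan_result` must cover exactly one contig", call. = FALSE)
  }
  if (all(scan_result$seq_hits == 0L)) {
    stop("contig absent from database: every window has zero hits", call. = FALSE)
  }
  k <- nchar(scan_result$sequence[1])
  n_windows <- max(scan_result$index) + 1L
  contig_length <- n_windows + k - 1L
  best <- dplyr::slice(dplyr::arrange(scan_result,
                                      dplyr::desc(.data$seq_hits), .data$index), 1)
  out <- tibble::tibble(
    contig_name = best$contig_name,
    index = best$index,
    sequence = best$sequence,
    k = k,
    left_flank = best$index,
    right_flank = contig_length - k - best$index,
    contig_length = contig_length,
    seq_hits = best$seq_hits
  )
  structure(out, class = c("anchor_spec", class(out)))
}

#' Recover contig-length fragments from database records
#'
#' Locates the first (5'-most) exact match to any isoform of the anchor
#' window in each record and slices out `left_flank` nucleotides before the
#' match plus `right_flank` after it, yielding a fragment of exactly the
#' contig length. Fragments sharing an anchor are aligned by construction.
#' Every record gets one of three outcomes: `recovered` (slice fully inside
#' the record), `truncated` (a match exists but a flank runs past a record
#' end, as happens when a database entry is missing its terminal 200-300
#' nucleotides) or `unmatched` (no isoform occurs). Records with several
#' anchor matches are anchored at the first and flagged.
#'
#' @param records Normalised records (`id`, `sequence`).
#' @param anchor An `anchor_spec` from [select_anchor()].
#' @return A tibble of class `fragment_set`, one row per record in database
#'   order: `id`, `outcome`, `match_offset` (0-based anchor start, NA if
#'   unmatched), `duplicate` (TRUE when the anchor matched more than once)
#'   and `fragment` (NA unless recovered). Attributes `contig_name`,
#'   `n_recovered`, `n_truncated`, `n_unmatched` summarise the set.
#' @export
recover_fragments <- function(records, anchor) {
  stopifnot(is.data.frame(records), is.data.frame(anchor), nrow(anchor) == 1L)
  if (!nrow(records)) stop("empty database", call. = FALSE)
  isoforms <- expand_isoforms(anchor$sequence)
  subj <- Biostrings::DNAStringSet(records$sequence)

  first <- rep(NA_integer_, nrow(records))
  n_hits <- integer(nrow(records))
  for (iso in isoforms) {
    m <- Biostrings::vmatchPattern(iso, subj)
    starts <- Biostrings::startIndex(m)
    has <- lengths(starts) > 0L
    n_hits[has] <- n_hits[has] + lengths(starts)[has]
    firsts <- vapply(starts[has], min, integer(1))
    first[has] <- pmin(first[has], firsts, na.rm = TRUE)
  }

  frag_start <- first - anchor$left_flank
  frag_end <- first + anchor$k + anchor$right_flank - 1L
  fits <- !is.na(first) & frag_start >= 1L & frag_end <= nchar(records$sequence)
  outcome <- dplyr::case_when(
    is.na(first) ~ "unmatched",
    fits ~ "recovered",
    TRUE ~ "truncated"
  )
  fragment <- rep(NA_character_, nrow(records))
  fragment[fits] <- substr(records$sequence[fits], frag_start[fits], frag_end[fits])

  out <- tibble::tibble(
    id = records$id,
    outcome = outcome,
    match_offset = first - 1L,
    duplicate = n_hits >= 2L,
    fragment = fragment
  )
  structure(out,
    contig_name = anchor$contig_name,
    n_recovered = sum(outcome == "recovered"),
    n_truncated = sum(outcome == "truncated"),
    n_unmatched = sum(outcome == "unmatched"),
    class = c("fragment_set", class(out))
  )
}

#' Recover the fragment for a single record
#'
#' Convenience wrapper around [recover_fragments()] for one record.
#'
#' @param record A one-row data frame (`id`, `sequence`).
#' @inheritParams recover_fragments
#' @return A one-row `fragment_set` tibble.
#' @export
recover_fragment <- function(record, anchor) {
  stopifnot(nrow(record) == 1L)
  recover_fragments(record, anchor)
}
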