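# Exact multi-pattern matching is delegated to Biostrings (PDict /
# vcountPDict / matchPDict, fixed = TRUE), so IUPAC ambiguity characters
# inside database records never match: only exact A/C/G/T equality counts,
# and degeneracy is handled by expanding contig windows into isoforms.

# per-window match-count matrix (windows x records), chunked over records
.window_counts <- function(window_seqs, record_seqs, chunk_size = 5000L) {
  iso <- lapply(window_seqs, expand_isoforms)
  group <- rep(seq_along(iso), lengths(iso))
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(unlist(iso)))
  n <- length(record_seqs)
  out <- matrix(0L, nrow = length(window_seqs), ncol = n)
  for (lo in seq(1L, n, by = chunk_size)) {
    hi <- min(lo + chunk_size - 1L, n)
    subj <- Biostrings::DNAStringSet(record_seqs[lo:hi])
    cnt <- Biostrings::vcountPDict(pdict, subj)
    out[, lo:hi] <- rowsum(cnt, group, reorder = TRUE)
  }
  out
}

#' Scan a sequence database for exact window-isoform matches
#'
#' For every k-mer window, counts the database records that contain at
#' least one exact substring match to any of the window's unambiguous
#' isoforms. A record is counted once however many matches it contains;
#' only the forward strand is searched (SSU databases store sequences in
#' the gene's sense orientation).
#'
#' @param windows A tibble of windows from [enumerate_windows()]; all
#'   window sequences must share one length k.
#' @param records A data frame of normalised records with columns `id` and
#'   `sequence` (see [read_fasta()]).
#' @param keep_positions Also collect 0-based match start offsets per hit
#'   record (needed for duplicate analysis and anchoring diagnostics;
#'   off by default as it visits every hit record individually).
#' @return A tibble of class `scan_result` with columns `contig_name`,
#'   `index`, `sequence`, `iso_count`, `seq_hits`, `n_dup_records`
#'   (records with two or more match positions) and `percent`
#'   (100 * seq_hits / n records). With `keep_positions = TRUE` a
#'   `hit_positions` list-column is added: per window, a list named by
#'   record id holding sorted 0-based offsets. Attribute `n_records`
#'   carries the denominator.
#' @examples
#' db <- tibble::tibble(id = c("r1", "r2"), sequence = c("TTAGATT", "CCCCCCC"))
#' scan_database(enumerate_windows(
#'   tibble::tibble(name = "toy", sequence = "RGAT"), k = 4), db)
#' @export
scan_database <- function(windows, records, keep_positions = FALSE) {
  stopifnot(is.data.frame(windows), is.data.frame(records))
  if (!nrow(records)) stop("empty database", call. = FALSE)
  if (!nrow(windows)) {
    return(structure(tibble::tibble(
      contig_name = character(), index = integer(), sequence = character(),
      iso_count = double(), seq_hits = integer(), n_dup_records = integer(),
      percent = double()
    ), n_records = nrow(records), class = c("scan_result", class(tibble::tibble()))))
  }
  k <- unique(nchar(windows$sequence))
  if (length(k) != 1L) stop("all windows must share one k", call. = FALSE)

  cnt <- .window_counts(windows$sequence, records$sequence)
  out <- dplyr::mutate(tibble::as_tibble(windows),
    seq_hits = as.integer(rowSums(cnt > 0L)),
    n_dup_records = as.integer(rowSums(cnt >= 2L)),
    percent = 100 * .data$seq_hits / nrow(records)
  )
  if (keep_positions) {
    iso_sets <- lapply(windows$sequence, expand_isoforms)
    out$hit_positions <- lapply(seq_len(nrow(windows)), function(w) {
      hit <- which(cnt[w, ] > 0L)
      pos <- lapply(hit, function(r) {
        starts <- sort(unlist(lapply(iso_sets[[w]], function(p) {
          Biostrings::start(Biostrings::matchPattern(p, records$sequence[r]))
        })))
        as.integer(starts) - 1L
      })
      stats::setNames(pos, records$id[hit])
    })
  }
  structure(out, n_records = nrow(records),
            class = c("scan_result", class(out)))
}

#' k-size specificity (duplicate-hit) analysis
#'
#' For each window length k, counts how often a window's isoform set
#' matches a record at two or more positions (a "duplicate reaction"),
#' aggregated by summing per-window duplicate-record counts over the
#' contig. Longer k-mers are more astringent, so the curve is
#' non-increasing in k; the working k is chosen at the inflection point of
#' the curve (the k with the largest positive second difference), falling
#' back to `default_k` when the curve is flat.
#'
#' @param contig A one-row data frame with columns `name` and `sequence`.
#' @param records Normalised database records (`id`, `sequence`).
#' @param k_range Integer vector of window lengths to test (default 9:15).
#' @param default_k Fallback selection for a flat curve (default 12).
#' @return A tibble of class `specificity_curve` with columns `k`,
#'   `duplicate_count` and `selected`; the chosen k is also attached as
#'   attribute `selected_k`.
#' @export
specificity_analysis <- function(contig, records, k_range = 9:15, default_k = 12L) {
  stopifnot(is.data.frame(contig), nrow(contig) == 1L)
  if (!nrow(records)) stop("empty database", call. = FALSE)
  k_range <- sort(as.integer(k_range))
  L <- nchar(contig$sequence)
  if (any(k_range < 1L) || any(k_range > L)) {
    stop("`k_range` must lie within [1, contig length]", call. = FALSE)
  }
  dup <- vapply(k_range, function(k) {
    cnt <- .window_counts(enumerate_windows(contig, k)$sequence, records$sequence)
    sum(cnt >= 2L)
  }, integer(1))

  selected_k <- default_k
  if (length(k_range) >= 3L && any(dup != dup[1])) {
    d2 <- diff(dup, differences = 2L) # at interior ks
    if (max(d2) > 0) selected_k <- k_range[which.max(d2) + 1L]
  }
  structure(
    tibble::tibble(k = k_range, duplicate_count = dup,
                   selected = k_range == selected_k),
    selected_k = selected_k,
    class = c("specificity_curve", class(tibble::tibble()))
  )
}
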