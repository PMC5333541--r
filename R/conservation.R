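#' Reduce fragments to a non-redundant table
#'
#' Groups identical fragment strings and counts their abundance. Ordering
#' is deterministic: descending abundance, ties broken lexicographically.
#' Working on non-redundant (NR) sequences removes the bias that heavily
#' sequenced taxa would otherwise impose on per-position frequencies.
#'
#' @param fragments Character vector of equal-length fragment strings, or a
#'   `fragment_set` / data frame with a `fragment` column (non-recovered
#'   rows are dropped).
#' @return A tibble of class `nr_table` with columns `fragment` and
#'   `abundance`; attribute `total_fragments` holds the input count.
#' @examples
#' dedupe_nr(c("AA", "AB", "AA", "AC"))
#' @export
dedupe_nr <- function(fragments) {
  if (is.data.frame(fragments)) fragments <- fragments$fragment
  fragments <- fragments[!is.na(fragments)]
  if (!length(fragments)) stop("no fragments to reduce", call. = FALSE)
  if (length(unique(nchar(fragments))) != 1L) {
    stop("fragments have mixed lengths", call. = FALSE)
  }
  out <- dplyr::count(tibble::tibble(fragment = fragments),
                      .data$fragment, name = "abundance")
  out <- dplyr::arrange(out, dplyr::desc(.data$abundance), .data$fragment)
  structure(out, total_fragments = length(fragments),
            class = c("nr_table", class(out)))
}

#' Number of NR sequences needed to cover a fraction of all fragments
#'
#' Smallest m such that the m most abundant NR sequences together account
#' for at least `fraction` of all fragments.
#'
#' @param nr An `nr_table` from [dedupe_nr()], or any data frame with an
#'   `abundance` column.
#' @param fraction Coverage fraction in (0, 1] (default 0.95).
#' @return Integer m.
#' @examples
#' nr <- dedupe_nr(rep(c("A", "C", "G", "T"), c(50, 30, 15, 5)))
#' nr_needed(nr, 0.95) # 3
#' @export
nr_needed <- function(nr, fraction = 0.95) {
  stopifnot(is.data.frame(nr), "abundance" %in% names(nr))
  if (!nrow(nr)) stop("empty NR table", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  ab <- sort(nr$abundance, decreasing = TRUE)
  total <- attr(nr, "total_fragments") %||% sum(ab)
  which(cumsum(ab) >= fraction * total)[1]
}

#' Percent reduction achieved by NR deduplication
#'
#' @param n_total Number of fragments before deduplication.
#' @param n_nr Number of non-redundant sequences after.
#' @return `100 * (1 - n_nr / n_total)`.
#' @examples
#' reduction_percent(454807, 746) # 99.84
#' @export
reduction_percent <- function(n_total, n_nr) {
  stopifnot(n_total > 0, n_nr >= 0, n_nr <= n_total)
  100 * (1 - n_nr / n_total)
}

#' Per-position nucleotide frequency matrix with fractional weighting
#'
#' Computes the fraction of A, C, G and T at every position of a set of
#' equal-length sequences. A degenerate IUPAC character contributes
#' fractionally to each base it denotes (R adds 0.5 to A and 0.5 to G, N
#' adds 0.25 to each). Two weighting modes mirror the two analyses:
#' `"all"` weights each NR sequence by its abundance (identical to running
#' over every raw fragment), `"nr"` gives every distinct sequence weight 1
#' so rare variants count as much as dominant ones.
#'
#' @param x Character vector of equal-length sequences, or an `nr_table`.
#' @param mode For an `nr_table`: `"nr"` (weight 1 per unique sequence,
#'   default) or `"all"` (abundance-weighted). Ignored for plain vectors.
#' @param weights Optional explicit numeric weights (overrides `mode`).
#' @return A tibble of class `position_freq` with columns `position`
#'   (1-based), `A`, `C`, `G`, `T`, `max_base`, `max_freq` and `flagged`
#'   (TRUE when non-IUPAC characters made the row sum fall short of 1).
#'   Attributes: `n_sequences` (total weight), `mode`.
#' @examples
#' position_frequencies(c("AR", "AA"))
#' @export
position_frequencies <- function(x, mode = c("nr", "all"), weights = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "nr_table") || (is.data.frame(x) && "fragment" %in% names(x))) {
    seqs <- x$fragment
    if (is.null(weights)) {
      weights <- if (mode == "all" && "abundance" %in% names(x)) x$abundance else rep(1, length(seqs))
    }
  } else {
    seqs <- x
    if (is.null(weights)) weights <- rep(1, length(seqs))
    mode <- "all"
  }
  if (!length(seqs)) stop("no sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L) stop("sequences have mixed lengths", call. = FALSE)
  stopifnot(length(weights) == length(seqs), all(weights > 0))

  L <- nchar(seqs[1])
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  total_w <- sum(weights)
  freq <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  known <- matrix(0, nrow = length(seqs), ncol = L)
  for (sym in rownames(.iupac_share_matrix)) {
    hit <- chars == sym
    if (!any(hit)) next
    known <- known + hit
    w_per_pos <- colSums(hit * weights)
    freq <- freq + outer(w_per_pos, .iupac_share_matrix[sym, ])
  }
  freq <- freq / total_w
  flagged <- colSums((1 - known) * weights) > 0

  out <- tibble::tibble(
    position = seq_len(L),
    A = unname(freq[, "A"]), C = unname(freq[, "C"]),
    G = unname(freq[, "G"]), T = unname(freq[, "T"]),
    max_base = c("A", "C", "G", "T")[max.col(freq, ties.method = "first")],
    max_freq = unname(apply(freq, 1, max)),
    flagged = unname(flagged)
  )
  structure(out, n_sequences = total_w, mode = mode,
            class = c("position_freq", class(out)))
}

#' Conservation mask at a frequency threshold
#'
#' A position is conserved when its most frequent base reaches at least
#' `theta` of the (fractionally weighted) sequences.
#'
#' @param pfm A `position_freq` matrix from [position_frequencies()].
#' @param theta Conservation threshold in (0, 1] (default 0.95, the
#'   frequency limit drawn on the per-position plots).
#' @return A tibble with columns `position`, `max_base`, `max_freq`,
#'   `conserved`; attribute `n_conserved`.
#' @export
conserved_positions <- function(pfm, theta = 0.95) {
  stopifnot(is.data.frame(pfm), all(c("position", "max_freq") %in% names(pfm)))
  if (!is.numeric(theta) || theta <= 0 || theta > 1) {
    stop("`theta` must be in (0, 1]", call. = FALSE)
  }
  out <- dplyr::mutate(
    dplyr::select(tibble::as_tibble(pfm), "position", "max_base", "max_freq"),
    conserved = .data$max_freq >= theta
  )
  structure(out, theta = theta, n_conserved = sum(out$conserved))
}

#' IUPAC consensus string from a frequency matrix
#'
#' Per position, every base whose frequency reaches the inclusion
#' threshold `tau` enters the consensus, written as the minimal IUPAC code
#' covering that base set. A low `tau` therefore yields highly degenerate
#' consensuses; positions where no base reaches `tau` are written N.
#'
#' @inheritParams conserved_positions
#' @param tau Inclusion threshold, `0 <= tau < 0.5` (default 0.05).
#' @return A single IUPAC string of the matrix length.
#' @export
consensus_iupac <- function(pfm, tau = 0.05) {
  stopifnot(is.data.frame(pfm), all(c("A", "C", "G", "T") %in% names(pfm)))
  if (!is.numeric(tau) || tau < 0 || tau >= 0.5) {
    stop("`tau` must satisfy 0 <= tau < 0.5", call. = FALSE)
  }
  freq <- as.matrix(pfm[, c("A", "C", "G", "T")])
  codes <- apply(freq, 1, function(row) {
    bases <- c("A", "C", "G", "T")[row >= tau & row > 0]
    if (!length(bases)) "N" else iupac_union(bases)
  })
  paste(codes, collapse = "")
}
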