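#' Assemble coordinate-anchored primers into primer contigs
#'
#' Published primers targeting one conserved region are aligned on the
#' E. coli 16S coordinate line and merged position-by-position: where several
#' primers overlap, each position gets the minimal IUPAC code covering the
#' union of their base sets. Primers separated by a gap cannot form one
#' continuous contig; each gap-free run becomes a sub-contig labelled
#' a/b/c... in coordinate order.
#'
#' @param primers A data frame with columns `sequence` (IUPAC strings) and
#'   `start` (1-based inclusive E. coli coordinate of the first base).
#' @param region_id Region identifier (1-10) used for the contig name.
#' @return A tibble of primer contigs with columns `name`, `sequence`,
#'   `start`, `end`, `length`, `sub_label`. One row per gap-free segment;
#'   `name` is `region_id` plus the sub-label when the region split.
#' @examples
#' assemble_contig(
#'   data.frame(sequence = c("ACAT", "ACGT"), start = c(1, 1)),
#'   region_id = 1
#' )
#' @export
assemble_contig <- function(primers, region_id = 1L) {
  stopifnot(is.data.frame(primers), all(c("sequence", "start") %in% names(primers)))
  if (!nrow(primers)) stop("`primers` is empty", call. = FALSE)
  if (any(is.na(primers$start)) || any(primers$start < 1)) {
    stop("primer `start` coordinates must be positive integers", call. = FALSE)
  }
  chars <- lapply(primers$sequence, .validate_iupac, arg = "primers$sequence")
  start <- as.integer(primers$start)
  end <- start + lengths(chars) - 1L

  lo <- min(start)
  hi <- max(end)
  merged <- rep(NA_character_, hi - lo + 1L)
  for (i in seq_along(chars)) {
    idx <- (start[i] - lo + 1L):(end[i] - lo + 1L)
    old <- merged[idx]
    new <- chars[[i]]
    take <- is.na(old)
    old[take] <- new[take]
    if (any(!take)) old[!take] <- .iupac_merge(old[!take], new[!take])
    merged[idx] <- old
  }

  covered <- !is.na(merged)
  runs <- rle(covered)
  seg_end <- cumsum(runs$lengths)
  seg_start <- seg_end - runs$lengths + 1L
  keep <- runs$values
  n_seg <- sum(keep)
  labels <- if (n_seg > 1L) letters[seq_len(n_seg)] else NA_character_

  out <- purrr::map2_dfr(seg_start[keep], seg_end[keep], function(s, e) {
    tibble::tibble(
      sequence = paste(merged[s:e], collapse = ""),
      start = lo + s - 1L,
      end = lo + e - 1L
    )
  })
  out <- dplyr::mutate(out,
    sub_label = labels,
    name = ifelse(is.na(.data$sub_label), as.character(region_id),
                  paste0(region_id, .data$sub_label)),
    length = .data$end - .data$start + 1L
  )
  if (n_seg > 1L) {
    rlang::signal(
      sprintf("region %s primers leave %d gap(s); returning %d sub-contigs",
              region_id, n_seg - 1L, n_seg),
      class = "conserved16s_contig_split"
    )
  }
  dplyr::select(out, "name", "sequence", "start", "end", "length", "sub_label")
}

#' The fifteen reference primer contigs
#'
#' Loads the packaged fixture of 15 primer contigs — degenerate consensuses
#' of published primers for the ten conserved regions of the bacterial 16S
#' rRNA gene (regions split by coordinate gaps carry sub-labels a/b/c), with
#' 1-based inclusive locations on the E. coli reference.
#'
#' @return A tibble with columns `name`, `sequence`, `start`, `end`,
#'   `length`, `degenerate_bases`.
#' @examples
#' reference_contigs()
#' @export
reference_contigs <- function() {
  path <- system.file("extdata", "primer_contigs.tsv", package = "conserved16s",
                      mustWork = TRUE)
  contigs <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    sequence = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer()
  ))
  contigs <- dplyr::mutate(contigs,
    length = nchar(.data$sequence),
    degenerate_bases = purrr::map_int(.data$sequence, degeneracy_count)
  )
  bad <- contigs$end - contigs$start + 1L != contigs$length
  if (any(bad)) {
    stop("contig fixture rows with span != sequence length: ",
         paste(contigs$name[bad], collapse = ", "), call. = FALSE)
  }
  contigs
}
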