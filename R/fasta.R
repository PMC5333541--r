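#' Normalise sequences into exact-matching DNA space
#'
#' Uppercases, strips alignment gap characters (`-`, `.`) and converts RNA
#' U to DNA T, so DNA-space primer k-mers match RNA-alphabet database
#' records exactly. Idempotent.
#'
#' @param x Character vector of sequences.
#' @return Normalised character vector.
#' @examples
#' normalize_sequences("ac-g.u") # "ACGT"
#' @export
normalize_sequences <- function(x) {
  chartr("U", "T", gsub("[-.]", "", toupper(x), perl = TRUE))
}

#' Read a sequence database from FASTA, normalising the SILVA dialect
#'
#' Reads FASTA records and normalises them for exact DNA-space matching:
#' sequences are uppercased, RNA U becomes T, and alignment gap characters
#' (`-` and `.`) are stripped, so both the aligned and unaligned SILVA
#' distributions work. Records shorter than `min_length` after
#' normalisation are dropped and counted (the study's 1,200-nt filter is
#' applied this way, never hardcoded).
#'
#' @param path Path to a FASTA file.
#' @param min_length Minimum normalised sequence length to keep (default 0).
#' @return A tibble with columns `id` (first whitespace-delimited header
#'   token), `description` (rest of the header; SILVA stores the taxonomy
#'   path here) and `sequence`. The number of records dropped by
#'   `min_length` is attached as attribute `n_too_short`. Duplicate ids
#'   raise a warning.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x some taxon", "acgu", ">y", "AC-G.U"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, min_length = 0L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  first <- which(nzchar(trimws(head_lines)))[1]
  if (!is.na(first) && !startsWith(trimws(head_lines[first]), ">")) {
    stop(sprintf("malformed FASTA: sequence before header at line %d of %s",
                 first, path), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seqs <- normalize_sequences(as.character(set))
  keep <- nchar(seqs) >= min_length
  if (anyDuplicated(id[keep])) {
    dup <- unique(id[keep][duplicated(id[keep])])
    warning("duplicate record ids: ", paste(utils::head(dup, 5), collapse = ", "),
            call. = FALSE)
  }
  out <- tibble::tibble(id = unname(id[keep]),
                        description = unname(description[keep]),
                        sequence = unname(seqs[keep]))
  attr(out, "n_too_short") <- sum(!keep)
  out
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()] for normalised records:
#' `read_fasta(write_fasta(x))` round-trips id, description and sequence.
#'
#' @param records A data frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output file path.
#' @param width Line-wrap width for sequences (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) {
    records$description
  } else {
    rep("", nrow(records))
  }
  desc[is.na(desc)] <- ""
  header <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- header
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
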