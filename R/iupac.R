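#' IUPAC nucleotide ambiguity alphabet
#'
#' The 15 IUPAC nucleotide symbols with the set of unambiguous bases each one
#' denotes and its multiplicity (the size of that set). Multiplicity is 1 for
#' A/C/G/T, 2 for R/Y/S/W/K/M, 3 for B/D/H/V and 4 for N.
#'
#' @return A tibble with columns `symbol`, `bases` (list of character
#'   vectors) and `multiplicity`.
#' @examples
#' iupac_alphabet()
#' @export
iupac_alphabet <- function() {
  tibble::tibble(
    symbol = names(.iupac_sets),
    bases = unname(.iupac_sets),
    multiplicity = lengths(.iupac_sets)
  )
}

# base sets in A < C < G < T order so isoform expansion is lexicographic
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.iupac_mult <- lengths(.iupac_sets)

# set (sorted base vector, collapsed) -> minimal covering code
.iupac_code_of <- local({
  keys <- vapply(.iupac_sets, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(keys), keys)
})

.validate_iupac <- function(sequence, arg = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop(sprintf("`%s` must be a single non-empty string", arg), call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(.iupac_sets))
  if (length(bad)) {
    stop(sprintf(
      "invalid IUPAC character '%s' at position %d of `%s`",
      chars[bad[1]], bad[1], arg
    ), call. = FALSE)
  }
  chars
}

#' Count degenerate positions in an IUPAC sequence
#'
#' A position is degenerate when its symbol denotes more than one base
#' (multiplicity > 1), i.e. anything other than A, C, G or T.
#'
#' @param sequence A single IUPAC nucleotide string.
#' @return Integer count of degenerate positions.
#' @examples
#' degeneracy_count("ATGTGGTTTAATTCGA") # 0
#' degeneracy_count("NNNN") # 4
#' @export
degeneracy_count <- function(sequence) {
  chars <- .validate_iupac(sequence)
  sum(.iupac_mult[chars] > 1L)
}

#' Multiplicity of a degenerate sequence
#'
#' The number of unambiguous sequences a degenerate IUPAC string denotes:
#' the product over positions of each symbol's multiplicity. A sequence with
#' a single K ("keto", T or G) has multiplicity 2; `expand_isoforms()`
#' enumerates the strings themselves.
#'
#' @inheritParams degeneracy_count
#' @return Integer (double for very degenerate sequences) product of
#'   per-position multiplicities; 1 for a degeneracy-free sequence.
#' @examples
#' sequence_multiplicity("ACGT") # 1
#' sequence_multiplicity("AKT") # 2
#' sequence_multiplicity("RNV") # 24
#' @export
sequence_multiplicity <- function(sequence) {
  chars <- .validate_iupac(sequence)
  prod(.iupac_mult[chars])
}

#' Expand a degenerate sequence into its unambiguous isoforms
#'
#' Replaces every IUPAC ambiguity symbol by each base it denotes, producing
#' the full cartesian set of A/C/G/T strings ("isoforms"). Order is
#' deterministic: lexicographic by position with A < C < G < T.
#'
#' @inheritParams degeneracy_count
#' @return Character vector of distinct A/C/G/T strings; its length equals
#'   [sequence_multiplicity()].
#' @examples
#' expand_isoforms("AK") # "AG" "AT"
#' expand_isoforms("RY") # "AC" "AT" "GC" "GT"
#' @export
expand_isoforms <- function(sequence) {
  chars <- .validate_iupac(sequence)
  out <- ""
  for (ch in chars) {
    bases <- .iupac_sets[[ch]]
    # outer rep keeps earlier positions as the slow-moving digit
    out <- paste0(rep(out, each = length(bases)), bases)
  }
  out
}

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases Character vector drawn from A/C/G/T (duplicates allowed).
#' @return The single IUPAC symbol whose base set equals the input set.
#' @examples
#' iupac_union(c("A", "G")) # "R"
#' iupac_union(c("A", "C", "G", "T")) # "N"
#' @export
iupac_union <- function(bases) {
  bases <- unique(bases)
  if (!length(bases) || !all(bases %in% c("A", "C", "G", "T"))) {
    stop("`bases` must be a non-empty subset of A/C/G/T", call. = FALSE)
  }
  unname(.iupac_code_of[paste(sort(bases), collapse = "")])
}

# fractional share each IUPAC symbol contributes to A/C/G/T
.iupac_share_matrix <- local({
  syms <- names(.iupac_sets)
  m <- matrix(0, nrow = length(syms), ncol = 4,
              dimnames = list(syms, c("A", "C", "G", "T")))
  for (s in syms) m[s, .iupac_sets[[s]]] <- 1 / length(.iupac_sets[[s]])
  m
})

.other_bases <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))

# ambiguity codes whose base set contains a given base
.codes_containing <- local({
  amb <- names(.iupac_sets)[.iupac_mult > 1L]
  lapply(stats::setNames(nm = c("A", "C", "G", "T")),
         function(b) amb[vapply(.iupac_sets[amb], function(s) b %in% s, TRUE)])
})

# union of two IUPAC symbols, vectorised over positions
.iupac_merge <- function(a, b) {
  mapply(function(x, y) iupac_union(c(.iupac_sets[[x]], .iupac_sets[[y]])),
         a, b, USE.NAMES = FALSE)
}
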