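# Independent brute-force oracles. These deliberately avoid the package's
# own expansion/matching code paths: the IUPAC map is restated here and
# matching is done with base-R substring search.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# cartesian expansion via expand.grid
oracle_expand <- function(seq) {
  sets <- oracle_iupac[strsplit(seq, "")[[1]]]
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = ""))
}

# all 0-based start offsets of `pattern` in `subject`, exact fixed matching
oracle_match_starts <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
}

# naive per-record, per-isoform scan of one window
oracle_scan_window <- function(window_seq, sequences) {
  isoforms <- oracle_expand(window_seq)
  per_record <- lapply(sequences, function(s) {
    sort(unique(unlist(lapply(isoforms, oracle_match_starts, subject = s))))
  })
  list(
    seq_hits = sum(lengths(per_record) > 0L),
    n_dup_records = sum(lengths(per_record) >= 2L),
    positions = per_record
  )
}

# random IUPAC string with a bounded number of degenerate positions
random_iupac <- function(len, n_degen) {
  n_degen <- min(n_degen, len)
  plain <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_degen > 0) {
    pos <- sample.int(len, n_degen)
    plain[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"),
                         n_degen, replace = TRUE)
  }
  paste(plain, collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
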