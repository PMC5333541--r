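#' Configuration for the synthetic SILVA-like database generator
#'
#' Bundles and validates the generator parameters. The generator emulates
#' the features of an SSU rRNA reference database that the pipeline must
#' cope with: RNA alphabet, occasional IUPAC ambiguity characters, missing
#' 200-300 nt end segments on a fraction of records, duplicated sequences
#' with a skewed abundance distribution, and conserved blocks embedded at
#' known coordinates with known per-position substitution rates.
#'
#' @param n_records Number of FASTA records to emit.
#' @param seed Integer seed; mandatory, every sampling decision derives
#'   from it.
#' @param template_length Record length before truncation (default 1542,
#'   the E. coli 16S gene length).
#' @param contigs Contigs to embed: a data frame with `name`, `sequence`
#'   (IUPAC) and `start` (1-based position in the template). Defaults to
#'   the reference contigs that fit the template.
#' @param substitution_rate Per-position probability that an embedded-
#'   region base differs from the planted isoform (scalar, default 0.02);
#'   substitutions are uniform over the three alternative bases.
#' @param degenerate_char_rate Probability that an emitted base is written
#'   as a random IUPAC ambiguity code containing it (default 0.001).
#' @param truncation_prob Probability a record loses one end
#'   (default 0.1); the lost length is uniform on `truncation_range` and
#'   the 5' or 3' end is chosen with equal probability.
#' @param truncation_range Two integers, lo <= hi (default c(200, 300)).
#' @param redundancy NULL for no redundancy (every record is its own
#'   variant), or a list with `n_variants` and either `exponent` (Zipf
#'   exponent for sampling variants per record) or `abundances` (explicit
#'   per-variant counts summing to `n_records`).
#' @param rna_alphabet Emit U instead of T, as SILVA does (default TRUE).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_records,
                              seed,
                              template_length = 1542L,
                              contigs = NULL,
                              substitution_rate = 0.02,
                              degenerate_char_rate = 0.001,
                              truncation_prob = 0.1,
                              truncation_range = c(200L, 300L),
                              redundancy = NULL,
                              rna_alphabet = TRUE) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  template_length <- as.integer(template_length)
  if (is.null(contigs)) {
    contigs <- reference_contigs()
    contigs <- contigs[contigs$start + nchar(contigs$sequence) - 1L <= template_length, ]
  }
  stopifnot(is.data.frame(contigs), all(c("name", "sequence", "start") %in% names(contigs)))
  contig_end <- contigs$start + nchar(contigs$sequence) - 1L
  if (any(contig_end > template_length)) {
    stop("template shorter than embedded contig coordinates: ",
         paste(contigs$name[contig_end > template_length], collapse = ", "),
         call. = FALSE)
  }
  ord <- order(contigs$start)
  if (any(contigs$start[ord][-1] <= contig_end[ord][-length(ord)])) {
    stop("embedded contigs overlap", call. = FALSE)
  }
  probs <- c(substitution_rate, degenerate_char_rate, truncation_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  truncation_range <- as.integer(truncation_range)
  if (length(truncation_range) != 2L || truncation_range[1] > truncation_range[2]) {
    stop("`truncation_range` must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  if (!is.null(redundancy)) {
    stopifnot(is.list(redundancy), !is.null(redundancy$n_variants))
    if (!is.null(redundancy$abundances) &&
        sum(redundancy$abundances) != n_records) {
      stop("explicit `redundancy$abundances` must sum to `n_records`", call. = FALSE)
    }
  }
  structure(list(
    n_records = as.integer(n_records), seed = as.integer(seed),
    template_length = template_length,
    contigs = tibble::as_tibble(contigs[, c("name", "sequence", "start")]),
    substitution_rate = substitution_rate,
    degenerate_char_rate = degenerate_char_rate,
    truncation_prob = truncation_prob,
    truncation_range = truncation_range,
    redundancy = redundancy,
    rna_alphabet = isTRUE(rna_alphabet)
  ), class = "sim_config")
}

#' Generate a synthetic SILVA-like database with a ground-truth manifest
#'
#' Builds a pool of distinct full-length variants, each carrying one
#' mutated copy of every embedded contig region, then emits records by
#' duplicating variants according to the redundancy model and applying
#' end truncation, ambiguity-code rewriting and the RNA alphabet. The
#' planted isoform of each contig is drawn once per database, so the true
#' per-position base distribution is: planted base with probability
#' 1 - substitution_rate, each alternative with substitution_rate / 3.
#' Output is deterministic for a fixed seed.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A list with `records` (tibble: `id`, `description`, `sequence`
#'   as emitted, i.e. possibly RNA with ambiguity codes) and `manifest`, a
#'   list recording every sampling decision: planted isoforms and
#'   substitution rate, realised variant abundances, per-record variant /
#'   truncation assignments, and the true per-contig fragment carried by
#'   each record (NA when truncation removed or cropped the region).
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .generate_database_impl(config))
}

.generate_database_impl <- function(config) {
  bases <- c("A", "C", "G", "T")
  n_rec <- config$n_records
  L <- config$template_length
  contigs <- config$contigs

  planted <- purrr::map_chr(contigs$sequence, function(s) {
    chars <- .validate_iupac(s)
    paste(vapply(chars, function(ch) {
      set <- .iupac_sets[[ch]]
      if (length(set) == 1L) set else sample(set, 1L)
    }, ""), collapse = "")
  })

  n_var <- if (is.null(config$redundancy)) n_rec else as.integer(config$redundancy$n_variants)
  pool <- matrix(sample(bases, n_var * L, replace = TRUE), nrow = n_var, ncol = L)
  for (i in seq_len(nrow(contigs))) {
    chars <- strsplit(planted[i], "", fixed = TRUE)[[1]]
    cols <- contigs$start[i]:(contigs$start[i] + length(chars) - 1L)
    region <- matrix(rep(chars, each = n_var), nrow = n_var)
    mut <- matrix(stats::runif(n_var * length(chars)) < config$substitution_rate,
                  nrow = n_var)
    if (any(mut)) {
      orig <- region[mut]
      pick <- sample.int(3L, sum(mut), replace = TRUE)
      region[mut] <- mapply(function(b, j) .other_bases[[b]][j], orig, pick)
    }
    pool[, cols] <- region
  }
  variant_seq <- do.call(paste0, asplit(pool, 2))

  if (is.null(config$redundancy)) {
    assignment <- seq_len(n_rec)
  } else if (!is.null(config$redundancy$abundances)) {
    assignment <- rep(seq_len(n_var), times = config$redundancy$abundances)
  } else {
    s <- config$redundancy$exponent %||% 1
    prob <- seq_len(n_var)^(-s)
    assignment <- sample.int(n_var, n_rec, replace = TRUE, prob = prob)
  }

  seqs <- variant_seq[assignment]
  truncated <- rep("none", n_rec)
  trunc_len <- rep(0L, n_rec)
  hit <- stats::runif(n_rec) < config$truncation_prob
  if (any(hit)) {
    side <- sample(c("prefix", "suffix"), sum(hit), replace = TRUE)
    len <- sample(seq(config$truncation_range[1], config$truncation_range[2]),
                  sum(hit), replace = TRUE)
    truncated[hit] <- side
    trunc_len[hit] <- len
    pre <- hit & truncated == "prefix"
    suf <- hit & truncated == "suffix"
    seqs[pre] <- substr(seqs[pre], trunc_len[pre] + 1L, L)
    seqs[suf] <- substr(seqs[suf], 1L, L - trunc_len[suf])
  }

  # ground-truth region content per record, in normalised DNA space
  offset <- ifelse(truncated == "prefix", trunc_len, 0L)
  fragments <- purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    w <- nchar(contigs$sequence[i])
    s <- contigs$start[i] - offset
    ok <- s >= 1L & (s + w - 1L) <= nchar(seqs)
    tibble::tibble(
      record = seq_len(n_rec),
      contig = contigs$name[i],
      fragment = ifelse(ok, substr(seqs, s, s + w - 1L), NA_character_)
    )
  })

  if (config$degenerate_char_rate > 0) {
    n_amb <- stats::rbinom(n_rec, nchar(seqs), config$degenerate_char_rate)
    for (r in which(n_amb > 0L)) {
      chars <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
      pos <- sample.int(length(chars), min(n_amb[r], length(chars)))
      chars[pos] <- vapply(chars[pos], function(b) {
        cand <- .codes_containing[[b]]
        cand[sample.int(length(cand), 1L)]
      }, "")
      seqs[r] <- paste(chars, collapse = "")
    }
  }

  ids <- sprintf("SYN%05d", seq_len(n_rec))
  emitted <- if (config$rna_alphabet) chartr("T", "U", seqs) else seqs
  records <- tibble::tibble(
    id = ids,
    description = sprintf("synthetic SILVA-like record variant=v%04d", assignment),
    sequence = emitted
  )
  manifest <- list(
    seed = config$seed,
    n_records = n_rec,
    template_length = L,
    substitution_rate = config$substitution_rate,
    degenerate_char_rate = config$degenerate_char_rate,
    truncation_prob = config$truncation_prob,
    truncation_range = config$truncation_range,
    rna_alphabet = config$rna_alphabet,
    planted = tibble::tibble(contig = contigs$name, start = contigs$start,
                             isoform = planted),
    variants = tibble::tibble(
      variant = seq_len(n_var),
      abundance = tabulate(assignment, nbins = n_var)
    ),
    records = tibble::tibble(id = ids, variant = assignment,
                             truncated = truncated, trunc_len = trunc_len),
    fragments = dplyr::mutate(fragments, id = ids[.data$record],
                              .keep = "unused", .before = 1)
  )
  list(records = records, manifest = manifest)
}

#' True per-position base distribution of an embedded contig
#'
#' The distribution the generator planted: the sampled isoform base with
#' probability `1 - substitution_rate`, each alternative base with
#' `substitution_rate / 3`.
#'
#' @param manifest A manifest from [generate_database()].
#' @param contig Contig name.
#' @return A `position_freq`-shaped tibble (`position`, `A`, `C`, `G`,
#'   `T`, `max_base`, `max_freq`).
#' @export
true_base_distribution <- function(manifest, contig) {
  row <- manifest$planted[manifest$planted$contig == contig, ]
  if (!nrow(row)) stop("contig not in manifest: ", contig, call. = FALSE)
  chars <- strsplit(row$isoform, "", fixed = TRUE)[[1]]
  eps <- manifest$substitution_rate
  freq <- matrix(eps / 3, nrow = length(chars), ncol = 4,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  freq[cbind(seq_along(chars), match(chars, colnames(freq)))] <- 1 - eps
  tibble::tibble(
    position = seq_along(chars),
    A = freq[, "A"], C = freq[, "C"], G = freq[, "G"], T = freq[, "T"],
    max_base = if (eps < 0.75) chars else c("A", "C", "G", "T")[max.col(freq)],
    max_freq = apply(freq, 1, max)
  )
}
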