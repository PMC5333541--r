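small_contigs <- function() {
  rc <- reference_contigs()
  tibble::tibble(
    name = c("1", "3"),
    sequence = rc$sequence[match(c("1", "3"), rc$name)],
    start = c(8L, 120L)
  )
}

test_that("simulation_config validates its parameters", {
  expect_error(simulation_config(n_records = 10), "seed")
  expect_error(
    simulation_config(10, seed = 1, template_length = 50,
                      contigs = small_contigs()),
    "template shorter")
  expect_error(
    simulation_config(10, seed = 1, substitution_rate = 1.5,
                      template_length = 200, contigs = small_contigs()[1, ]),
    "probabilities")
  expect_error(
    simulation_config(10, seed = 1, truncation_range = c(300, 200)),
    "lo <= hi")
  expect_error(
    simulation_config(10, seed = 1,
                      redundancy = list(n_variants = 2, abundances = c(3, 3))),
    "sum to")
  overlapping <- tibble::tibble(name = c("a", "b"),
                                sequence = c("ACGTACGT", "TTTTCCCC"),
                                start = c(10L, 12L))
  expect_error(simulation_config(10, seed = 1, template_length = 100,
                                 contigs = overlapping), "overlap")
})

test_that("the same seed reproduces records and manifest byte-for-byte", {
  cfg <- simulation_config(40, seed = 99, template_length = 300,
                           contigs = small_contigs(), truncation_prob = 0.3)
  a <- generate_database(cfg)
  b <- generate_database(cfg)
  expect_identical(a, b)
  other <- generate_database(
    simulation_config(40, seed = 100, template_length = 300,
                      contigs = small_contigs(), truncation_prob = 0.3))
  expect_false(identical(a$records$sequence, other$records$sequence))
  # RNG state of the session is untouched
  set.seed(1); x <- runif(1)
  set.seed(1); generate_database(cfg); y <- runif(1)
  expect_identical(x, y)
})

test_that("a clean database carries exact contig isoforms in every record", {
  cfg <- simulation_config(60, seed = 7, template_length = 300,
                           contigs = small_contigs(),
                           substitution_rate = 0, degenerate_char_rate = 0,
                           truncation_prob = 0)
  db <- generate_database(cfg)
  recs <- tibble::tibble(id = db$records$id,
                         sequence = normalize_sequences(db$records$sequence))
  windows <- enumerate_windows(reference_contigs()[reference_contigs()$name == "3", ],
                               k = 12)
  sc <- scan_database(windows, recs)
  expect_true(all(sc$percent == 100))
  # the planted isoform is an isoform of the degenerate contig
  iso3 <- db$manifest$planted$isoform[db$manifest$planted$contig == "3"]
  expect_true(iso3 %in% expand_isoforms(small_contigs()$sequence[2]))
})

test_that("manifest ground truth matches the emitted records", {
  cfg <- simulation_config(80, seed = 13, template_length = 300,
                           contigs = small_contigs(),
                           substitution_rate = 0.05, degenerate_char_rate = 0,
                           truncation_prob = 0.4, truncation_range = c(50, 80))
  db <- generate_database(cfg)
  man <- db$manifest
  recs <- normalize_sequences(db$records$sequence)

  # truncation bookkeeping matches sequence lengths
  expect_identical(nchar(recs),
                   man$template_length - man$records$trunc_len)
  # fragments slice out of the records exactly where the manifest says
  f3 <- man$fragments[man$fragments$contig == "3", ]
  off <- ifelse(man$records$truncated == "prefix", man$records$trunc_len, 0L)
  for (i in which(!is.na(f3$fragment))[1:20]) {
    s <- 120L - off[i]
    expect_identical(substr(recs[i], s, s + 43L), f3$fragment[i])
  }
  # variant abundances sum to the record count
  expect_identical(sum(man$variants$abundance), cfg$n_records)
})

test_that("redundancy, ambiguity emission and RNA alphabet behave as configured", {
  cfg <- simulation_config(
    100, seed = 31, template_length = 300, contigs = small_contigs(),
    degenerate_char_rate = 0.01, truncation_prob = 0,
    redundancy = list(n_variants = 5, exponent = 1), rna_alphabet = TRUE)
  db <- generate_database(cfg)
  expect_true(any(grepl("U", db$records$sequence)))   # RNA alphabet
  expect_false(any(grepl("T", db$records$sequence)))
  amb <- gsub("[ACGU]", "", paste(db$records$sequence, collapse = ""))
  expect_gt(nchar(amb), 0)                            # ambiguity codes present
  expect_true(all(strsplit(amb, "")[[1]] %in%
                  c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")))
  expect_lte(max(db$manifest$records$variant), 5)
  # rewriting never changes record length, and the manifest fragment (the
  # underlying bases) is covered by each emitted ambiguity code
  recs <- normalize_sequences(db$records$sequence)
  expect_identical(nchar(recs), rep(300L, 100))
  f1 <- db$manifest$fragments[db$manifest$fragments$contig == "1", ]
  emitted <- substr(recs, 8, 8 + 19)
  for (i in seq_len(20)) {
    e <- strsplit(emitted[i], "")[[1]]
    truth <- strsplit(f1$fragment[i], "")[[1]]
    covered <- mapply(function(code, base) base %in% oracle_iupac[[code]], e, truth)
    expect_true(all(covered))
  }
})

test_that("background base composition is uniform (chi-square sanity)", {
  cfg <- simulation_config(50, seed = 77, template_length = 400,
                           contigs = small_contigs()[1, ],
                           degenerate_char_rate = 0, truncation_prob = 0)
  db <- generate_database(cfg)
  recs <- normalize_sequences(db$records$sequence)
  background <- substr(recs, 200, 400)  # away from the embedded contig
  counts <- table(strsplit(paste(background, collapse = ""), "")[[1]])
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("the packaged regression fixture is pinned to its config", {
  fx <- regression_fixture()
  expect_identical(nrow(fx$records), 50L)
  # regenerating from the frozen config reproduces the packaged FASTA exactly
  db <- generate_database(regression_fixture_config())
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(db$records, tmp)
  expect_identical(readLines(tmp), readLines(fx$fasta_path))
  # planted NR composition: 7 variants with known abundances
  nr <- dedupe_nr(fx$records$sequence)
  expect_identical(nrow(nr), 7L)
  expect_identical(sort(nr$abundance, decreasing = TRUE),
                   c(20L, 11L, 8L, 5L, 3L, 2L, 1L))
  expect_identical(sum(nr$abundance), 50L)
  # cumulative-sum oracle for the planted abundance vector
  expect_identical(nr_needed(nr, 0.95), 6L)
  expect_identical(nr_needed(nr, 0.5), 2L)
})
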