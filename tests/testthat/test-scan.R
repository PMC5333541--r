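toy_windows <- function(seq, name = "toy", k = nchar(seq)) {
  enumerate_windows(tibble::tibble(name = name, sequence = seq), k = k)
}

test_that("scan_database counts records containing any isoform once", {
  db <- tibble::tibble(
    id = c("r1", "r2", "r3"),
    sequence = c("TTAGATT", "CCCCCCC", "AGATAGAT")
  )
  sc <- scan_database(toy_windows("RGAT"), db)
  expect_identical(sc$seq_hits, 2L)             # r1 and r3, r3 counted once
  expect_identical(sc$n_dup_records, 1L)        # r3 has two matches
  expect_equal(sc$percent, 100 * 2 / 3)

  absent <- scan_database(toy_windows("GGGG"), db)
  expect_identical(absent$seq_hits, 0L)
  expect_identical(absent$percent, 0)

  expect_error(scan_database(toy_windows("RGAT"), db[0, ]), "empty database")
  empty <- scan_database(toy_windows("ACGT")[0, ], db)
  expect_identical(nrow(empty), 0L)
})

test_that("IUPAC ambiguity inside database records does not match", {
  db <- tibble::tibble(id = c("amb", "plain"), sequence = c("TARATT", "TAGATT"))
  sc <- scan_database(toy_windows("AGAT"), db)
  expect_identical(sc$seq_hits, 1L)   # only the unambiguous record
})

test_that("scan_database equals the naive per-isoform substring oracle", {
  set.seed(202)
  rc <- reference_contigs()
  contig <- rc[rc$name == "5b", ]
  # synthetic records: random background, half with a planted window isoform
  db <- tibble::tibble(
    id = sprintf("r%03d", 1:60),
    sequence = vapply(1:60, function(i) {
      s <- random_dna(150)
      if (i %% 2 == 0) {
        win <- sample(enumerate_windows(contig, 12)$sequence, 1)
        iso <- sample(expand_isoforms(win), 1)
        at <- sample.int(150 - 12, 1)
        s <- paste0(substr(s, 1, at), iso, substr(s, at + 13, 150))
      }
      s
    }, "")
  )
  windows <- enumerate_windows(contig, 12)
  sc <- scan_database(windows, db, keep_positions = TRUE)
  for (w in seq_len(nrow(windows))) {
    oracle <- oracle_scan_window(windows$sequence[w], db$sequence)
    expect_identical(sc$seq_hits[w], oracle$seq_hits)
    expect_identical(sc$n_dup_records[w], oracle$n_dup_records)
    got <- sc$hit_positions[[w]]
    want <- oracle$positions[lengths(oracle$positions) > 0]
    names(want) <- db$id[lengths(oracle$positions) > 0]
    expect_identical(lapply(got, as.integer), want)
  }
})

test_that("longer windows anchored at the same position never gain hits", {
  set.seed(303)
  rc <- reference_contigs()
  contig <- rc[rc$name == "3", ]
  db <- tibble::tibble(
    id = sprintf("r%03d", 1:40),
    sequence = vapply(1:40, function(i) {
      iso <- sample(expand_isoforms(contig$sequence), 1)
      paste0(random_dna(30), iso, random_dna(30))
    }, "")
  )
  hits_by_k <- sapply(9:15, function(k) {
    sc <- scan_database(enumerate_windows(contig, k), db)
    # compare windows anchored at the same contig offsets
    sc$seq_hits[sc$index %in% 0:(44 - 15)]
  })
  for (j in 2:ncol(hits_by_k)) {
    expect_true(all(hits_by_k[, j] <= hits_by_k[, j - 1]))
  }
})

test_that("specificity analysis finds planted duplicates exactly", {
  contig <- tibble::tibble(name = "t", sequence = "ACGTACGGTTCAGCAT")
  # every record carries exactly one occurrence of the full contig
  set.seed(11)
  singles <- tibble::tibble(
    id = sprintf("s%02d", 1:12),
    sequence = vapply(1:12, function(i)
      paste0(random_dna(40), contig$sequence, random_dna(40)), "")
  )
  curve <- specificity_analysis(contig, singles, k_range = 9:15)
  expect_true(all(curve$duplicate_count == 0))
  expect_identical(attr(curve, "selected_k"), 12L)  # flat curve falls back

  # a record with the same 12-mer twice: once in seq_hits, once per window in dups
  w12 <- substr(contig$sequence, 1, 12)
  dup_rec <- tibble::tibble(id = "d1",
                            sequence = paste0(w12, "GGGGGGGG", w12))
  sc <- scan_database(toy_windows(w12, k = 12), dup_rec)
  expect_identical(sc$seq_hits, 1L)
  curve2 <- specificity_analysis(contig, dup_rec, k_range = c(12, 13))
  expect_identical(curve2$duplicate_count[curve2$k == 12], 1L)
  expect_identical(curve2$duplicate_count[curve2$k == 13], 0L)
})

test_that("duplicate counts are non-increasing in k on random databases", {
  rc <- reference_contigs()
  for (seed in c(21, 22)) {
    set.seed(seed)
    contig <- rc[rc$name == sample(c("3", "5a", "8a"), 1), ]
    iso_full <- expand_isoforms(contig$sequence)
    db <- tibble::tibble(
      id = sprintf("r%03d", 1:30),
      sequence = vapply(1:30, function(i) {
        # some records carry the region twice to provoke duplicates
        n_copies <- sample(1:2, 1)
        paste0(random_dna(25),
               paste(vapply(seq_len(n_copies),
                            function(j) paste0(sample(iso_full, 1), random_dna(10)),
                            ""), collapse = ""),
               random_dna(25))
      }, "")
    )
    curve <- specificity_analysis(contig, db, k_range = 9:15)
    expect_true(all(diff(curve$duplicate_count) <= 0))
  }
})

test_that("specificity k_range is validated against contig length", {
  contig <- tibble::tibble(name = "t", sequence = "ACGTACGTAC")
  db <- tibble::tibble(id = "r", sequence = "ACGTACGTAC")
  expect_error(specificity_analysis(contig, db, k_range = 9:15), "contig length")
})
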