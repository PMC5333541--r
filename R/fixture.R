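#' Configuration that generated the packaged regression database
#'
#' The frozen generator settings behind the small synthetic database
#' shipped with the package: 50 records on a 600-nt template carrying
#' contigs 1, 3 and a relocated 6b, seven variants with planted abundances
#' 20/11/8/5/3/2/1, a 2% per-position substitution rate and the RNA
#' alphabet. Truncation and per-record ambiguity rewriting are off so
#' duplicates of a variant are exact strings and the fixture's NR
#' composition is known by construction. Regenerating with this config
#' reproduces the packaged FASTA byte for byte.
#'
#' @return A `sim_config`.
#' @export
regression_fixture_config <- function() {
  ref <- reference_contigs()
  contigs <- tibble::tibble(
    name = c("1", "3", "6b"),
    sequence = ref$sequence[match(c("1", "3", "6b"), ref$name)],
    start = c(8L, 320L, 500L)
  )
  simulation_config(
    n_records = 50L,
    seed = 20170228L,
    template_length = 600L,
    contigs = contigs,
    substitution_rate = 0.02,
    degenerate_char_rate = 0,
    truncation_prob = 0,
    redundancy = list(n_variants = 7L, abundances = c(20L, 11L, 8L, 5L, 3L, 2L, 1L)),
    rna_alphabet = TRUE
  )
}

#' Load the packaged synthetic regression database
#'
#' A tiny (50-record) synthetic SILVA-like database with a ground-truth
#' manifest, version-pinned in `inst/extdata/` so the whole pipeline can
#' be exercised in seconds without any download. The variant abundances
#' are planted, so its non-redundant composition is known by construction.
#'
#' @return A list: `records` (normalised tibble as from [read_fasta()]),
#'   `manifest` (parsed ground-truth manifest), `fasta_path`,
#'   `manifest_path`.
#' @export
regression_fixture <- function() {
  fasta_path <- system.file("extdata", "synthetic_regression_db.fasta",
                            package = "conserved16s", mustWork = TRUE)
  manifest_path <- system.file("extdata", "synthetic_regression_manifest.json",
                               package = "conserved16s", mustWork = TRUE)
  list(
    records = read_fasta(fasta_path),
    manifest = jsonlite::fromJSON(manifest_path),
    fasta_path = fasta_path,
    manifest_path = manifest_path
  )
}
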