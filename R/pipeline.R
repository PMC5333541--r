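#' Pipeline run configuration
#'
#' Defaults reproduce the study parameterisation: 12-mer windows, a 95%
#' conservation threshold, a 0.05 consensus inclusion threshold and 95%
#' coverage for the NR-needed count.
#'
#' @param database Path to a FASTA database, or NULL to simulate.
#' @param simulate A `sim_config` from [simulation_config()] used when
#'   `database` is NULL.
#' @param out_dir Output directory for reports (created if missing).
#' @param k Window length (default 12).
#' @param theta Conservation threshold (default 0.95).
#' @param tau Consensus inclusion threshold (default 0.05).
#' @param coverage_fraction Fraction for the NR-needed count (default 0.95).
#' @param min_length Minimum record length kept when reading the database
#'   (default 0; the study used 1200).
#' @param contig_names Contigs to analyse; NULL means all reference contigs
#'   (contigs absent from the database are skipped with a note).
#' @param contigs Contig table (`name`, `sequence`); default
#'   [reference_contigs()].
#' @param stage How far to run: `"contigs"` (summary only), `"scan"`,
#'   `"recover"` or `"consensus"` (everything, default).
#' @param run_specificity Also run the k-size duplicate analysis for each
#'   analysed contig (default FALSE; it rescans the database per k).
#' @param specificity_k_range k values for the specificity analysis.
#' @param write_fragments Write recovered fragments as per-contig FASTA
#'   (default TRUE).
#' @return A list of class `run_config`.
#' @export
run_config <- function(database = NULL, simulate = NULL, out_dir = tempfile("c16s_"),
                       k = 12L, theta = 0.95, tau = 0.05,
                       coverage_fraction = 0.95, min_length = 0L,
                       contig_names = NULL, contigs = NULL,
                       stage = c("consensus", "recover", "scan", "contigs"),
                       run_specificity = FALSE, specificity_k_range = 9:15,
                       write_fragments = TRUE) {
  stage <- match.arg(stage)
  if (is.null(contigs)) contigs <- reference_contigs()
  structure(list(
    database = database, simulate = simulate, out_dir = out_dir,
    k = as.integer(k), theta = theta, tau = tau,
    coverage_fraction = coverage_fraction, min_length = as.integer(min_length),
    contig_names = contig_names, contigs = contigs, stage = stage,
    run_specificity = run_specificity, specificity_k_range = specificity_k_range,
    write_fragments = write_fragments
  ), class = "run_config")
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", name))
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

.fmt2 <- function(x) sprintf("%.2f", x)

#' Run the full conservation pipeline
#'
#' Orchestrates contig summarisation, window enumeration, database
#' scanning, anchor selection, fragment recovery, NR reduction, position
#' frequencies and consensus calling, writing the report tables a study
#' of conserved-region conservation needs: a contig characteristics table,
#' a per-window scan table with the top window per contig, an NR summary
#' (fragments, NR count, reduction, NR needed for coverage) and aligned
#' primer-contig / all-sequence / NR consensuses. Reports carry the
#' parameter set; re-running an identical config (and simulation seed)
#' reproduces them byte for byte.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list of class `pipeline_result` holding every
#'   intermediate tibble (`contigs`, `summary`, `records` info, `scan`,
#'   `anchors`, per-contig `fragments`, `nr`, `freq_all`, `freq_nr`,
#'   `nr_summary`, `consensus`, `metadata`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(config = config)
  stage_rank <- c(contigs = 1, scan = 2, recover = 3, consensus = 4)
  want <- stage_rank[[config$stage]]

  contigs <- config$contigs
  out$contigs <- contigs
  out$summary <- .stage("contigs", contig_summary(contigs, config$k))
  readr::write_tsv(out$summary, file.path(config$out_dir, "contig_summary.tsv"))

  if (want >= 2) {
    db <- .stage("database", {
      if (!is.null(config$database)) {
        list(records = read_fasta(config$database, min_length = config$min_length),
             manifest = NULL)
      } else if (!is.null(config$simulate)) {
        sim <- generate_database(config$simulate)
        write_fasta(sim$records, file.path(config$out_dir, "synthetic_db.fasta"))
        jsonlite::write_json(sim$manifest,
                             file.path(config$out_dir, "synthetic_manifest.json"),
                             auto_unbox = TRUE, digits = NA)
        list(records = tibble::tibble(
               id = sim$records$id,
               description = sim$records$description,
               sequence = normalize_sequences(sim$records$sequence)),
             manifest = sim$manifest)
      } else {
        stop("neither `database` nor `simulate` given")
      }
    })
    records <- db$records
    out$n_records <- nrow(records)
    out$manifest <- db$manifest

    analyse <- config$contig_names %||% contigs$name
    sel <- contigs[contigs$name %in% analyse, ]
    windows <- .stage("kmers", enumerate_windows(sel, config$k))
    readr::write_tsv(windows, file.path(config$out_dir, "windows.tsv"))
    scan <- .stage("scan", scan_database(windows, records))
    scan_report <- dplyr::mutate(tidy(scan), percent = .fmt2(.data$percent))
    readr::write_tsv(scan_report, file.path(config$out_dir, "scan.tsv"))
    out$scan <- scan

    anchors <- .stage("anchors", {
      purrr::map_dfr(unique(scan$contig_name), function(nm) {
        part <- scan[scan$contig_name == nm, ]
        if (all(part$seq_hits == 0L)) {
          message(sprintf("  contig %s absent from database; skipped", nm))
          return(NULL)
        }
        select_anchor(part)
      })
    })
    if (!nrow(anchors)) stop("stage 'anchors' failed: no contig hit the database",
                             call. = FALSE)
    anchor_report <- dplyr::mutate(
      dplyr::select(anchors, "contig_name", "index", "sequence", "seq_hits"),
      percent = .fmt2(100 * .data$seq_hits / nrow(records))
    )
    readr::write_tsv(anchor_report, file.path(config$out_dir, "anchors.tsv"))
    out$anchors <- anchors

    if (config$run_specificity) {
      out$specificity <- .stage("specificity", {
        purrr::map(stats::setNames(nm = anchors$contig_name), function(nm) {
          curve <- specificity_analysis(contigs[contigs$name == nm, ], records,
                                        k_range = config$specificity_k_range,
                                        default_k = config$k)
          readr::write_tsv(tibble::as_tibble(curve),
                           file.path(config$out_dir,
                                     sprintf("specificity_%s.tsv", nm)))
          curve
        })
      })
    }
  }

  if (want >= 3) {
    out$fragments <- .stage("recover", {
      purrr::map(stats::setNames(nm = anchors$contig_name), function(nm) {
        fs <- recover_fragments(records, anchors[anchors$contig_name == nm, ])
        readr::write_tsv(fs, file.path(config$out_dir,
                                       sprintf("recovery_%s.tsv", nm)))
        if (config$write_fragments) {
          rec <- fs[fs$outcome == "recovered", ]
          write_fasta(tibble::tibble(id = rec$id, sequence = rec$fragment),
                      file.path(config$out_dir, sprintf("fragments_%s.fasta", nm)))
        }
        fs
      })
    })
  }

  if (want >= 4) {
    consensus_rows <- list()
    nr_rows <- list()
    out$nr <- list(); out$freq_all <- list(); out$freq_nr <- list()
    .stage("consensus", {
      for (nm in names(out$fragments)) {
        fs <- out$fragments[[nm]]
        frags <- fs$fragment[fs$outcome == "recovered"]
        if (!length(frags)) next
        nr <- dedupe_nr(frags)
        readr::write_tsv(tibble::as_tibble(nr),
                         file.path(config$out_dir, sprintf("nr_%s.tsv", nm)))
        freq_all <- position_frequencies(nr, mode = "all")
        freq_nr <- position_frequencies(nr, mode = "nr")
        for (m in c("all", "nr")) {
          pfm <- if (m == "all") freq_all else freq_nr
          tab <- dplyr::mutate(
            conserved_positions(pfm, config$theta),
            dplyr::across(c("max_freq"), ~ round(.x, 6))
          )
          readr::write_tsv(dplyr::bind_cols(tab,
                             dplyr::select(tibble::as_tibble(pfm), "A", "C", "G", "T")),
                           file.path(config$out_dir,
                                     sprintf("freq_%s_%s.tsv", m, nm)))
        }
        cons_all <- consensus_iupac(freq_all, config$tau)
        cons_nr <- consensus_iupac(freq_nr, config$tau)
        write_fasta(tibble::tibble(
          id = c(sprintf("%s_primer_contig", nm),
                 sprintf("%s_consensus_all tau=%g", nm, config$tau),
                 sprintf("%s_consensus_nr tau=%g", nm, config$tau)),
          sequence = c(contigs$sequence[contigs$name == nm], cons_all, cons_nr)
        ), file.path(config$out_dir, sprintf("consensus_%s.fasta", nm)))

        g <- glance(nr, fraction = config$coverage_fraction)
        nr_rows[[nm]] <- tibble::tibble(
          contig_name = nm,
          n_fragments = g$n_fragments,
          n_nr = g$n_nr,
          nr_percent = .fmt2(100 * g$n_nr / g$n_fragments),
          reduction_percent = .fmt2(g$reduction_percent),
          nr_needed = g$nr_needed,
          needed_percent = .fmt2(100 * g$nr_needed / g$n_nr)
        )
        consensus_rows[[nm]] <- tibble::tibble(
          contig_name = nm,
          primer_contig = contigs$sequence[contigs$name == nm],
          consensus_all = cons_all,
          consensus_nr = cons_nr,
          n_conserved_all = sum(freq_all$max_freq >= config$theta),
          n_conserved_nr = sum(freq_nr$max_freq >= config$theta)
        )
        out$nr[[nm]] <- nr
        out$freq_all[[nm]] <- freq_all
        out$freq_nr[[nm]] <- freq_nr
      }
      invisible(NULL)
    })
    out$nr_summary <- dplyr::bind_rows(nr_rows)
    out$consensus <- dplyr::bind_rows(consensus_rows)
    readr::write_tsv(out$nr_summary, file.path(config$out_dir, "nr_summary.tsv"))
    readr::write_tsv(out$consensus, file.path(config$out_dir, "consensus_summary.tsv"))
  }

  meta <- list(
    tool = "conserved16s",
    version = as.character(utils::packageVersion("conserved16s")),
    parameters = list(
      k = config$k, theta = config$theta, tau = config$tau,
      coverage_fraction = config$coverage_fraction,
      min_length = config$min_length, stage = config$stage,
      database = config$database,
      simulate_seed = if (!is.null(config$simulate)) config$simulate$seed
    ),
    n_contigs = nrow(contigs),
    n_records = out$n_records
  )
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  out$metadata <- meta
  class(out) <- "pipeline_result"
  invisible(out)
}
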