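---
title: "How conserved is a 'conserved' 16S region? The conserved16s pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How conserved is a 'conserved' 16S region? The conserved16s pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conserved16s)
library(dplyr)
```

## The question and the approach

Universal 16S rRNA primers are designed against regions of the gene assumed
to be near-invariant across bacteria. `conserved16s` quantifies how far that
assumption holds, using only exact string matching against a reference
database — no alignment, no PCR model. The procedure:

1. **Primer contigs.** All published primers targeting one conserved region
   are aligned on the E. coli coordinate line and merged position by
   position into a degenerate consensus, the *primer contig*. Where two
   primers disagree at a position, the contig carries the minimal IUPAC
   code covering the union of their base sets; where primers leave a
   coordinate gap, the region splits into sub-contigs (labels a/b/c). The
   package ships the fifteen reference contigs as a fixture
   (`reference_contigs()`), so the literature-curation step is data, not
   code.

2. **k-mer windows and isoforms.** Each contig of length $L$ yields
   $L - k + 1$ windows of length $k$ (default $k = 12$; window indices are
   0-based). A degenerate window denotes
   $\prod_i m_i$ unambiguous *isoforms*, where $m_i$ is the multiplicity of
   the IUPAC symbol at position $i$ (1 for A/C/G/T; 2 for R, Y, S, W, K, M;
   3 for B, D, H, V; 4 for N). `expand_isoforms()` enumerates them;
   `contig_summary()` reproduces the per-contig table of lengths,
   degeneracies, window and isoform counts.

3. **Exact database scan.** Every isoform is searched as an exact substring
   of every (normalised) database record; a record counts once per window
   however many matches it contains (`scan_database()`). Normalisation
   (`read_fasta()` / `normalize_sequences()`) uppercases, strips alignment
   gaps and maps U to T so DNA-space isoforms match RNA-alphabet SSU
   records. Ambiguity codes *inside database records* never match — the
   scan asks whether the exact sequence is present, so a database N is
   evidence of absence, not a wildcard. Only the forward strand is
   scanned: SSU reference databases store sequences in the gene's sense
   orientation.

4. **Anchored fragment recovery.** Per contig, the window with the highest
   record frequency becomes the *anchor* (`select_anchor()`; ties break to
   the smaller index). For each record, the first (5'-most) anchor match
   is located and flanks are extended to full contig length
   (`recover_fragments()`). Fragments sharing an anchor are aligned by
   construction — no multiple alignment is needed because every fragment
   carries the anchor at the same offset. Records where a flank would run
   past a record end are counted `truncated` and excluded from consensus
   analysis (the gene's terminal 200–300 nucleotides are missing from many
   database entries, and padding would fabricate sequence); records
   without any anchor match are `unmatched`.

5. **Non-redundant reduction and conservation statistics.** Identical
   fragments collapse into an NR table with abundances (`dedupe_nr()`);
   `nr_needed()` reports how few NR sequences cover a given fraction of
   all fragments. `position_frequencies()` builds a per-position A/C/G/T
   frequency matrix in which a degenerate character contributes
   fractionally (R gives 0.5 to A and 0.5 to G, N gives 0.25 to each).
   Two weightings matter scientifically: abundance weighting reproduces
   the all-fragments view, while NR weighting (each distinct sequence
   counts once) removes the dominance of heavily sequenced taxa — the
   contrast between the two is the package's core result. A position is
   *conserved* when its majority base reaches $\theta$ (default 0.95);
   `consensus_iupac()` writes the IUPAC consensus of all bases reaching
   the inclusion threshold $\tau$.

```{r table2}
contig_summary(reference_contigs()) |> tail(4)
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 12 | window length (nt); chosen at the inflection of the duplicate-hit curve (`specificity_analysis()`): longer k-mers are more specific but match fewer records |
| `theta` | 0.95 | per-position conservation threshold on the majority-base frequency |
| `tau` | 0.05 | consensus inclusion threshold: bases with frequency ≥ τ enter the IUPAC consensus |
| `coverage_fraction` | 0.95 | coverage level for the NR-needed statistic |
| `min_length` | 0 | record length filter at read time (a SILVA-style study would use 1200) |

The consensus-calling rule deserves a note: published consensus strings of
this kind are highly degenerate for NR data, which implies a low inclusion
threshold; τ is therefore an explicit, always-reported parameter rather
than a hidden constant, with 0.05 as default. With τ = 0 the package still
requires a base to have been observed (frequency > 0) to enter the code;
including never-observed bases would make τ = 0 output all-N strings.

The inflection-point rule for selecting k is made concrete as "the k with
the largest positive second difference of the duplicate-count curve",
falling back to 12 on a flat curve. Duplicate counts are aggregated per
contig by summing per-window duplicate-record counts; since two distinct
isoforms can never match at the same start offset, per-window match
counts are exact duplicate evidence.

## The synthetic database generator

Desk-scale testing needs a database whose truth is known.
`simulation_config()` / `generate_database()` emulate the features of an
SSU reference database that the pipeline must survive:

* RNA alphabet (U) and occasional IUPAC ambiguity characters
  (`degenerate_char_rate`, default 0.001 — each rewritten base becomes a
  random code containing it);
* missing end segments: with probability `truncation_prob` (default 0.1) a
  record loses a uniform 200–300 nt prefix or suffix (equal probability —
  both gene ends show depressed coverage in real scans);
* redundancy: records are drawn from a pool of distinct variants, either
  one per record (default), Zipf-skewed, or with explicit planted
  abundances;
* embedded conserved blocks: each contig's region is a *single* isoform
  sampled once per database, then substituted per variant at rate
  `substitution_rate` (default 0.02), uniformly over the three alternative
  bases. Sampling the isoform once — rather than per record — keeps the
  planted per-position distribution well-defined (majority base with
  probability $1-\varepsilon$), which is what makes parameter-recovery
  tests meaningful. The 1542-nt template mirrors the E. coli gene.

Every sampling decision is recorded in a ground-truth manifest (variant
assignments, truncations, per-record region content, planted isoforms),
and the same seed reproduces the FASTA and manifest byte for byte.

What the generator does **not** emulate: phylogenetic correlation between
variants (substitutions are independent), indels (real "sequencing error"
includes frame-shifting single-base indels that exact matching is blind
to), chimeras, and taxonomy strings. Passing the parameter-recovery tests
therefore shows the machinery is correct and unbiased under the stated
model — not that real databases satisfy that model.

A 50-record regression database with planted NR composition
(7 variants, abundances 20/11/8/5/3/2/1) is packaged under `extdata/` and
regenerated byte-identically from `regression_fixture_config()`; truncation
and ambiguity rewriting are disabled there because per-record rewriting
would break exact duplication and the fixture's purpose is a known NR
table.

## Numerical and edge-case choices

* Window indices are 0-based; E. coli coordinates are 1-based inclusive.
* Anchor ties break to the smallest window index; NR ordering is
  descending abundance, then lexicographic — all outputs are deterministic.
* On multiple anchor matches in one record the 5'-most wins and the record
  is flagged; such duplicate-bearing records are counted in scan reports.
* Frequency rows over IUPAC-only input sum to 1 within 1e-9; characters
  outside the IUPAC alphabet leave a deficit and flag the position rather
  than erroring.
* `position_frequencies()` weights are exact rationals over a common
  denominator, so abundance-weighted NR frequencies equal raw all-fragment
  frequencies identically (tested to 1e-12).
* Degenerate inputs: a contig shorter than k yields zero windows, not an
  error; an empty database or an all-zero scan is an error (there is
  nothing to anchor).

## Problem sizes used by the test-suite studies

Parameter recovery runs at 5000 records (ε = 0.02), where the binomial
standard error per position (~0.002) is an order of magnitude below the
±0.02 acceptance band; truncation recovery uses 2000 records at p = 0.3.
Oracle-equivalence checks run the naive per-record, per-isoform substring
search on databases of ≤ 100 records; the end-to-end pipeline study uses
1000 full-length records.

## Known limitations

* **Anchor conditioning.** Fragments are recovered only from records whose
  anchor 12-mer is intact, so recovered frequencies at the 12 anchor
  positions are exactly 1 — ε above the planted majority frequency —
  while positions outside the anchor are unaffected (substitutions are
  independent across positions under the generator's model).
* **Chance anchor matches.** An anchor isoform can occur by chance outside
  the true region (more likely for high-multiplicity anchors); the
  resulting mis-anchored fragments add background noise that slightly
  inflates apparent variation. The first-match rule keeps this
  deterministic; the duplicate flag in recovery logs is the audit trail.
* **Exact matching only.** A single indel in a record shifts every
  downstream window out of register; such records are simply unmatched.
  This mirrors the method's design (it measures exact-sequence presence),
  but it means "unmatched" conflates true divergence, indels and missing
  segments — the truncation counters separate only the last of these.
* **Forward strand only**; reverse-complement occurrences are invisible by
  design, appropriate for sense-oriented SSU databases.
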