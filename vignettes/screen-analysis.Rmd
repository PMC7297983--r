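---
title: "Pooled in vivo shRNA screens of germinal center entry: model and methods"
author: "gcscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled in vivo shRNA screens of germinal center entry: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The screen this package models

A pooled shRNA screen for regulators of germinal center (GC) B cell
differentiation works by competition. Antigen-specific B cells are
transduced with a retroviral library of hairpin constructs (here ~390
constructs targeting 78 genes, five hairpins per gene), transferred into
recipient mice, and immunized. Ten days later the spleen is sorted into a
GC and a non-GC B cell compartment, the integrated hairpin cassettes are
amplified from genomic DNA by nested PCR — **five parallel amplifications
per compartment** — and sequenced. A construct whose knockdown removes a
positive regulator of GC entry is depleted from the GC compartment
relative to the non-GC compartment; knockdown of a negative regulator
enriches it.

`gcscreen` implements both halves of this workflow:

* the **analysis path**: cassette-aware read counting, median-of-replicates
  abundance, a scarcity filter, GC/non-GC fold changes with a
  reciprocal-standard-deviation consistency measure, construct and gene
  rankings, and the 2^-ddCt qPCR utility used for hit validation;
* a **synthetic screen generator** that reproduces the statistical
  structure of such data — skewed plasmid pool, founder-cell bottleneck,
  per-gene fate effects, clonal expansion, overdispersed parallel PCR
  replicates, FASTQ reads with substitution errors — and records the
  ground truth, so the analysis path can be validated end to end in the
  absence of deposited raw data.

## Hairpin cassette grammar

A cloning oligo is modelled as the concatenation

```
leader + sense + loop + antisense + terminator + trailer
```

with `antisense = reverse_complement(sense)`. The defaults
(`GATCC` / `TTCAAGAGA` / `TTTTTT` / `GATATCG`, stems 19-22 nt) are the
elements shared by the classic pSIREN-style cassettes; all four reference
oligos shipped in `inst/extdata/reference_cassettes.tsv` parse and
reassemble byte-for-byte under this grammar, which is the package's
round-trip fixture test.

`parse_hairpin()` scans **all** occurrences of the loop motif and accepts
the unique one whose flanking stems are equal-length, in range, and
reverse complements — a stem could coincidentally contain the motif, so
position alone is not trusted. Zero structurally valid splits is an
error, as are two or more (ambiguity).

Stem design rules, enforced by `assemble_hairpin()` and the library
generator: stems contain no loop motif, no reverse complement of the loop
motif (the antisense stem would otherwise contain the loop), no run of
six or more T (terminator collision), and no run of six or more A (its
antisense partner would carry the T run). `generate_library()` adds a
minimum pairwise Hamming distance between sense stems (default 3), so a
single sequencing error can never convert one construct's read into
another's — the guarantee that makes exact-match counting safe.

## The synthetic screen, stage by stage

All stages are driven by one master seed; each stage derives a named
sub-seed (`derive_seed()`), so runs are reproducible as a whole and per
stage. Defaults live in `sim_config()`.

1. **Plasmid pool** — proportions are normalized log-normal draws
   (`pool_lognormal_sigma = 0.5`). This reproduces a skewed but
   near-complete pool: at the default skew, well over 90% of a
   400-construct pool exceeds the 0.025% scarcity threshold, matching how
   such libraries are verified by sequencing before use. `sigma = 0`
   gives the exactly uniform pool.
2. **Founder bottleneck** — `n_founder_cells = 4000` founders are drawn
   multinomially from the pool. For a 390-construct library this is
   ~10-fold construct coverage, the coverage regime of the screen design
   this package targets. The bottleneck is the dominant noise source in
   the whole model (see *Sensitivity limits* below).
3. **Fate selection** — each founder enters the GC compartment with
   probability `clamp(baseline_gc_prob * gc_effect[gene], 0, 1)`;
   `baseline_gc_prob = 0.05` reflects that only a small fraction of
   transduced cells reaches the GC phenotype, and is a free parameter,
   not a measured one. Effects are multiplicative: `gc_effect = 1`
   neutral, `< 1` depleting (knockdown of a positive regulator), `> 1`
   enriching. The model is a single binary two-compartment snapshot at
   the analysis day; dark-zone/light-zone cycling within the GC is
   deliberately not modelled because the readout is a one-time sort.
4. **Clonal expansion** — GC founders expand by a rounded log-normal
   burst (`mu = log(8) - 0.32`, `sigma = 0.8`, i.e. mean ~8 cells, floored
   at 1); non-GC founders contribute one cell each. The burst creates the
   realistic dominance of a few clones inside the GC; its parameters are
   modelling conventions, configurable and not derived from data.
5. **Parallel PCR replicates** — each of the five amplifications draws
   independent Gamma-Poisson (negative binomial) counts per construct,
   mean proportional to cell counts, expected depth
   `reads_per_replicate = 100000`, shape `pcr_dispersion = 8`. The Gamma
   mixing models early-cycle amplification jackpots — the heavy-tailed
   replicate noise that motivates the median-of-five reduction
   downstream. Small shapes give an extreme jackpot regime; `Inf`
   recovers pure Poisson sampling.
6. **Reads** — every read embeds the full cassette inside the constant
   second-round amplicon context (forward-primer region upstream, reverse
   complement of the reverse primer downstream, constant filler out to
   `read_length = 150`), on a uniformly random strand, with independent
   substitution errors at `seq_error_rate = 0.001`, Phred+33 qualities,
   shuffled read order, and ids that carry no truth information. The
   ground truth (founder, GC and non-GC cell counts, expected log2 fold
   change) is written next to the FASTQ files.

What the generator does **not** emulate: indels and quality-dependent
errors, adapter or primer-dimer artifacts, PCR chimeras between
constructs, UMI structure, paired-end reads, and the recipient mice as
separate units (the screen pools them before sorting). Passing tests on
synthetic data therefore validate the arithmetic and the statistical
behaviour of the pipeline under this noise model, not robustness to
every artifact of real libraries.

## Quantification

`count_reads()` assigns a read to a construct when the construct's match
key occurs **exactly** in the read or its reverse complement. The default
key is the full stem region `sense + loop + antisense` (51-53 nt),
maximally specific; `match_mode = "sense"` is available for reads too
short to span the hairpin. Reads matching two or more constructs (e.g.
chimeras) are counted `ambiguous` and excluded; per replicate,
`matched + ambiguous + unmatched = total` always holds.

The production counter is anchored: every key contains the loop motif
exactly once, so candidate windows around all loop occurrences (both
strands, all stem lengths) enumerate precisely the matches an all-pairs
substring scan would find. The naive all-pairs scan is kept as
`method = "naive"` and the test suite checks exact equality of the two,
plus equality against an independent `grepl()`-based oracle.

Exact matching loses reads to sequencing errors at the expected rate
`(1 - e)^L` for key length `L` — about 5% at the default error rate —
but the loss is unbiased between compartments, so fold changes are
unaffected; the test suite verifies the rate.

Percentages divide by **matched** reads per replicate (vector-only and
artifact reads would otherwise distort abundances); a total-read
denominator is available via `denominator = "total"`. A replicate with a
zero denominator becomes `NA` and is excluded from the median.
`median_abundance()` takes the exact sample median over replicates —
permutation invariant and robust to a single jackpot replicate
(`{0.1, 0.2, 0.3, 0.4, 10} -> 0.3`).

## Scoring

* **Scarcity filter** — `filter_threshold(N, f) = 100 / (N * f)` percent:
  one `f`-th of the uniform share, 0.025% for 400 constructs at the
  conventional `f = 10`. A construct passes in a screen when its median
  abundance **strictly exceeds** the threshold in either compartment
  ("exceeding", hence strict), and is consistently recovered when it
  passes in every screen.
* **Fold change** — `FC = (gc + delta) / (nongc + delta)`, reported as
  log2. The pseudocount `delta` defaults to half the smallest nonzero
  value in the pair of abundance vectors at hand, which keeps constructs
  entirely absent from the GC — the strongest depletion signals — finite
  and rankable rather than `-Inf`. Compartment swap negates `log2_fc`
  exactly at fixed `delta`.
* **Consistency** — the sample SD of a construct's log2 fold-change
  estimates and its reciprocal, capped (default 100) so identical
  estimates do not produce infinities. Because the source of the SD is a
  design choice, both readings are implemented:
  `consistency_mode = "replicate_pairs"` (default) pairs replicate *i*
  of the GC sample with replicate *i* of the non-GC sample within each
  screen (5 pairs x screens estimates), which keeps the SD
  non-degenerate even for a single screen; `"screen_medians"` uses one
  estimate per screen (needs >= 2 screens). The mode is recorded on the
  scores object.
* **Hit calling** — depleted candidates: `log2_fc <= -fc_cut` (inclusive)
  and `inv_sd` at or above the `consistency_quantile` of the consistent
  set; enriched symmetric. Defaults `fc_cut = 2`,
  `consistency_quantile = 0.5` are explicit conventions standing in for
  what is otherwise a visual call on the fold-change versus 1/SD
  scatter. Ordering ties break by `inv_sd` then construct id, so ranks
  are deterministic. No multiple-testing control is applied: the
  procedure is a ranking, not a testing procedure.
* **Gene summary** — per gene, constructs recovered in all screens / in
  at least one but not all / in none (the three counts always sum to the
  construct count), and the median `log2_fc` over all-screen-recovered
  constructs; genes are ordered most-depleted first.

```{r example}
library(gcscreen)
out <- run_demo(tempdir(), seed = 7)   # 78 x 5 library, 2 screens
head(out$gene_summary)
out$hits$depleted[1:5, c("construct_id", "gene", "log2_fc", "inv_sd")]
```

## Sensitivity limits under the founder bottleneck

The default configuration places ~4,000 founders over 390 constructs with
a GC-entry probability of 0.05 — roughly 200 GC founders, about half a
founder per construct. The validation suite quantifies two consequences
that any user of this screen design should expect:

1. **Construct dropout dominates the GC compartment.** Under neutral
   effects roughly 60% of constructs realize zero GC cells, so their
   log2 fold changes sit at the pseudocount floor. The construct-level
   log2 fold-change distribution is therefore strongly left-shifted
   (mean around -2.5 rather than 0), and entire neutral genes can lose
   all constructs from the GC by chance. This is a property of the
   experiment's sampling design, not of the arithmetic: the same
   pipeline run at matched compartment coverage (e.g. GC entry 0.5 with
   no expansion noise) is unbiased, with mean log2 fold change within
   0.1 of zero — the test suite checks both regimes.
2. **Strong depletion is detectable but not uniquely rankable.** A
   planted gene with `gc_effect = 0.05` reliably lands in the depleted
   tail, but its floored constructs are statistically exchangeable with
   neutral genes that went extinct in the GC stochastically, so it tops
   the depleted gene ranking in only a minority of two-screen runs;
   planted enrichment (`gc_effect = 4`) recovers the top rank more
   often but not always. Heavy dropout is also what the original screen
   design reports (85 of ~400 constructs consistently recovered), which
   is why such screens validate individual hits with dedicated
   follow-up rather than trusting the ranking alone.

Raising founder numbers or GC entry in `sim_config()` shows both
limitations dissolving with coverage, which is the main practical use of
the simulator when planning a screen.

## Numerical and engineering choices

* Exact matching only, no mismatch rescue; the pairwise-distance
  guarantee would make one-mismatch rescue safe to add, but it is off by
  design.
* Degenerate inputs are first-class: empty FASTQ files are valid and
  count as zero; an all-zero cell pool warns and yields zero-count
  replicates; an all-`NA` sample (no matched reads anywhere) is an
  error; both-zero medians with a zero pseudocount are an error rather
  than a silent `NaN`.
* Classed conditions (`gcs_*`) distinguish grammar mismatches, hairpin
  violations, ambiguity, parse errors, configuration errors, and
  insufficient replication, so callers can react programmatically.
* FASTQ reading is a minimal validating four-line-record reader returning
  plain character vectors: quantification needs only raw sequences, and
  this keeps counting at millions of reads per minute on one CPU.
* Test problem sizes: unit tests run libraries of tens of constructs at
  a few thousand reads; the end-to-end validation runs the full
  390-construct design at five replicates of 100,000 reads per
  compartment, ten seeds for the neutral-null study and twenty
  two-screen runs for the planted-effect study — sizes chosen so the
  whole suite completes in minutes on a laptop while keeping
  Monte-Carlo error well below the effects under test.

## Limitations

Beyond the generator's scope listed above: the analysis assumes one
cassette per read (no multi-insert amplicons), treats the cassette purely
as a string (no restriction-site or thermodynamic semantics), and
provides no formal false-discovery control — rankings are inputs to
experimental validation, for which the 2^-ddCt utility covers the
standard qPCR readout.
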