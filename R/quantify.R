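#' Count shRNA cassette occurrences in FASTQ replicates
#'
#' A read is assigned to a construct when the construct's match key occurs
#' as an exact substring of the read or of its reverse complement. The
#' default key is the full hairpin stem region `sense + loop + antisense`
#' (maximally specific); `match_mode = "sense"` matches on the sense stem
#' alone for reads too short to span the hairpin. A read matching two or
#' more different constructs (e.g. a PCR chimera) is counted as ambiguous
#' and excluded from per-construct counts; a read matching one construct on
#' both strands counts once. No mismatches are tolerated: the library
#' generator's minimum pairwise stem distance makes exact matching safe,
#' and sequencing errors then remove reads without biasing the GC versus
#' non-GC comparison.
#'
#' Two implementations are provided: `"anchored"` (default) enumerates
#' candidate key windows around every occurrence of the loop motif, which
#' is exhaustive because every key contains the loop exactly once;
#' `"naive"` scans every key against every read. Both return identical
#' counts; the naive scan is the reference implementation.
#'
#' @param files Character vector of FASTQ paths, one per parallel PCR
#'   replicate (optionally gzipped).
#' @param manifest An `shrna_manifest`.
#' @param grammar A [cassette_grammar()]; defaults to the manifest's.
#' @param match_mode `"cassette"` (sense+loop+antisense) or `"sense"`.
#' @param method `"anchored"` or `"naive"` (sense mode always scans
#'   naively since a lone stem carries no anchor).
#' @param sample Sample label stored on the result.
#' @return A `screen_counts` object: integer `counts` matrix (constructs x
#'   replicates), a `totals` data frame (per replicate: `total`, `matched`,
#'   `ambiguous`, `unmatched`), and the construct id/gene columns.
#' @export
count_reads <- function(files, manifest, grammar = NULL,
                        match_mode = c("cassette", "sense"),
                        method = c("anchored", "naive"), sample = "sample") {
  match_mode <- match.arg(match_mode)
  method <- match.arg(method)
  grammar <- grammar %||% attr(manifest, "grammar") %||% cassette_grammar()
  manifest <- validate_manifest(manifest, grammar)
  keys <- cassette_key(manifest$sense, grammar, match_mode)
  if (anyDuplicated(keys)) {
    gcs_stop("gcs_config_error", "match keys are not unique under mode '%s'",
             match_mode)
  }
  if (length(files) == 0L) {
    gcs_stop("gcs_config_error", "no FASTQ files given")
  }
  n <- nrow(manifest)
  counts <- matrix(0L, n, length(files),
                   dimnames = list(manifest$construct_id,
                                   paste0("rep", seq_along(files))))
  totals <- data.frame(replicate = paste0("rep", seq_along(files)),
                       total = 0L, matched = 0L, ambiguous = 0L,
                       unmatched = 0L, stringsAsFactors = FALSE)
  for (f in seq_along(files)) {
    reads <- load_fastq(files[f])
    res <- if (match_mode == "cassette" && method == "anchored") {
      count_anchored(reads, keys, grammar$loop)
    } else {
      count_naive(reads, keys)
    }
    counts[, f] <- res$counts
    totals$total[f] <- length(reads)
    totals$matched[f] <- sum(res$counts)
    totals$ambiguous[f] <- res$ambiguous
    totals$unmatched[f] <- length(reads) - sum(res$counts) - res$ambiguous
  }
  structure(
    list(sample = sample, construct_id = manifest$construct_id,
         gene = manifest$gene, counts = counts, totals = totals),
    class = "screen_counts"
  )
}

# Internal constructor used by tests and count-level pipelines to wrap a
# bare count matrix (e.g. straight from simulate_replicates()) as a
# screen_counts object without a FASTQ round trip.
new_screen_counts <- function(counts, manifest, sample = "sample") {
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(manifest$construct_id,
                           paste0("rep", seq_len(ncol(counts))))
  totals <- data.frame(replicate = colnames(counts),
                       total = as.integer(colSums(counts)),
                       matched = as.integer(colSums(counts)),
                       ambiguous = 0L, unmatched = 0L,
                       stringsAsFactors = FALSE)
  structure(
    list(sample = sample, construct_id = manifest$construct_id,
         gene = manifest$gene, counts = counts, totals = totals),
    class = "screen_counts"
  )
}

# Anchored counter: every cassette key contains the loop motif exactly once
# (stems may not contain it), so any exact key occurrence in a read implies
# a loop occurrence at the key's stem boundary. Enumerating windows around
# all loop hits on both strands therefore finds exactly the key matches the
# all-pairs scan would.
count_anchored <- function(reads, keys, loop) {
  n_keys <- length(keys)
  stem_lens <- unique((stringi::stri_length(keys) - nchar(loop)) %/% 2L)
  pairs_read <- integer(0L)
  pairs_key <- integer(0L)
  for (strand in 1:2) {
    sr <- if (strand == 1L) reads else rc_chr(reads)
    rl <- stringi::stri_length(sr)
    n_occ <- stringi::stri_count_fixed(sr, loop)
    if (sum(n_occ) == 0L) next
    ridx <- which(n_occ >= 1L)
    starts <- stringi::stri_locate_first_fixed(sr[ridx], loop)[, 1L]
    multi <- which(n_occ >= 2L) # rare: loop motif more than once in a read
    if (length(multi) > 0L) {
      locs <- stringi::stri_locate_all_fixed(sr[multi], loop)
      extra_r <- rep.int(multi, n_occ[multi] - 1L)
      extra_s <- unlist(lapply(locs, function(m) m[-1L, 1L]), use.names = FALSE)
      ridx <- c(ridx, extra_r)
      starts <- c(starts, extra_s)
    }
    for (s in stem_lens) {
      from <- starts - s
      to <- starts + nchar(loop) + s - 1L
      ok <- from >= 1L & to <= rl[ridx]
      if (!any(ok)) next
      cand <- stringi::stri_sub(sr[ridx[ok]], from[ok], to[ok])
      hit <- match(cand, keys)
      found <- !is.na(hit)
      pairs_read <- c(pairs_read, ridx[ok][found])
      pairs_key <- c(pairs_key, hit[found])
    }
  }
  if (length(pairs_read) == 0L) {
    return(list(counts = integer(n_keys), ambiguous = 0L))
  }
  dedup <- !duplicated(pairs_read * (n_keys + 1L) + pairs_key)
  pairs_read <- pairs_read[dedup]
  pairs_key <- pairs_key[dedup]
  per_read <- tabulate(pairs_read, nbins = length(reads))
  unambig <- per_read[pairs_read] == 1L
  list(counts = tabulate(pairs_key[unambig], nbins = n_keys),
       ambiguous = sum(per_read > 1L))
}

# Reference counter: all keys x all reads x both strands, exact substrings.
count_naive <- function(reads, keys) {
  n_match <- integer(length(reads))
  last_key <- integer(length(reads))
  rc <- rc_chr(reads)
  for (k in seq_along(keys)) {
    hit <- stringi::stri_detect_fixed(reads, keys[k]) |
      stringi::stri_detect_fixed(rc, keys[k])
    n_match[hit] <- n_match[hit] + 1L
    last_key[hit] <- k
  }
  list(counts = tabulate(last_key[n_match == 1L], nbins = length(keys)),
       ambiguous = sum(n_match > 1L))
}

#' Convert replicate counts to within-replicate percentages
#'
#' The percentage of a construct in a replicate is
#' `100 * count / matched reads` in that replicate, so percentages sum to
#' 100 over constructs wherever at least one read matched. The matched-read
#' denominator follows the screen's definition of abundance among
#' sequenced shRNA fragments; `denominator = "total"` divides by all reads
#' in the replicate instead. A replicate with a zero denominator yields
#' `NA` percentages and is excluded from downstream medians.
#'
#' @param x A `screen_counts` object.
#' @param denominator `"matched"` (default) or `"total"`.
#' @return An `abundance_pct` object wrapping the percentage matrix.
#' @export
to_percentages <- function(x, denominator = c("matched", "total")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(x, "screen_counts"))
  denom <- if (denominator == "matched") x$totals$matched else x$totals$total
  pct <- 100 * t(t(x$counts) / denom)
  pct[, denom <= 0L] <- NA_real_
  structure(
    list(sample = x$sample, construct_id = x$construct_id, gene = x$gene,
         pct = pct, denominator = denominator),
    class = "abundance_pct"
  )
}

#' Median abundance over parallel PCR replicates
#'
#' Reduces the replicate percentages of each construct to their exact
#' sample median (midpoint of the two central values for an even count).
#' The median is invariant under replicate permutation and absorbs a
#' single PCR-jackpot replicate. Replicates flagged `NA` (zero matched
#' reads) are dropped before taking the median; if every replicate of the
#' sample is missing an error is raised.
#'
#' @param x An `abundance_pct` object from [to_percentages()], or a bare
#'   numeric matrix (rows = constructs) or vector (one construct) of
#'   replicate percentages.
#' @return For `abundance_pct` input, an `abundance_table` data frame with
#'   columns `construct_id`, `gene`, `rep<i>_pct`, `median_pct`; for bare
#'   numeric input, the per-construct median(s).
#' @export
#' @examples
#' median_abundance(c(0.1, 0.2, 0.3, 0.4, 10)) # jackpot absorbed -> 0.3
median_abundance <- function(x) {
  if (is.numeric(x)) {
    m <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
    if (all(is.na(m))) {
      gcs_stop("gcs_empty_sample", "all replicates missing")
    }
    med <- apply(m, 1L, median, na.rm = TRUE)
    return(if (is.matrix(x)) med else unname(med))
  }
  stopifnot(inherits(x, "abundance_pct"))
  if (all(is.na(x$pct))) {
    gcs_stop("gcs_empty_sample",
             "sample '%s': no replicate has matched reads", x$sample)
  }
  out <- data.frame(construct_id = x$construct_id, gene = x$gene,
                    stringsAsFactors = FALSE)
  pct <- x$pct
  colnames(pct) <- paste0(colnames(pct), "_pct")
  out <- cbind(out, as.data.frame(pct, row.names = NULL))
  out$median_pct <- apply(x$pct, 1L, median, na.rm = TRUE)
  attr(out, "sample") <- x$sample
  attr(out, "denominator") <- x$denominator
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Quantify one sample: FASTQ replicates to median abundances
#'
#' Convenience composition of [count_reads()], [to_percentages()] and
#' [median_abundance()].
#'
#' @inheritParams count_reads
#' @inheritParams to_percentages
#' @return An `abundance_table` data frame.
#' @export
quantify_sample <- function(files, manifest, grammar = NULL,
                            match_mode = "cassette", method = "anchored",
                            sample = "sample",
                            denominator = "matched") {
  counts <- count_reads(files, manifest, grammar, match_mode, method, sample)
  message(sprintf("[quantify] %s: %d replicates, %s matched reads", sample,
                  ncol(counts$counts),
                  paste(counts$totals$matched, collapse = "/")))
  median_abundance(to_percentages(counts, denominator))
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("screen_counts '%s': %d constructs x %d replicates\n",
              x$sample, nrow(x$counts), ncol(x$counts)))
  print(x$totals)
  invisible(x)
}
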