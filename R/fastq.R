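# Amplicon context for emitted reads: the cassette sits inside the
# second-round nested-PCR amplicon, so every read carries a constant
# upstream flank (the forward primer region), the cassette, and a constant
# downstream flank (reverse complement of the reverse primer), padded with
# constant vector-derived filler out to the read length.
LEFT_FLANK <- "GGACTATCATATGCTTACCGTAACTTGA"
RIGHT_FLANK <- "TCGCACACATTCCACATCCA"
PAD_UNIT <- "CTGCAGGCATGCAAGCTTGGCGTAATCATGGTCATAGCTG"

#' Emit FASTQ files for one compartment's replicate counts
#'
#' Writes one Phred+33 FASTQ file per replicate, named
#' `{screen}_{compartment}_{rep}.fastq[.gz]`. Each read embeds the
#' construct's full cassette oligo in the constant amplicon context, padded
#' or truncated to `read_length`; strand is chosen uniformly at random,
#' independent substitution errors are applied at `seq_error_rate`, and
#' read order is shuffled so that neither read ids nor file order encode
#' the originating construct.
#'
#' @param read_counts Integer matrix from [simulate_replicates()]
#'   (constructs x replicates).
#' @param manifest The `shrna_manifest` the counts refer to.
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param screen,compartment Sample labels used in file names.
#' @param seed Integer seed.
#' @param compress Write gzip-compressed files (`.fastq.gz`); plain
#'   `.fastq` when `FALSE`.
#' @return Character vector of file paths, one per replicate.
#' @export
emit_fastq <- function(read_counts, manifest, config = sim_config(),
                       out_dir, screen = "screen1", compartment = "gc",
                       seed = derive_seed(config$seed,
                                          paste0(screen, "/fastq_", compartment)),
                       compress = TRUE) {
  stopifnot(is.matrix(read_counts), nrow(read_counts) == nrow(manifest))
  max_cassette <- max(nchar(manifest$oligo))
  min_len <- nchar(LEFT_FLANK) + max_cassette
  if (config$read_length < min_len) {
    gcs_stop("gcs_config_error",
             "read_length %d too short: need >= %d (left flank + cassette)",
             config$read_length, min_len)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pad <- stringi::stri_dup(PAD_UNIT, ceiling(config$read_length / nchar(PAD_UNIT)))
  tmpl_fwd <- substr(paste0(LEFT_FLANK, manifest$oligo, RIGHT_FLANK, pad),
                     1L, config$read_length)
  tmpl_rev <- rc_chr(tmpl_fwd)
  qual <- strrep("I", config$read_length)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  paths <- character(ncol(read_counts))
  withr::with_seed(seed, {
    for (r in seq_len(ncol(read_counts))) {
      counts <- read_counts[, r]
      n_reads <- sum(counts)
      reads <- rep(tmpl_fwd, counts)
      if (n_reads > 0L) {
        rev_strand <- runif(n_reads) < 0.5
        reads[rev_strand] <- rep(tmpl_rev, counts)[rev_strand]
        reads <- inject_errors(reads, config$seq_error_rate)
        reads <- reads[sample.int(n_reads)]
      }
      path <- file.path(out_dir, paste0(screen, "_", compartment, "_rep",
                                        r, ext))
      ids <- sprintf("@%s_%s_rep%d:%d", screen, compartment, r,
                     seq_len(max(n_reads, 0L)))
      con <- if (compress) gzfile(path, "wb") else file(path, "wb")
      rec <- if (n_reads > 0L) {
        as.vector(rbind(ids, reads, "+", qual))
      } else {
        character(0L)
      }
      writeLines(rec, con)
      close(con)
      paths[r] <- path
    }
  })
  paths
}

# Internal: independent per-base substitution errors. Error positions are
# drawn per read as Binomial(read_length, rate); each error replaces the
# base by one of the three alternatives uniformly.
inject_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  len <- stringi::stri_length(reads)
  n_err <- rbinom(length(reads), len, rate)
  idx <- which(n_err > 0L)
  if (length(idx) == 0L) return(reads)
  read_idx <- rep.int(idx, n_err[idx])
  pos <- floor(runif(length(read_idx)) * len[read_idx]) + 1L
  shift <- sample.int(3L, length(read_idx), replace = TRUE)
  bases <- c("A", "C", "G", "T")
  # apply one error per read per pass; reads with k errors need k passes
  rank_in_read <- sequence(n_err[idx])
  for (pass in seq_len(max(rank_in_read))) {
    sel <- rank_in_read == pass
    ri <- read_idx[sel]; po <- pos[sel]
    orig <- stringi::stri_sub(reads[ri], po, po)
    new <- bases[(match(orig, bases) - 1L + shift[sel]) %% 4L + 1L]
    stringi::stri_sub(reads[ri], po, po) <- new
  }
  reads
}

#' Load reads from a FASTQ file
#'
#' Reads plain or gzipped four-line-record FASTQ and returns the read
#' sequences as a character vector for the exact substring matcher. Record
#' structure is validated (`@` header, `+` separator, sequence and quality
#' of equal length) and violations are reported with the index of the
#' offending record. The reader is deliberately minimal — quantification
#' needs only the raw sequence strings, at a rate of millions of reads per
#' minute.
#'
#' @param path FASTQ path, optionally gzipped.
#' @return Character vector of read sequences.
#' @export
load_fastq <- function(path) {
  if (!file.exists(path)) {
    gcs_stop("gcs_config_error", "FASTQ file not found: %s", path)
  }
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    gcs_stop("gcs_fastq_parse",
             "malformed FASTQ %s: %d lines is not a multiple of 4 (near record %d)",
             path, length(lines), length(lines) %/% 4L + 1L)
  }
  if (length(lines) == 0L) return(character(0L))
  heads <- lines[seq(1L, length(lines), 4L)]
  seqs <- lines[seq(2L, length(lines), 4L)]
  seps <- lines[seq(3L, length(lines), 4L)]
  quals <- lines[seq(4L, length(lines), 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+") |
                 stringi::stri_length(seqs) != stringi::stri_length(quals))
  if (length(bad) > 0L) {
    gcs_stop("gcs_fastq_parse", "malformed FASTQ %s: record %d", path, bad[1L])
  }
  seqs
}

#' Simulate one full screen to FASTQ
#'
#' Composes [simulate_pool()], [simulate_fates()], [simulate_replicates()]
#' (once per compartment), and [emit_fastq()] into one deterministic run:
#' for a fixed `config$seed` and screen label, every output file is
#' byte-identical across reruns. Writes the ground-truth table
#' (`{screen}_truth.tsv`) and a JSON manifest of outputs alongside the
#' FASTQ files.
#'
#' @param manifest An `shrna_manifest`.
#' @param effects An [effect_table()].
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param screen Screen label, used as seed namespace and file prefix.
#' @param pool Optional pre-computed pool proportions (so that two screens
#'   of the same physical library can share one pool); simulated from
#'   `config` when `NULL`.
#' @param compress Gzip FASTQ output.
#' @return A list with `fastq` (per-compartment path vectors), `truth`
#'   (GroundTruth data frame), `truth_path`, `pool`, and `counts`
#'   (per-compartment true read-count matrices).
#' @export
simulate_screen <- function(manifest, effects, config = sim_config(),
                            out_dir, screen = "screen1", pool = NULL,
                            compress = TRUE) {
  manifest <- validate_manifest(manifest,
                                attr(manifest, "grammar") %||% cassette_grammar())
  if (is.null(pool)) {
    pool <- simulate_pool(manifest, sigma = config$pool_lognormal_sigma,
                          seed = derive_seed(config$seed, paste0(screen, "/pool")))
  }
  truth <- simulate_fates(manifest, pool, effects, config,
                          seed = derive_seed(config$seed, paste0(screen, "/fates")))
  counts <- list(
    gc = simulate_replicates(setNames(truth$gc_cell_count, truth$construct_id),
                             config,
                             seed = derive_seed(config$seed, paste0(screen, "/pcr_gc"))),
    nongc = simulate_replicates(setNames(truth$nongc_cell_count, truth$construct_id),
                                config,
                                seed = derive_seed(config$seed, paste0(screen, "/pcr_nongc")))
  )
  fastq <- lapply(names(counts), function(cp) {
    emit_fastq(counts[[cp]], manifest, config, out_dir,
               screen = screen, compartment = cp, compress = compress)
  })
  names(fastq) <- names(counts)
  truth_path <- file.path(out_dir, paste0(screen, "_truth.tsv"))
  write_tsv(truth, truth_path)
  run_info <- list(
    screen = screen, config = unclass(config),
    n_constructs = nrow(manifest),
    fastq = fastq, truth = truth_path,
    tool_version = as.character(packageVersion("gcscreen"))
  )
  jsonlite::write_json(run_info,
                       file.path(out_dir, paste0(screen, "_outputs.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("[simulate] %s: %d founders -> %d GC / %d non-GC cells",
                  screen, sum(truth$founder_count), sum(truth$gc_cell_count),
                  sum(truth$nongc_cell_count)))
  list(fastq = fastq, truth = truth, truth_path = truth_path, pool = pool,
       counts = counts)
}
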