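# Shared small fixtures built in code.

small_manifest <- function(n_genes = 10, k = 3, seed = 42) {
  generate_library(n_genes, k, seed = seed)
}

# Random grammar-valid sense stems (independent of the library generator).
random_valid_senses <- function(n, len = 21, seed = 1,
                                grammar = cassette_grammar()) {
  withr::with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
      if (gcscreen:::stem_violation(cand, grammar) == "") out <- c(out, cand)
    }
    out
  })
}

# Write reads (character vector) as a temporary FASTQ file.
write_fastq_fixture <- function(reads, path = tempfile(fileext = ".fastq")) {
  rec <- as.vector(rbind(paste0("@r", seq_along(reads)),
                         reads, "+", strrep("I", nchar(reads))))
  writeLines(if (length(reads)) rec else character(0), path)
  path
}

# Embed a cassette oligo in the constant amplicon context at a given length.
embedded_read <- function(oligo, read_length = 150) {
  pad <- strrep(gcscreen:::PAD_UNIT, ceiling(read_length / nchar(gcscreen:::PAD_UNIT)))
  substr(paste0(gcscreen:::LEFT_FLANK, oligo, gcscreen:::RIGHT_FLANK, pad),
         1, read_length)
}

# Count-level two-screen simulation for scoring studies (no FASTQ round
# trip); returns the screen_scores table.
simulate_and_score <- function(manifest, effects, config, seed,
                               n_screens = 2, shared_pool = TRUE, ...) {
  pool <- if (shared_pool) {
    simulate_pool(manifest, config$pool_lognormal_sigma, seed = seed)
  } else {
    NULL
  }
  screens <- lapply(seq_len(n_screens), function(s) {
    sseed <- derive_seed(seed, paste0("s", s))
    p <- pool %||% simulate_pool(manifest, config$pool_lognormal_sigma,
                                 seed = sseed)
    truth <- simulate_fates(manifest, p, effects, config,
                            seed = derive_seed(sseed, "fates"))
    list(
      gc = simulate_replicates(truth$gc_cell_count, config,
                               seed = derive_seed(sseed, "gc")),
      nongc = simulate_replicates(truth$nongc_cell_count, config,
                                  seed = derive_seed(sseed, "nongc"))
    )
  })
  score_counts(screens, manifest, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
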