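#' Generate a synthetic shRNA library manifest
#'
#' Draws random sense stems satisfying the cassette design rules (see
#' [assemble_hairpin()]) and a minimum pairwise Hamming distance, then
#' assembles full cloning oligos. Genes are named `G001`, `G002`, ... with
#' `k_per_gene` constructs each (`G001-1` ... `G001-k`). The pairwise
#' distance (default 3 mismatches) guarantees that a single substitution
#' error cannot convert one construct's read into another's, which keeps
#' exact-match counting safe.
#'
#' @param n_genes,k_per_gene Number of genes and constructs per gene.
#' @param grammar A [cassette_grammar()].
#' @param min_pairwise_mismatches Minimum Hamming distance between any two
#'   sense stems.
#' @param seed Integer seed; the same seed reproduces the manifest exactly.
#' @param stem_length Stem length for generated constructs (within the
#'   grammar's range).
#' @param max_attempts Cap on rejection-sampling draws before failing.
#' @return A `shrna_manifest` data frame with columns `construct_id`,
#'   `gene`, `sense`, `oligo`, carrying the grammar as an attribute.
#' @export
#' @examples
#' m <- generate_library(3, 2, seed = 1)
#' m$construct_id
generate_library <- function(n_genes, k_per_gene,
                             grammar = cassette_grammar(),
                             min_pairwise_mismatches = 3L, seed = 1L,
                             stem_length = 21L, max_attempts = NULL) {
  n_genes <- as.integer(n_genes); k_per_gene <- as.integer(k_per_gene)
  if (is.na(n_genes) || n_genes < 1L || is.na(k_per_gene) || k_per_gene < 1L) {
    gcs_stop("gcs_config_error", "n_genes and k_per_gene must be positive")
  }
  stem_length <- as.integer(stem_length)
  if (stem_length < grammar$stem_min || stem_length > grammar$stem_max) {
    gcs_stop("gcs_config_error", "stem_length %d outside grammar range %d-%d",
             stem_length, grammar$stem_min, grammar$stem_max)
  }
  n_total <- n_genes * k_per_gene
  max_attempts <- max_attempts %||% (200L * n_total + 1000L)
  bases <- c("A", "C", "G", "T")

  sense <- character(0L)
  accepted <- NULL # integer matrix, one row per accepted stem
  attempts <- 0L
  withr::with_seed(seed, {
    while (length(sense) < n_total) {
      if (attempts >= max_attempts) {
        gcs_stop("gcs_generation_failure",
                 "could not draw %d stems after %d attempts (distance >= %d)",
                 n_total, attempts, min_pairwise_mismatches)
      }
      attempts <- attempts + 1L
      cand <- paste(sample(bases, stem_length, replace = TRUE), collapse = "")
      if (stem_violation(cand, grammar) != "") next
      codes <- utf8ToInt(cand)
      if (!is.null(accepted)) {
        mm <- rowSums(accepted != matrix(codes, nrow(accepted), stem_length,
                                         byrow = TRUE))
        if (any(mm < min_pairwise_mismatches)) next
      }
      accepted <- rbind(accepted, codes)
      sense <- c(sense, cand)
    }
  })

  width <- max(3L, nchar(as.character(n_genes)))
  genes <- sprintf(paste0("G%0", width, "d"), seq_len(n_genes))
  gene_col <- rep(genes, each = k_per_gene)
  id_col <- paste0(gene_col, "-", rep(seq_len(k_per_gene), n_genes))
  manifest <- data.frame(
    construct_id = id_col, gene = gene_col, sense = sense,
    oligo = assemble_hairpin(sense, grammar),
    stringsAsFactors = FALSE
  )
  new_manifest(manifest, grammar)
}

new_manifest <- function(df, grammar) {
  rownames(df) <- NULL
  structure(df, class = c("shrna_manifest", "data.frame"), grammar = grammar)
}

#' Validate an shRNA library manifest
#'
#' Checks construct id and sense uniqueness, and for every row that the
#' oligo parses under the grammar, that its sense stem matches the `sense`
#' column, and that both stems satisfy the design rules (no loop motif, no
#' long T/A runs).
#'
#' @param manifest A manifest data frame (columns `construct_id`, `gene`,
#'   `sense`, `oligo`).
#' @param grammar A [cassette_grammar()].
#' @return The manifest, invisibly, as a validated `shrna_manifest`.
#' @export
validate_manifest <- function(manifest, grammar = cassette_grammar()) {
  req <- c("construct_id", "gene", "sense", "oligo")
  miss <- setdiff(req, names(manifest))
  if (length(miss) > 0L) {
    gcs_stop("gcs_parse_error", "manifest missing column(s): %s",
             paste(miss, collapse = ", "))
  }
  if (nrow(manifest) == 0L) {
    gcs_stop("gcs_config_error", "manifest is empty")
  }
  dup <- manifest$construct_id[duplicated(manifest$construct_id)]
  if (length(dup) > 0L) {
    gcs_stop("gcs_parse_error", "duplicated construct_id: %s", dup[1L])
  }
  dup <- manifest$sense[duplicated(manifest$sense)]
  if (length(dup) > 0L) {
    gcs_stop("gcs_parse_error", "duplicated sense sequence: %s", dup[1L])
  }
  for (i in seq_len(nrow(manifest))) {
    parsed <- tryCatch(parse_hairpin(manifest$oligo[i], grammar),
      gcs_error = function(e) {
        gcs_stop("gcs_parse_error", "row %d (%s): %s", i,
                 manifest$construct_id[i], conditionMessage(e))
      })
    if (parsed$sense != manifest$sense[i]) {
      gcs_stop("gcs_parse_error",
               "row %d (%s): oligo stems disagree with sense column",
               i, manifest$construct_id[i])
    }
    v <- stem_violation(parsed$sense, grammar)
    if (v != "") {
      gcs_stop("gcs_parse_error", "row %d (%s): %s", i,
               manifest$construct_id[i], v)
    }
  }
  invisible(new_manifest(as.data.frame(manifest)[req], grammar))
}

#' Read / write a library manifest TSV
#'
#' The manifest is a UTF-8, tab-separated file with a header row and columns
#' `construct_id`, `gene`, `sense`, and optionally `oligo`; a missing
#' `oligo` column is assembled from `sense` under the grammar. Row order is
#' preserved and `read_manifest(write_manifest(m))` returns `m` unchanged.
#'
#' @param path File path.
#' @param grammar A [cassette_grammar()].
#' @return `read_manifest()` returns a validated `shrna_manifest`;
#'   `write_manifest()` returns `path` invisibly.
#' @export
read_manifest <- function(path, grammar = cassette_grammar()) {
  if (!file.exists(path)) {
    gcs_stop("gcs_config_error", "manifest file not found: %s", path)
  }
  df <- read_tsv(path, colClasses = "character")
  req <- c("construct_id", "gene", "sense")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    gcs_stop("gcs_parse_error", "manifest %s missing column(s): %s", path,
             paste(miss, collapse = ", "))
  }
  if (!"oligo" %in% names(df) || all(is.na(df$oligo)) || all(df$oligo == "")) {
    df$oligo <- assemble_hairpin(df$sense, grammar)
  }
  validate_manifest(df, grammar)
}

#' @rdname read_manifest
#' @param manifest A manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  write_tsv(as.data.frame(manifest)[c("construct_id", "gene", "sense", "oligo")],
            path)
}

#' @export
print.shrna_manifest <- function(x, ...) {
  cat(sprintf("shRNA library manifest: %d constructs, %d genes\n",
              nrow(x), length(unique(x$gene))))
  print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
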