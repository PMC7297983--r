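#' One-command synthetic end-to-end screen demo
#'
#' Reproduces the full screening workflow on synthetic data: generate (or
#' load) a library manifest, plant per-gene GC-entry effects, simulate
#' `screens` independent screens to FASTQ (sharing one plasmid pool),
#' quantify each compartment from the FASTQ files, score constructs across
#' screens, and summarize genes. All outputs (manifest, effects, FASTQ,
#' counts, abundances, scores, gene summary, scatter data for the log2
#' fold-change versus reciprocal-SD plot, and a provenance record) are
#' written under `out_dir`; the run is fully determined by `seed`.
#'
#' By default two genes are planted as strong positive-regulator targets
#' (`gc_effect = 0.05`; their knockdown constructs should deplete from the
#' GC compartment) and one as a negative-regulator target
#' (`gc_effect = 4`).
#'
#' @param out_dir Output directory (created; must be writable).
#' @param seed Master seed for the whole run.
#' @param n_genes,k_per_gene Library shape (defaults 78 genes x 5).
#' @param screens Number of independent screens (>= 2 for gene summaries).
#' @param config A [sim_config()]; its seed is overridden per screen from
#'   the master seed.
#' @param effects Optional [effect_table()]; defaults to the planted
#'   effects described above.
#' @param manifest_path Optional existing manifest TSV to use instead of
#'   generating one.
#' @param fc_cut,consistency_quantile Hit-calling parameters, see
#'   [score_screens()].
#' @param compress Gzip the FASTQ files.
#' @return Invisibly, a list with the manifest, effects, per-screen
#'   simulation results, abundance tables, scores, gene summary, hit
#'   lists, and output paths.
#' @export
run_demo <- function(out_dir, seed = 7L, n_genes = 78L, k_per_gene = 5L,
                     screens = 2L, config = sim_config(),
                     effects = NULL, manifest_path = NULL,
                     fc_cut = 2, consistency_quantile = 0.5,
                     compress = TRUE) {
  if (!is.null(manifest_path) && !file.exists(manifest_path)) {
    gcs_stop("gcs_config_error", "manifest file not found: %s", manifest_path)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grammar <- cassette_grammar()

  manifest <- if (is.null(manifest_path)) {
    generate_library(n_genes, k_per_gene, grammar,
                     seed = derive_seed(seed, "library"))
  } else {
    read_manifest(manifest_path, grammar)
  }
  message(sprintf("[library] %d constructs over %d genes", nrow(manifest),
                  length(unique(manifest$gene))))
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))

  genes <- unique(manifest$gene)
  if (is.null(effects)) {
    planted <- c(0.05, 0.05, 4)[seq_len(min(3L, length(genes)))]
    names(planted) <- genes[seq_along(planted)]
    effects <- effect_table(genes, planted = planted)
  }
  write_effects(effects, file.path(out_dir, "effects.tsv"))

  pool <- simulate_pool(manifest, sigma = config$pool_lognormal_sigma,
                        seed = derive_seed(seed, "pool"))

  sims <- list()
  abundances <- list()
  for (s in seq_len(screens)) {
    screen_name <- paste0("screen", s)
    cfg_s <- config
    cfg_s$seed <- derive_seed(seed, screen_name)
    sims[[screen_name]] <-
      simulate_screen(manifest, effects, cfg_s,
                      out_dir = file.path(out_dir, screen_name),
                      screen = screen_name, pool = pool, compress = compress)
    ab <- list()
    for (cp in c("gc", "nongc")) {
      ab[[cp]] <- quantify_sample(sims[[screen_name]]$fastq[[cp]], manifest,
                                  grammar,
                                  sample = paste0(screen_name, "_", cp))
      write_tsv(ab[[cp]],
                file.path(out_dir, paste0(screen_name, "_", cp,
                                          "_abundance.tsv")))
    }
    abundances[[screen_name]] <- ab
  }

  policy <- filter_policy(nrow(manifest))
  scores <- score_screens(abundances, policy, fc_cut = fc_cut,
                          consistency_quantile = consistency_quantile)
  write_tsv(scores, file.path(out_dir, "scores.tsv"))
  hits <- rank_hits(scores, fc_cut, consistency_quantile)
  genes_tab <- gene_summary(scores)
  write_tsv(genes_tab, file.path(out_dir, "gene_summary.tsv"))
  write_tsv(scores[c("construct_id", "gene", "log2_fc", "inv_sd")],
            file.path(out_dir, "scatter.tsv"))
  message(sprintf(
    "[score] %d/%d constructs consistently recovered (%d genes); %d depleted, %d enriched candidates",
    sum(scores$consistent), nrow(scores),
    length(unique(scores$gene[scores$consistent])),
    nrow(hits$depleted), nrow(hits$enriched)))

  provenance <- list(
    tool = "gcscreen", version = as.character(packageVersion("gcscreen")),
    seed = seed, n_genes = n_genes, k_per_gene = k_per_gene,
    screens = screens, config = unclass(config),
    filter = unclass(policy), fc_cut = fc_cut,
    consistency_quantile = consistency_quantile,
    planted_effects = effects[effects$gc_effect != 1, ],
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(manifest = manifest, effects = effects, pool = pool,
                 sims = sims, abundances = abundances, scores = scores,
                 hits = hits, gene_summary = genes_tab,
                 out_dir = out_dir))
}

#' Score screens directly from simulated count matrices
#'
#' Count-level variant of the scoring pipeline used for calibration
#' studies: takes per-screen, per-compartment read-count matrices (e.g.
#' from [simulate_screen()]'s `counts`, or [simulate_replicates()])
#' and runs percentages, medians, and [score_screens()] without a FASTQ
#' round trip.
#'
#' @param count_screens List (one per screen) of lists with `gc` and
#'   `nongc` count matrices (constructs x replicates).
#' @param manifest The `shrna_manifest`.
#' @inheritParams score_screens
#' @return A `screen_scores` data frame.
#' @export
score_counts <- function(count_screens, manifest, policy = NULL, ...) {
  policy <- policy %||% filter_policy(nrow(manifest))
  screens <- lapply(count_screens, function(sc) {
    lapply(sc, function(m) {
      median_abundance(to_percentages(new_screen_counts(m, manifest)))
    })
  })
  score_screens(screens, policy, ...)
}
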