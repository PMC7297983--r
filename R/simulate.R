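#' Simulation configuration for a synthetic screen
#'
#' Bundles every stochastic-stage parameter of the synthetic screen. The
#' founder bottleneck (4,000 transduced cells for a ~390-construct library,
#' i.e. ~10-fold construct coverage), the five parallel PCR amplifications
#' per compartment, the single-end 150 nt reads, and the per-base
#' substitution error rate reflect the screen design this package targets;
#' the pool skew, clonal expansion, and PCR overdispersion parameters are
#' free modelling choices documented in the methods vignette.
#'
#' @param n_founder_cells Number of transduced founder cells seeding the
#'   response (the in vivo bottleneck).
#' @param baseline_gc_prob Probability that a neutral founder enters the GC
#'   compartment by the analysis day.
#' @param pool_lognormal_sigma Log-normal sigma of plasmid-pool skew
#'   (0 = perfectly uniform pool).
#' @param expansion_lognormal_mu,expansion_lognormal_sigma Log-normal
#'   parameters of the clonal burst size of a GC founder (burst is rounded
#'   and floored at 1 cell). Defaults give a mean burst of ~8 cells.
#' @param n_replicates Parallel PCR amplifications per compartment.
#' @param reads_per_replicate Expected sequencing depth per replicate.
#' @param pcr_dispersion Gamma-Poisson shape of per-replicate amplification
#'   noise; small values give a PCR-jackpot regime, `Inf` gives pure
#'   Poisson sampling.
#' @param read_length Single-end read length (nt).
#' @param seq_error_rate Per-base substitution error probability.
#' @param seed Master seed; each stage derives its own sub-seed from it via
#'   [derive_seed()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_founder_cells = 4000L, baseline_gc_prob = 0.05,
                       pool_lognormal_sigma = 0.5,
                       expansion_lognormal_mu = log(8) - 0.8^2 / 2,
                       expansion_lognormal_sigma = 0.8,
                       n_replicates = 5L, reads_per_replicate = 100000L,
                       pcr_dispersion = 8, read_length = 150L,
                       seq_error_rate = 0.001, seed = 1L) {
  cfg <- list(
    n_founder_cells = as.integer(n_founder_cells),
    baseline_gc_prob = baseline_gc_prob,
    pool_lognormal_sigma = pool_lognormal_sigma,
    expansion_lognormal_mu = expansion_lognormal_mu,
    expansion_lognormal_sigma = expansion_lognormal_sigma,
    n_replicates = as.integer(n_replicates),
    reads_per_replicate = as.integer(reads_per_replicate),
    pcr_dispersion = pcr_dispersion,
    read_length = as.integer(read_length),
    seq_error_rate = seq_error_rate,
    seed = as.integer(seed)
  )
  probs <- c(cfg$baseline_gc_prob, cfg$seq_error_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    gcs_stop("gcs_config_error", "probabilities must lie in [0, 1]")
  }
  counts <- c(cfg$n_founder_cells, cfg$n_replicates, cfg$reads_per_replicate,
              cfg$read_length)
  if (anyNA(counts) || any(counts < 1L)) {
    gcs_stop("gcs_config_error", "counts and lengths must be positive")
  }
  if (!is.finite(cfg$pool_lognormal_sigma) || cfg$pool_lognormal_sigma < 0 ||
      cfg$expansion_lognormal_sigma < 0) {
    gcs_stop("gcs_config_error", "lognormal sigmas must be >= 0")
  }
  if (is.na(cfg$pcr_dispersion) || cfg$pcr_dispersion <= 0) {
    gcs_stop("gcs_config_error", "pcr_dispersion must be > 0 (Inf allowed)")
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Flat `key: value` YAML mirroring the [sim_config()] arguments; unknown
#' keys are rejected, missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config` object.
#' @export
sim_config_from_file <- function(path) {
  if (!file.exists(path)) {
    gcs_stop("gcs_config_error", "config file not found: %s", path)
  }
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0L) {
    gcs_stop("gcs_config_error", "unknown config key(s): %s",
             paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

#' Per-gene effect table on GC-compartment entry
#'
#' Each gene carries a nonnegative multiplier on the baseline probability
#' that a founder transduced with one of its constructs enters the GC
#' compartment: 1 is neutral, values < 1 deplete (knockdown of a positive
#' regulator of GC differentiation), values > 1 enrich (knockdown of a
#' negative regulator). The effective probability is clamped to [0, 1].
#'
#' @param genes Character vector of gene names (typically
#'   `unique(manifest$gene)`).
#' @param gc_effect Default multiplier for all genes.
#' @param planted Optional named numeric vector of per-gene overrides,
#'   e.g. `c(G001 = 0.05, G003 = 4)`.
#' @return A data frame with columns `gene`, `gc_effect`.
#' @export
effect_table <- function(genes, gc_effect = 1, planted = NULL) {
  eff <- data.frame(gene = unique(genes), gc_effect = gc_effect,
                    stringsAsFactors = FALSE)
  if (!is.null(planted)) {
    missing_genes <- setdiff(names(planted), eff$gene)
    if (length(missing_genes) > 0L) {
      gcs_stop("gcs_config_error", "planted gene(s) not in manifest: %s",
               paste(missing_genes, collapse = ", "))
    }
    eff$gc_effect[match(names(planted), eff$gene)] <- unname(planted)
  }
  if (any(!is.finite(eff$gc_effect)) || any(eff$gc_effect < 0)) {
    gcs_stop("gcs_config_error", "gc_effect must be finite and >= 0")
  }
  eff
}

#' @rdname effect_table
#' @param path TSV path with columns `gene`, `gc_effect`.
#' @export
read_effects <- function(path) {
  if (!file.exists(path)) {
    gcs_stop("gcs_config_error", "effects file not found: %s", path)
  }
  df <- read_tsv(path)
  if (!all(c("gene", "gc_effect") %in% names(df))) {
    gcs_stop("gcs_parse_error", "effects TSV needs columns gene, gc_effect")
  }
  effect_table(df$gene, planted = setNames(df$gc_effect, df$gene))
}

#' @rdname effect_table
#' @param effects An effect table data frame.
#' @export
write_effects <- function(effects, path) write_tsv(effects, path)

#' Simulate the plasmid-pool composition of a library
#'
#' Construct proportions are drawn from a normalized log-normal: real pools
#' are skewed by cloning and packaging biases but remain near-complete, with
#' the large majority of constructs above one tenth of the uniform share.
#' `sigma = 0` returns the exactly uniform pool.
#'
#' @param manifest An `shrna_manifest`.
#' @param sigma Log-normal sigma of the skew.
#' @param seed Integer seed.
#' @return Named numeric vector of proportions summing to 1.
#' @export
simulate_pool <- function(manifest, sigma = 0.5, seed = 1L) {
  n <- nrow(manifest)
  if (is.null(n) || n == 0L) gcs_stop("gcs_config_error", "manifest is empty")
  if (!is.finite(sigma) || sigma < 0) {
    gcs_stop("gcs_config_error", "sigma must be >= 0")
  }
  p <- if (sigma == 0) {
    rep(1 / n, n)
  } else {
    w <- withr::with_seed(seed, rlnorm(n, meanlog = 0, sdlog = sigma))
    w / sum(w)
  }
  setNames(p, manifest$construct_id)
}

#' Simulate founder transduction and GC/non-GC fate selection
#'
#' Founders are drawn multinomially from the pool (`n_founder_cells`
#' draws). Each founder independently enters the GC compartment with
#' probability `clamp(baseline_gc_prob * gc_effect[gene], 0, 1)`; GC
#' founders expand clonally by a rounded log-normal burst (at least one
#' cell), while non-GC founders contribute a single cell each. The realized
#' cell pools define each construct's ground-truth expected log2 GC/non-GC
#' fold change, computed from normalized percentages with the same
#' half-minimum pseudocount rule as [fold_change()].
#'
#' @param manifest An `shrna_manifest`.
#' @param pool Proportions from [simulate_pool()].
#' @param effects Effect table from [effect_table()].
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to a stage seed derived from
#'   `config$seed`).
#' @return A `GroundTruth` data frame: `construct_id`, `gene`,
#'   `founder_count`, `gc_cell_count`, `nongc_cell_count`,
#'   `expected_log2fc`.
#' @export
simulate_fates <- function(manifest, pool, effects, config = sim_config(),
                           seed = derive_seed(config$seed, "fates")) {
  n <- nrow(manifest)
  stopifnot(length(pool) == n)
  missing_genes <- setdiff(unique(manifest$gene), effects$gene)
  if (length(missing_genes) > 0L) {
    gcs_stop("gcs_config_error", "no gc_effect for gene(s): %s",
             paste(missing_genes, collapse = ", "))
  }
  eff <- effects$gc_effect[match(manifest$gene, effects$gene)]
  p_gc <- pmin(1, pmax(0, config$baseline_gc_prob * eff))
  withr::with_seed(seed, {
    founders <- as.integer(rmultinom(1L, config$n_founder_cells, pool))
    gc_founders <- rbinom(n, founders, p_gc)
    gc_cells <- integer(n)
    total_gc <- sum(gc_founders)
    if (total_gc > 0L) {
      burst <- pmax(1, round(rlnorm(total_gc, config$expansion_lognormal_mu,
                                    config$expansion_lognormal_sigma)))
      by_construct <- rowsum(burst, rep.int(seq_len(n), gc_founders))
      gc_cells[as.integer(rownames(by_construct))] <- as.integer(by_construct)
    }
  })
  nongc_cells <- founders - gc_founders
  truth <- data.frame(
    construct_id = manifest$construct_id, gene = manifest$gene,
    founder_count = founders, gc_cell_count = gc_cells,
    nongc_cell_count = nongc_cells, stringsAsFactors = FALSE
  )
  pct_gc <- if (sum(gc_cells) > 0) 100 * gc_cells / sum(gc_cells) else rep(0, n)
  pct_ngc <- if (sum(nongc_cells) > 0) 100 * nongc_cells / sum(nongc_cells) else rep(0, n)
  delta <- half_min_positive(c(pct_gc, pct_ngc))
  truth$expected_log2fc <- if (delta > 0) {
    log2((pct_gc + delta) / (pct_ngc + delta))
  } else {
    rep(NA_real_, n)
  }
  truth
}

#' Simulate parallel PCR replicate read counts from a cell pool
#'
#' Each of the `n_replicates` parallel amplifications draws an independent
#' Gamma-Poisson (negative binomial) count per construct with mean
#' proportional to its cell count and expected total depth
#' `reads_per_replicate`. The Gamma mixing (shape `pcr_dispersion`) models
#' early-cycle amplification jackpots, the heavy-tailed replicate noise
#' that motivates taking the median over replicates downstream.
#'
#' @param cell_pool Nonnegative per-construct cell counts.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Integer matrix, constructs x replicates (`rep1` ... `repN`).
#' @export
simulate_replicates <- function(cell_pool, config = sim_config(),
                                seed = derive_seed(config$seed, "replicates")) {
  if (any(cell_pool < 0) || anyNA(cell_pool)) {
    gcs_stop("gcs_config_error", "cell_pool must be nonnegative")
  }
  n <- length(cell_pool)
  reps <- config$n_replicates
  out <- matrix(0L, n, reps,
                dimnames = list(names(cell_pool), paste0("rep", seq_len(reps))))
  if (sum(cell_pool) == 0) {
    gcs_warn("gcs_empty_compartment",
             "cell pool is empty; returning zero-count replicates")
    return(out)
  }
  mu <- config$reads_per_replicate * cell_pool / sum(cell_pool)
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      out[, r] <- as.integer(if (is.infinite(config$pcr_dispersion)) {
        rpois(n, mu)
      } else {
        rnbinom(n, size = config$pcr_dispersion, mu = mu)
      })
    }
  })
  out
}
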