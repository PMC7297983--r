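#' Scarcity-filter threshold
#'
#' The abundance cut-off below which a construct is treated as lost from a
#' compartment: one `scarcity_factor`-th of the uniform expected abundance,
#' `100 / (library_size * scarcity_factor)` percent. For a 400-construct
#' library and the conventional factor 10 this is 0.025%.
#'
#' @param library_size Number of constructs in the library.
#' @param scarcity_factor How many times below the uniform share a median
#'   abundance may fall before the construct counts as lost.
#' @return Threshold in percent.
#' @export
#' @examples
#' filter_threshold(400, 10) # 0.025
filter_threshold <- function(library_size, scarcity_factor = 10) {
  if (!is.numeric(library_size) || length(library_size) != 1L ||
      !is.finite(library_size) || library_size < 1) {
    gcs_stop("gcs_config_error", "library_size must be >= 1")
  }
  if (!is.numeric(scarcity_factor) || length(scarcity_factor) != 1L ||
      !is.finite(scarcity_factor) || scarcity_factor <= 0) {
    gcs_stop("gcs_config_error", "scarcity_factor must be > 0")
  }
  100 / (library_size * scarcity_factor)
}

#' Filter policy for consistent construct recovery
#'
#' A construct passes the filter in one screen when its median abundance
#' strictly exceeds the scarcity threshold in either the GC or the non-GC
#' compartment; it is consistently recovered when it passes in every
#' screen. Strict inequality implements "exceeding" the threshold.
#'
#' @inheritParams filter_threshold
#' @return A `filter_policy` object with the computed `threshold` (percent),
#'   `compartments_rule = "either"` and `screens_rule = "all"`.
#' @export
filter_policy <- function(library_size, scarcity_factor = 10) {
  structure(
    list(library_size = as.integer(library_size),
         scarcity_factor = scarcity_factor,
         threshold = filter_threshold(library_size, scarcity_factor),
         compartments_rule = "either", screens_rule = "all"),
    class = "filter_policy"
  )
}

# Internal: check that all screens cover the same constructs in the same
# order and return the shared id/gene columns.
check_screens <- function(screens) {
  if (length(screens) == 0L) {
    gcs_stop("gcs_config_error", "no screens given")
  }
  ids <- screens[[1L]]$gc$construct_id
  for (s in seq_along(screens)) {
    for (cp in c("gc", "nongc")) {
      tab <- screens[[s]][[cp]]
      if (is.null(tab) || !inherits(tab, "data.frame") ||
          !identical(tab$construct_id, ids)) {
        gcs_stop("gcs_config_error",
                 "screen %d/%s does not cover the same constructs in the same order",
                 s, cp)
      }
    }
  }
  list(construct_id = ids, gene = screens[[1L]]$gc$gene)
}

#' Apply the scarcity filter across screens
#'
#' @param screens A list with one element per screen, each a list with
#'   `gc` and `nongc` [median_abundance()] tables over the same manifest.
#' @param policy A [filter_policy()].
#' @return Data frame: `construct_id`, `gene`, `pass_screen<i>` logicals,
#'   and `consistent` (passed in every screen).
#' @export
#' @examples
#' # a construct at exactly the threshold in both compartments fails
apply_filter <- function(screens, policy) {
  shared <- check_screens(screens)
  out <- data.frame(construct_id = shared$construct_id, gene = shared$gene,
                    stringsAsFactors = FALSE)
  thr <- policy$threshold
  for (s in seq_along(screens)) {
    out[[paste0("pass_screen", s)]] <-
      screens[[s]]$gc$median_pct > thr | screens[[s]]$nongc$median_pct > thr
  }
  pass_cols <- grep("^pass_screen", names(out))
  out$consistent <- rowSums(as.matrix(out[pass_cols])) == length(screens)
  out
}

#' GC/non-GC fold change of median abundances
#'
#' `FC = (median_gc + delta) / (median_nongc + delta)` with pseudocount
#' `delta`; by default `delta` is half the smallest nonzero median in the
#' pair of compartment vectors, which keeps constructs entirely absent
#' from one compartment (the strongest depletion signals) finite and
#' rankable instead of collapsing them to minus infinity.
#'
#' @param median_gc,median_nongc Nonnegative median percentage vectors.
#' @param pseudocount Pseudocount `delta`; `NULL` for the half-minimum
#'   rule.
#' @return A list with vectors `fold_change` and `log2_fc`.
#' @export
#' @examples
#' fold_change(0.05, 0.20, pseudocount = 1e-9)$log2_fc # -2
fold_change <- function(median_gc, median_nongc, pseudocount = NULL) {
  if (any(median_gc < 0, na.rm = TRUE) || any(median_nongc < 0, na.rm = TRUE)) {
    gcs_stop("gcs_config_error", "median abundances must be >= 0")
  }
  delta <- pseudocount %||% half_min_positive(c(median_gc, median_nongc))
  if (delta == 0 && any(median_gc == 0 & median_nongc == 0)) {
    gcs_stop("gcs_undefined_ratio",
             "both medians are 0 and the pseudocount is 0")
  }
  fc <- (median_gc + delta) / (median_nongc + delta)
  list(fold_change = fc, log2_fc = log2(fc))
}

#' Consistency of a construct's fold-change estimates
#'
#' The sample standard deviation (n-1 denominator) of a construct's log2
#' fold-change estimates, and its reciprocal capped at `cap`. A large
#' reciprocal marks a consistent (reproducible) effect; the cap keeps
#' identical estimates (SD 0) from producing infinities.
#'
#' @param estimates Numeric vector of log2 fold-change estimates (>= 2).
#' @param cap Upper bound on the reciprocal.
#' @return A list with `fc_sd` and `inv_sd`.
#' @export
#' @examples
#' consistency(c(-2, -1)) # sd 0.707, reciprocal 1.414
consistency <- function(estimates, cap = 100) {
  estimates <- estimates[is.finite(estimates)]
  if (length(estimates) < 2L) {
    gcs_stop("gcs_insufficient_replication",
             "need >= 2 finite estimates, got %d", length(estimates))
  }
  s <- sd(estimates)
  list(fc_sd = s, inv_sd = if (s == 0) cap else min(1 / s, cap))
}

#' Score constructs across screens
#'
#' Computes, per construct: filter status per screen and consistent
#' recovery; log2 GC/non-GC fold-change estimates; their mean (`log2_fc`,
#' with `fold_change = 2^log2_fc`); their standard deviation and capped
#' reciprocal; and a hit category. Estimates are formed per screen either
#' from replicate pairs (`"replicate_pairs"`, the default: replicate i of
#' the GC sample against replicate i of the non-GC sample, giving
#' `n_replicates x n_screens` estimates) or from the per-screen medians
#' (`"screen_medians"`, one estimate per screen, needing >= 2 screens).
#' Each estimate uses the [fold_change()] pseudocount rule within its own
#' pair of abundance vectors.
#'
#' Categories: `excluded` for constructs failing consistent recovery;
#' otherwise `positive_regulator_candidate` when `log2_fc <= -fc_cut`
#' (knockdown depleted from GC), `negative_regulator_candidate` when
#' `log2_fc >= fc_cut`, both additionally requiring `inv_sd` at or above
#' the `consistency_quantile` of the consistent set; else `neutral`.
#'
#' @inheritParams apply_filter
#' @param pseudocount Fixed pseudocount, or `NULL` for the half-minimum
#'   rule per estimate pair.
#' @param consistency_mode `"replicate_pairs"` or `"screen_medians"`.
#' @param inv_sd_cap Cap for the reciprocal standard deviation.
#' @param fc_cut Absolute log2 fold-change cut for hit categories.
#' @param consistency_quantile Quantile of `inv_sd` (over consistently
#'   recovered constructs) that hits must reach.
#' @return A `screen_scores` data frame.
#' @export
score_screens <- function(screens, policy, pseudocount = NULL,
                          consistency_mode = c("replicate_pairs",
                                               "screen_medians"),
                          inv_sd_cap = 100, fc_cut = 2,
                          consistency_quantile = 0.5) {
  consistency_mode <- match.arg(consistency_mode)
  shared <- check_screens(screens)
  n <- length(shared$construct_id)
  filt <- apply_filter(screens, policy)

  est <- NULL # columns = estimates, rows = constructs
  for (s in seq_along(screens)) {
    gc_tab <- screens[[s]]$gc
    ngc_tab <- screens[[s]]$nongc
    if (consistency_mode == "replicate_pairs") {
      rep_cols <- grep("^rep[0-9]+_pct$", names(gc_tab), value = TRUE)
      for (rc in rep_cols) {
        g <- gc_tab[[rc]]
        ng <- ngc_tab[[rc]]
        if (all(is.na(g)) || all(is.na(ng))) next # dead replicate pair
        est <- cbind(est, fold_change(g, ng, pseudocount)$log2_fc)
      }
    } else {
      est <- cbind(est, fold_change(gc_tab$median_pct, ngc_tab$median_pct,
                                    pseudocount)$log2_fc)
    }
  }
  if (is.null(est) || ncol(est) < 2L) {
    gcs_stop("gcs_insufficient_replication",
             "scoring needs >= 2 fold-change estimates per construct (mode %s)",
             consistency_mode)
  }
  log2_fc <- rowMeans(est)
  fc_sd <- apply(est, 1L, sd)
  inv_sd <- ifelse(fc_sd == 0, inv_sd_cap, pmin(1 / fc_sd, inv_sd_cap))

  median_gc <- rowMeans(vapply(screens, function(s) s$gc$median_pct,
                               numeric(n)))
  median_nongc <- rowMeans(vapply(screens, function(s) s$nongc$median_pct,
                                  numeric(n)))

  scores <- data.frame(construct_id = shared$construct_id,
                       gene = shared$gene,
                       median_gc_pct = median_gc,
                       median_nongc_pct = median_nongc,
                       stringsAsFactors = FALSE)
  for (col in grep("^pass_screen", names(filt), value = TRUE)) {
    scores[[col]] <- filt[[col]]
  }
  scores$consistent <- filt$consistent
  scores$fold_change <- 2^log2_fc
  scores$log2_fc <- log2_fc
  scores$fc_sd <- fc_sd
  scores$inv_sd <- inv_sd

  qv <- if (any(scores$consistent)) {
    quantile(inv_sd[scores$consistent], consistency_quantile, names = FALSE)
  } else {
    NA_real_
  }
  category <- rep("neutral", n)
  category[scores$consistent & log2_fc <= -fc_cut & inv_sd >= qv] <-
    "positive_regulator_candidate"
  category[scores$consistent & log2_fc >= fc_cut & inv_sd >= qv] <-
    "negative_regulator_candidate"
  category[!scores$consistent] <- "excluded"
  scores$category <- category

  attr(scores, "policy") <- policy
  attr(scores, "consistency_mode") <- consistency_mode
  attr(scores, "fc_cut") <- fc_cut
  attr(scores, "consistency_quantile") <- consistency_quantile
  attr(scores, "inv_sd_threshold") <- qv
  attr(scores, "n_estimates") <- ncol(est)
  class(scores) <- c("screen_scores", "data.frame")
  scores
}

#' Rank candidate regulators from construct scores
#'
#' Depleted candidates are consistently recovered constructs with
#' `log2_fc <= -fc_cut` (inclusive) and `inv_sd` at or above the requested
#' quantile of the consistent set, sorted ascending by `log2_fc`; enriched
#' candidates analogously with `log2_fc >= fc_cut`, sorted descending.
#' Ties break by `inv_sd` (descending) then `construct_id`, so the
#' ordering is deterministic.
#'
#' @param scores A `screen_scores` data frame.
#' @param fc_cut,consistency_quantile See [score_screens()].
#' @return A list with data frames `depleted` and `enriched` and the
#'   applied `inv_sd_threshold`.
#' @export
rank_hits <- function(scores, fc_cut = 2, consistency_quantile = 0.5) {
  cons <- scores[scores$consistent, , drop = FALSE]
  if (nrow(cons) == 0L) {
    gcs_warn("gcs_empty_consistent_set",
             "no construct is consistently recovered; returning empty lists")
    return(list(depleted = cons, enriched = cons,
                inv_sd_threshold = NA_real_))
  }
  qv <- quantile(cons$inv_sd, consistency_quantile, names = FALSE)
  dep <- cons[cons$log2_fc <= -fc_cut & cons$inv_sd >= qv, , drop = FALSE]
  dep <- dep[order(dep$log2_fc, -dep$inv_sd, dep$construct_id), , drop = FALSE]
  enr <- cons[cons$log2_fc >= fc_cut & cons$inv_sd >= qv, , drop = FALSE]
  enr <- enr[order(-enr$log2_fc, -enr$inv_sd, enr$construct_id), , drop = FALSE]
  rownames(dep) <- rownames(enr) <- NULL
  list(depleted = dep, enriched = enr, inv_sd_threshold = qv)
}

#' Per-gene construct recovery and effect summary
#'
#' Partitions each gene's constructs into recovered in all screens,
#' recovered in at least one but not all, and lost in all screens, and
#' summarizes the gene's effect as the median `log2_fc` over its
#' all-screen-recovered constructs (`NA` when none). Rows are ordered by
#' that median, most depleted first (`NA` last), with ties broken by the
#' number of recovered constructs (descending) then gene name.
#'
#' @param scores A `screen_scores` data frame from >= 2 screens.
#' @return A `gene_summary` data frame: `gene`, `n_constructs`,
#'   `n_recovered_all_screens`, `n_recovered_one_screen`,
#'   `n_lost_all_screens`, `median_log2fc`.
#' @export
gene_summary <- function(scores) {
  pass_cols <- grep("^pass_screen", names(scores), value = TRUE)
  if (length(pass_cols) < 2L) {
    gcs_stop("gcs_config_error", "gene_summary needs >= 2 screens")
  }
  n_pass <- rowSums(as.matrix(scores[pass_cols]))
  n_screens <- length(pass_cols)
  by_gene <- function(v, f) as.vector(tapply(v, scores$gene, f))
  genes <- sort(unique(scores$gene))
  all_rec <- n_pass == n_screens
  med <- rep(NA_real_, length(genes))
  for (i in seq_along(genes)) {
    sel <- scores$gene == genes[i] & all_rec
    if (any(sel)) med[i] <- median(scores$log2_fc[sel])
  }
  out <- data.frame(
    gene = genes,
    n_constructs = as.vector(table(factor(scores$gene, levels = genes))),
    n_recovered_all_screens =
      as.vector(rowsum(as.integer(all_rec), scores$gene)[genes, ]),
    n_recovered_one_screen =
      as.vector(rowsum(as.integer(n_pass > 0L & n_pass < n_screens),
                       scores$gene)[genes, ]),
    n_lost_all_screens =
      as.vector(rowsum(as.integer(n_pass == 0L), scores$gene)[genes, ]),
    median_log2fc = med,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$median_log2fc, -out$n_recovered_all_screens, out$gene,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_summary", "data.frame")
  out
}

#' Relative expression fold difference from qPCR cycle thresholds
#'
#' The 2^-ddCt statistic: target expression normalized to a reference gene
#' within each sample, then the test sample expressed relative to the
#' control sample.
#' `ddCt = (Ct_target_test - Ct_reference_test) -
#' (Ct_target_control - Ct_reference_control)`.
#'
#' @param ct_target_test,ct_reference_test Ct values in the test sample.
#' @param ct_target_control,ct_reference_control Ct values in the control
#'   sample.
#' @return Fold difference `2^-ddCt` (vectorized).
#' @export
#' @examples
#' ddct_fold(20, 15, 24, 15) # ddCt = -4 -> 16
ddct_fold <- function(ct_target_test, ct_reference_test,
                      ct_target_control, ct_reference_control) {
  ct <- cbind(ct_target_test, ct_reference_test,
              ct_target_control, ct_reference_control)
  if (!is.numeric(ct) || any(!is.finite(ct))) {
    gcs_stop("gcs_input_error", "all Ct values must be finite numbers")
  }
  ddct <- (ct[, 1L] - ct[, 2L]) - (ct[, 3L] - ct[, 4L])
  unname(2^(-ddct))
}
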