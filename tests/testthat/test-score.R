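test_that("scarcity threshold formula and validation", {
  expect_identical(filter_threshold(400, 10), 0.025)
  expect_identical(filter_threshold(200, 10), 0.05)
  expect_identical(filter_threshold(1, 1), 100)
  expect_error(filter_threshold(0, 10), class = "gcs_config_error")
  expect_error(filter_threshold(400, 0), class = "gcs_config_error")
  pol <- filter_policy(400)
  expect_equal(pol$threshold, 0.025)
  expect_identical(pol$compartments_rule, "either")
  expect_identical(pol$screens_rule, "all")
})

fake_abundance <- function(gc, nongc, ids = names(gc)) {
  mk <- function(v) data.frame(construct_id = ids, gene = ids,
                               rep1_pct = v, rep2_pct = v, median_pct = v,
                               stringsAsFactors = FALSE)
  list(gc = mk(gc), nongc = mk(nongc))
}

test_that("scarcity filter uses strict exceedance in either compartment", {
  s1 <- fake_abundance(gc = c(A = 0.5, B = 0.0, C = 0.01, D = 0.5),
                       nongc = c(A = 0.0, B = 0.5, C = 0.01, D = 0.5))
  pol <- filter_policy(400) # threshold 0.025
  f <- apply_filter(list(s1), pol)
  expect_identical(f$construct_id[f$pass_screen1], c("A", "B", "D"))

  # exactly at the threshold in both compartments: fails ("exceeding")
  at <- fake_abundance(gc = c(E = 0.025), nongc = c(E = 0.025))
  expect_false(apply_filter(list(at), pol)$pass_screen1)

  # consistent recovery requires passing every screen
  s2 <- fake_abundance(gc = c(A = 0.0, B = 0.5, C = 0.5, D = 0.5),
                       nongc = c(A = 0.0, B = 0.5, C = 0.01, D = 0.5))
  f2 <- apply_filter(list(s1, s2), pol)
  # A drops out in screen 2, C is below threshold in screen 1
  expect_identical(f2$construct_id[f2$consistent], c("B", "D"))
  expect_false(f2$consistent[f2$construct_id == "A"])

  # screens must cover the same constructs
  s3 <- fake_abundance(gc = c(X = 1), nongc = c(X = 1))
  expect_error(apply_filter(list(s1, s3), pol), class = "gcs_config_error")
})

test_that("fold change follows the pseudocount rule and known arithmetic", {
  eq <- fold_change(0.3, 0.3)
  expect_equal(eq$fold_change, 1)
  expect_equal(eq$log2_fc, 0)

  fc <- fold_change(0.05, 0.20, pseudocount = 1e-12)
  expect_equal(fc$fold_change, 0.25, tolerance = 1e-9)
  expect_equal(fc$log2_fc, -2, tolerance = 1e-9)

  # a GC-absent construct stays finite and strongly depleted
  fc0 <- fold_change(0, 0.4, pseudocount = 0.01)
  expect_equal(fc0$fold_change, 0.01 / 0.41)
  expect_equal(fc0$log2_fc, log2(0.01 / 0.41))

  # default delta: half the smallest nonzero median in the pair
  fcd <- fold_change(c(0, 0.2), c(0.4, 0.2))
  expect_equal(fcd$fold_change[1], 0.1 / 0.5)

  expect_error(fold_change(0, 0, pseudocount = 0),
               class = "gcs_undefined_ratio")
  expect_error(fold_change(-1, 1), class = "gcs_config_error")
})

test_that("swapping compartments negates log2 fold change exactly", {
  withr::with_seed(70, {
    gc <- runif(50, 0, 2) * rbinom(50, 1, 0.8)
    ngc <- runif(50, 0, 2) * rbinom(50, 1, 0.8)
  })
  delta <- 0.013
  fwd <- fold_change(gc, ngc, pseudocount = delta)$log2_fc
  rev <- fold_change(ngc, gc, pseudocount = delta)$log2_fc
  expect_equal(fwd, -rev, tolerance = 1e-12)
})

test_that("consistency summarizes estimate spread with a capped reciprocal", {
  cs <- consistency(c(-2, -1))
  expect_equal(cs$fc_sd, sd(c(-2, -1)))
  expect_equal(cs$inv_sd, 1 / sd(c(-2, -1)))
  expect_equal(cs$fc_sd, 0.7071068, tolerance = 1e-6)
  expect_equal(consistency(rep(-1.5, 4))$inv_sd, 100) # identical -> cap
  perm <- withr::with_seed(71, sample(c(-2, 0.5, -1, 3)))
  expect_identical(consistency(perm), consistency(c(-2, 0.5, -1, 3)))
  expect_error(consistency(-2), class = "gcs_insufficient_replication")
})

test_that("rank_hits applies inclusive cuts and deterministic tie-breaks", {
  scores <- data.frame(
    construct_id = c("a", "b", "c", "d", "e", "f"),
    gene = "g",
    log2_fc = c(-3, -2, -1, 2, 2.5, -4),
    inv_sd = c(5, 5, 5, 5, 5, 0.1),
    consistent = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  hits <- rank_hits(scores, fc_cut = 2, consistency_quantile = 0)
  # boundary value -2 and +2 included; excluded construct f never appears
  expect_identical(hits$depleted$construct_id, c("a", "b"))
  expect_identical(hits$enriched$construct_id, c("e", "d"))

  # ties in log2_fc break by inv_sd then id
  tie <- data.frame(
    construct_id = c("t2", "t1", "t3"), gene = "g",
    log2_fc = c(-2.5, -2.5, -2.5), inv_sd = c(4, 9, 4),
    consistent = TRUE, stringsAsFactors = FALSE
  )
  expect_identical(rank_hits(tie, 2, 0)$depleted$construct_id,
                   c("t1", "t2", "t3"))

  none <- scores[scores$consistent == FALSE, ]
  expect_warning(empty <- rank_hits(none), class = "gcs_empty_consistent_set")
  expect_equal(nrow(empty$depleted), 0)
})

test_that("gene_summary partitions construct recovery and orders genes", {
  scores <- data.frame(
    construct_id = paste0("gA-", 1:5),
    gene = "gA",
    log2_fc = c(-3, 0, 1, 2, -1),
    inv_sd = 1,
    pass_screen1 = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    pass_screen2 = c(TRUE, FALSE, TRUE, TRUE, FALSE),
    consistent = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  scores2 <- data.frame(
    construct_id = paste0("gB-", 1:3),
    gene = "gB",
    log2_fc = c(-5, -5, -5),
    inv_sd = 1,
    pass_screen1 = TRUE, pass_screen2 = TRUE, consistent = TRUE,
    stringsAsFactors = FALSE
  )
  gs <- gene_summary(rbind(scores, scores2))
  a <- gs[gs$gene == "gA", ]
  # 2 recovered in both screens, 2 in exactly one, 1 in none
  expect_equal(a$n_recovered_all_screens, 2)
  expect_equal(a$n_recovered_one_screen, 2)
  expect_equal(a$n_lost_all_screens, 1)
  expect_equal(a$n_constructs, 5)
  expect_equal(a$n_recovered_all_screens + a$n_recovered_one_screen +
                 a$n_lost_all_screens, a$n_constructs)
  expect_equal(a$median_log2fc, median(c(-3, 1)))
  b <- gs[gs$gene == "gB", ]
  expect_equal(b$n_recovered_all_screens, 3)
  expect_equal(b$n_recovered_one_screen + b$n_lost_all_screens, 0)
  # most depleted gene first
  expect_identical(gs$gene[1], "gB")
  expect_error(gene_summary(scores[, setdiff(names(scores), "pass_screen2")]),
               class = "gcs_config_error")
})

test_that("scores are invariant to rescaling a replicate's counts", {
  m <- small_manifest(6, 2, seed = 80)
  cfg <- sim_config(n_replicates = 3, reads_per_replicate = 5000,
                    n_founder_cells = 1000, baseline_gc_prob = 0.3, seed = 81)
  base <- simulate_and_score(m, effect_table(m$gene), cfg, seed = 82)

  pool <- simulate_pool(m, cfg$pool_lognormal_sigma, seed = 82)
  mk <- function(scale) {
    lapply(1:2, function(s) {
      sseed <- derive_seed(82, paste0("s", s))
      truth <- simulate_fates(m, pool, effect_table(m$gene), cfg,
                              seed = derive_seed(sseed, "fates"))
      gc <- simulate_replicates(truth$gc_cell_count, cfg,
                                seed = derive_seed(sseed, "gc"))
      ngc <- simulate_replicates(truth$nongc_cell_count, cfg,
                                 seed = derive_seed(sseed, "nongc"))
      gc[, 2] <- gc[, 2] * scale # rescale one replicate uniformly
      ngc[, 1] <- ngc[, 1] * scale
      list(gc = gc, nongc = ngc)
    })
  }
  s1 <- score_counts(mk(1L), m)
  s7 <- score_counts(mk(7L), m)
  expect_equal(s1$log2_fc, s7$log2_fc, tolerance = 1e-12)
  expect_equal(s1$median_gc_pct, s7$median_gc_pct, tolerance = 1e-12)
  expect_identical(s1$consistent, s7$consistent)
  expect_equal(base$log2_fc, s1$log2_fc, tolerance = 1e-12)
})

test_that("mean log2 fold change is nondecreasing in the planted effect", {
  m <- small_manifest(10, 3, seed = 90)
  cfg <- sim_config(reads_per_replicate = 20000, n_replicates = 3, seed = 0)
  effects_grid <- c(0.05, 0.25, 1, 4)
  mean_fc <- sapply(effects_grid, function(e) {
    vals <- sapply(1:4, function(r) {
      eff <- effect_table(m$gene, planted = c(G005 = e))
      sc <- simulate_and_score(m, eff, cfg, seed = 9000 + r)
      mean(sc$log2_fc[sc$gene == "G005"])
    })
    mean(vals)
  })
  expect_true(all(diff(mean_fc) > 0))
})

test_that("pipeline introduces no compartment bias under a well-covered null", {
  # symmetric design (GC entry 0.5, no expansion noise) isolates pipeline
  # bias from bottleneck dropout; the mean log2 fold change must vanish
  m <- small_manifest(20, 3, seed = 91)
  cfg <- sim_config(n_founder_cells = 20000, baseline_gc_prob = 0.5,
                    expansion_lognormal_mu = 0, expansion_lognormal_sigma = 0,
                    reads_per_replicate = 30000, n_replicates = 3, seed = 0)
  means <- sapply(1:2, function(r) {
    sc <- simulate_and_score(m, effect_table(m$gene), cfg, seed = 9100 + r)
    mean(sc$log2_fc)
  })
  expect_lt(abs(mean(means)), 0.1)
})

test_that("screen_medians consistency mode needs and uses per-screen medians", {
  m <- small_manifest(5, 2, seed = 92)
  cfg <- sim_config(n_replicates = 3, reads_per_replicate = 5000,
                    n_founder_cells = 2000, baseline_gc_prob = 0.3, seed = 0)
  sc <- simulate_and_score(m, effect_table(m$gene), cfg, seed = 93,
                           consistency_mode = "screen_medians")
  expect_equal(attr(sc, "n_estimates"), 2)
  expect_true(all(is.finite(sc$log2_fc)))
})

test_that("2^-ddCt fold difference matches the closed form", {
  expect_equal(ddct_fold(20, 20, 20, 20), 1)
  expect_equal(ddct_fold(18, 15, 16, 15), 0.25) # ddCt = +2
  expect_equal(ddct_fold(20, 15, 24, 15), 16)   # ddCt = -4
  expect_equal(ddct_fold(c(20, 20), c(15, 20), c(24, 20), c(15, 20)),
               c(16, 1))
  expect_error(ddct_fold(NA, 1, 1, 1), class = "gcs_input_error")
  expect_error(ddct_fold(Inf, 1, 1, 1), class = "gcs_input_error")
})
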