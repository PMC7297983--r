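test_that("simulate_pool is a normalized, seeded, near-complete pool", {
  m <- generate_library(80, 5, seed = 2) # 400 constructs
  uniform <- simulate_pool(m, sigma = 0, seed = 1)
  expect_true(all(uniform == 1 / 400))
  for (sigma in c(0.2, 0.5, 1.5)) {
    p <- simulate_pool(m, sigma = sigma, seed = 3)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
  expect_identical(simulate_pool(m, 0.5, seed = 9),
                   simulate_pool(m, 0.5, seed = 9))
  # at the default skew, >= 90% of constructs exceed the 0.025% scarcity cut
  p <- simulate_pool(m, sigma = 0.5, seed = 4)
  expect_gte(mean(100 * p > filter_threshold(400, 10)), 0.90)
  expect_error(simulate_pool(m, sigma = -1), class = "gcs_config_error")
})

test_that("simulate_fates conserves founders and respects effects", {
  m <- small_manifest(10, 3)
  pool <- simulate_pool(m, 0.5, seed = 5)
  eff <- effect_table(m$gene, planted = c(G002 = 0))
  cfg <- sim_config(seed = 6)
  truth <- simulate_fates(m, pool, eff, cfg)
  expect_equal(sum(truth$founder_count), cfg$n_founder_cells)
  expect_true(all(truth$nongc_cell_count <= truth$founder_count))
  expect_true(all(truth$nongc_cell_count >= 0))
  # forced extinction: gc_effect 0 removes the gene from the GC compartment
  expect_true(all(truth$gc_cell_count[truth$gene == "G002"] == 0))
  # determinism
  expect_identical(truth, simulate_fates(m, pool, eff, cfg))
  # every gene needs an effect entry
  expect_error(simulate_fates(m, pool, eff[-1, ], cfg),
               class = "gcs_config_error")
})

test_that("neutral effects give equal expected GC/non-GC ratios across constructs", {
  m <- small_manifest(8, 3, seed = 21)
  eff <- effect_table(m$gene)
  cfg <- sim_config(baseline_gc_prob = 0.2, expansion_lognormal_mu = log(8),
                    expansion_lognormal_sigma = 0)
  pool <- simulate_pool(m, 0.3, seed = 22)
  gc_sum <- ngc_sum <- numeric(nrow(m))
  for (r in 1:100) {
    truth <- simulate_fates(m, pool, eff, cfg, seed = 5000 + r)
    gc_sum <- gc_sum + truth$gc_cell_count
    ngc_sum <- ngc_sum + truth$nongc_cell_count
  }
  ratio <- gc_sum / ngc_sum
  expect_true(all(abs(log2(ratio / median(ratio))) < 0.8))
})

test_that("simulate_replicates draws overdispersed, reproducible counts", {
  m <- small_manifest(5, 2)
  cells <- setNames(rep(100L, nrow(m)), m$construct_id)
  cfg <- sim_config(n_replicates = 5, reads_per_replicate = 50000, seed = 8)
  counts <- simulate_replicates(cells, cfg)
  expect_true(is.integer(counts))
  expect_true(all(counts >= 0))
  expect_identical(dim(counts), c(10L, 5L))
  expect_identical(counts, simulate_replicates(cells, cfg))

  # no-overdispersion limit with a single positive construct: every read
  # belongs to that construct
  lone <- setNames(c(50L, rep(0L, 9)), m$construct_id)
  cfg_inf <- sim_config(pcr_dispersion = Inf, seed = 9)
  cnt <- simulate_replicates(lone, cfg_inf)
  expect_true(all(cnt[-1, ] == 0))
  expect_true(all(cnt[1, ] > 0))

  # jackpot regime: among-replicate CV far exceeds the Poisson expectation
  cfg_jack <- sim_config(n_replicates = 30, reads_per_replicate = 20000,
                         pcr_dispersion = 0.3, seed = 10)
  jack <- simulate_replicates(cells, cfg_jack)
  pct <- 100 * t(t(jack) / colSums(jack))
  cv <- apply(pct, 1, sd) / rowMeans(pct)
  mu <- 20000 / 10
  poisson_cv <- 1 / sqrt(mu)
  expect_gt(median(cv), 3 * poisson_cv)

  # empty compartment warns and returns zeros
  expect_warning(
    zero <- simulate_replicates(setNames(rep(0L, 10), m$construct_id), cfg),
    class = "gcs_empty_compartment"
  )
  expect_true(all(zero == 0))
})

test_that("emitted FASTQ closes the loop with the counter at zero error rate", {
  m <- reference_manifest()
  cfg <- sim_config(seq_error_rate = 0, n_replicates = 3,
                    reads_per_replicate = 300, seed = 11)
  counts <- matrix(c(3L, 2L, 0L, 5L,
                     0L, 0L, 0L, 0L,
                     10L, 1L, 7L, 2L), nrow = 4)
  out <- tempfile()
  paths <- emit_fastq(counts, m, cfg, out, screen = "s", compartment = "gc",
                      compress = FALSE)
  expect_length(paths, 3)
  got <- count_reads(paths, m)
  expect_equal(got$counts, counts, ignore_attr = TRUE)
  expect_true(all(got$totals$unmatched == 0))
  expect_true(all(got$totals$ambiguous == 0))

  # replicate 2 has zero reads: a valid empty FASTQ
  expect_identical(load_fastq(paths[2]), character(0))
  empty <- emit_fastq(matrix(0L, 4, 1), m, cfg, out, screen = "z",
                      compartment = "gc", compress = FALSE)
  expect_identical(load_fastq(empty[1]), character(0))
})

test_that("counting is strand symmetric", {
  m <- reference_manifest()
  cfg <- sim_config(seq_error_rate = 0, n_replicates = 1,
                    reads_per_replicate = 100, seed = 12)
  paths <- emit_fastq(matrix(c(4L, 3L, 2L, 1L), 4, 1), m, cfg, tempfile(),
                      screen = "s", compartment = "gc", compress = FALSE)
  reads <- load_fastq(paths[1])
  flipped <- write_fastq_fixture(reverse_complement(reads))
  expect_identical(count_reads(paths[1], m)$counts[, 1],
                   count_reads(flipped, m)$counts[, 1])
})

test_that("FASTQ emission is deterministic and rejects short reads", {
  m <- reference_manifest()
  cfg <- sim_config(n_replicates = 1, seed = 13)
  cnt <- matrix(c(5L, 5L, 5L, 5L), 4, 1)
  p1 <- emit_fastq(cnt, m, cfg, tempfile(), compress = FALSE)
  p2 <- emit_fastq(cnt, m, cfg, tempfile(), compress = FALSE)
  expect_identical(readLines(p1[1]), readLines(p2[1]))

  cfg_short <- sim_config(read_length = 60)
  expect_error(emit_fastq(cnt, m, cfg_short, tempfile()),
               class = "gcs_config_error")
})

test_that("simulate_screen writes gzipped FASTQ, truth and run manifest", {
  m <- small_manifest(4, 2, seed = 30)
  eff <- effect_table(m$gene)
  cfg <- sim_config(n_replicates = 2, reads_per_replicate = 2000,
                    n_founder_cells = 400, seed = 31)
  out <- tempfile()
  suppressMessages(sim <- simulate_screen(m, eff, cfg, out, screen = "screen1"))
  expect_true(all(file.exists(unlist(sim$fastq))))
  expect_true(all(grepl("screen1_(gc|nongc)_rep[12]\\.fastq\\.gz$",
                        unlist(sim$fastq))))
  expect_true(file.exists(sim$truth_path))
  expect_true(file.exists(file.path(out, "screen1_outputs.json")))
  expect_equal(sum(sim$truth$founder_count), 400)
  # gzipped output loads transparently
  expect_gt(length(load_fastq(sim$fastq$gc[1])), 0)
  # rerun is byte-identical
  out2 <- tempfile()
  suppressMessages(sim2 <- simulate_screen(m, eff, cfg, out2, screen = "screen1"))
  expect_identical(load_fastq(sim$fastq$gc[1]), load_fastq(sim2$fastq$gc[1]))
  expect_identical(sim$truth, sim2$truth)
})
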