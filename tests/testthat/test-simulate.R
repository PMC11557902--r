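test_that("the synthetic baseline is deep, heavy-tailed and reproducible", {
  b1 <- synthetic_baseline(1000, seed = 3, min_total = 1e6)
  b2 <- synthetic_baseline(1000, seed = 3, min_total = 1e6)
  expect_identical(b1, b2)
  expect_length(b1, 1000)
  expect_true(all(b1 >= 0))
  expect_gte(sum(b1), 1e6)
  # abundance spans at least four orders of magnitude
  pos <- b1[b1 > 0]
  expect_gte(log10(max(pos) / min(pos)), 4)
  expect_error(synthetic_baseline(500), ">= 1000")
})

test_that("random libraries have the requested shape and determinism", {
  genes <- sprintf("g%05d", 1:2000)
  lib <- random_library(genes, n_sets = 200, set_size = 30, seed = 4)
  expect_equal(nrow(lib), 200L)
  expect_true(all(lengths(lib$genes) == 30L))
  expect_true(all(vapply(lib$genes, anyDuplicated, 0L) == 0L))
  expect_identical(lib, random_library(genes, 200, 30, seed = 4))
  expect_error(random_library(genes[1:10], 5, 30), "set_size")
})

test_that("truth selection splits sets evenly and flags conflicts", {
  genes <- sprintf("g%05d", 1:500)
  lib <- random_library(genes, n_sets = 200, set_size = 30, seed = 5)
  truth <- select_de_sets(lib, frac_de = 0.05, seed = 6)
  expect_length(truth$up_set_ids, 5L)
  expect_length(truth$down_set_ids, 5L)
  expect_length(intersect(truth$up_set_ids, truth$down_set_ids), 0L)

  # with 300 genes drawn twice from 500, conflicts are certain to appear in
  # some draws; conflicted genes must be excluded from both signal lists
  expect_length(intersect(truth$up_genes, truth$down_genes), 0L)
  up_union <- unique(unlist(lib$genes[lib$set_id %in% truth$up_set_ids]))
  down_union <- unique(unlist(lib$genes[lib$set_id %in% truth$down_set_ids]))
  expect_setequal(truth$conflicted_genes, intersect(up_union, down_union))

  none <- select_de_sets(lib, frac_de = 0, seed = 6)
  expect_length(none$up_set_ids, 0L)
  expect_length(none$up_genes, 0L)
})

test_that("thinning preserves zeros, hits the target total exactly", {
  thin <- thin_counts(c(a = 10, b = 0), 5, seed = 1)
  expect_equal(unname(thin), c(5, 0))
  expect_equal(names(thin), c("a", "b"))

  counts <- c(gA = 100, gB = 300, gC = 0, gD = 600)
  full <- thin_counts(counts, 1000, seed = 2)
  expect_equal(sum(full), 1000)
  expect_error(thin_counts(counts, 2000), "exceeds")

  # multinomial moments: empirical means within 3 SE of depth * p_i
  draws <- vapply(1:1000, function(i) thin_counts(counts, 500, seed = i), counts)
  p <- counts / sum(counts)
  se <- sqrt(500 * p * (1 - p) / 1000)
  expect_true(all(abs(rowMeans(draws) - 500 * p) <= 3 * se + 1e-9))
})

test_that("multiplicative noise is unbiased, nonnegative and optional", {
  x <- c(a = 100, b = 2000, c = 0)
  expect_identical(add_noise(x, 0, seed = 1), x)

  set.seed(30)
  big <- rep(10000, 20000)
  noised <- add_noise(big, 0.5, seed = 31)
  expect_true(all(noised >= 0))
  ratio <- noised / big
  se <- 0.5 / sqrt(length(big))
  expect_lt(abs(mean(ratio) - 1), 3 * se + 0.01)

  # per-gene SDs shared across a row of a matrix input
  m <- matrix(5000, nrow = 50, ncol = 4)
  noised_m <- add_noise(m, 0.6, seed = 32, per_gene_sd = TRUE)
  expect_equal(dim(noised_m), dim(m))
  expect_true(all(noised_m >= 0))
})

test_that("signal injection is signed, rounded and skips conflicts", {
  lib <- gs_library(c("U", "D"), list(c("g1", "g2", "gX"), c("g3", "gX", "g4")))
  truth <- new_truth <- select_de_sets(lib, frac_de = 1, seed = 7)
  # force known directions for the assertion regardless of the draw
  truth$up_set_ids <- "U"; truth$down_set_ids <- "D"
  truth$up_genes <- c("g1", "g2"); truth$down_genes <- c("g3", "g4")
  truth$conflicted_genes <- "gX"

  x <- c(g1 = 100, g2 = 10, g3 = 100, g4 = 7, gX = 50, g9 = 11)
  y <- inject_signal(x, truth, 0.5)
  expect_equal(unname(y["g1"]), round(100 * 2^0.5))  # 141
  expect_equal(unname(y["g3"]), round(100 * 2^-0.5))
  expect_equal(unname(y["gX"]), 50)
  expect_equal(unname(y["g9"]), 11)
  expect_identical(inject_signal(x, truth, 0), x)
})

test_that("pseudosample generation is deterministic with correct shape", {
  baseline <- synthetic_baseline(2000, seed = 8, min_total = 5e6)
  cfg <- sim_config(n_sets = 40, set_size = 10, frac_de = 0.1,
                    target_depth = 1e6, noise_sd = 0.2, min_mean = 5)
  sim1 <- make_pseudosamples(baseline, cfg, seed = 9)
  sim2 <- make_pseudosamples(baseline, cfg, seed = 9)
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$truth, sim2$truth)

  expect_equal(ncol(sim1$counts), 6L)
  expect_equal(levels(sim1$groups), c("control", "case"))
  # control samples total the target depth exactly; case samples moved by
  # noise rounding and injection only
  ctrl_totals <- colSums(sim1$counts[, sim1$groups == "control"])
  expect_true(all(abs(ctrl_totals - 1e6) / 1e6 < 0.05))
  expect_true(all(sim1$background %in% rownames(sim1$counts)))
  expect_gt(length(sim1$background), 100)
})

test_that("strong noiseless signal dominates the DE ranking", {
  baseline <- synthetic_baseline(2000, seed = 10, min_total = 5e6)
  cfg <- sim_config(n_sets = 40, set_size = 10, frac_de = 0.1,
                    log2fc_magnitude = 4, target_depth = 1e6, noise_sd = 0,
                    min_mean = 5)
  sim <- make_pseudosamples(baseline, cfg, seed = 11)
  de <- nb_wald_test(sim$counts[sim$background, ], sim$groups)
  injected <- de$gene_id %in% c(sim$truth$up_genes, sim$truth$down_genes)
  ord <- order(-abs(de$test_statistic))
  top <- ord[seq_len(sum(injected))]
  expect_gt(mean(which(injected) %in% top), 0.9)
})

test_that("null simulations give exchangeable groups and calibrated DE p", {
  baseline <- synthetic_baseline(2000, seed = 12, min_total = 5e6)
  cfg <- sim_config(n_sets = 40, set_size = 10, frac_de = 0,
                    target_depth = 1e6, noise_sd = 0, min_mean = 5)
  ps <- unlist(lapply(1:3, function(r) {
    sim <- make_pseudosamples(baseline, cfg, seed = 100 + r)
    nb_wald_test(sim$counts[sim$background, ], sim$groups)$p_value
  }))
  # approximately uniform p-values under the global null (subsampled so the
  # KS test probes the approximation, not the engine's mild conservatism)
  sub <- sample(ps, 500)
  expect_gt(suppressWarnings(ks.test(sub, "punif")$p.value), 0.01)
})

test_that("the injected effect size is recovered by the DE engine", {
  baseline <- synthetic_baseline(4000, seed = 13, min_total = 2e7)
  cfg <- sim_config(n_sets = 100, set_size = 30, frac_de = 0.1,
                    log2fc_magnitude = 0.5, target_depth = 1e7, noise_sd = 0.1,
                    min_mean = 5)
  sim <- make_pseudosamples(baseline, cfg, seed = 14)
  de <- nb_wald_test(sim$counts[sim$background, ], sim$groups)
  up <- de$gene_id %in% sim$truth$up_genes & de$base_mean > 50
  down <- de$gene_id %in% sim$truth$down_genes & de$base_mean > 50
  expect_lt(abs(mean(de$log2_fold_change[up]) - 0.5), 0.15)
  expect_lt(abs(mean(de$log2_fold_change[down]) + 0.5), 0.15)
})

test_that("the paired cohort couples samples within subjects", {
  baseline <- synthetic_baseline(1500, seed = 15, min_total = 4e6)
  cfg <- sim_config(n_sets = 30, set_size = 10, frac_de = 0.2,
                    log2fc_magnitude = 1, target_depth = 1e6, noise_sd = 0.1,
                    min_mean = 5)
  cohort <- simulate_paired_cohort(baseline, cfg, n_subjects = 6,
                                   subject_sd = 0.3, seed = 16)
  expect_equal(ncol(cohort$counts), 12L)
  expect_equal(length(unique(cohort$pairs)), 6L)
  # within-subject correlation of log counts exceeds between-subject
  lc <- log1p(cohort$counts[cohort$background, ])
  within <- cor(lc[, 1], lc[, 2])
  between <- cor(lc[, 1], lc[, 4])
  expect_gt(within, between)
  expect_identical(
    cohort$counts,
    simulate_paired_cohort(baseline, cfg, n_subjects = 6, subject_sd = 0.3,
                           seed = 16)$counts
  )
})
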