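test_that("contingency tables follow the stated background handling", {
  lib <- gs_library(c("A", "B"), list(paste0("g", 1:5), paste0("g", 6:10)))
  fg <- paste0("g", 1:3)
  bg <- paste0("g", 1:20)
  set1 <- paste0("g", 1:5)

  t_all <- build_contingency(fg, bg, set1, "retain_all")
  expect_equal(as.list(t_all), list(k = 3L, n = 3L, K = 5L, N = 20L))

  t_ann <- build_contingency(fg, bg, set1, "annotated_only",
                             annotated = annotated_genes(lib))
  expect_equal(as.list(t_ann), list(k = 3L, n = 3L, K = 5L, N = 10L))

  expect_warning(
    t2 <- build_contingency(c(fg, "g99"), bg, set1, "retain_all"),
    "1 foreground"
  )
  expect_equal(t2$n, 3L)

  t3 <- build_contingency(fg, bg, paste0("g", 21:25), "retain_all")
  expect_equal(t3$K, 0L)
})

test_that("hypergeometric p matches exhaustive enumeration", {
  expect_equal(hypergeom_pvalue(0, 3, 5, 20), 1)
  expect_equal(hypergeom_pvalue(3, 3, 5, 20), 10 / 1140)
  expect_equal(hypergeom_pvalue(4, 4, 5, 10), 5 / 210)

  set.seed(1)
  for (i in 1:300) {
    N <- sample(5:50, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(hypergeom_pvalue(k, n, K, N), enum_fisher_p(k, n, K, N),
                 tolerance = 1e-13)
  }
})

test_that("fold enrichment is the observed/expected ratio", {
  expect_equal(fold_enrichment(3, 3, 5, 20), 4)
  expect_equal(fold_enrichment(0, 3, 5, 20), 0)
  expect_equal(fold_enrichment(5, 10, 10, 20), 1)
  expect_true(is.na(fold_enrichment(0, 0, 5, 20)))
  expect_true(is.na(fold_enrichment(0, 3, 0, 20)))
})

test_that("BH adjustment matches the hand step-up and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
    ord <- order(p)
    expect_true(!is.unsorted(adj[ord]))
  }
})

test_that("run_ora reproduces the worked toy in every mode", {
  toy <- toy_instance()

  correct <- run_ora(toy$lib, toy$fg, toy$bg, ora_mode("correct"))
  expect_equal(correct$set_id, c("S1", "S2"))
  expect_equal(correct$p_value[1], 10 / 1140)
  expect_equal(correct$fdr[1], 2 * 10 / 1140)
  expect_equal(correct$p_value[2], 1)
  expect_equal(correct$fdr[2], 1)
  expect_equal(correct$fold_enrichment[1], 4)
  expect_equal(correct$overlap[[1]], paste0("g", 1:3))

  bg_bug <- run_ora(toy$lib, toy$fg, toy$bg, ora_mode("bug-bg"))
  expect_equal(bg_bug$p_value[1], 10 / 120)
  expect_equal(bg_bug$N[1], 10L)

  fdr_bug <- run_ora(toy$lib, toy$fg, toy$bg, ora_mode("bug-fdr"))
  expect_equal(fdr_bug$set_id, "S1")
  expect_equal(fdr_bug$fdr, 10 / 1140)

  expect_equal(attr(correct, "n_detected"), 2L)
  expect_equal(significant_sets(correct, 0.05), "S1")
  expect_equal(significant_sets(correct, 1), "S1")  # fdr = 1 is never a call
  expect_equal(significant_sets(correct[0, ], 0.05), character())
})

test_that("run_ora warns and returns empty when nothing is detected", {
  lib <- gs_library("S1", list(paste0("h", 1:6)))
  expect_warning(
    res <- run_ora(lib, paste0("g", 1:2), paste0("g", 1:10)),
    "no detected"
  )
  expect_equal(nrow(res), 0L)
})

test_that("the appended universe set makes the buggy background exact", {
  # Workaround equivalence: bug-bg mode on the augmented library reproduces
  # the correct-mode quadruples and p-values for every original set.
  set.seed(3)
  for (i in 1:40) {
    inst <- random_ora_instance()
    cfg <- ora_config(min_set_size = 2)
    correct <- run_ora(inst$lib, inst$fg, inst$bg,
                       ora_config("retain_all", "all_detected", min_set_size = 2))
    fixed <- run_ora(append_universe_set(inst$lib, inst$bg), inst$fg, inst$bg,
                     ora_config("annotated_only", "all_detected", min_set_size = 2))
    expect_equal(tidy(fixed), tidy(correct), ignore_attr = TRUE)
  }
})

test_that("p = 1 padding makes the buggy FDR scope exact", {
  set.seed(4)
  for (i in 1:40) {
    inst <- random_ora_instance()
    correct <- run_ora(inst$lib, inst$fg, inst$bg,
                       ora_config("retain_all", "all_detected", min_set_size = 2))
    bugged <- run_ora(inst$lib, inst$fg, inst$bg,
                      ora_config("retain_all", "overlapping_only", min_set_size = 2))
    fixed <- apply_fdr_workaround(bugged, attr(bugged, "n_detected"))
    shared <- match(fixed$set_id, correct$set_id)
    expect_equal(fixed$fdr, correct$fdr[shared])
    # and the buggy FDRs can only be too small
    expect_true(all(bugged$fdr <= correct$fdr[shared] + 1e-15))
  }
})

test_that("the FDR workaround handles its edge cases", {
  rec <- tibble::tibble(set_id = c("a", "b"), p_value = c(0.01, 0.02),
                        fdr = bh_adjust(c(0.01, 0.02)))
  fixed <- apply_fdr_workaround(rec, 4)
  expect_equal(fixed$fdr, c(0.04, 0.04))
  expect_equal(apply_fdr_workaround(rec, 2)$fdr, rec$fdr)
  expect_error(apply_fdr_workaround(rec, 1), "smaller")
  expect_true(all(fixed$fdr >= rec$fdr))
})

test_that("the background problem deflates enrichment by exactly N'/N", {
  # With a fully annotated foreground, annotated_only fold enrichment equals
  # the retain_all value scaled by the universe shrinkage factor.
  set.seed(6)
  for (i in 1:30) {
    inst <- random_ora_instance()
    ann <- annotated_genes(inst$lib)
    fg <- intersect(inst$fg, ann)
    if (length(fg) == 0) next
    cfg_a <- ora_config("retain_all", "all_detected", min_set_size = 2)
    cfg_b <- ora_config("annotated_only", "all_detected", min_set_size = 2)
    ra <- run_ora(inst$lib, fg, inst$bg, cfg_a)
    ao <- run_ora(inst$lib, fg, inst$bg, cfg_b)
    shared <- intersect(ra$set_id, ao$set_id)
    ia <- match(shared, ra$set_id)
    ib <- match(shared, ao$set_id)
    ratio <- ao$N[1] / ra$N[1]
    expect_true(ratio <= 1)
    expect_equal(ao$fold_enrichment[ib], ra$fold_enrichment[ia] * ratio)
  }
})

test_that("ORA records satisfy their invariants on random instances", {
  set.seed(7)
  for (i in 1:25) {
    inst <- random_ora_instance()
    res <- run_ora(inst$lib, inst$fg, inst$bg,
                   ora_config(min_set_size = 2))
    expect_true(all(res$k <= pmin(res$n, res$K)))
    expect_true(all(res$K <= res$N & res$n <= res$N))
    expect_true(all(res$p_value > 0 & res$p_value <= 1))
    expect_true(all(res$fdr >= res$p_value))
    expect_true(all(res$fdr <= 1))
    expect_true(!is.unsorted(res$p_value))
    with_k <- res$k > 0
    expect_equal(res$fold_enrichment[with_k],
                 (res$k / res$n)[with_k] / (res$K / res$N)[with_k])
  }
})

test_that("glance and tidy summarise an ORA result", {
  toy <- toy_instance()
  res <- run_ora(toy$lib, toy$fg, toy$bg)
  g <- glance(res)
  expect_equal(g$universe_size, 20L)
  expect_equal(g$n_significant, 1L)
  td <- tidy(res)
  expect_equal(td$overlap[1], "g1,g2,g3")
})
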