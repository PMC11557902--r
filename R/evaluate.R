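#' Jaccard index of two set-id collections
#'
#' `|a intersect b| / |a union b|`. Two empty collections are identical
#' outcomes and return 1 (logged).
#'
#' @param a,b Character vectors (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    inform("both collections empty; Jaccard defined as 1")
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Score signed enrichment calls against simulated truth
#'
#' Predictions and truths are signed `(set_id, direction)` pairs, so an
#' up-truth set reported only as down costs both a false positive and a
#' false negative.
#'
#' @param sig_up,sig_down Character vectors of set IDs called significant in
#'   each direction.
#' @param truth A `sim_truth` from [select_de_sets()].
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `precision_undefined` (TRUE when nothing was called, in which case
#'   precision is reported as 0 with this flag set).
#' @export
score_against_truth <- function(sig_up, sig_down, truth) {
  called <- signed_pairs(sig_up, sig_down)
  truths <- signed_pairs(truth$up_set_ids, truth$down_set_ids)
  tp <- length(intersect(called, truths))
  fp <- length(setdiff(called, truths))
  fn <- length(setdiff(truths, called))
  precision_undefined <- (tp + fp) == 0L
  precision <- if (precision_undefined) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    precision_undefined = precision_undefined
  )
}

#' Compare two enrichment runs
#'
#' Quantifies how much an analysis mode changed the outcome: Jaccard index
#' of the significant-set lists, sets gained and lost, and per-set p/FDR
#' deltas for sets reported in both runs.
#'
#' @param records_a,records_b Result tibbles with `set_id`, `p_value`, `fdr`.
#' @param alpha FDR threshold defining significance.
#' @return An `ora_comparison` list: `jaccard`, `n_sig_a`, `n_sig_b`,
#'   `gained` (significant in b only), `lost` (in a only), and `deltas`, a
#'   tibble of shared sets with `delta_p` and `delta_fdr` (b minus a).
#' @export
compare_runs <- function(records_a, records_b, alpha = 0.05) {
  sig_a <- significant_sets(records_a, alpha)
  sig_b <- significant_sets(records_b, alpha)
  shared <- intersect(records_a$set_id, records_b$set_id)
  ia <- match(shared, records_a$set_id)
  ib <- match(shared, records_b$set_id)
  deltas <- tibble::tibble(
    set_id = shared,
    delta_p = records_b$p_value[ib] - records_a$p_value[ia],
    delta_fdr = records_b$fdr[ib] - records_a$fdr[ia]
  )
  structure(
    list(
      jaccard = jaccard(sig_a, sig_b),
      n_sig_a = length(sig_a),
      n_sig_b = length(sig_b),
      gained = setdiff(sig_b, sig_a),
      lost = setdiff(sig_a, sig_b),
      deltas = deltas,
      alpha = alpha
    ),
    class = "ora_comparison"
  )
}

# Signed (direction, set_id) labels; empty inputs yield no labels.
signed_pairs <- function(up, down) {
  c(if (length(up)) paste0("up:", unique(up)),
    if (length(down)) paste0("down:", unique(down)))
}

ora_method_names <- c("ora_default", "ora_bgfix", "ora_fdrfix",
                      "ora_bothfix", "ora_correct")

# Signed significant-set calls for one ORA analysis mode. The foreground
# selection rule (fdr < fg_alpha, else the fallback_n smallest-p genes) is
# applied per direction; each direction gets its own ORA run.
ora_signed_calls <- function(de, background, lib, method,
                             min_set_size = 5, detection_min = 2,
                             alpha = 0.05, fg_alpha = 0.05,
                             fallback_n = 200) {
  use_lib <- lib
  if (method %in% c("ora_bgfix", "ora_bothfix")) {
    use_lib <- append_universe_set(lib, background)
  }
  config <- if (method == "ora_correct") {
    ora_mode("correct", min_set_size = min_set_size,
             detection_min = detection_min, alpha = alpha)
  } else {
    ora_mode("bug-both", min_set_size = min_set_size,
             detection_min = detection_min, alpha = alpha)
  }
  calls <- lapply(c(up = "up", down = "down"), function(dir) {
    fg <- select_foreground(de, dir, alpha = fg_alpha, fallback_n = fallback_n)
    res <- run_ora(use_lib, fg, background, config)
    if (method %in% c("ora_fdrfix", "ora_bothfix")) {
      res <- apply_fdr_workaround(res, attr(res, "n_detected"))
    }
    significant_sets(res, alpha)
  })
  calls
}

fcs_signed_calls <- function(de, lib, min_set_size = 5, alpha = 0.05,
                             n_perm = 1000, seed = 1) {
  res <- run_fcs(de, lib, min_set_size = min_set_size, n_perm = n_perm,
                 seed = seed)
  sig <- res[res$fdr < alpha, ]
  list(up = sig$set_id[sig$direction == "up"],
       down = sig$set_id[sig$direction == "down"])
}

#' Run the simulation benchmark
#'
#' The full study loop: at each noise level and replicate, a simulated
#' experiment with pathway ground truth is generated from the baseline
#' ([make_pseudosamples()]), differential expression is computed
#' ([nb_wald_test()]) on low-count-filtered genes, each requested method
#' makes signed significant-set calls, and the calls are scored against the
#' truth. Methods:
#'
#' * `ora_default` — ORA with both the background and the FDR problem;
#' * `ora_bgfix` — same, with the background appended as a gene set;
#' * `ora_fdrfix` — same, with p = 1 padding before BH re-adjustment;
#' * `ora_bothfix` — both workarounds (equivalent to `ora_correct` by
#'   construction — a property the test suite asserts);
#' * `ora_correct` — full-background, all-detected-sets ORA;
#' * `fcs` — the preranked comparator ([run_fcs()]).
#'
#' @param baseline Named baseline count vector.
#' @param config A [sim_config()]; its `noise_sd` is overridden by
#'   `noise_grid`.
#' @param methods Subset of the method names above.
#' @param n_reps Replicates per noise level.
#' @param noise_grid Numeric vector of noise SDs.
#' @param seed Master seed; every replicate derives its own streams.
#' @param fcs_n_perm Permutations for the FCS null.
#' @param alpha Significance threshold on adjusted values.
#' @param fg_alpha,fallback_n Foreground selection rule parameters.
#' @return A `sim_study` list with `replicates` (method, noise_sd, rep, tp,
#'   fp, fn, precision, recall, f1) and `summary` (per method x noise mean
#'   and Monte-Carlo standard error of each metric).
#' @export
run_simulation_study <- function(baseline, config = sim_config(),
                                 methods = c(ora_method_names, "fcs"),
                                 n_reps = 100, noise_grid = c(0, 0.2, 0.4, 0.6),
                                 seed = 1, fcs_n_perm = 1000, alpha = 0.05,
                                 fg_alpha = 0.05, fallback_n = 200) {
  methods <- match.arg(methods, c(ora_method_names, "fcs"),
                       several.ok = TRUE)
  grid <- tidyr::expand_grid(noise_sd = noise_grid, rep = seq_len(n_reps))
  rep_seeds <- derive_seeds(seed, 2L * nrow(grid))
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$noise_sd <- grid$noise_sd[i]
    sim <- make_pseudosamples(baseline, cfg, seed = rep_seeds[2L * i - 1L])
    filtered <- sim$counts[sim$background, , drop = FALSE]
    de <- nb_wald_test(filtered, sim$groups)
    purrr::map(methods, function(m) {
      calls <- if (m == "fcs") {
        fcs_signed_calls(de, sim$library, alpha = alpha, n_perm = fcs_n_perm,
                         seed = rep_seeds[2L * i])
      } else {
        ora_signed_calls(de, sim$background, sim$library, m, alpha = alpha,
                         fg_alpha = fg_alpha, fallback_n = fallback_n)
      }
      dplyr::bind_cols(
        tibble::tibble(method = m, noise_sd = grid$noise_sd[i],
                       rep = grid$rep[i]),
        score_against_truth(calls$up, calls$down, sim$truth)
      )
    }) |> dplyr::bind_rows()
  })
  replicates <- dplyr::bind_rows(rows)
  structure(
    list(
      replicates = replicates,
      summary = summarise_study(replicates),
      config = config, noise_grid = noise_grid, n_reps = n_reps, seed = seed
    ),
    class = "sim_study"
  )
}

#' Summarise benchmark replicates
#'
#' Per method and noise level: mean precision, recall and F1 with their
#' Monte-Carlo standard errors (`sd / sqrt(n_reps)`), so scaled-down
#' replications carry an explicit tolerance.
#'
#' @param replicates The `replicates` tibble of a [run_simulation_study()]
#'   result.
#' @return A tibble with one row per method x noise level.
#' @export
summarise_study <- function(replicates) {
  mean_def <- function(x, def) if (any(def)) mean(x[def]) else NA_real_
  se_def <- function(x, def) {
    if (sum(def) > 1) sd(x[def]) / sqrt(sum(def)) else NA_real_
  }
  replicates |>
    dplyr::group_by(.data$method, .data$noise_sd) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      # precision is averaged over replicates where it is defined (something
      # was called); replicates flagged undefined carry no precision
      # information and would otherwise masquerade as zeros
      n_precision_defined = sum(!.data$precision_undefined),
      precision_mean = mean_def(.data$precision, !.data$precision_undefined),
      precision_se = se_def(.data$precision, !.data$precision_undefined),
      recall_mean = mean(.data$recall),
      recall_se = sd(.data$recall) / sqrt(dplyr::n()),
      f1_mean = mean(.data$f1),
      f1_se = sd(.data$f1) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Jaccard similarity across foreground sizes
#'
#' Re-runs a pair of ORA modes at a sweep of foreground sizes (top-k genes
#' by p-value, per direction) and records the Jaccard index of their signed
#' significant-set calls. The FDR problem grows as the foreground shrinks,
#' which this sweep makes visible.
#'
#' @param de A `de_result` tibble.
#' @param background Character vector of background gene IDs.
#' @param lib A gene-set library tibble.
#' @param sizes Ascending foreground sizes (genes per direction).
#' @param modes Length-2 character vector of [ora_mode()] names to compare.
#' @param alpha Significance threshold.
#' @param min_set_size,detection_min Passed to the ORA configs.
#' @return A tibble: `size`, `n_sig_a`, `n_sig_b`, `jaccard`.
#' @export
run_foreground_sweep <- function(de, background, lib,
                                 sizes = c(125, 250, 500, 1000, 2000),
                                 modes = c("bug-fdr", "correct"),
                                 alpha = 0.05, min_set_size = 5,
                                 detection_min = 2) {
  if (is.unsorted(sizes)) abort("sizes must be ascending")
  if (length(modes) != 2L) abort("modes must name exactly two analysis modes")
  cfgs <- lapply(modes, ora_mode, min_set_size = min_set_size,
                 detection_min = detection_min, alpha = alpha)
  purrr::map(sizes, function(k) {
    calls <- lapply(cfgs, function(cfg) {
      signed <- lapply(c(up = "up", down = "down"), function(dir) {
        fg <- select_foreground_topk(de, dir, k)
        significant_sets(run_ora(lib, fg, background, cfg), alpha)
      })
      signed_pairs(signed$up, signed$down)
    })
    tibble::tibble(
      size = k,
      n_sig_a = length(calls[[1L]]),
      n_sig_b = length(calls[[2L]]),
      jaccard = jaccard(calls[[1L]], calls[[2L]])
    )
  }) |> dplyr::bind_rows()
}

#' Down-sampling consistency of enrichment calls
#'
#' Measures how stable each method's significant pathways are as the cohort
#' shrinks. The full paired dataset defines each method's reference calls
#' once; then, at each subset size and replicate, subjects are sampled
#' without replacement, the paired differential-expression test and the
#' method are re-run, and calls are classified as consistent (present in
#' the reference with the same direction) or inconsistent. The proportion
#' of inconsistent calls estimates the method's realised false discovery
#' rate; the consistent count tracks its sensitivity.
#'
#' @param counts Gene x sample count matrix (two samples per subject).
#' @param groups Condition factor (two levels), one per sample.
#' @param pairs Subject label per sample.
#' @param lib A gene-set library tibble.
#' @param sizes Numbers of subjects to retain; each must not exceed the
#'   number of subjects.
#' @param n_reps Resamples per size (default 50).
#' @param methods Subset of `c("ora", "fcs")`; `"ora"` is the correct mode
#'   with the standard foreground rule.
#' @param alpha Significance threshold.
#' @param seed Master seed; each replicate draws a fresh derived stream.
#' @param min_mean Low-count filter threshold (recomputed per subsample).
#' @param fcs_n_perm Permutations for the FCS null.
#' @param fg_alpha,fallback_n Foreground selection rule parameters.
#' @return A tibble: `method`, `size`, `rep`, `n_sig`, `n_consistent`,
#'   `n_inconsistent`, `prop_inconsistent`, `n_full` (reference call count).
#' @export
downsample_consistency <- function(counts, groups, pairs, lib,
                                   sizes, n_reps = 50,
                                   methods = c("ora", "fcs"),
                                   alpha = 0.05, seed = 1, min_mean = 10,
                                   fcs_n_perm = 1000, fg_alpha = 0.05,
                                   fallback_n = 200) {
  methods <- match.arg(methods, c("ora", "fcs"), several.ok = TRUE)
  subjects <- unique(as.character(pairs))
  if (any(sizes > length(subjects))) {
    abort("a requested size exceeds the number of subjects")
  }
  run_methods <- function(cols) {
    sub_counts <- low_count_filter(counts[, cols, drop = FALSE], min_mean)
    de <- nb_wald_test(sub_counts, groups[cols], pairs = pairs[cols])
    background <- rownames(sub_counts)
    out <- list()
    if ("ora" %in% methods) {
      calls <- ora_signed_calls(de, background, lib, "ora_correct",
                                alpha = alpha, fg_alpha = fg_alpha,
                                fallback_n = fallback_n)
      out$ora <- signed_pairs(calls$up, calls$down)
    }
    if ("fcs" %in% methods) {
      calls <- fcs_signed_calls(de, lib, alpha = alpha, n_perm = fcs_n_perm,
                                seed = seed)
      out$fcs <- signed_pairs(calls$up, calls$down)
    }
    out
  }
  full <- run_methods(seq_len(ncol(counts)))
  grid <- tidyr::expand_grid(size = sizes, rep = seq_len(n_reps))
  rep_seeds <- derive_seeds(seed, nrow(grid))
  purrr::map(seq_len(nrow(grid)), function(i) {
    keep <- withr::with_seed(rep_seeds[i], {
      sample(subjects, grid$size[i])
    })
    calls <- run_methods(which(as.character(pairs) %in% keep))
    purrr::map(methods, function(m) {
      n_cons <- length(intersect(calls[[m]], full[[m]]))
      n_inc <- length(setdiff(calls[[m]], full[[m]]))
      tibble::tibble(
        method = m, size = grid$size[i], rep = grid$rep[i],
        n_sig = length(calls[[m]]),
        n_consistent = n_cons,
        n_inconsistent = n_inc,
        prop_inconsistent = if (n_cons + n_inc > 0) {
          n_inc / (n_cons + n_inc)
        } else 0,
        n_full = length(full[[m]])
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
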