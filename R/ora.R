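#' Configure an overrepresentation analysis
#'
#' The two switches encode the failure modes this package exists to study:
#'
#' * `background_handling`: `"retain_all"` keeps the full background list as
#'   the hypergeometric universe (correct); `"annotated_only"` silently
#'   intersects the universe with the genes annotated to at least one set,
#'   shrinking N and deflating enrichment — the *background problem*.
#' * `fdr_scope`: `"all_detected"` adjusts p-values over every detected set,
#'   counting zero-overlap sets as the tests they are (correct);
#'   `"overlapping_only"` drops sets with no foreground overlap before
#'   Benjamini-Hochberg adjustment, understating the number of tests — the
#'   *FDR problem*.
#'
#' @param background_handling `"retain_all"` or `"annotated_only"`.
#' @param fdr_scope `"all_detected"` or `"overlapping_only"`.
#' @param min_set_size,max_set_size Set-size filter applied to
#'   background-restricted membership by default (`size_on_restricted`).
#' @param detection_min A set counts as detected (and hence as a test) when at
#'   least this many of its members are in the background; default 2.
#' @param alpha Significance threshold on adjusted p-values.
#' @param size_on_restricted If `FALSE`, the size filter uses raw library
#'   sizes instead of background-restricted sizes.
#' @return An `ora_config` list.
#' @seealso [ora_mode()] for the named correct/buggy presets.
#' @export
ora_config <- function(background_handling = c("retain_all", "annotated_only"),
                       fdr_scope = c("all_detected", "overlapping_only"),
                       min_set_size = 5,
                       max_set_size = Inf,
                       detection_min = 2,
                       alpha = 0.05,
                       size_on_restricted = TRUE) {
  background_handling <- match.arg(background_handling)
  fdr_scope <- match.arg(fdr_scope)
  if (detection_min < 1) abort("detection_min must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (min_set_size > max_set_size) abort("min_set_size exceeds max_set_size")
  structure(
    list(
      background_handling = background_handling,
      fdr_scope = fdr_scope,
      min_set_size = min_set_size,
      max_set_size = max_set_size,
      detection_min = detection_min,
      alpha = alpha,
      size_on_restricted = size_on_restricted
    ),
    class = "ora_config"
  )
}

#' Named ORA mode presets
#'
#' `"correct"` is the unbiased analysis; `"bug-bg"` reproduces the background
#' problem, `"bug-fdr"` the FDR problem, and `"bug-both"` both at once.
#'
#' @param mode One of `"correct"`, `"bug-bg"`, `"bug-fdr"`, `"bug-both"`.
#' @param ... Further arguments passed to [ora_config()].
#' @return An `ora_config` list.
#' @export
ora_mode <- function(mode = c("correct", "bug-bg", "bug-fdr", "bug-both"), ...) {
  mode <- match.arg(mode)
  switch(mode,
    "correct" = ora_config("retain_all", "all_detected", ...),
    "bug-bg" = ora_config("annotated_only", "all_detected", ...),
    "bug-fdr" = ora_config("retain_all", "overlapping_only", ...),
    "bug-both" = ora_config("annotated_only", "overlapping_only", ...)
  )
}

#' Build the 2x2 contingency quadruple behind one ORA test
#'
#' Computes the overlap count `k`, effective foreground size `n`, detected set
#' size `K` and universe size `N` for one gene set under a stated background
#' handling. Foreground genes absent from the background are dropped with a
#' warning counting them. Under `"annotated_only"` the universe is the
#' background intersected with the library's annotated genes, and the
#' foreground shrinks with it.
#'
#' @param foreground,background Character vectors of gene IDs.
#' @param set_members Character vector of one set's member genes.
#' @param annotated For `"annotated_only"` mode, the annotated-gene universe
#'   (e.g. `annotated_genes(lib)`); ignored for `"retain_all"`.
#' @param background_handling `"retain_all"` or `"annotated_only"`.
#' @return A one-row tibble with columns `k`, `n`, `K`, `N`.
#' @export
build_contingency <- function(foreground, background, set_members,
                              background_handling = c("retain_all", "annotated_only"),
                              annotated = NULL) {
  background_handling <- match.arg(background_handling)
  bg <- unique(as.character(background))
  if (length(bg) == 0L) abort("background is empty")
  fg <- unique(as.character(foreground))
  n_outside <- sum(!(fg %in% bg))
  if (n_outside > 0L) {
    warn(paste0("dropped ", n_outside, " foreground gene(s) absent from background"))
    fg <- fg[fg %in% bg]
  }
  if (background_handling == "annotated_only") {
    if (is.null(annotated)) abort("annotated universe required for annotated_only mode")
    universe <- bg[bg %in% annotated]
    fg <- fg[fg %in% universe]
  } else {
    universe <- bg
  }
  if (length(universe) == 0L) abort("universe is empty")
  set_in <- unique(set_members)[unique(set_members) %in% universe]
  tibble::tibble(
    k = sum(fg %in% set_in),
    n = length(fg),
    K = length(set_in),
    N = length(universe)
  )
}

#' Upper-tail hypergeometric p-value
#'
#' Returns `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` — the probability of
#' drawing at least the observed overlap when `n` foreground genes are drawn
#' from a universe of `N` genes of which `K` belong to the set. Equal to the
#' one-sided ("greater") Fisher exact test on the 2x2 table. The `>= k`
#' convention matches clusterProfiler-style ORA.
#'
#' @param k,n,K,N Contingency counts (vectorised).
#' @return p-values in `(0, 1]`; `k = 0` gives exactly 1.
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  stopifnot(all(k >= 0), all(K <= N), all(n <= N), all(k <= pmin(n, K)))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fold enrichment of an overlap
#'
#' The ratio of observed to expected overlap, `(k/n) / (K/N)`; the package's
#' effect-size surrogate for ORA results. Undefined (NA) when `n` or `K` is
#' zero.
#'
#' @inheritParams hypergeom_pvalue
#' @return Numeric vector of fold enrichments.
#' @export
fold_enrichment <- function(k, n, K, N) {
  ifelse(n > 0 & K > 0, (k / n) / (K / N), NA_real_)
}

#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up adjusted p-values, capped at 1, order-preserving with the input.
#' Unlike [stats::p.adjust()] this refuses values outside `(0, 1]` rather
#' than propagating them.
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted values, elementwise `>=` the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Run overrepresentation analysis over a gene-set library
#'
#' The full ORA pipeline under an explicit [ora_config()]: the library is
#' restricted to the background, size-filtered, reduced to detected sets
#' (those with at least `detection_min` background members), each set is
#' tested with the upper-tail hypergeometric test, and Benjamini-Hochberg
#' adjustment is applied over the scope the config dictates. Under
#' `fdr_scope = "overlapping_only"` sets with zero foreground overlap are
#' silently dropped before adjustment, shrinking the number of tests — the
#' FDR problem. An appended `"__UNIVERSE__"` set influences the universe but
#' is never reported.
#'
#' @param lib A gene-set library tibble.
#' @param foreground,background Character vectors of gene IDs; the foreground
#'   is sanitised to the background with a warning for dropped IDs.
#' @param config An [ora_config()] (or [ora_mode()]) object.
#' @param universe_id Reserved id of the appended background set, excluded
#'   from results.
#' @return An `ora_result` tibble with one row per reported set: `set_id`,
#'   `k`, `n`, `K`, `N`, `p_value`, `fold_enrichment`, `fdr`, `overlap`
#'   (list-column of overlapping gene IDs), sorted by `p_value` then
#'   `set_id`. The config, universe size and number of detected sets travel
#'   as attributes; see [glance.ora_result()].
#' @examples
#' lib <- gs_library(c("S1", "S2"), list(paste0("g", 1:5), paste0("g", 6:10)))
#' run_ora(lib, paste0("g", 1:3), paste0("g", 1:20),
#'         config = ora_config(min_set_size = 1))
#' @export
run_ora <- function(lib, foreground, background, config = ora_config(),
                    universe_id = "__UNIVERSE__") {
  bg <- unique(as.character(background))
  if (length(bg) == 0L) abort("background is empty")
  fg <- unique(as.character(foreground))
  n_outside <- sum(!(fg %in% bg))
  if (n_outside > 0L) {
    warn(paste0("dropped ", n_outside, " foreground gene(s) absent from background"))
    fg <- fg[fg %in% bg]
  }

  if (config$background_handling == "annotated_only") {
    universe <- bg[bg %in% annotated_genes(lib)]
    fg <- fg[fg %in% universe]
  } else {
    universe <- bg
  }
  if (length(universe) == 0L) abort("universe is empty after background handling")

  restricted <- lib
  restricted$genes <- lapply(lib$genes, function(g) g[g %in% universe])
  keep_size <- if (config$size_on_restricted) {
    lengths(restricted$genes)
  } else {
    lengths(lib$genes)
  }
  detected <- lengths(restricted$genes) >= config$detection_min &
    keep_size >= config$min_set_size & keep_size <= config$max_set_size &
    restricted$set_id != universe_id
  restricted <- restricted[detected, ]

  if (nrow(restricted) == 0L) {
    warn("no detected gene sets; returning empty result")
    out <- tibble::tibble(
      set_id = character(), k = integer(), n = integer(), K = integer(),
      N = integer(), p_value = numeric(), fold_enrichment = numeric(),
      fdr = numeric(), overlap = list()
    )
    return(new_ora_result(out, config, length(universe), 0L, length(fg)))
  }

  overlap <- lapply(restricted$genes, function(g) fg[fg %in% g])
  out <- tibble::tibble(
    set_id = restricted$set_id,
    k = lengths(overlap),
    n = length(fg),
    K = lengths(restricted$genes),
    N = length(universe),
    overlap = overlap
  )
  n_detected <- nrow(out)

  if (config$fdr_scope == "overlapping_only") {
    out <- out[out$k > 0L, ]
  }
  out$p_value <- hypergeom_pvalue(out$k, out$n, out$K, out$N)
  out$fold_enrichment <- fold_enrichment(out$k, out$n, out$K, out$N)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set_id),
             c("set_id", "k", "n", "K", "N", "p_value", "fold_enrichment",
               "fdr", "overlap")]
  new_ora_result(out, config, length(universe), n_detected, length(fg))
}

new_ora_result <- function(x, config, universe_size, n_detected, n_foreground) {
  structure(
    x,
    class = c("ora_result", class(tibble::tibble())),
    config = config,
    universe_size = universe_size,
    n_detected = n_detected,
    n_foreground = n_foreground
  )
}

#' Re-adjust FDR values for tests hidden by the FDR problem (workaround)
#'
#' A tool affected by the FDR problem reports only sets overlapping the
#' foreground, so its Benjamini-Hochberg correction ran over too few tests.
#' The published workaround appends a p-value of 1 for each of the
#' `expected_set_count - nrow(records)` missing sets and re-runs the
#' adjustment; the corrected values are written back to `fdr`. The expected
#' count is the number of sets with at least `detection_min` background
#' members — i.e. what [run_ora()] with `fdr_scope = "all_detected"` would
#' have tested.
#'
#' @param records An `ora_result` (or any tibble with `p_value` and `fdr`).
#' @param expected_set_count The true number of tests conducted.
#' @return `records` with corrected `fdr`, elementwise `>=` the original.
#' @export
apply_fdr_workaround <- function(records, expected_set_count) {
  n_obs <- nrow(records)
  if (expected_set_count < n_obs) {
    abort("expected_set_count is smaller than the number of observed records")
  }
  if (n_obs == 0L) return(records)
  padded <- c(records$p_value, rep(1, expected_set_count - n_obs))
  records$fdr <- bh_adjust(padded)[seq_len(n_obs)]
  records
}

#' Significant set IDs at an FDR threshold
#'
#' @param records A result tibble with `set_id` and `fdr` columns.
#' @param alpha FDR threshold; sets with `fdr < alpha` are returned.
#' @return Character vector of significant set IDs.
#' @export
significant_sets <- function(records, alpha = 0.05) {
  if (nrow(records) == 0L) return(character())
  records$set_id[records$fdr < alpha]
}
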