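#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ORA result
#'
#' Returns the per-set records as a plain tibble with the overlap
#' list-column flattened to a comma-joined string — the shape written to
#' disk by [write_result_tsv()].
#'
#' @param x An `ora_result` from [run_ora()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ora_result
#' @export
tidy.ora_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$overlap <- vapply(out$overlap, paste, "", collapse = ",")
  out
}

#' One-row summary of an ORA result
#'
#' @param x An `ora_result` from [run_ora()].
#' @param ... Unused.
#' @return A tibble with the analysis mode, universe size, foreground size,
#'   number of detected sets, number reported and number significant at the
#'   config's alpha.
#' @method glance ora_result
#' @export
glance.ora_result <- function(x, ...) {
  config <- attr(x, "config")
  tibble::tibble(
    background_handling = config$background_handling,
    fdr_scope = config$fdr_scope,
    universe_size = attr(x, "universe_size"),
    n_foreground = attr(x, "n_foreground"),
    n_detected = attr(x, "n_detected"),
    n_reported = nrow(x),
    n_significant = length(significant_sets(x, config$alpha))
  )
}

#' @method tidy fcs_result
#' @export
tidy.fcs_result <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of an FCS result
#'
#' @param x An `fcs_result` from [run_fcs()].
#' @param alpha Significance threshold.
#' @param ... Unused.
#' @return A tibble with set counts by direction and significance.
#' @method glance fcs_result
#' @export
glance.fcs_result <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_tested = nrow(x),
    n_significant = sum(x$fdr < alpha),
    n_sig_up = sum(x$fdr < alpha & x$direction == "up"),
    n_sig_down = sum(x$fdr < alpha & x$direction == "down")
  )
}

#' @method tidy sim_study
#' @export
tidy.sim_study <- function(x, ...) x$replicates

#' Per-condition summary of a simulation study
#'
#' @param x A `sim_study` from [run_simulation_study()].
#' @param ... Unused.
#' @return The per-method, per-noise summary tibble (means with Monte-Carlo
#'   standard errors).
#' @method glance sim_study
#' @export
glance.sim_study <- function(x, ...) x$summary

#' @method tidy ora_comparison
#' @export
tidy.ora_comparison <- function(x, ...) x$deltas

#' @method glance ora_comparison
#' @export
glance.ora_comparison <- function(x, ...) {
  tibble::tibble(
    jaccard = x$jaccard,
    n_sig_a = x$n_sig_a,
    n_sig_b = x$n_sig_b,
    n_gained = length(x$gained),
    n_lost = length(x$lost),
    alpha = x$alpha
  )
}

#' @export
print.ora_comparison <- function(x, ...) {
  cat("ORA run comparison (alpha =", x$alpha, ")\n")
  cat("  significant: a =", x$n_sig_a, ", b =", x$n_sig_b,
      "; Jaccard =", signif(x$jaccard, 4), "\n")
  cat("  gained:", length(x$gained), " lost:", length(x$lost), "\n")
  invisible(x)
}
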