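#' Write a self-contained toy workspace
#'
#' Creates small input files used by the documentation, tests and CLI
#' examples, reproducible byte-for-byte from the seed:
#'
#' * `foreground.txt`, `background.txt`, `toy.gmt` — a 20-gene toy where the
#'   background holds unannotated genes (so the background problem visibly
#'   changes the result) and one set lies outside the background entirely;
#' * `sim_counts.tsv`, `sim_truth.tsv`, `sim_background.txt`,
#'   `sim_library.gmt`, `sim_groups.tsv` — a small simulated two-group
#'   experiment with pathway ground truth.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for the simulated component.
#' @return Character vector of the paths written, invisibly.
#' @export
write_fixture <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  write_gene_list(paste0("g", 1:3), p("foreground.txt"))
  write_gene_list(paste0("g", 1:20), p("background.txt"))
  toy <- gs_library(
    c("S1", "S2", "S3"),
    list(paste0("g", 1:5), paste0("g", 6:10), paste0("g", 21:25)),
    c("fully in background", "in background, no overlap", "outside background")
  )
  write_gmt(toy, p("toy.gmt"))

  baseline <- synthetic_baseline(1000, seed = seed, min_total = 1e6)
  cfg <- sim_config(n_sets = 20, set_size = 10, frac_de = 0.1,
                    log2fc_magnitude = 1, target_depth = 2e5,
                    noise_sd = 0.2, min_mean = 5)
  sim <- make_pseudosamples(baseline, cfg, seed = seed)
  meta <- run_metadata(cfg, seed)
  write_counts(sim$counts, p("sim_counts.tsv"), meta)
  write_result_tsv(
    tibble::tibble(
      set_id = c(sim$truth$up_set_ids, sim$truth$down_set_ids),
      direction = rep(c("up", "down"), c(length(sim$truth$up_set_ids),
                                         length(sim$truth$down_set_ids)))
    ),
    p("sim_truth.tsv"), meta
  )
  write_gene_list(sim$background, p("sim_background.txt"))
  write_gmt(sim$library, p("sim_library.gmt"))
  write_result_tsv(
    tibble::tibble(sample_id = colnames(sim$counts),
                   group = as.character(sim$groups)),
    p("sim_groups.tsv"), meta
  )
  invisible(p(c("foreground.txt", "background.txt", "toy.gmt",
                "sim_counts.tsv", "sim_truth.tsv", "sim_background.txt",
                "sim_library.gmt", "sim_groups.tsv")))
}
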