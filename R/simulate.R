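#' Simulation configuration
#'
#' Defaults mirror the benchmark's study conditions: a library of 200 random
#' gene sets of 30 genes, 5% of sets differentially expressed with an equal
#' up/down split, signal of +/-0.5 log2 fold change injected into member
#' genes of case samples, three pseudosamples per group thinned to 20
#' million reads, and multiplicative Gaussian noise with SD between 0 and
#' 0.6.
#'
#' @param n_sets Number of random gene sets.
#' @param set_size Members per set.
#' @param frac_de Fraction of sets carrying injected signal;
#'   `frac_de * n_sets` must be an even integer (or zero) so the up/down
#'   split is equal.
#' @param log2fc_magnitude Absolute injected log2 fold change.
#' @param target_depth Reads per pseudosample after thinning.
#' @param noise_sd SD of the multiplicative noise factor, in `[0, 0.6]`
#'   under the study conditions (larger values are permitted).
#' @param n_per_group Pseudosamples per group.
#' @param per_gene_sd If `TRUE`, each gene instead draws its own noise SD
#'   uniformly from `[0, noise_sd]`.
#' @param min_mean Low-count filter threshold defining the background.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sets = 200, set_size = 30, frac_de = 0.05,
                       log2fc_magnitude = 0.5, target_depth = 2e7,
                       noise_sd = 0, n_per_group = 3, per_gene_sd = FALSE,
                       min_mean = 10) {
  n_de <- frac_de * n_sets
  if (abs(n_de - round(n_de)) > 1e-9 || (round(n_de) %% 2 != 0)) {
    abort("frac_de * n_sets must be an even integer (equal up/down split)")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(
    list(
      n_sets = n_sets, set_size = set_size, frac_de = frac_de,
      log2fc_magnitude = log2fc_magnitude, target_depth = target_depth,
      noise_sd = noise_sd, n_per_group = n_per_group,
      per_gene_sd = per_gene_sd, min_mean = min_mean
    ),
    class = "sim_config"
  )
}

#' Synthetic deep-coverage baseline expression profile
#'
#' Generates a single-sample count vector standing in for a deeply sequenced
#' bulk RNA-seq run: per-gene means follow a heavy-tailed log-normal
#' (meanlog 4, sdlog 2), counts are the rounded means, and the profile is
#' rescaled so the total is at least `min_total` reads. Deterministic given
#' `seed`. The resulting abundance distribution spans several orders of
#' magnitude, as real transcriptomes do.
#'
#' @param n_genes Number of genes (>= 1000).
#' @param seed Integer seed.
#' @param min_total Minimum total read count of the profile.
#' @return Named integer-valued numeric vector of counts (`gene00001`, ...).
#' @export
synthetic_baseline <- function(n_genes = 20000, seed = 1, min_total = 5e7) {
  if (n_genes < 1000) abort("n_genes must be >= 1000")
  x <- withr::with_seed(seed, stats::rlnorm(n_genes, meanlog = 4, sdlog = 2))
  if (sum(x) < min_total) x <- x * (min_total / sum(x))
  counts <- round(x)
  while (sum(counts) < min_total) {
    x <- x * 1.01
    counts <- round(x)
  }
  names(counts) <- sprintf("gene%05d", seq_len(n_genes))
  counts
}

#' Random gene-set library
#'
#' Each set is a uniform sample of `set_size` genes without replacement
#' (within a set); sets are drawn independently, so overlap between sets is
#' allowed. Deterministic given `seed`.
#'
#' @param gene_ids Character vector of candidate gene IDs.
#' @param n_sets Number of sets.
#' @param set_size Members per set; must not exceed `length(gene_ids)`.
#' @param seed Integer seed.
#' @return A `geneset_library` tibble with set IDs `set001`, `set002`, ...
#' @export
random_library <- function(gene_ids, n_sets = 200, set_size = 30, seed = 1) {
  if (set_size > length(gene_ids)) {
    abort("set_size exceeds the number of available genes")
  }
  genes <- withr::with_seed(seed, {
    lapply(seq_len(n_sets), function(i) sample(gene_ids, set_size))
  })
  gs_library(sprintf("set%03d", seq_len(n_sets)), genes, "random set")
}

#' Choose ground-truth differentially expressed sets
#'
#' Selects `frac_de * nrow(lib)` sets uniformly at random and splits them
#' half up-, half down-regulated. Member unions define the genes to be
#' perturbed; genes belonging to both an up- and a down-set are recorded as
#' conflicted and receive no injected signal.
#'
#' @param lib A gene-set library tibble.
#' @param frac_de Fraction of sets to perturb.
#' @param seed Integer seed.
#' @return A `sim_truth` list: `up_set_ids`, `down_set_ids`, `up_genes`,
#'   `down_genes`, `conflicted_genes`.
#' @export
select_de_sets <- function(lib, frac_de = 0.05, seed = 1) {
  n_de <- round(frac_de * nrow(lib))
  if (n_de == 0) {
    return(new_sim_truth(character(), character(), lib))
  }
  if (n_de %% 2 != 0) abort("frac_de * n_sets must be even")
  chosen <- withr::with_seed(seed, sample(lib$set_id, n_de))
  new_sim_truth(chosen[seq_len(n_de / 2)], chosen[(n_de / 2 + 1):n_de], lib)
}

new_sim_truth <- function(up_ids, down_ids, lib) {
  up_genes <- unique(unlist(lib$genes[lib$set_id %in% up_ids]))
  down_genes <- unique(unlist(lib$genes[lib$set_id %in% down_ids]))
  conflicted <- intersect(up_genes, down_genes)
  structure(
    list(
      up_set_ids = up_ids,
      down_set_ids = down_ids,
      up_genes = setdiff(up_genes, conflicted),
      down_genes = setdiff(down_genes, conflicted),
      conflicted_genes = conflicted
    ),
    class = "sim_truth"
  )
}

#' Thin a count profile to a fixed total depth
#'
#' One multinomial draw of `target_depth` reads with per-gene probabilities
#' proportional to the input counts; the output total equals `target_depth`
#' exactly and genes with zero input stay zero.
#'
#' @param counts Nonnegative numeric vector of counts.
#' @param target_depth Total reads to draw; must not exceed `sum(counts)`.
#' @param seed Integer seed.
#' @return Thinned counts, same names and length as the input.
#' @export
thin_counts <- function(counts, target_depth, seed = 1) {
  if (target_depth > sum(counts)) {
    abort("target_depth exceeds the total input counts")
  }
  out <- withr::with_seed(seed, {
    stats::rmultinom(1, size = target_depth, prob = counts)[, 1L]
  })
  names(out) <- names(counts)
  out
}

#' Multiplicative Gaussian noise on counts
#'
#' Each count is multiplied by an independent factor drawn from
#' `Normal(1, sd)` truncated at zero, then rounded to the nearest integer.
#' With `per_gene_sd = TRUE` each gene first draws its own SD uniformly from
#' `[0, noise_sd]` (shared across samples of a matrix input's row).
#'
#' @param counts Numeric vector or matrix of counts.
#' @param noise_sd Noise SD (condition-level), or the upper bound of the
#'   per-gene uniform when `per_gene_sd = TRUE`.
#' @param seed Integer seed.
#' @param per_gene_sd Draw a per-gene SD instead of using a fixed one.
#' @return Noised counts, same shape as the input.
#' @export
add_noise <- function(counts, noise_sd, seed = 1, per_gene_sd = FALSE) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (noise_sd == 0) return(counts)
  withr::with_seed(seed, {
    n_gene <- if (is.matrix(counts)) nrow(counts) else length(counts)
    sds <- if (per_gene_sd) stats::runif(n_gene, 0, noise_sd) else noise_sd
    fac <- pmax(stats::rnorm(length(counts), mean = 1, sd = sds), 0)
    out <- round(counts * fac)
    attributes(out) <- attributes(counts)
    out
  })
}

#' Inject signed fold-change signal into truth genes
#'
#' Multiplies up-regulated genes by `2^m` and down-regulated genes by
#' `2^-m` (case samples only, by convention of the caller), rounding to
#' integers. Conflicted genes are left unchanged.
#'
#' @param counts Named numeric vector or matrix (rownames = gene IDs).
#' @param truth A `sim_truth` from [select_de_sets()].
#' @param log2fc_magnitude Absolute log2 fold change `m`.
#' @return Counts with signal injected.
#' @export
inject_signal <- function(counts, truth, log2fc_magnitude = 0.5) {
  ids <- if (is.matrix(counts)) rownames(counts) else names(counts)
  up <- ids %in% truth$up_genes
  down <- ids %in% truth$down_genes
  if (is.matrix(counts)) {
    counts[up, ] <- round(counts[up, , drop = FALSE] * 2^log2fc_magnitude)
    counts[down, ] <- round(counts[down, , drop = FALSE] * 2^-log2fc_magnitude)
  } else {
    counts[up] <- round(counts[up] * 2^log2fc_magnitude)
    counts[down] <- round(counts[down] * 2^-log2fc_magnitude)
  }
  counts
}

#' Generate a simulated two-group experiment with pathway ground truth
#'
#' From a deep baseline profile: draws a random gene-set library, selects
#' truth sets, then builds `n_per_group` control and case pseudosamples by
#' independently thinning the baseline to `target_depth` reads and applying
#' multiplicative noise; case samples additionally receive the signed
#' fold-change injection into truth-set member genes. The background list is
#' the set of genes passing the low-count filter on the finished matrix.
#' Fully deterministic given `seed`.
#'
#' @param baseline Named count vector (see [synthetic_baseline()]).
#' @param config A [sim_config()].
#' @param seed Integer seed governing the whole generator chain.
#' @return A list: `counts` (gene x sample matrix), `groups` (factor,
#'   control/case), `truth` (`sim_truth`), `background` (character vector),
#'   `library` (the random `geneset_library`).
#' @export
make_pseudosamples <- function(baseline, config = sim_config(), seed = 1) {
  if (sum(baseline) < config$target_depth) {
    abort("baseline total is below target_depth")
  }
  n_tot <- 2L * config$n_per_group
  seeds <- derive_seeds(seed, 2L * n_tot + 2L)
  lib <- random_library(names(baseline), config$n_sets, config$set_size,
                        seed = seeds[1L])
  truth <- select_de_sets(lib, config$frac_de, seed = seeds[2L])
  cols <- matrix(0, nrow = length(baseline), ncol = n_tot,
                 dimnames = list(names(baseline), c(
                   paste0("ctrl", seq_len(config$n_per_group)),
                   paste0("case", seq_len(config$n_per_group))
                 )))
  for (j in seq_len(n_tot)) {
    x <- thin_counts(baseline, config$target_depth, seed = seeds[2L * j + 1L])
    x <- add_noise(x, config$noise_sd, seed = seeds[2L * j + 2L],
                   per_gene_sd = config$per_gene_sd)
    cols[, j] <- x
  }
  groups <- factor(rep(c("control", "case"), each = config$n_per_group),
                   levels = c("control", "case"))
  case <- groups == "case"
  cols[, case] <- inject_signal(cols[, case, drop = FALSE], truth,
                                config$log2fc_magnitude)
  background <- rownames(low_count_filter(cols, config$min_mean))
  list(counts = cols, groups = groups, truth = truth,
       background = background, library = lib)
}

#' Simulated paired tumour/normal cohort
#'
#' Builds a paired dataset for the down-sampling consistency analysis: for
#' each subject, a "normal" and a "tumour" sample are independently thinned
#' from the baseline and share a subject-specific multiplicative expression
#' profile (gene-wise factors `Normal(1, subject_sd)` truncated at zero),
#' which induces the within-subject correlation that paired testing
#' exploits; tumour samples additionally receive the truth-set signal
#' injection.
#'
#' @inheritParams make_pseudosamples
#' @param n_subjects Number of subjects (two samples each).
#' @param subject_sd SD of the subject-level multiplicative profile.
#' @return A list: `counts`, `groups` (normal/tumour), `pairs` (subject
#'   labels), `truth`, `background`, `library`.
#' @export
simulate_paired_cohort <- function(baseline, config = sim_config(),
                                   n_subjects = 10, subject_sd = 0.2,
                                   seed = 1) {
  seeds <- derive_seeds(seed, 5L * n_subjects + 2L)
  lib <- random_library(names(baseline), config$n_sets, config$set_size,
                        seed = seeds[1L])
  truth <- select_de_sets(lib, config$frac_de, seed = seeds[2L])
  n_genes <- length(baseline)
  cols <- matrix(0, nrow = n_genes, ncol = 2L * n_subjects,
                 dimnames = list(names(baseline), paste0(
                   rep(c("normal", "tumour"), n_subjects), "_s",
                   rep(seq_len(n_subjects), each = 2)
                 )))
  for (s in seq_len(n_subjects)) {
    base_idx <- 2L + 5L * (s - 1L)
    subj_fac <- withr::with_seed(seeds[base_idx + 1L], {
      pmax(stats::rnorm(n_genes, 1, subject_sd), 0)
    })
    prof <- baseline * subj_fac
    for (cond in 1:2) {
      x <- thin_counts(prof, config$target_depth,
                       seed = seeds[base_idx + 2L * cond])
      x <- add_noise(x, config$noise_sd,
                     seed = seeds[base_idx + 2L * cond + 1L],
                     per_gene_sd = config$per_gene_sd)
      cols[, 2L * (s - 1L) + cond] <- x
    }
  }
  tumour <- grepl("^tumour", colnames(cols))
  cols[, tumour] <- inject_signal(cols[, tumour, drop = FALSE], truth,
                                  config$log2fc_magnitude)
  list(
    counts = cols,
    groups = factor(ifelse(tumour, "tumour", "normal"),
                    levels = c("normal", "tumour")),
    pairs = paste0("s", rep(seq_len(n_subjects), each = 2)),
    truth = truth,
    background = rownames(low_count_filter(cols, config$min_mean)),
    library = lib
  )
}

# Derive k child seeds (< 2^31) from a master seed without disturbing the
# caller's RNG state.
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
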