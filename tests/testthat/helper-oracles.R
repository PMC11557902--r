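# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the enumeration Fisher p uses binomial coefficients
# only, and the BH oracle is a literal step-up transcription.

# One-sided (greater) Fisher exact p for the 2x2 with margins (N, K, n) and
# observed overlap k, by direct enumeration of the hypergeometric mass.
enum_fisher_p <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Literal Benjamini-Hochberg step-up: sort, multiply by m/rank, enforce
# monotonicity from the largest rank down, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(ord)]
}

# Random small ORA instance: background, a library over a superset of it
# (some genes unannotated, some sets outside), and a foreground.
random_ora_instance <- function(n_bg = 40, n_sets = 8, max_set = 12,
                                n_fg = 8) {
  all_genes <- paste0("g", seq_len(n_bg + 15))
  bg <- paste0("g", seq_len(n_bg))
  genes <- lapply(seq_len(n_sets), function(i) {
    sample(all_genes, sample(2:max_set, 1))
  })
  lib <- gs_library(paste0("S", seq_len(n_sets)), genes)
  fg <- sample(bg, n_fg)
  list(lib = lib, bg = bg, fg = fg)
}

# The worked 20-gene toy used throughout the documentation: S1 overlaps the
# foreground, S2 is detected with no overlap, S3 lies outside the
# background, and g11..g20 are unannotated background genes.
toy_instance <- function() {
  list(
    lib = gs_library(
      c("S1", "S2", "S3"),
      list(paste0("g", 1:5), paste0("g", 6:10), paste0("g", 21:25))
    ),
    bg = paste0("g", 1:20),
    fg = paste0("g", 1:3)
  )
}

# Small NB count matrix for DE tests: ng genes, 3v3, mean mu, dispersion
# disp, with optional log2 fold change in a leading subset of genes.
nb_counts <- function(ng, mu = 500, disp = 0.05, lfc = 0, n_de = 0,
                      n_per_group = 3) {
  # the leading n_de genes are identical replicates of the scenario of
  # interest (mean mu, true log2FC lfc); the remainder is a null background
  # with spread means so the dispersion trend is estimable
  mu_gene <- rep(mu, ng)
  if (ng > n_de) {
    mu_gene[(n_de + 1):ng] <- exp(rnorm(ng - n_de, log(mu), 1))
  }
  # injected effects are split half up, half down so median-of-ratios
  # normalisation stays unbiased
  mu_case <- mu_gene
  if (n_de > 0) {
    half <- ceiling(n_de / 2)
    mu_case[seq_len(half)] <- mu * 2^lfc
    mu_case[(half + 1):n_de] <- mu * 2^-lfc
  }
  ctrl <- matrix(rnbinom(ng * n_per_group, mu = mu_gene, size = 1 / disp), ng)
  case <- matrix(rnbinom(ng * n_per_group, mu = mu_case, size = 1 / disp), ng)
  m <- cbind(ctrl, case)
  dimnames(m) <- list(sprintf("g%05d", seq_len(ng)),
                      paste0("s", seq_len(2 * n_per_group)))
  m
}

de_groups <- function(n_per_group = 3) {
  factor(rep(c("ctrl", "case"), each = n_per_group), levels = c("ctrl", "case"))
}
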