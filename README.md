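# orabench

Overrepresentation analysis (ORA) with the two places popular tools
silently go wrong made explicit — plus the machinery to measure what those
bugs cost.

ORA tests, for every set in a gene-set library, whether a foreground list
of selected genes (say, the significant hits of a differential-expression
analysis) overlaps the set more than expected given a background universe
of detected genes. The test is the upper-tail hypergeometric probability
`P(X >= k)` for `X ~ Hypergeom(N, K, n)` — one-sided Fisher on the 2x2
table — with fold enrichment `(k/n)/(K/N)` as the effect size and
Benjamini–Hochberg correction across sets.

Two defects are widespread in deployed ORA tools:

* **the background problem** — background genes not annotated to any set
  are silently dropped from the universe, shrinking `N` and deflating
  every enrichment score and p-value;
* **the FDR problem** — sets with zero foreground overlap are discarded
  *before* multiple-testing correction, understating the number of tests
  and deflating FDR values, which inflates false positives.

`orabench` implements correct ORA, both failure modes as switchable
configuration (`ora_mode("correct" | "bug-bg" | "bug-fdr" | "bug-both")`),
and the two published workarounds — appending the background as a gene set,
and padding the p-value list with 1s before re-adjustment — which the test
suite proves reproduce the correct analysis *exactly*. Around that core it
ships a negative-binomial Wald differential-expression stand-in, a
preranked functional-class-scoring (FCS) comparator, an RNA-seq count
simulator with pathway-level ground truth, and benchmarking tools that
score every analysis mode by signed precision/recall/F1.

Audience: bioinformaticians who interpret enrichment results, method
developers who want a controlled harness for ORA behaviour, and anyone who
needs to know whether a published ORA result would survive a correct
background and a correct FDR correction.

## Worked example

A 20-gene background where genes g11–g20 are annotated to no set, and a
foreground of three genes all inside set S1:

```r
library(orabench)

lib <- gs_library(
  c("S1", "S2", "S3"),
  list(paste0("g", 1:5), paste0("g", 6:10), paste0("g", 21:25))
)
fg <- paste0("g", 1:3)
bg <- paste0("g", 1:20)

tidy(run_ora(lib, fg, bg, ora_mode("correct")))
#> # A tibble: 2 x 9
#>   set_id     k     n     K     N p_value fold_enrichment    fdr overlap
#>   <chr>  <int> <int> <int> <int>   <dbl>           <dbl>  <dbl> <chr>
#> 1 S1         3     3     5    20 0.00877               4 0.0175 g1,g2,g3
#> 2 S2         0     3     5    20 1                     0 1      ""
```

S1's p-value is `C(5,3)/C(20,3) = 10/1140 ≈ 0.00877`; S2 was tested (zero
overlap is still a test) and S3 is excluded — none of its members are
detected. The buggy modes change exactly what the theory predicts:

```r
tidy(run_ora(lib, fg, bg, ora_mode("bug-bg")))[, c("set_id", "N", "p_value")]
#> 1 S1        10  0.0833   # universe shrank to the 10 annotated genes
#> 2 S2        10  1

tidy(run_ora(lib, fg, bg, ora_mode("bug-fdr")))[, c("set_id", "p_value", "fdr")]
#> 1 S1     0.00877 0.00877  # S2 vanished before BH, so m = 1 and the FDR halves
```

Under `bug-bg` the same overlap now looks ~9.5x less surprising
(`p = 10/120`); under `bug-fdr` the FDR drops from 0.0175 to 0.00877
because only one test was counted. `append_universe_set()` and
`apply_fdr_workaround()` undo these exactly.

The simulation benchmark compares correct/buggy/fixed ORA and the FCS
comparator against generated pathway truth:

```r
baseline <- synthetic_baseline(20000, seed = 1)
study <- run_simulation_study(baseline, sim_config(), n_reps = 20,
                              noise_grid = c(0, 0.4), seed = 1,
                              fcs_n_perm = 10000)
glance(study)    # per method x noise: mean precision/recall/F1 with MC SEs
plot_study_metrics(study)
```

Typical behaviour (visible already at modest replicate counts): at noise
0.4 the FCS arm keeps recall near 1 while every ORA variant's recall falls
below ~0.15, and the doubly-buggy default loses precision fastest — the
FDR problem, not the background problem, drives most of the damage.

## Command line

A thin CLI wraps the same functions (`inst/cli/orabench.R`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","orabench.R",package="orabench"))')" \
    ora --foreground fg.txt --background bg.txt --gmt sets.gmt \
        --mode correct --out results.tsv
```

Subcommands: `ora`, `de`, `fcs`, `simulate`, `benchmark`, `sweep`,
`downsample`, `compare`, `fixture`. Every output TSV starts with `#`
header lines carrying the tool version, a configuration hash and the seed;
`fixture` writes a self-contained toy workspace (the example above plus a
small simulated experiment) for experimentation.

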