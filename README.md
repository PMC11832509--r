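# sembeddings

Pre-data screening of questionnaire measurement models from item-embedding
similarities.

## The problem

Scale developers normally learn that two items are redundant, or that a
scale is secretly two-dimensional, only after collecting hundreds of
responses and watching a confirmatory factor analysis (CFA) misfit. Yet much
of that structure is encoded in the items' wording. Sentence-embedding
models map item texts to vectors whose cosine similarities approximate
inter-item correlations; treating the item-by-item cosine-similarity matrix
`S` as a pseudo-correlation matrix lets you fit the intended measurement
model *before* any data collection and catch structural problems while
editing an item is still free.

`sembeddings` implements that screening procedure for R, tidyverse-style:
item tables in and tibbles out, with `tidy()`/`glance()` methods on fitted
models and `autoplot()` methods on screening results.

## The model

For items assigned to factors by a loading pattern, the package fits the
standard CFA covariance structure

```
Sigma(theta) = Lambda Phi Lambda' + Theta
```

by minimizing the maximum-likelihood discrepancy

```
F = log|Sigma| - log|S| + tr(S Sigma^-1) - p
```

with factor variances fixed to 1 (correlation-scale identification). A
nominal sample size `n_pseudo` (default 10000) turns the discrepancy into a
chi-square statistic `T = (N-1) F`, from which CFI, TLI, SRMR and RMSEA are
computed against an independence baseline fitted by the same engine. A model
is flagged as a **misfit** when two or more indices are poor (CFI or
TLI < 0.90, SRMR or RMSEA > 0.08; all configurable). For misfitting scales,
modification indices — score-based or exact refit-based — rank the fixed
residual covariances and cross-loadings whose freeing would most improve
fit, annotated with both items' verbatim texts so the suggestion can be
judged on wording.

Validation batteries mirror how the procedure is stress-tested: a
*wrong-model battery* forces a single factor over every pair of scales
(k(k-1)/2 models; the fit indices should object), and a *verdict-agreement
experiment* measures how verdicts transfer from a noisy similarity proxy to
the true population matrix as proxy fidelity varies.

## Worked example

Simulate a 4-scale instrument in which one scale carries a hidden residual
correlation of 0.3 between its first and third items (the classic
redundant-wording defect), then screen every scale for unidimensionality on
the population matrix:

```r
library(sembeddings)

inj <- tibble::tibble(item_i = "q001", item_j = "q003", value = 0.3)
sim <- make_instrument(4, 4, seed = 42, injected_pairs = inj)
screen <- unidimensional_screen(sim$population_R, sim$items)
dplyr::select(tibble::as_tibble(screen),
              scale_id, chisq, df, cfi, tli, srmr, rmsea, verdict)
#> # A tibble: 4 × 8
#>   scale_id chisq    df   cfi   tli     srmr rmsea verdict
#>   <chr>    <dbl> <dbl> <dbl> <dbl>    <dbl> <dbl> <chr>
#> 1 scale_01 1676.     2 0.928 0.784 6.70e- 2 0.289 misfit
#> 2 scale_02    0      2 1     1.00  8.18e-10 0     adequate
#> 3 scale_03    0      2 1     1.00  1.63e- 9 0     adequate
#> 4 scale_04    0      2 1     1.00  4.70e- 9 0     adequate
```

The three clean scales fit perfectly (`chisq = 0`); the corrupted scale is
flagged by TLI and RMSEA. The report pairs each top modification index with
the item texts:

```r
cat(head(screen_report(screen, sim$items), 9), sep = "\n")
#> == scale_01 ==
#>   chisq = 1675.789 (df = 2)  CFI = 0.928  TLI = 0.784  SRMR = 0.067  RMSEA = 0.289
#>   verdict: misfit (2 poor)
#>   top modification indices:
#>     1. residual_cov q001 ~~ q003  (MI = 1668.30)
#>        q001: "I often approach tasks related to trait area 01 (form 1)."
#>        q003: "People say I show the qualities of trait area 01 (form 3)."
#>     2. residual_cov q002 ~~ q004  (MI = 1668.30)
#>        q002: "I always enjoy situations involving trait area 01 (form 2)."
```

The injected pair q001–q003 attains the top index (MI ≈ 1668, the chi-square
drop from freeing that residual). Note the exact tie with the complementary
pair q002–q004: in a four-item scale the two partitions are statistically
equivalent explanations, so the report should be read together with the
wording. In a real workflow the researcher would now merge or reword one of
the near-duplicate items and re-screen — no data collection involved.

With real items you would replace the simulated matrix by embeddings from
any sentence-embedding model:

```r
items <- read_items("items.csv")              # item_id, scale_id, text
E     <- read_embeddings("embeddings.csv", items)  # one vector per item
S     <- cosine_similarity_matrix(E)
cross_loading_screen(S, items)                 # jingle-jangle check
unidimensional_screen(S, items)                # per-scale CFA verdicts
wrong_model_battery(S, items)                  # misfit-detection control
```

A thin command-line front end over the same functions lives at
`inst/cli/sembeddings.R` (subcommands `run`, `similarity`, `crossload`,
`screen`, `battery`, `compare-matrices`, `simulate`), and `run_pipeline()`
executes the whole workflow from a YAML config, writing a manifest with
content hashes.

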