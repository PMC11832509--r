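---
title: "Screening measurement models from item-embedding similarities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening measurement models from item-embedding similarities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sembeddings)
```

## The idea

Questionnaire development usually discovers structural problems — redundant
items, scales that split into two facets, items that belong to a different
construct — only after data collection, when a confirmatory factor analysis
(CFA) on the empirical correlation matrix misfits. The lexical premise behind
this package is that much of that structure is already visible in the items'
wording: sentence-embedding models map item texts to vectors whose cosine
similarities behave like a noisy proxy for inter-item correlations. If the
similarity matrix of a drafted item pool is treated as a pseudo-correlation
matrix, the intended measurement model can be fitted to it *before* any
respondent is recruited, and gross misspecification can be caught while
changing an item is still free.

The package implements that screening procedure end to end:

1. read an item table (id, scale, verbatim text) and an externally produced
   embedding matrix;
2. build the cosine-similarity matrix and inspect it descriptively for
   cross-scale similarity (jingle-jangle candidates);
3. fit one single-factor CFA per scale on the scale's similarity submatrix,
   judge each fit with conventional indices, and inspect modification indices
   of misfitting scales with the item texts attached;
4. optionally run a wrong-model battery (one factor forced over every pair of
   scales) as a positive control that the procedure can detect misfit at all.

Embedding models themselves stay outside the package behind a provider
contract (`embed_items()` takes any function mapping texts to fixed-length
numeric rows); tests and examples use mock providers and simulated matrices.

## The fitting engine

The engine minimizes the normal-theory maximum-likelihood discrepancy

$$F(\theta) = \log|\Sigma(\theta)| - \log|S| +
  \operatorname{tr}\!\big(S\,\Sigma(\theta)^{-1}\big) - p,$$

with $\Sigma = \Lambda \Phi \Lambda^\top + \Theta$, over the free loadings in
$\Lambda$, factor correlations in $\Phi$ and residual (co)variances in
$\Theta$. Because the input is on the correlation scale, identification fixes
factor variances to 1 and leaves all patterned loadings free; this avoids the
arbitrariness of a marker item and makes $\Phi$ directly interpretable as
factor correlations.

A similarity matrix is not an estimated covariance matrix, so there is no
sample size; a nominal `n_pseudo` (default 10000) converts the discrepancy to
a chi-square statistic $T = (N-1)\,\hat F$ on the usual scale, and all
chi-square-based indices inherit it. The default follows the screening
convention of using a large nominal N so that index behavior is dominated by
the discrepancy, not by N.

Numerical choices:

* **Optimizer.** Quasi-Newton (`nlminb`) with the analytic gradient
  $\partial F/\partial\theta_k = \operatorname{tr}[(\Sigma^{-1} -
  \Sigma^{-1} S \Sigma^{-1})\,\partial\Sigma/\partial\theta_k]$, started from
  $\lambda^{(0)} = \sqrt{\bar r_{\text{within}}}$, $\theta^{(0)} = 1 -
  \lambda^{(0)2}$, $\phi^{(0)} = 0$. If the projected gradient norm is not
  below $10^{-7}$ after the quasi-Newton run, a few Fisher-scoring steps on
  the expected information polish the solution. A fit whose projected
  gradient norm stays above $10^{-6}$ is returned with `converged = FALSE`
  and a warning — never a silent success.
* **Heywood cases.** Residual variances are box-bounded below at $10^{-4}$;
  estimates at the bound are reported in `$heywood`. Deliberately
  misspecified models must still yield indices (the wrong-model battery
  produces CFI values down to roughly 0.5 on simulated populations), so
  boundary solutions are flagged rather than aborted.
* **Near-singular input.** Similarity submatrices can be numerically
  singular (e.g. two near-identical item texts). If the smallest eigenvalue
  falls below $10^{-8}$ the matrix is ridged and renormalized to unit
  diagonal, and the ridge is recorded in the fit object.
* **Baseline model.** CFI and TLI compare against the independence model
  ($\Sigma_b$ diagonal, variances free) fitted by the same engine, so the
  baseline statistic is internally consistent with the target statistic. On
  unit-diagonal input its optimum has the closed form $F_b = -\log|S|$,
  which the test suite exploits as an independent check.

## Fit indices and the misfit rule

`fit_indices()` computes

* $\mathrm{CFI} = 1 - \max(T - df, 0)\,/\,\max(T_b - df_b,\, T - df,\, 0)$,
* $\mathrm{TLI} = \big(\tfrac{T_b}{df_b} - \tfrac{T}{df}\big)\big/
  \big(\tfrac{T_b}{df_b} - 1\big)$, deliberately uncapped (screening
  batteries produce TLI values outside $[0,1]$, which is informative),
* $\mathrm{RMSEA} = \sqrt{\max(T - df, 0)\,/\,(df\,(N-1))}$,
* SRMR as the root mean square of standardized residuals
  $(s_{ij}-\hat\sigma_{ij})/\sqrt{s_{ii}s_{jj}}$ over the lower triangle
  *including* the diagonal. SRMR has several variants in circulation; the
  diagonal-inclusive form is stated here precisely so that tests can be
  exact. With free residual variances the diagonal residuals are near zero,
  so the variant choice moves third decimals only.

For a saturated model ($df = 0$) TLI and RMSEA are undefined and reported as
`NA`, never as 0 — a just-identified triad "fits perfectly" only in the
trivial sense, and the verdict logic counts an `NA` index as not-poor while
flagging it.

`classify_fit()` applies the screening rule: an index is poor when CFI or
TLI < 0.90 or SRMR or RMSEA > 0.08, and a model misfits when **two or more**
indices are poor. Both cutoffs and the rule's threshold are deliberately
non-stringent: the screen is meant to catch substantial misspecification in
a proxy matrix, not to certify fit. All cutoffs are configurable.

## Modification indices

Both classical routes are implemented, because they answer slightly
different questions and their agreement is itself a useful diagnostic:

* `method = "refit"` frees one candidate parameter, refits, and reports the
  exact chi-square drop. It is the definition of the quantity, at the cost
  of one optimization per candidate.
* `method = "score"` computes the univariate expected-information score
  statistic $\tfrac{N-1}{2}\, g_k^2 / (d_{kk} - d_{kf} D_{ff}^{-1} d_{fk})$
  at the restricted solution. It needs no refitting and approaches the
  refit value as the freed estimate goes to zero; across simulated misfits
  with injected residual correlations of 0.15–0.30 the two agree within
  about 6–8% on the top candidate.

The candidate set contains all fixed-to-zero residual covariances plus, in
multi-factor models, all fixed cross-loadings. No multiple-testing
correction is applied: modification indices here are descriptive screening
output, ranked and annotated with both items' verbatim texts, and the
decision to act on one belongs to the researcher.

One structural caveat that the tests encode explicitly: in a four-item
single-factor model, a residual correlation between items $\{1,2\}$ is
statistically indistinguishable at population level from one between the
complementary pair $\{3,4\}$ — both refits absorb the same misfit, so their
modification indices tie exactly. Reports should therefore be read as "this
pair *or its complement*", which is also how diagnosed four-item scales
behave in practice (the two tied pairs typically partition the scale into
its two wording clusters).

## The synthetic-data module

Since real embeddings and respondent data are external, the package ships a
generator that emulates the screening setting:

* `make_instrument()` builds an `n_scales × items_per_scale` instrument
  (default shape 24 × 4, mirroring a full-length character-strengths style
  inventory). Loadings are drawn uniformly from (0.5, 0.85) and factor
  correlations from (0.1, 0.5) — values a psychometrician would call typical
  for moderately reliable trait scales; both ranges are parameters. Local
  misfit is injected as residual correlations on chosen item pairs, checked
  against residual-matrix positive semidefiniteness before use.
* `sample_responses()` draws latent multivariate-normal scores and
  discretizes them into 5-point Likert categories at standard-normal
  thresholds (default: equal-probability quintile cuts, a symmetric choice
  that centers responses at 3).
* `pseudo_similarity()` manufactures a proxy matrix whose lower-triangle
  correlation with the source is controlled: seeded Gaussian noise on the
  off-diagonal, iteratively rescaled until the achieved agreement is within
  0.03 of the target, then eigenvalue-clipped and renormalized to a valid
  unit-diagonal PSD matrix. The noise is additive Gaussian because no
  generative model of embedding error is available; what matters for the
  experiments is the *agreement knob*, not the noise shape. Empirically
  reported embedding-vs-correlation agreement sits around $r \approx 0.67$,
  which is the default target in `write_simulation()`.
* `verdict_agreement_experiment()` is the validation loop: generate a proxy
  at a given fidelity, screen both the proxy and the true population matrix,
  and cross-classify the verdicts over replicates. At fidelity 1.0 the arms
  agree exactly by construction; disagreement grows as fidelity drops (about
  9% of scale-verdicts at 0.9 and 21% at 0.8 under the default experiment in
  `scripts/acceptance.R`).

What the generator does **not** emulate: method variance and acquiescence
styles, non-normal latent traits, unmodeled cross-loadings in the
population, and any text-to-embedding stage (pseudo-similarity perturbs the
population matrix directly). Passing simulation experiments therefore shows
that the screening machinery is correct and that verdict transfer degrades
gracefully with proxy fidelity — not that any particular embedding model
achieves a given fidelity on real items.

## Problem sizes and determinism

All randomness flows from explicit integer seeds; screens and reports are
deterministic given their inputs, and the pipeline manifest records MD5
hashes so reruns are verifiable. The validation experiments use sizes chosen
to exercise the full instrument shape while staying desk-scale: the
wrong-model battery fits all 276 scale-pair models of a 24-scale instrument;
recovery and oracle checks use 20 random 4–8 item models each; the
verdict-agreement experiment runs 50 replicates per fidelity on the 96-item
instrument.

## Known limitations

* The engine is a screening fitter, not a general SEM package: no standard
  errors, no robust or categorical estimators, no multigroup models. For
  single-factor and few-factor measurement models on (pseudo-)correlation
  matrices it agrees with an established ML factor-analysis implementation
  to well under $10^{-3}$ on every index.
* The two-or-more-poor rule is descriptive. Verdicts on a proxy matrix are
  conservative in one direction only under high fidelity; with a noisy
  proxy, false alarms occur (and did occur in the CLI example in the
  README), which is why misfit reports always carry modification indices
  and item texts rather than a bare verdict.
* Scales need at least three items to be screened at all, and four for a
  testable ($df > 0$) unidimensional model; three-item scales are fitted
  just-identified and judged only on SRMR/CFI.
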