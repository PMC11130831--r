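---
title: "Multinomial mixed-link models for gastric IM risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multinomial mixed-link models for gastric IM risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmlink)
```

## The modelling problem

Gastric intestinal metaplasia (IM) is a precancerous replacement of the
stomach mucosa by intestinal-type epithelium.  The response modelled here is
a three-level risk label per tissue sample — Normal, MIM (mild IM, low
risk) and IM (high risk) — and the predictors are the sample's mitotic age
and its gastric-atrophy grade.  Mitotic age enters as TNSC, the total
number of stem-cell divisions per stem cell estimated from DNA-methylation
beta values by the simplified epiTOC2 clock

$$\mathrm{TNSC}(s) = \frac{1}{n_c} \sum_{i=1}^{n_c}
  \frac{2\,\beta_{is}}{\delta_i},$$

a weighted average over the clock's $n_c = 163$ PRC2-marked CpG sites,
where $\beta_{is} \in [0,1]$ is the methylation fraction of CpG $i$ in
sample $s$ and $\delta_i$ the site's probability of de novo methylation.
TNSC for gastric tissue sits on a scale of thousands to tens of thousands
of divisions.  Gastric atrophy is a five-level factor (Marked, Moderate,
Mild, Negative, Unknown), dummy-coded with Marked as baseline; a
three-level restriction (Negative baseline) applies after dropping the
sparse Marked and uninformative Unknown classes.

## Mixed-link multinomial regression

With categories $j = 1, \dots, J$ ($J = 3$; category $J$, IM, is the
baseline), a model is defined by three choices:

1. **Structure** — which category ratio $\rho_{ij}$ is modelled:
   baseline-category $\pi_{ij}/(\pi_{ij} + \pi_{iJ})$, cumulative
   $\pi_{i1} + \cdots + \pi_{ij}$, adjacent-categories
   $\pi_{ij}/(\pi_{ij} + \pi_{i,j+1})$, or continuation-ratio
   $\pi_{ij}/(\pi_{ij} + \cdots + \pi_{iJ})$.  All four share the matrix
   form $\rho_{ij} = L_j^T\pi_i\,/\,(R_j^T\pi_i + \pi_{iJ} b_j)$ with
   constant 0/1 matrices returned by `structure_matrices()`.
2. **Links** — one function $g_j$ per comparison, from
   logit, probit, loglog ($-\log(-\log\rho)$) and cloglog
   ($\log(-\log(1-\rho))$).  Allowing *different* links across $j$ is the
   point of the mixed-link family: classical multinomial logit, cumulative
   link and continuation-ratio models are the equal-link special cases.
3. **Odds type** — nonproportional odds (npo), $g_j(\rho_{ij}) =
   \beta_{0j} + \beta_j^T x_i$, with $p = (d+1)(J-1)$ parameters; or
   proportional odds (po), sharing one slope vector, $p = d + J - 1$.

With 4 structures, $4^{J-1}$ link assignments and 2 odds types, $J = 3$
gives the 128-candidate space that `enumerate_candidates()` spans and
`select_best()` ranks.

## Likelihood, scoring and its numerics

Responses at covariate setting $x_i$ are
$Y_i \sim \mathrm{Multinomial}(n_i; \pi_{i1}, \dots, \pi_{iJ})$, giving
$\ell(\theta) = \sum_i \sum_j Y_{ij} \log \pi_{ij}(\theta)$ up to a
constant.  `fit_mle()` maximizes this by Fisher scoring with the chain-rule
Jacobian $\eta \to \rho \to \pi$ (closed-form structure Jacobians, verified
against central differences in the tests) and step-halving line search.
Numerical choices that matter:

* **Covariate standardization.**  TNSC has scale $10^4$, which makes the
  raw-parameterization information matrix numerically singular.  Fitting
  internally standardizes each covariate (centre, unit SD) and maps
  coefficients and covariance back exactly afterwards.
* **Convergence** is declared on the Newton decrement
  $\mathrm{nd}^2 = s^T \mathcal{I}^{-1} s / 2$ (the expected attainable
  likelihood gain), which is invariant to covariate scale, with tolerance
  $10^{-12}$, plus a relative log-likelihood change below $10^{-10}$; at
  most 200 iterations.
* **Feasibility.**  Cumulative models require increasing $\rho_{i1} <
  \rho_{i2}$; infeasible iterates score $-\infty$ and the line search
  halves through them.  Repeated negligible gains or steps surviving only
  extreme halving indicate a likelihood asymptote (quasi-separation) and
  stop the loop early, flagged as non-converged.
* **Fallbacks.**  If scoring stalls away from a stationary point, a BFGS
  pass with the analytic gradient is tried; on small instances
  ($m \le 500$) where an optimum pressed against the cumulative
  feasibility boundary defeats gradient methods, a restarted penalized
  Nelder–Mead polish follows.  `optim()`'s reported minimum is never
  trusted without re-evaluating the likelihood at the returned point,
  which can be infeasible.
* **Probability clipping.**  Inverse links clip at $10^{-12}$ from the
  boundary so likelihood logarithms stay finite.  A consequence worth
  stating: link round trips $g(g^{-1}(\eta)) = \eta$ are exact only on the
  range where double precision resolves the saturating tail (roughly
  $|\eta| \lesssim 18$ for logit/loglog/cloglog, $\lesssim 5.5$ for probit
  upper tail); the tests assert the round trip there.
* **Covariance.**  The reported `vcov` inverts the observed information,
  obtained by central-difference differentiation of the analytic score
  with per-coordinate steps scaled by each coordinate's
  $\eta$-sensitivity; if not positive definite the expected information is
  used, then a pseudo-inverse with a `singular_vcov` flag.  Wald intervals
  and p-values (`wald_inference()`) follow the usual normal approximation.

Grouped counts and individual-level rows (all $n_i = 1$, the study design)
are both supported; grouping is an optimization, not a semantic change.

## Model selection and cross-validation

`information_criteria()` implements $\mathrm{AIC} = -2\hat\ell + 2p$ and
$\mathrm{BIC} = -2\hat\ell + p\log n$, so $\mathrm{BIC} - \mathrm{AIC} =
(\log n - 2)\,p$ exactly — a rowwise identity asserted on every sweep
report.  `select_best()` fits all candidates, ranks by the chosen
criterion (AIC recommended at these sample sizes), breaks ties by smaller
$p$ then spec label, keeps non-convergent candidates flagged and ranked
last rather than silently dropping them, and summarizes the best link pair
per (structure, odds) group — the shape of the study's selection tables.

Out-of-sample comparison uses $k$-fold cross-validated cross-entropy,
$CE(B) = -\tfrac1n \sum_i \log \hat\pi_{i, y_i}^{(k(i))}$, with the model
family fixed across folds (no per-fold re-selection) and held-out
probabilities clipped at $10^{-12}$.  Partitions are unstratified balanced
random splits (`make_partition()`; stratification is deliberately not the
default, matching the plain random-partition design); ten partitions of
ten folds with seeds `seed_base + 0:9` are the default in `cv_compare()`.
Improvements are tested with a one-sided paired $t$-test across
partitions; the degenerate zero-variance case returns the limiting 0 or 1,
and all-zero differences are an error rather than a fabricated p-value.

## The synthetic-data generator

Real study data require a GEO download plus a clinical supplement, so the
package ships a generator that emulates the design instead:

* TNSC $\sim$ Uniform(2000, 20000).  The study's empirical TNSC
  distribution is not published; this range is where the selected models'
  linear predictors (intercepts ≈ 4–5, TNSC slope ≈ $-4\times10^{-4}$)
  traverse the informative probability region, which is what matters for
  recovery and selection experiments.
* Atrophy class probabilities (Marked 0.024, Moderate 0.2, Mild 0.3,
  Negative 0.29, Unknown 0.186) for the five-class design and (Negative
  0.37, Mild 0.38, Moderate 0.25) for the three-class design.  Only the
  Marked (3/124) and Unknown (23/124) class sizes are published; the
  remaining mass is split plausibly and is config-overridable.
* Labels are drawn per sample ($n_i = 1$) from `category_probs()` under
  one of the three selected models' published coefficients
  (`study_model()`), so ground truth is known exactly.
* The methylation route is emulated by a synthetic delta table
  (`synthetic_epitoc_params()`, $\delta \sim$ Uniform($2\times10^{-5}$,
  $8\times10^{-5}$), chosen so beta values in $[0,1]$ can realize TNSC up
  to $\sim 25000$) and `simulate_beta_matrix()`, which reproduces target
  TNSC scores exactly by construction plus weight-orthogonal jitter.

What passing tests on these data do **not** show: robustness to the real
450k platform's probe correlation and batch structure, to measurement
error in beta values, or to covariate distributions unlike the uniform
emulation.  The generator validates the statistical machinery, not the
biology.

## Problem sizes and open choices

Recovery experiments use 20 replicates of $n = 5000$ — large enough that
coefficient bias is measured against Monte-Carlo standard errors a few
percent of each effect, small enough that a full run takes seconds.  The
self-selection check sweeps all 128 candidates on 20 such replicates.  The
sample-size choices for the in-repo analysis scripts mirror the study
($n = 124$).

Where the design was genuinely open, the choices were: Wald (not
likelihood-ratio) inference, matching the single-coefficient report the
selected models need; per-fold refitting of a fixed spec rather than
per-fold re-selection; retaining flagged non-convergent sweeps; and
reporting confidence intervals as (lower, upper) ordered bounds.  Known
limitations: partial-proportional-odds and po–npo mixture models are out
of scope, as are the full epiTOC2 estimator (cell-replication-rate and age
terms), GEO retrieval and array preprocessing; quasi-separated fits are
reported honestly as non-converged rather than regularized.
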