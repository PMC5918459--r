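---
title: "Fuzzy generalized MDR: model, defaults and design notes"
author: "fgmdr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy generalized MDR: model, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmdr)
```

## The problem

Single-SNP association scans miss trait variation that is carried by
gene-gene interactions: two loci whose joint genotype predicts the trait
while neither locus shows a marginal effect.  Multifactor dimensionality
reduction (MDR) attacks this by pooling the $3^k$ genotype cells of a
$k$-SNP combination into high- and low-risk groups and scoring the pooled
binary classifier.  Two well-known limitations motivate this package:

* classical MDR handles only binary traits and cannot adjust for
  covariates such as sex, age or ancestry principal components, and
* the hard high/low split treats a cell barely above the threshold the
  same as one far above it, and cells on opposite sides of the threshold
  as maximally different, however close their risk estimates are.

The generalized MDR (GMDR) family fixes the first problem by replacing
case/control counts with score residuals from a null generalized linear
model.  The fuzzy variant implemented here (FGMDR) fixes the second by
grading cell membership in the high- and low-risk groups continuously.

## Scores from the null model

For trait $y_i$ with expectation $\mu_i$ the covariate-only model is
$l(\mu_i) = \alpha + z_i^\top\gamma$ — identity link and least squares for
a continuous trait, logit link and maximum likelihood for a binary one.
Genotypes never enter this fit, so the residuals carry whatever signal the
interaction search is looking for.  Each sample gets a studentized score

$$S_i = \frac{y_i - \hat\mu_i}{\sqrt{\widehat{\mathrm{Var}}(y_i - \hat\mu_i)}}.$$

`studentized_scores()` defaults to internal studentization: the gaussian
residual divided by $\hat\sigma\sqrt{1-h_i}$ with $h_i$ the leverage, and
the leverage-adjusted Pearson residual in the binomial case.  The
denominator variant is a choice the method's description leaves open; the
`variant` argument (`"internal"`, `"pearson"`, `"none"`) exposes the
alternatives, and all downstream quantities are invariant to a global
positive rescaling of the scores (thresholds scale along), so the choice
mainly matters for interpretability of the default membership band.
Without covariates and with a binary trait, the score's sign is the
case/control label — which is exactly why classical MDR and FMDR are the
covariate-free special cases of the score-based search (`method = "mdr"`
and `"fmdr"` in `search_config()`).  This score-based unification is also
what lets "MDR" run on a continuous trait at all, which the count-based
original cannot do.

Degenerate inputs fail loudly: a covariate set that fits the trait
perfectly leaves no residual variance and raises an error rather than
emitting all-zero scores, which would silently make every cell "tied".

## Cells, fuzzy membership and BA$_{\mathrm{FUZZY}}$

For a combination of $k$ SNPs (additively coded 0/1/2), every sample with
complete genotypes falls into one of $3^k$ cells; cell $j$ collects

* $S^j_{+1}$: the sum of its nonnegative scores (`pos_sum`),
* $|S^j_{+0}|$: the magnitude of the sum of its negative scores
  (`neg_mag`), and
* $S^j_\bullet$: its mean score.

The high-risk membership of a cell is the piecewise sigmoid

$$\mu_H(s) = \begin{cases}
0 & s < t_l\\[2pt]
\dfrac{1}{1 + \left(\dfrac{s - t_h}{s - t_l}\right)^2} & t_l \le s < t_h\\[8pt]
1 & s \ge t_h
\end{cases}
\qquad \mu_L(s) = 1 - \mu_H(s),$$

continuous and monotone in $s$, with $\mu_H$ exactly $\tfrac12$ at the
band midpoint.  The four fuzzy confusion masses are membership-weighted
score masses summed over nonempty cells,

$$\mathrm{TP} = \sum_j S^j_{+1}\,\mu_H(S^j_\bullet),\quad
\mathrm{FN} = \sum_j S^j_{+1}\,\mu_L(S^j_\bullet),\quad
\mathrm{FP} = \sum_j |S^j_{+0}|\,\mu_H(S^j_\bullet),\quad
\mathrm{TN} = \sum_j |S^j_{+0}|\,\mu_L(S^j_\bullet),$$

and the ranking measure is the balanced accuracy
$\mathrm{BA}_{\mathrm{FUZZY}} = \tfrac12(\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})
+ \mathrm{TN}/(\mathrm{TN}+\mathrm{FP}))$.

Three conventions deserve emphasis:

* **Negative mass enters as a magnitude.**  Taking $S^j_{+0}$ literally as
  a (negative) sum would make FP and TN negative and push BA outside
  $[0,1]$; the magnitude convention keeps all four masses nonnegative and
  preserves the analogy with the case/control-count fuzzy MDR, where the
  two masses are the case and control counts of a cell.  With indicator
  membership the two conventions coincide up to sign bookkeeping.
* **Empty cells contribute nothing.**  They have no mean score, hence no
  defensible membership; this matches standard MDR practice of ignoring
  unobserved genotype combinations.
* **Ties go to H.**  A cell whose mean equals the crisp threshold is
  high-risk ("nonnegative" rule), implemented as `>=` everywhere,
  including inside the indicator membership.

With an indicator membership $\mu_H(s) = \mathbf{1}[s \ge T]$ the fuzzy
sums collapse to the crisp H/L partition sums, so
$\mathrm{BA}_{\mathrm{FUZZY}}$ *equals* the classical GMDR balanced
accuracy — bit-exactly, because multiplying by exact 0/1 weights and
adding exact zeros does not perturb floating-point sums.  The test suite
asserts this identity on a thousand randomized instances, and an
independent brute-force oracle (`brute_force_ba()`, direct per-sample
loops sharing no code with the production path) pins the sigmoid case to
within $10^{-12}$.

### Choosing $t_l$ and $t_h$

The band must be fixed a priori; no published choice exists to adopt, and
absolute results can be sensitive to it.  Two defaults are provided, both
zero-centred because score residuals are centred near zero:

* `default_thresholds(cell_means, spread)` builds a band from a supplied
  set of cell means — `spread` times their population (divide-by-$n$)
  standard deviation — for interactive use on a single combination, e.g.
  when drawing a cell report.
* The search and power pipelines fix **one band per analysis, before any
  combination is examined**: $t_h = c \cdot \hat\sigma_S / \sqrt{n/3^k}$,
  $t_l = -t_h$ — `spread` ($c$, default 1) standard errors of a typical
  cell mean, computed from the score vector (training scores, within each
  fold).  Cells whose mean lies within sampling noise of the threshold —
  exactly the "tied" cells that motivate the fuzzy extension — are the
  graded ones; cells beyond the band are effectively crisp.  A band must
  *not* be re-derived per combination from that combination's own cell
  means: doing so makes BA$_{\mathrm{FUZZY}}$ invariant to each pair's
  signal scale, so noise pairs are graded as favourably as the causal
  pair and the ranking degrades measurably.

Fixed `t_l`/`t_h` overrides are available everywhere; `spread = 0` (or
$t_l = t_h$) degenerates to the indicator, i.e. GMDR.  At $s = t_l$
exactly, the interior branch of $\mu_H$ is singular; the limit value 0 is
used, keeping the function continuous from the left branch.

## Search, cross-validation and model selection

`cross_validated_search()` evaluates every $\binom{p}{k}$ combination
under 10-fold cross-validation.  Scores are computed once on the full data
— the null model contains no genotype terms, so full-data residuals leak
none of the tested signal; per-fold refitting is available as
`refit_scores = TRUE` and changes little.  Folds are seed-deterministic,
near-equal in size, and stratified by case/control status for binary
traits.  Within a fold, combinations are ranked by training BA; the fold
winner is recorded, and cross-validation consistency (CVC) counts the
folds each combination wins, so CVC sums to the fold count.  Testing BA
drops held-out samples into the training-defined cells with
training-learned memberships.  Two situations the method's description
leaves open are resolved as follows:

* a test cell that was empty in training contributes nothing (no
  membership exists for it);
* a test fold whose retained cells carry only positive or only negative
  score mass has no defined BA; the fold is dropped from that
  combination's testing mean (at the default 10 folds and $n \ge 200$
  this is essentially never triggered).

The best model maximizes CVC, tie-broken by testing BA and then
lexicographic SNP order.  "Minimum prediction error and maximum CVC" has
no stated precedence; CVC-first matches how reported models are described
(selected for high consistency, then judged on testing accuracy).
Searches beyond `max_combinations` (default $10^5$) are refused with
advice to pre-filter candidate SNPs — the method is routinely applied to
10–30 pre-selected candidates rather than genome-wide.

## The simulator

`make_penetrance_model()` builds two-locus 3×3 penetrance tables with *no
marginal effects*: a named epistasis pattern (XOR, dominant-dominant,
recessive-recessive, additive-product, threshold) is double-centred under
the Hardy-Weinberg cell weights of the causal MAF and scaled around a
constant baseline (0.5) to hit a target heritability
$h^2 = \mathrm{Var}_g / (\bar f(1-\bar f))$, the HWE-weighted variance of
the table relative to its Bernoulli variance.  This penetrance-scale
definition is scenario-independent, so one model can drive all three
scenarios.  The classical catalogue of 70 such tables is an external
publication and is not bundled; `read_penetrance_model()` loads
user-supplied tables for exact reproduction.  Note that the attainable
$h^2$ range depends on pattern and MAF (a recessive-recessive interaction
at MAF 0.2 concentrates its signal on a cell of HWE weight $0.04^2$, so
its ceiling is below 0.002); unattainable targets raise an error stating
the maximum.

The three scenarios share the population model — genetic effect
$X_i \sim N(f(g_{i1}, g_{i2}), 0.1)$, covariate $Z_i \sim N(0, 0.7^2)$,
$\alpha = 0$, $\beta = \gamma = 1$, causal pair at HWE with the model MAF,
non-causal SNPs at HWE with MAFs uniform on $[0.05, 0.5]$, defaults
$n = 2000$, $p = 100$ — and differ in the trait:

1. **Continuous:** $Y_i = \alpha + \beta X_i + \gamma Z_i + \varepsilon_i$,
   $\varepsilon_i \sim N(0, 1)$.
2. **Dichotomized:** the same latent value with error sd 0.5, thresholded
   at its per-replicate median (exactly 1000/1000 at $n = 2000$).
3. **Logit:** $\mathrm{logit}\,P(Y_i{=}1) = \alpha + 0.5\,X_i + \gamma Z_i
   + \varepsilon_i$ with $\varepsilon_i \sim N(0, 2^2)$ inside the linear
   predictor (an over-dispersion device, retained as stated), sampled by
   rejection to exact case/control quotas.

Everything is bit-reproducible from one seed.  What the generator does
*not* emulate: linkage disequilibrium between SNPs, population structure,
genotyping error, missingness patterns, more-than-two-locus causal
models.  Power numbers obtained on these data therefore demonstrate the
ranking machinery, not performance on real cohorts.

## Power evaluation

`replicate_hit()` scores a replicate as a success iff the causal pair
attains the *strictly* highest BA among all pairs on the full data; ties
count as misses (conservative, and measure-zero for continuous scores).
Cross-validated ranking inside each replicate is available via
`with_cv = TRUE`; the cheap full-data reading is the default since the
power definition refers only to "highest BAs".  `estimate_power()` uses
seed `base_seed + r` for replicate $r$, and `power_grid()` evaluates all
methods on the *same* datasets so per-model powers are paired;
`compare_methods()` then applies the standard paired Wilcoxon signed-rank
test (zero differences dropped).

## Problem sizes used by the shipped checks

The packaged tests and `scripts/acceptance.R` run the full pipeline at
desk scale, chosen to keep a complete run in minutes while leaving the
study-scale defaults ($n = 2000$, $p = 100$, 100 replicates, 70 models)
untouched in the generator: power grids use $p = 20$ SNPs, 10–25
replicates, patterns XOR and dominant-dominant at MAF $\{0.2, 0.4\}$ and
$h^2 \in \{0.01, 0.05, 0.1, 0.2\}$ (plus an XOR cell at $h^2 = 0.4$,
MAF 0.4, where that target is attainable); null calibration runs at the
full $p = 100$.  What these runs show, and do not show: covariate-adjusted
methods clearly dominate covariate-blind ones whenever a real covariate
drives the trait, and the no-covariate fuzzy method does at least as well
as crisp MDR on the shipped grid.  The fuzzy-vs-crisp contrast itself is
small by nature: with the default band, FGMDR and GMDR produce identical
causal-pair rankings on the large majority of replicates, and their grid
mean powers differ by a few thousandths — within Monte-Carlo noise at
these replicate counts, and sensitive to the membership band, for which
no published value exists.  Absolute average powers likewise depend on
the band, the stand-in penetrance patterns and the scaled-down grid, and
match study-scale values only loosely.

## Known limitations

* Only gaussian and binomial traits; other exponential-family links would
  drop in at `fit_null_model()` but are unexercised.
* Exhaustive search only; no heuristic screening for large $p$.
* The default membership band is a reasoned convention, not an estimate;
  conclusions about a specific dataset should be checked across a small
  range of `spread` values.
* No significance test is attached to the selected model; CVC and testing
  BA are descriptive.
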