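---
title: "Base-calling flow-cycle pyrosequencing data with a weighted Hurdle Poisson model"
author: "hurdlecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-calling flow-cycle pyrosequencing data with a weighted Hurdle Poisson model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In flow-cycle sequencing-by-synthesis (the 454 pyrosequencing design and
its relatives), the four nucleotide solutions are washed over the plate in
a fixed, known order — here TACG by default, four flows per cycle. When the
flowed nucleotide matches the template, the whole homopolymer run is
incorporated at once and the emitted light scales with the number of
incorporated bases. Base-calling therefore reduces to estimating, for
every flow, a small non-negative integer: the homopolymer length (HPL).
Two features of the data shape everything that follows:

* **Excess zeros.** Roughly half of all flows interrogate a nucleotide
  that is not present at the template cursor; they produce only background
  optical noise.
* **Attenuation.** The signal increase per additional incorporated base
  shrinks as the run gets longer, so adjacent HPLs overlap more and more —
  homopolymer undercalls and overcalls are the dominant error mode, and
  they get worse with HPL.

`hurdlecall` treats calling as probabilistic classification over HPLs. The
payoff over rounding flowgram values is that the same per-flow probability
distribution that produces the call also produces quality scores that say
*which* error — undercall or overcall — is the likelier one.

## The count model

Let \(N\) be the HPL of one flow. The hurdle model splits zero and
positive counts:

\[
\Pr(N = n) =
\begin{cases}
1 - \Pi & n = 0\\
\Pi \, f_{ZTWP}(n; \lambda, \theta) & n \ge 1
\end{cases}
\]

with \(f_{ZTWP}\) the zero-truncated version of an exponentially weighted
Poisson density

\[
f_{WP}(n; \lambda, \theta) = w_n \frac{e^{-\lambda}\lambda^n}{W\,n!},
\qquad w_n = e^{-\theta(\lambda - n)^2},
\qquad W = \sum_{m \ge 0} \frac{e^{-\lambda}\lambda^m w_m}{m!} .
\]

The weights pull mass toward counts near \(\lambda\); positive flow counts
are strongly *underdispersed* (variance well below the mean), which a
plain Poisson cannot represent. \(\theta = 0\) recovers the Poisson limit
and is admitted throughout so the reduction can be tested against closed
forms. \(\theta\) is a single global parameter; \(\Pi\) and \(\lambda\)
vary per flow through covariates.

Both linear predictors are additive models:
\(\mathrm{logit}(\Pi) = \beta_0 + \sum_j f_j(x_j)\) and
\(\log(\lambda) = \gamma_0 + \sum_j g_j(y_j)\), with smooth functions of
per-flow covariates. The intercepts are global constants: flow dependence
enters only through the covariates, otherwise the model would not be
identifiable.

### Covariates

From each read's ordered flows the package builds (see `build_features()`):
the current flowgram value `fg0`; the log2 raw intensity `lraw0`,
optionally centered on a read-specific baseline (the median log2 raw
intensity of the read's presumed zero flows, those with flowgram < 0.5,
falling back to the read median when fewer than 4 such flows exist);
cumulative sums of both over strictly earlier flows, which proxy
cycle/position effects; and flowgram values 1, 4 and 8 flows before and
after, which carry information about neighbouring homopolymers. Lags and
leads beyond the read boundary are filled with 0, the natural background
flowgram value. The default sets are `{fg0, lraw0, cum_fg, fg_lag1,
fg_lead1}` for the binomial part and all nine signal covariates for the
Poisson part; both are configurable through `feature_config()`, and the
raw-intensity terms can be dropped (the model remains valid without them,
at some cost in accuracy).

## Smooths, penalties, fitting

Each smooth is a cubic B-spline basis of dimension 10 with knots at the
covariate's quantiles, centered on its training column means so the
intercept is carried separately; outside the training range the basis is
extended *linearly*, so mild extrapolation cannot oscillate. Covariates
with too few distinct values degrade to plain linear terms.

The wiggliness penalty is a second-order difference penalty on the
coefficients, taken as **divided differences over the Greville
abscissae**. With non-uniform (quantile) knots, plain coefficient
differences penalize some strictly linear functions of the covariate; the
divided-difference form has exactly the constant and linear functions in
its null space, so as the smoothing parameter grows every smooth collapses
to an ordinary linear GLM term — a property the test suite checks against
`glm()`.

Both submodels are fitted by penalized iteratively reweighted least
squares (IRLS). For the Bernoulli part the score and curvature are the
usual \(z - \mu\) and \(\mu(1-\mu)\); for the zero-truncated weighted
Poisson part they are central finite differences (step `1e-3`) of the
per-flow log-likelihood in \(\eta = \log\lambda\), which keeps the code
independent of the algebra of \(W(\lambda,\theta)\). Every IRLS step is
halved until the penalized deviance does not increase, so the penalized
deviance is non-increasing across iterations (asserted in tests at
`1e-10`); convergence is a relative penalized-deviance change below
`1e-6`, capped at 100 iterations. The linear predictor of the Poisson part
is clipped to \([-10, 5]\) as an overflow guard (rates outside
\([e^{-10}, e^{5}]\) have no meaning for flow data); a warning reports a
clip that is still active at the optimum. Complete separation in the
binomial part — a real possibility, since clean flow data are nearly
separable in `fg0` — triggers a refit with a small ridge (`1e-6`) and a
warning.

A single smoothing parameter is shared by the smooths of a submodel and
chosen by approximate GCV, \(n D / (n - \mathrm{edf})^2\) on the working
model, over the log-spaced grid \(10^{-4} \dots 10^{4}\).

### Estimating the dispersion weight

\(\theta\) is estimated by profile likelihood: `estimate_theta()` refits
the Poisson part on the grid \(\{0, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6\}\) and
refines an interior argmax by golden-section search on \(\log\theta\)
(tolerance `1e-3`). Smoothing selection and the profile are alternated
once — smoothing parameter at \(\theta = 0\), profile, re-selection at
\(\hat\theta\) — rather than jointly optimized.

One boundary case needs care. On very clean data the positive counts are
nearly deterministic given the covariates, and the profile likelihood
rises monotonically in \(\theta\): the weighted Poisson approaches a point
mass at the integer nearest \(\lambda\), and the maximum sits at the
degenerate boundary \(\theta \to \infty\). The profile is therefore
allowed to expand geometrically past the top of the grid, but only up to
\(\theta_{\max} = -\log(10^{-15}) \approx 34.5\): at that value the weight
of a count one away from \(\lambda\) is already below the `1e-15` floor
applied to every reported probability, so a larger \(\theta\) cannot
change any emitted probability or quality score — it can only make the
internal distribution degenerate, which destroys the informativeness of
scores for the rare genuinely ambiguous flows. A flat profile (range
below `1e-6`) returns the smallest grid value with a warning.

## Calling and quality scores

`predict()` on a fitted model returns \(\hat\Pi\) and \(\hat\lambda\) per
flow (flows whose covariates fall outside three times the span observed in
training are flagged as extrapolated, but still scored).
`predict_probabilities()` assembles the distribution over HPLs
\(0 \dots n_{\max}\): the zero class gets exactly \(1 - \hat\Pi\) and the
positive classes share \(\hat\Pi\) proportionally to \(f_{ZTWP}\)
renormalized over \(1 \dots n_{\max}\) (the tail beyond \(n_{\max}\),
which defaults to the largest training HPL plus 3 with a floor of 12, is
negligible for flow-data rates). The call is the HPL of maximal
probability, with exact ties broken toward the smaller HPL — conservative
against overcalls.

For the \(k\)-th base of a called homopolymer, the two error tails are
\(P(N < k)\) — the probability the base is an overcall — and
\(P(N > k)\) — the probability at least one base is missing beyond
position \(k\). Tails are floored at `1e-15` before
\(-10\log_{10}\). The per-base Phred-like score is the rounded overcall
score, trimmed to \([0, 40]\); the signed combined score is
\(I_{dir}\times\mathrm{round}(\min(QS_{under}, QS_{over}))\) with
\(I_{dir} = -1\) exactly when the undercall score is strictly smaller, a
magnitude cap of 40, and rounding half away from zero (the rounding rule
is validated in the tests against worked examples whose printed scores
discriminate it from truncation). Position \(k = 0\) scores the no-base
situation of a zero call on the undercall side — something per-base Phred
scores cannot express at all. FASTQ (Sanger, Phred+33) carries the capped
per-base scores; signed and per-position scores go to a TSV sidecar,
since FASTQ cannot encode signs.

## The simulator

`simulate_flow_data()` generates desk-scale data with the phenomena the
model targets, and ground truth for evaluation:

* reference sequences with i.i.d. geometric homopolymer runs
  (`hpl_geometric_p = 0.7`, mean run length ≈ 1.43 — a realistic
  genomic run-length profile) and run nucleotides uniform among the three
  alternatives;
* flow conversion by walking the TACG flow order (each flow consumes the
  maximal matching run, emitting 0 for non-matching flows) — with uniform
  successor nucleotides the distance to the next productive flow is
  uniform on {1, 2, 3}, so about half of all flows are zero flows;
* signals: zero flows draw `raw = 2^N(5, 0.7)` and
  `flowgram = |N(0, 0.1)|`; productive flows draw
  `raw = 64 n^0.8 LogNormal(0, 0.25)` and
  `flowgram = n + N(0, 0.1 sqrt(n))` floored at 0. The sub-linear raw
  exponent (0.8) and the √n flowgram noise make adjacent HPLs overlap
  increasingly with n, reproducing the rising miscall rate with HPL
  (about 1–2% at HPL 4 and above 10% at HPL 7 under the defaults).

Every read derives its own RNG substream from the seed by counter, so a
read's data do not depend on how many reads are generated. A second mode,
`simulate_from_model()`, draws counts from a *specified* hurdle law
(Bernoulli plus inverse-CDF on the truncated ZTWP table) and is the basis
of the parameter-recovery and calibration tests.

What the simulator deliberately does not emulate: carry-forward /
incomplete-extension chemistry, spatial plate effects, adapter/key
sequences, or base composition bias. Passing the end-to-end tests
therefore shows that the estimator recovers the model from data with the
right zero/attenuation/underdispersion structure — not that it handles
every artefact of a real instrument run.

## Numerical choices

* Series over counts (normalizing constant, truncated normalizer,
  moments) stop once, past the mode, the next raw term falls below
  `1e-15` of the running sum, with a hard cap at n = 200; the vectorized
  fitting path uses the equivalent fixed bound
  \(\lambda + 12\sqrt{\lambda+1} + 15\). Tails decay factorially, so both
  agree with a brute-force 200-term oracle to `1e-10` on the tested grid.
* Probabilities are floored at `1e-15` in output files and before
  logarithms; score caps (40) and floors (0) are applied after rounding.
* The IRLS linear solve uses an escalating scaled ridge
  (`0, 1e-12, 1e-9, 1e-6` times the mean diagonal) only when the plain
  solve fails, which happens when the smoothing penalty dwarfs the data
  information.
* Training refuses fewer than 50 positive flows, an absent `ref_hpl`
  column, or single-class data for the binomial part; prediction refuses
  a feature configuration different from the training one.

## Scale of the checks

The test suite fits the model at the sizes the method is meant for while
staying desk-scale: parameter recovery uses 50,000 model-based flows
(recovering \(\Pi(x)\) to RMSE < 0.05, \(\lambda(x)\) to < 5% relative
RMSE over the central 90% of covariate mass, and \(\theta = 0.4\) within
±0.1), and the end-to-end check trains on 1,000 simulated reads —
matching the training-set size used for calibrating the method on real
reference runs — and evaluates on 2,000 held-out reads, asserting the
rise of per-HPL error rates and the calibration of predicted versus
observed quality scores (within 2 score units for groups of at least
1,000 bases).

## Limitations

The single global \(\theta\) ties the sharpness of the positive-count
distribution together across HPLs; when the true conditional noise scale
varies strongly with HPL the model is exactly calibrated only where the
data mass is. The quality of \(\hat\Pi\) and \(\hat\lambda\) outside the
training covariate range rests on linear basis extension and is flagged,
not guaranteed. Vendor binary formats are out of scope by design: the
ingestion contract is the documented flow-table TSV.
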