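---
title: "Context effects in review-stream choice: models, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context effects in review-stream choice: models, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A star rating shown next to a restaurant is not consumed in isolation: the
decision-maker sees a *choice set* — the similar, nearby alternatives — and
a long line of laboratory work indicates that option values are rescaled
relative to that context. This package implements the full observational
pipeline needed to detect such context effects in review-platform data
(choice-set reconstruction, time-indexed displayed ratings, context
statistics, mixed-effects regressions) together with a synthetic world in
which the ground-truth mechanisms are known, so that every stage can be
validated by parameter recovery rather than by faith.

## The two mechanisms

**Choice: divisive normalization + softmax.** An option displaying rating
$r_i$ in a set with ratings $r_1,\dots,r_n$ carries subjective value

$$v_i = \frac{r_i}{\sigma + \omega \sum_j r_j},$$

and is chosen with probability $p_i \propto \exp(v_i/\tau)$.

- $\sigma$ (stars, $>0$): semi-saturation; sets the value scale. Default 1.
- $\omega$ (unitless, $\ge 0$): context weight. $\omega = 0$ recovers plain
  logit, which satisfies independence of irrelevant alternatives (IIA): the
  top-vs-second choice *ratio* is independent of the remaining options.
  $\omega > 0$ compresses values as the pooled context grows, producing two
  signatures: fewer ratings-maximizing choices in higher-rated sets, and a
  top-vs-second ratio that falls as the "distractor" options improve.
  Default 0.5.
- $\tau$ (unitless, $>0$): softmax temperature. Default 0.05, calibrated to
  the normalized value scale (values are of order $0.1$–$0.5$ at the
  default $\sigma, \omega$), giving realistic, noisy-but-informative target
  rates. Note that $\tau$ is only meaningful relative to the value scale:
  an $\omega = 0$ world at $\tau = 0.05$ has values on the raw 1–5 star
  scale and is effectively deterministic; the package's null-world tests
  use $\tau = 0.5$ there so that the response varies.

**Rating: prediction error against a contextual expectation.** The emitted
rating for a chosen option with running mean $m_c$ in a context (other
options) with mean displayed rating $m_{-c}$ is

$$\text{rating} = u + \kappa\,(m_{-c} - 3), \qquad u \sim
\mathcal N(m_c,\ \sigma_u^2),$$

i.e. experienced utility minus an expectation that richer contexts lower in
proportion $\kappa$. The midpoint 3 anchors the 1–5 scale so that $\kappa$
*is* the slope of the expected rating deviation on the context mean.
Defaults: $\kappa = 0.4$, $\sigma_u = 0.7$ stars. In discretized mode
(default) ratings are rounded half-away-from-zero to whole stars and
clamped to $[1,5]$; in continuous mode they are returned unclamped so that
the closed form $E[\text{deviation} \mid m_{-c}] = \kappa\,(m_{-c}-3)$ is
exact — this is the mode the slope-recovery checks use, because clamping
attenuates (but never sign-flips) the slope near the scale boundaries.

## The stated world

The reference configuration (`world_config()` defaults) was chosen once and
is not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| cities × clusters × restaurants | 4 × 15 × 12 | ~60 neighborhoods, ~180 choice sets: binned statistics average over set composition instead of measuring the idiosyncrasy of a handful of sets; 12 per neighborhood matches observed real-world neighborhood densities (~11). |
| categories | 3 terms | (cluster × category) sets average ~4 members, the realistic 3–7 range. |
| users × events | 200 × 100 | ~20k decisions; every user passes the ≥ 100-review eligibility rule by construction. |
| seed reviews / restaurant | Poisson(25) | every option has a displayable rating before the stream starts; Poisson (not constant) counts because identical counts would make review-count covariates degenerate in the static check-in/order snapshots. |
| latent quality | $\mathcal N(3.7, 0.8)$ truncated to $[1,5]$ | 3.7 is the well-known platform-wide average rating. |
| prices | 30/40/20/10% over 1–4 dollar signs | typical platform composition. |

Users are assigned a home city and choose only among that city's sets with
at least 2 members, so the event stream has no mechanical skips and user
review counts are exactly the configured value.

**What the generator emulates:** the display pipeline (running means,
half-star rounding, leave-one-out timing), choice-set structure (spatial
clusters × inferred categories), four behavioral streams (reviews,
anonymous check-ins, static-rating delivery orders, a 135/135/5
choice/rating/catch lab session), and the two context mechanisms above.

**What it does not emulate:** natural language (review text is a bag of
category-term tokens, because only term counts are consumed downstream),
platform review filtering, social-network effects, temporal
non-stationarity of tastes, and any geographic realism beyond Gaussian
clusters. A green recovery test therefore establishes that the *analysis
code* measures what the *stated mechanisms* generate — not that real
consumers obey divisive normalization.

## Numerical conventions

- **Displayed rating**: running mean over strictly earlier reviews
  (`timestamp < t`), excluding the focal review even when stamped earlier,
  clamped into $[1,5]$ and rounded to the nearest half star with exact
  midpoints rounding up; idempotent on the 9-value lattice. Options with no
  prior reviews are omitted from snapshots (no displayable rating exists).
- **Timestamps** are unique per business by construction (a strict global
  event clock), so prefix means are always well defined.
- **Target choice**: chosen displayed rating equals the set maximum; ties
  count as target ("possibly non-unique highest-rated").
- **Set statistics**: population variance (the set is the full context, not
  a sample); `gap12` is the difference of the first two order statistics
  (tied maxima give 0); the distractor mean averages everything below the
  first two positions of the descending sort, ties included.
- **Distractor (IIA) analysis**: restricted to sets of ≥ 3 options where
  the chosen option sat in the top two *and the top two are not tied* —
  with a tie the top-vs-second response is undefined and the
  tie-counts-as-target convention would force `chose_top = TRUE`,
  biasing the distractor coefficient. Under $\omega = 0$ the conditional
  choice is a function of the gap alone, so the package's null checks
  condition on `gap12`; the unadjusted coefficient carries an
  omitted-variable (composition) bias that is not an IIA violation. In an
  $\omega = 0,\ \tau = 0.5$ world the gap-adjusted logit recovers the
  analytic gap slope $1/\tau$, a built-in correctness check.
- **Rating deviation** is `user_stars - raw_prior_mean_chosen` (signed,
  user minus mean) on the *unrounded* running mean — the deviation concerns
  the option's standing value, while all set-level context statistics use
  the rounded values users actually see. The rounded-vs-exact choice for
  set statistics is exposed as `use_rounded_display`.
- **Category inference**: case-insensitive whole-word (phrase) counts of
  each assigned term over the business's pooled review text; the umbrella
  term "Restaurants" identifies restaurants and never competes; ties break
  by count, then assigned-term position, then lexicographically; empty text
  falls back to the first term with a warning; umbrella-only businesses are
  excluded with a distinct error class.
- **DBSCAN**: Euclidean distance in raw decimal degrees (matching how the
  search radius is specified); one point per review, so restaurants enter
  with popularity multiplicity — duplicates are collapsed to weighted
  unique coordinates, which is exactly equivalent and keeps the pairwise
  cost at restaurant scale. Core points need `min_pts` (weighted) points in
  the closed `eps`-ball; border points join the first discovering cluster
  under the input order (deterministic); noise restaurants belong to no
  choice set. Tuning: `eps` is the median 8th-nearest-neighbor distance
  among a city's restaurant coordinates and `min_pts` is 1% of the city's
  review points (floor 3). `k = 8` is a one-time calibration: the tuned
  clustering of the reference world then carries a mean occupancy of ~12
  restaurants per neighborhood, bracketing the observed real-world density;
  `k = min_pts` (a literature heuristic) is degenerate here because
  `min_pts` counts review points while tuning runs on restaurant
  coordinates.

## Inference

`fit_mixed()` standardizes predictors internally and back-transforms all
estimates (including per-user effects) to the original predictor scale.
Count covariates enter as `log(x)`, text length as `log(x + 1)`.

- **`method = "mixed"`** (default): lme4 with every fixed effect also a
  per-user random effect (uncorrelated slopes). Logistic fits use
  `nAGQ = 0` — a small fixed-effect approximation bought for large
  speedups and robustness on big grouped tables; conditional modes (the
  subject effects) are unaffected.
- **`method = "fast"`**: pooled ML with a hand-rolled CR0 cluster-robust
  sandwich over users (with a $G/(G-1)$ correction). Logistic separation is
  detected and answered with a ridge-penalized IRLS refit (penalty matching
  a normal prior of scale 10 on standardized predictors) plus a warning.
- **`method = "mcmc"`**: a self-contained Metropolis-within-Gibbs sampler
  for the hierarchical model with diagonal random-effect covariance.
  Priors are weakly informative: $\beta_j \sim \mathcal N(0, 10^2)$ on
  standardized predictors and half-normal(5) on random-effect and residual
  SDs — proper but weak, avoiding improper-prior pathologies. Gaussian
  user coefficients are conjugate draws; logistic ones use an adaptive
  random-walk proposal tuned during warmup. Reported: posterior means,
  central 95% intervals, $2\min(P(\beta>0), P(\beta<0))$ tail
  probabilities, split-$\widehat R$ and a crude autocorrelation ESS. Fits
  with $\widehat R > 1.05$ are flagged, not silently returned.

Check-in and order streams carry no user identity, so their models are
pooled (`group = NULL`); the package never pretends random effects exist
where no grouping does. The experiment models use the MCMC engine in the
pipeline because the concordance analysis needs per-participant conditional
effects with non-degenerate spread: maximum-likelihood random-slope
variances can collapse to exactly zero, while posterior means cannot.

`concordance()` median-splits the choice-side subject effects, and fits a
Huber-loss IRLS regression (via `MASS::rlm`) of rating-side effects on
choice-side effects, with a case-resampling bootstrap two-sided p-value.

## The laboratory emulation and its power limit

`simulate_experiment()` draws participant-level $(\omega_p, \kappa_p)$ from
a bivariate normal with configurable SDs and correlation; choice trials run
the divisive-normalization model with $\omega_p$, rating trials report
0–100 expected satisfaction $a + b\,r - c_p\,(\text{context mean}) +
\text{noise}$ with $c_p \propto \kappa_p$, and catch trials (choose the
highest-rated option) are answered correctly up to a configurable lapse
rate, with the 60% accuracy rule enforced downstream.

One genuine limitation deserves emphasis, because the acceptance suite
reports it honestly as a failing check rather than hiding it. The
subject-level *choice* context effect — the per-participant regression
coefficient of target choice on set mean — is an intrinsically poor readout
of $\omega_p$ under this mechanism. The coefficient is non-monotone in
$\omega$: it grows from zero on a narrow ascending branch (roughly while
$\omega \sum_j r_j < \sigma$) and is then compressed away as normalization
flattens all values. Crucially, the regimes where the coefficient responds
to $\omega$ are the regimes where choice is nearly deterministic, so 135
binary trials pin each participant's coefficient down to a standard error
several times larger than the true between-participant spread, at every
$(\omega\text{-mean}, \omega\text{-SD}, \tau)$ combination we probed. The
rating-side subject effects recover well; the choice-side ones are mostly
shrinkage noise. Consequently the positive choice–rating concordance that
correlated $(\omega_p, \kappa_p)$ should produce is under-powered at 100
participants, and the corresponding acceptance assertions fail with
slopes fluctuating around zero. The defaults place participants on the
ascending branch ($\omega_p \sim \mathcal N(0.15, 0.10)$ truncated at 0,
lab temperature 0.02) where the readout direction is at least correct, and
the zero-correlation control is null — though partly for the same low-power
reason, which is why the concordance operation itself is additionally
validated on directly planted subject effects, where it recovers slope,
significance and outlier-robustness correctly.

## Known limitations

- The order-stream analysis identifies its context effect from only as
  many (city, cuisine) sets as the world contains (12 by default), so its
  coefficient is noisy and not part of the headline sign battery.
- Real-data coefficient values are not reproducible from synthetic worlds
  and are never targeted; only directions and recoverable generative
  parameters are asserted.
- The MCMC engine is built for experiment-scale data (hundreds of groups,
  tens of thousands of rows), not the full review stream; use the lme4 or
  fast paths there.
- Continuous-mode ratings may leave $[1,5]$ (by design, to keep the
  deviation slope exact); snapshot means are clamped before display
  rounding so the half-star lattice invariant always holds.
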