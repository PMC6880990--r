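---
title: "Screening the phenome for disease comorbidities: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening the phenome for disease comorbidities: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phescreen)
```

This vignette is the package's account of its statistical method, the choices
behind the implementation, and what the synthetic-data tests do and do not
establish about real medical-record data.

## The screening model

The unit of analysis is the *phecode*: a clinical phenotype grouping a set of
ICD-9 billing codes (for instance, a single depression phecode groups the
mild single-episode, mild recurrent-episode and NEC depressive-disorder
codes). For each phecode $c_k$ the screen fits, by maximum likelihood,

$$\operatorname{logit} P(\text{case}) = \beta_0 + \beta_m m_k + \beta_a a_k + \beta_s s_k,$$

where $m_k$ is a per-subject aggregate measure of the phecode, $a_k$ is age
and $s_k$ sex. The coefficient of interest is $\theta = \beta_m$, a log odds
ratio. Three aggregate measures are supported, chosen per study design:
binary presence, occurrence count, and first-to-last duration in years. The
interpretation of $\theta$ differs by measure — one more *occurrence* is not
one more *year* — so the null interval below must be chosen with the measure
in mind.

On a covariate-free binary design the model is saturated and
$e^{\hat\theta}$ equals the 2×2 cross-product odds ratio exactly; the test
suite holds the fit to that closed form to four significant figures over a
thousand random tables.

## Interval nulls and the second-generation p-value

A classical point-null test run over ~1,800 phecodes at EMR sample sizes
flags effects far too small to matter clinically. The screen instead declares
an *indifference zone* of odds ratios before the analysis — $[0.3, 1.5]$ is a
typical clinician-chosen default, and asymmetric zones such as $[0.3, 1.1]$
are legitimate when even small risk increases are of interest for a severe
outcome. With $I$ the Wald CI and $N$ the null interval, the
second-generation p-value is

$$p_\delta = \frac{|I \cap N|}{|I|}\quad (|I| \le 2|N|), \qquad
  p_\delta = \frac{|I \cap N|}{2|N|}\quad (|I| > 2|N|),$$

so $p_\delta = 0$ exactly when the data support only clinically relevant
effect sizes. The wide-interval correction never changes the set of
$p_\delta = 0$ calls (a disjoint overlap is zero under either denominator);
it only stops very wide, low-information intervals from being read as
evidence *for* the null.

**Scale.** Overlap proportions are not scale-invariant, so one canonical
scale must be fixed: all interval arithmetic happens on the log-odds scale,
where the regression coefficient lives and where a symmetric zone around
"no effect" is actually symmetric. Configs state nulls on the odds-ratio
scale (how clinicians think) and `null_interval()` logs both forms. The
$p_\delta = 0$ / $p_\delta = 1$ calls are provably identical under either
scale, and a property test checks the whole value, not just the calls.

**Direction.** Findings whose CI lies entirely *below* the null zone
(protective direction) are usually of less clinical interest for a
comorbidity screen. They keep $p_\delta = 0$ — the definition is two-sided —
and carry a `negative_direction` flag instead; filtering is the analyst's
decision, never the statistic's.

## Power function and empirical-Bayes PPV

Under $\hat\theta \sim N(\theta, se^2)$, the probability of a significant
call is

$$P(p_\delta = 0 \mid \theta)
  = \Phi\!\Big(\frac{\theta_0^- - \theta}{se} - z\Big)
  + \Phi\!\Big(\frac{\theta - \theta_0^+}{se} - z\Big),$$

with $z$ the two-sided quantile of the CI level. The positive predictive
value of a $p_\delta = 0$ finding is then

$$PPV = 1 - \Big[1 + \frac{1-\tilde\beta}{\tilde\alpha}
        \cdot \frac{1-\pi_0}{\pi_0}\Big]^{-1},$$

where $\tilde\alpha$ averages the power over $\theta \sim U[\theta_0^-,
\theta_0^+]$ (uniform over the null zone) and $1-\tilde\beta$ averages it
over $\theta \sim U[\hat\theta_l, \hat\theta_u]$ — uniform over the
*observed* interval. That second weight function is the empirical-Bayes
element: its form is fixed a priori but its location comes from the data,
recomputed per phecode. The prior $\pi_0$ defaults to $0.5$
(non-informative); PPV is strictly decreasing in $\pi_0$.

**Numerics.** Both averages are one-dimensional integrals of a smooth
function; they are evaluated with fixed 64-node Gauss–Legendre quadrature,
which makes the PPV deterministic to well below $10^{-8}$ — the tests
validate it against a million-draw two-stage Monte-Carlo oracle (draw
$\theta$ from the weight density, then $\hat\theta$ around it, then apply
the interval-disjoint decision) to within 0.01 across a 20-point grid of
$(se, \text{CI}, N)$ configurations. If $\tilde\alpha$ underflows to zero
the PPV is clamped to 1 and flagged rather than dividing by zero.

## Cohort construction

**Censoring.** Three modes restrict the visits entering the aggregate:
an age interval (e.g. all visits from age seven on), and windows 0–w years
before (left) or after (right) the index diagnosis. The phrasing
"0–5 years before/after" leaves the endpoints open; the package fixes them
as *closed on the side nearest the diagnosis, open at the far bound*, so the
diagnosis year itself is always included when the window starts at 0. The
choice is stated, tested, and applied symmetrically to both directions.

**Controls under diagnosis-anchored windows.** Controls have no diagnosis
date. Each matched control inherits its case's diagnosis age as a reference
age (standard risk-set alignment), which makes the window well defined on
both arms.

**Matching.** Greedy nearest-neighbour: cases in descending reference-age
order, exact on sex, nearest on age, sampling the pool without replacement,
with ties broken by a seeded shuffle so runs are reproducible. Pool members
carrying any exclusion phecode of the index disease (each phecode's
exclusion range, defaulting to the phecode itself) are removed first — this
keeps near-cases out of the control arm. Exhausted strata produce fewer
controls with a warning rather than silent reuse. No caliper or
propensity-score matching is attempted; the method's published use matched
on age and sex only.

**Covariates.** $a_k$ is the subject's mean age over their censored visits
(a single per-subject scalar is what the mean model takes; subjects with no
visits in the window fall back to their reference age and keep $m_k = 0$ —
dropping them would condition on the outcome of the visit process). Sex is
coded female = 1, male = 0; unknown sex is excluded with a warning.

**Carrier filter.** Phecodes with fewer than 5 carriers in either class are
skipped and reported, not fitted: below that, the Wald interval is
meaningless and separation is near-certain. Separation that still occurs is
flagged and the phecode excluded from SGPV/PPV (no Firth or penalized
fallback, which would change the estimator's semantics).

## Literature novelty

Phecodes become PubMed queries through concept expansion: ICD-9 children →
concept identifiers → all synonym strings, lower-cased and deduplicated.
A paper counts if it co-mentions any disease string and any phecode string
in title/abstract/keywords. The *PubMed proportion* divides by the papers
mentioning the disease; the novelty score is $N_s = 1 - \hat F(x)$ with
$\hat F$ the empirical CDF of the proportions under consideration, and
$NFI = PPV \cdot N_s \cdot 10$.

Three conventions had to be fixed:

* **Reference set of the ECDF** — "proportions under consideration" could
  mean all screened phecodes or only the significant ones. The default is
  all screened phecodes (a larger set gives a stabler CDF and a ranking that
  does not shift when one finding enters or leaves significance);
  `only_significant = TRUE` gives the narrower reading.
* **Tie/continuity rule** — the ECDF is self-inclusive ($\le$), making the
  most-studied pairing score exactly 0 and ties share a value.
* **When NFI exists** — only for $p_\delta = 0$ findings, where the PPV is
  defined; everything else carries `NA`.

Live counts drift as the literature grows, so analyses pin counts in a
fixture file (or a query-keyed JSON cache); the live NCBI E-utilities
provider is rate-limited to 3 requests/s and retried before a hard error.
The test-suite runs entirely from fixtures and a recorded-response double.

## The synthetic cohort generator

Real screening cohorts come from private EMR systems, so the package ships a
generator whose output exercises every pipeline stage. Carriage of each
phecode is drawn per subject from the logistic carriage model: background
prevalence $p_0$ in controls, and in cases the probability solving
$\text{odds}_1 = \text{odds}_0 e^{\theta^*}$ for the planted log odds ratio
$\theta^*$ (a combination implying a probability outside $(0,1)$ is a
configuration error). Carriers are then *exploded* into visit rows —
$1 + \text{Poisson}(\lambda)$ visits with ICD-9 codes drawn from the
phecode's children in a (synthetic or real) map, at ages consistent with
the censoring scenario — so the ICD-9 mapping path is tested, not just the
statistics. Ages are truncated normal on $[0, 100]$ (mean 55, sd 15 by
default); the sex ratio is even.

What the generator does *not* emulate: inter-phecode correlation beyond
case status, coding noise and upcoding drift, disease-progression dynamics,
and informative visit frequency. Passing tests therefore demonstrate that
the estimator and decision rules behave as designed under their assumed
model — not that any particular clinical finding would replicate.

Study-scale checks in the test-suite use these problem sizes: 2,000 subjects
per arm at carriage prevalence 0.05 for the recovery runs (planted OR 4
recovered in at least 95 of 100 seeded replicates; planted OR 1.2, inside
the null zone, flagged in at most 2); all-null cohorts at 500/2,000/8,000
per arm for the shrinking-type-I check; and 30-replicate batches for
coverage and unbiasedness. These sizes give the Monte-Carlo error bands the
tests assert; larger runs sharpen the bands without changing the design.

## Known limitations

* ICD-9 only; ICD-10/SNOMED mapping is out of scope.
* No phecode hierarchy roll-up: a child code does not count toward its
  parent phecode unless the map says so explicitly. The published method's
  behaviour here is unstated; no roll-up is the conservative reading and a
  map preprocessed with roll-up works unchanged.
* Wald intervals only; likelihood-support or credible intervals would plug
  into the same overlap definition but are not implemented.
* Co-mention is a proxy: a paper mentioning both terms need not study their
  association, and multi-condition studies may omit key terms from their
  abstracts. The novelty score inherits both biases.
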