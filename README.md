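# phescreen

Phenome-disease association screening over coded medical-record data, with
findings ranked by **statistical reliability** (second-generation p-values and
an empirical-Bayes positive predictive value) and by **literature novelty**
(a PubMed-proportion-based Novelty Finding Index).

## Who this is for

Clinical data scientists mining EMR extracts for comorbidities, risk factors
or prognostic factors of one index disease. The screen answers two questions
a plain PheWAS leaves open: *which associations are clinically — not just
statistically — significant?* and *which of those are actually new to the
literature?*

## The method

Visit-level ICD-9 billing codes are grouped into **phecodes** (hierarchical
clinical phenotypes). After optional visit censoring (an age interval, or a
window 0–w years before / after the index diagnosis) and age/sex-matched
control selection with exclusion-code hygiene, each phecode `c_k` gets a
per-subject aggregate measure `m_k` (presence, count, or first-to-last
duration) and a logistic regression

```
logit P(case) = b0 + bm*m_k + ba*age + bs*sex
```

The coefficient of interest is `theta = bm`, the log odds ratio.

**Second-generation p-value (SGPV).** A null interval of clinically
uninteresting odds ratios (e.g. `[0.3, 1.5]`) is declared *before* the
analysis. With `I` the 95% Wald CI and `N` the null interval (both on the
log-odds scale), `p_delta = |I∩N|/|I|`, replaced by `|I∩N|/(2|N|)` when
`|I| > 2|N|`. `p_delta = 0` (CI clear of the null zone) is a significant
finding; `p_delta = 1` confirms the null; anything between is inconclusive.
Because the whole CI must clear the indifference zone, the type-I error of
this rule vanishes as samples grow.

**Positive predictive value.** For `p_delta = 0` findings, an empirical-Bayes
PPV is computed from the SGPV power function
`P(p_delta=0|theta) = Phi((lo-theta)/se - z) + Phi((theta-hi)/se - z)`:

```
PPV = 1 - [1 + (1-beta~)/alpha~ * (1-pi0)/pi0]^-1
```

with `alpha~` the power averaged over `theta ~ Uniform(N)`, `1-beta~` the
power averaged over `theta ~ Uniform(observed CI)`, and prior `pi0 = 0.5` by
default. Integrals use deterministic 64-node Gauss–Legendre quadrature.

**Novelty.** Each phecode expands (via ICD-9 → concept identifier → synonym
strings) into a PubMed query; the *PubMed proportion* is papers co-mentioning
phecode and disease over papers mentioning the disease. The novelty score is
`Ns = 1 - F(x)` with `F` the empirical CDF of the proportions under
consideration, and the **Novelty Finding Index** is `NFI = PPV * Ns * 10`
on `[0, 10]`: near 0 = well known (or unreliable), near 10 = reliable and
understudied.

## Worked example

No real EMR ships with the package; the synthetic generator plants known
effects so the full path is runnable anywhere:

```r
library(phescreen)

nl <- null_interval(c(0.3, 1.5))          # pre-specified indifference zone
cfg <- sim_config(
  n_cases = 1000, n_controls = 1000,
  catalog = sim_catalog(8, prevalence = 0.08),
  planted = tibble::tibble(phecode = c("101.1", "104.1"),
                           log_or  = c(log(4), log(1.2))),
  seed = 42
)
cohort <- simulate_cohort(cfg)
mapped <- map_visits(cohort$visits, synthetic_phecode_map(cfg$catalog$phecode))
mat    <- aggregate_phecodes(mapped, cohort$subjects, measure = "binary")
res    <- run_screen(mat) |> add_sgpv(nl)

# literature counts from a pinned fixture file (a live PubMed provider exists)
counts <- fetch_counts(
  "index disease",
  setNames(as.list(cfg$catalog$phecode), cfg$catalog$phecode),
  lit_fixture_provider("pubmed_counts.csv")
)
res    <- add_novelty(res, counts)
dplyr::select(res, phecode, or, or_lo, or_hi, p_delta, ppv, n_s, nfi)
```

```
# A tibble: 8 × 8
  phecode    or or_lo or_hi p_delta    ppv   n_s   nfi
1 101.1   3.28  2.51   4.29   0      0.998 0.875  8.74
2 102.1   0.927 0.679  1.27   1     NA     0.125 NA
3 103.1   1.05  0.761  1.44   1     NA     0.25  NA
4 104.1   1.10  0.795  1.53   0.967 NA     0.375 NA
...
```

Reading it: the phecode planted at OR 4 is the only one whose CI clears the
null zone (`p_delta = 0`); its PPV says the finding is almost certainly real,
and because its literature proportion is low its NFI of 8.7 flags it as a
novel, reliable lead. The phecode planted at OR 1.2 sits inside the
indifference zone — a large-sample classical test would have flagged it;
the SGPV correctly keeps it inconclusive/confirmed-null. `autoplot(res)`
draws the odds-ratio plot with the gray null band and NFI colouring.

A single-config driver and a thin CLI wrap the same steps:

```sh
Rscript inst/cli/phescreen.R run --config study.yaml --out-dir out/
```

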