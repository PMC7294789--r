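---
title: "Scoring familial longevity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring familial longevity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Human longevity — survival into the extreme tail of one's birth cohort —
clusters in families, but any individual long-lived person may instead be a
*phenocopy*: someone who reached old age through era, environment or luck
rather than a heritable predisposition. Genetic studies that recruit cases
on individual age alone therefore dilute their case group. `lrckit`
implements a family-history approach: quantify how much longevity clusters
among a person's ancestral blood relatives, and admit as cases only people
whose families are demonstrably enriched.

## Survival percentiles from cohort life tables

All ages are judged against sex- and birth-year-specific cohort life
tables giving the yearly hazard of death $h_x$ between exact ages $x$ and
$x+1$. Within a year of age the hazard is treated as constant (the standard
actuarial piecewise-exponential convention), so the cumulative hazard

$$H(t \mid t_0) = \sum_{x < \lfloor t \rfloor} h_x
  + (t - \lfloor t \rfloor)\, h_{\lfloor t \rfloor} - H(t_0)$$

is piecewise linear and exactly additive over adjacent intervals, and
$S(t \mid t_0) = e^{-H(t \mid t_0)}$ is continuous in $t$. A person's
survival percentile within their own cohort is $P = 1 - S(\text{age at
death})$; membership of the top fraction $Z$ of survivors uses the
inclusive test $P \ge 1 - Z$. The source tables publish only yearly
hazards, so any within-year interpolation rule is a convention; the
piecewise-exponential choice was made because it keeps $H$ additive to
machine precision and $S$ continuous.

Two table-handling rules matter in practice:

* **Exact-key lookup only.** A missing (sex, birth year) table is an
  error. Silently borrowing a neighbouring cohort would bias percentiles,
  because secular mortality decline makes adjacent cohorts genuinely
  different.
* **Tail policy.** Published cohort tables often stop at age 99 while
  long-lived subjects exceed it. The default `hold_last` policy extends
  the table by holding the final hazard constant; `error` refuses instead.

## The Longevity Relatives Count score

For a focal person $i$ with ancestral blood relatives $k = 1, \dots, N_i$,

$$\mathrm{LRC}_i =
  \frac{\sum_k w_k \, I(P_k \ge 1 - Z)}{\sum_k w_k},$$

where $w_k$ is the relationship coefficient (expected genome sharing:
parents and siblings 0.5; grandparents, aunts and uncles 0.25) and $Z$
defaults to 0.10, the tail at which longevity has been shown to be
heritable. The score is the kinship-weighted *proportion* of relatives who
became long-lived: always on a 0–1 scale, indifferent to family size, and
transferable across reference populations.

Weights come from the standard recursive kinship algorithm on the pedigree
as given (founders unrelated, no inbreeding correction), not from a lookup
table — so half-relationships get the weights the recursion implies (a
half-aunt 0.125, for example). The default relative set for a focal person
is the two ascending generations: parents, grandparents, and aunts/uncles;
siblings of the focal person can be switched on but are excluded by
default, matching a score built from ancestors whose lifespans are
complete.

Inclusion rules, and why:

* Relatives with an unknown age at death enter **neither** sum. An unknown
  lifespan is evidence for neither class, and treating it as "not
  long-lived" would drag scores toward zero exactly in the families with
  the worst records.
* Relatives still alive are excluded by default. The optional
  `alive_if_exceeds` rule counts an alive relative as long-lived once
  their *current* age already clears the percentile threshold (it can only
  rise), supporting prospective use; alive relatives below the threshold
  stay excluded because their final class is unknown.
* A focal person with no usable relatives is **unscorable** (`NA`), never
  0: a 0/0 must not silently become a family control.

Classification uses the cut-offs: score 0 = family control; (0, 0.2) =
unselected (no demonstrated excess survival at these levels); [0.2, 0.3) =
nonclassified; ≥ 0.30 = family case, boundary included. The nine reporting
bins are g1 = {0}, g2 = (0, 0.1), then left-closed tenths up to
g9 = [0.7, 1.0], which absorbs the sparse top scores.

## Standardized mortality ratios

A group's SMR compares observed deaths $d$ with the expectation under the
reference tables, $e = \sum_i H(t_i \mid t_{0i})$, summed over each
person's own sex- and birth-year table up to their age at death or last
observation. Conditioning on the entry age $t_{0i}$ corrects for left
truncation: anyone only observable after surviving to some age (a spouse
observable from marriage, an index person sampled because they reached 80)
must have the hazard before that age removed from the expectation, or the
group looks spuriously long-lived. The same mechanism, applied per group
through caller-supplied entry ages, covers the delayed-entry adjustments
needed when a group could not by construction die before some age.

Exact confidence limits use the chi-square quantile form for a Poisson
count: $LL = \chi^2_{\alpha/2, 2d} / 2e$ (defined as 0 when $d = 0$, the
standard convention) and $UL = \chi^2_{1-\alpha/2, 2(d+1)} / 2e$. A
family-resampling percentile bootstrap (families are the independent
units) is provided as a cross-check; the two agree closely on family data
of realistic size, which is why the cheap exact limits are the default.
$\alpha$ defaults to 0.05 throughout.

## The shared-frailty survival contrast

Family cases and controls are compared with a Cox-type random effects
model
$$\lambda(t_{ij}) = u_i\, \lambda_0(t_{ij})
  \exp(\beta' Z_{ij} + \gamma' X_{ij}),$$
with an unspecified baseline hazard, a per-family multiplicative frailty
$u_i$, left truncation via counting-process entry, and adjustment for
sibship-size category (single child; 1–2, the reference; 3–5; 6–8; 9+),
birth year and sex. The frailty distribution is fixed to mean-1 gamma with
variance $\theta$ — the canonical estimable choice for shared frailty; the
model class itself does not dictate a distribution. Estimation is
penalized partial likelihood via `survival::coxph`; at $\theta = 0$ the
model is by definition an ordinary Cox fit, and the implementation reduces
to exactly that (verified to $10^{-6}$ and beyond in the tests). With a
single family the frailty variance is unidentifiable and the fit refuses
rather than returning something arbitrary.

Scheme A contrasts cases against controls. Scheme B adds the spouses of
each group — married-in, sharing household but not blood — entering the
risk set at their group's first observed death age (spouses are only
observable once married). The first death defines the entry age and is
kept at risk; spouses censored at or before entry are unobservable under
left truncation and are dropped (and counted). Scheme B omits the sibship
adjustment: married-in spouses have no sibship within the family.

## The synthetic world

Real multigenerational genealogies with mortality follow-up are
restricted-access, so the generator produces a cohort with the same
*shape*: families built around an F1 index couple, ascertained 2:1 into a
case arm (index person died at 80+) and a control arm (died 40–59); index
persons born 1860–1875; roughly three children per reproducing couple
(zero-truncated Poisson, configurable); two descendant generations with
married-in spouses; right censoring at calendar year 2019; and
role-specific missing-age rates (about 10% for descendants, 40–60% for
spouses) matching the records the design emulates.

Mortality follows a Gompertz–Makeham law per sex,
$h(x) = a + b e^{cx}$, with defaults (female $a = 0.009$,
$b = 0.85\times10^{-4}$; male $a = 0.011$, $b = 1.25\times10^{-4}$;
$c = 0.09$) chosen so that life expectancy at birth sits in the
mid-50s and the top-10% age near 80 for the earliest cohorts — coarse but
recognizable late-19th-century European values — plus a 1%-per-birth-year
proportional hazard decline standing in for the secular trend. Tables are
discretized as exact integral increments $h_x = H(x+1) - H(x)$, so table
survival matches the continuous law exactly at integer ages. Lifetimes are
drawn by inverting the piecewise-linear cumulative hazard at exponential
deviates; every run is bit-reproducible from its seed.

Familial clustering is induced by a per-family gamma frailty $u$ (mean 1,
variance $\theta$, default 0.25 — in the range shared-frailty studies of
adult lifespan report). Two design choices deserve emphasis:

* **Frailty acts on the senescent component only** (default
  `frailty_mode = "senescent"`: hazard $a + u\,b e^{cx}$). Multiplying
  the *whole* hazard would make mid-life deaths as familial as longevity,
  so ascertaining control families on a death at 40–59 would select
  high-frailty families whose descendants die visibly early — whereas the
  data being emulated show control descendants tracking the general
  population. Senescent-only frailty reproduces that asymmetry: dying at
  45 is mostly background (non-familial), reaching 85 is mostly
  senescence (familial). The textbook fully-proportional mechanism
  remains available (`frailty_mode = "proportional"`) and is what the
  Laplace-transform marginalization check
  $S_{\mathrm{pop}}(t) = (1 + \theta H(t))^{-1/\theta}$ describes and
  tests.
* **Ascertainment is joint rejection on $(u, T_{\mathrm{IP}})$.** The
  family's frailty and the index person's lifetime are redrawn together
  until the death age lands in the arm's window, so each arm carries the
  exact frailty posterior its selection implies — case families skew to
  low frailty, and that skew, shared with descendants, is what makes
  high-LRC descendants long-lived downstream. Married-in spouses always
  carry $u = 1$: their survival mirrors the general population.

What a green test does *not* establish: the generator has no explicit
genetic transmission (frailty is a family constant, not a meiotic draw),
no fertility–mortality dependence (children can be conceived close to a
parent's death age), no calibrated historical demography (infant
mortality, marriage patterns, migration), and spouses are demographically
exchangeable with the population rather than assortatively matched.
Conclusions about the *machinery* — percentiles, scores, SMR calibration,
truncation corrections, frailty-model recovery — transfer; conclusions
about Dutch historical demography do not.

A second frailty-world artifact: selecting descendants with *no*
long-lived ancestors (score 0) slightly favours high-frailty families —
their ancestors were unlikely to be long-lived — so the family-control
group's true SMR sits a percent or two above 1 rather than exactly at it,
with substantial family-cluster noise on top. Tests of "controls track
the population" therefore run at sample sizes where this is resolved, and
interval checks, not point equality, are asserted.

One structural consequence worth knowing: with the default three children
per couple, a focal person's weighted ancestor total is usually ≈ 2.0–2.5,
so a single long-lived parent already implies a score of about 0.2–0.25
and very low positive scores are rare. Decompositions that need a
populated (0, 0.2) band (the "long-lived parent but low family score"
group) are exercised with a larger-sibship scenario (`children_mean = 6`).

## Numerical and testing choices

* Acceptance checks on the frailty model use the spec-level generator
  values (hazard ratio 0.75, $\theta$ = 0.2, 400 families of 5) with 100
  replicates; null-calibration coverage uses 500 independent small-cohort
  replicates. Monte-Carlo-limited trend checks (the nine-bin SMR gradient)
  run at 4,000 families so that per-bin standard errors are small against
  the expected decline; nothing about the generating law differs from the
  defaults.
* The whole-population null SMR excludes F1 index persons: their death
  ages are conditioned on by the ascertainment itself, which is the same
  reason the emulated study left-truncates its index persons at 80 or
  declares their SMR inestimable.
* Exact-CI and quantile computations are checked against an independent
  gamma-quantile oracle ($\chi^2_{p,2k}/2 = $ `qgamma(p, k)`), not against
  a re-statement of the same formula.
* Convergence: penalized fits run with coefficient tolerance $10^{-6}$
  and a bounded outer iteration count; non-convergence raises an error
  with the iteration history rather than returning a doubtful fit.

## Known limitations

* Inbreeding is ignored: kinship assumes founders unrelated and non-inbred,
  appropriate for shallow (3–5 generation) pedigrees.
* Period (cross-sectional) life tables, mortality forecasting, and
  cause-specific mortality are out of scope.
* The score treats parent links as biological; adoption and step
  relationships are not modelled.
* Bootstrap limits are percentile-method; no bias correction or
  acceleration.
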