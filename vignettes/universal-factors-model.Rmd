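---
title: "The universal-factors model of embryo transfer outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The universal-factors model of embryo transfer outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniplant)
```

## The model

When several embryos are transferred in one IVF procedure, their outcomes
are not independent: conditions that act on the whole transfer — endometrial
receptivity, transfer technique, culture conditions, maternal factors —
either permit implantation or block it for every embryo at once. `uniplant`
models this with two kinds of parameters:

* **LBR**, the live birth rate per embryo: the marginal probability that
  one transferred embryo results in a live-born infant. LBRs are estimated
  per age group and per transfer category (fresh/frozen crossed with
  cleavage-stage/blastocyst).
* **UNI**, the universal factors fraction: the probability that
  transfer-level conditions are favorable. When they are not (probability
  `1 - UNI`), no embryo can implant. When they are, each embryo delivers
  independently with the conditional probability `LBR / UNI`.

For a transfer of $n$ embryos with rates $L_1, \dots, L_n$ the outcome
count $k$ (number of live-born infants) has

$$P(k) = \mathrm{UNI} \cdot \mathrm{PB}_k\!\left(\tfrac{L_1}{\mathrm{UNI}},
\dots, \tfrac{L_n}{\mathrm{UNI}}\right) \quad (k \ge 1), \qquad
P(0) = (1 - \mathrm{UNI}) + \mathrm{UNI}\prod_i
\left(1 - \tfrac{L_i}{\mathrm{UNI}}\right),$$

where $\mathrm{PB}_k$ is the Poisson-binomial probability of exactly $k$
successes. Two consequences anchor the model: each embryo's marginal birth
probability is exactly its $L_i$ (so single-embryo outcomes carry no
information about UNI), and for two embryos the twin probability is
$L_1 L_2 / \mathrm{UNI}$ — larger than the independent $L_1 L_2$ whenever
$\mathrm{UNI} < 1$. A smaller UNI concentrates births into fewer, more
productive transfers: more twins, fewer singletons, same marginal rate.
With $\mathrm{UNI} = 1$ the model reduces to independent implantation.

The distribution is computed by an $O(n^2)$ dynamic-programming
convolution rather than closed-form factorial expressions; it is exact,
stable, and supports heterogeneous per-embryo rates (useful when embryos
of different quality are transferred together, even though the clinic fit
assigns all embryos in a transfer their cell's common rate).

`outcome_distribution()` is the primitive; `delivery_rate()` and
`multiples_fractions()` derive the counseling quantities from it.

```{r}
outcome_distribution(c(0.3, 0.3), uni = 0.7)
multiples_fractions(c(0.3, 0.3), uni = 0.7)
```

Only dizygotic multiples (distinct embryos) are modelled. Monozygotic
splitting adds roughly 1–2% to real multiple-gestation risk and must be
counselled separately; it is deliberately outside the model.

## Estimating live birth rates

Each transfer contributes one linear equation, `n_embryos × LBR =
births`. Within an age group × category cell the scalar least-squares
solution is

$$\hat L = \frac{\sum_i n_i b_i}{\sum_i n_i^2},$$

which weights larger transfers more than the pooled ratio
$\sum b_i / \sum n_i$; the two coincide when all $n_i$ are equal.
`estimate_lbr()` implements the least-squares form, the default of
`fit_lbr_table()`; `estimate_lbr_simplified()` provides the pooled ratio,
the "simplified clinic mode" that can be computed by hand
(`mode = "simplified"`).

Age groups follow the moving-group design: ages at oocyte retrieval up to
34 form one pooled group (rates change slowly there and per-age counts
are small; ages under 25 are included in this group rather than
extrapolated), and each target age 35–43 is estimated from the 5-year
window centered on it — the rate reported for 35-year-olds uses ages
33–37, taken as raw ages regardless of the pooled group's boundary.
Windows at the edges extend symmetrically (41–45 for target 43) and use
whatever records fall inside; no estimates are produced beyond 43. Because
windows overlap, one record can inform up to five target ages.

Smoothing has an estimand worth stating: a window's least-squares value
is the $n^2$-weighted average of the true rates at the ages it pools.
When the cohort's age mix is skewed (as real clinics are), that average
sits slightly off the center-age rate; the package's parameter-recovery
tests therefore compare each fitted cell to its window estimand, not to
the center-age truth.

Cell uncertainty comes from a percentile bootstrap (`bootstrap_lbr_ci()`)
that resamples whole transfers — the independent units of the equations —
with replacement; cells with fewer than two transfers get a flagged,
undefined CI rather than a fabricated one, and unpopulated cells are
absent from the table rather than reported as zero. The same machinery
runs with ongoing pregnancy (fetal heartbeat at 6–8 weeks) as the outcome
(`outcome = "ongoing_pregnancy"`).

## Estimating the universal factors fraction

Only multiple-embryo transfers inform UNI. A transfer of $n$ embryos at
cell rate $L$ delivers exactly one infant with probability

$$P(\text{singleton}) = n L \left(1 - \tfrac{L}{\mathrm{UNI}}\right)^{n-1},$$

which increases monotonically in UNI on $[L, 1]$: higher UNI means more
singletons and fewer multiples at fixed marginal rates. `fit_uni()`
maximizes the Bernoulli likelihood of each multiple-embryo transfer's
singleton indicator over a grid of UNI values — the default grid step of
0.01 matches the two-decimal precision at which the fraction is counselled
— restricted to `[max cell rate, 1]` so the model stays well-formed
(`lbr > uni` is always a hard error, never a silent clamp: clamping would
hide exactly the identifiability failures the flag below is for). Ties
break toward the larger UNI. A full-multinomial likelihood over all
outcome counts is available (`likelihood = "multinomial"`) as a
sensitivity check; the singleton-indicator form is the default because the
singleton count is the fitting target. Fresh and frozen transfers are
fitted separately by the higher-level tools, reflecting the expectation
that uterine conditions differ between fresh and frozen cycles.

**Identifiability.** Some cohorts show more singletons than even
independent implantation (UNI = 1) predicts; no UNI in $(0, 1]$ fits such
data. `fit_uni()` reports the constrained maximum (at 1) and raises a
`non_identifiable` flag when the likelihood is still rising at 1 *and*
the observed singleton count exceeds the independence prediction by more
than two binomial standard errors. The significance guard is a design
choice: without it, chance fluctuation flags about half of all cohorts
whose true UNI is 1, which would make the flag useless; with it, the flag
marks only excesses that independence cannot plausibly explain (small
frozen-cleavage subgroups are the typical real-world case).

`bootstrap_uni_ci()` quantifies second-stage uncertainty: it resamples
the multiple-embryo transfers with replacement and refits UNI **against
the fixed fitted rate table**. Conditioning on the rate table mirrors the
two-stage fitting procedure (rates first, from the whole cohort including
single-embryo transfers; UNI second) and attributes to UNI only the
uncertainty of its own stage. Internally the resampling is collapsed to a
multinomial draw over the distinct (rate, size, outcome) combinations,
which is distributionally identical to resampling transfers and makes the
refit cost independent of cohort size.

## Validating a fit

`cross_validate()` replicates a tenfold cross-validation: transfers are
assigned to folds by independent uniform draws (unequal fold sizes are
expected; an assignment with an empty fold is redrawn), each fold is
predicted from a model fitted to the other nine, and every held-out
transfer's outcome is simulated from the fitted model to build
parametric-bootstrap predictive distributions of three fold-level rates —
singleton deliveries, twin deliveries, and total deliveries per transfer.
The fold's standardized error is (observed − predictive mean)/predictive
SD; with $k$ folds the mean standardized error is Z-tested against zero
with standard error $1/\sqrt{k}$, and `qq_points()` pairs the ordered
errors with normal quantiles at positions $(i - 0.5)/n$ for
quantile–quantile diagnostics. Standardization at the fold level is the
one unit that yields a $k$-sample Z-test; degenerate predictive
distributions (SD 0, e.g. all-zero rates) yield flagged `NA` errors
rather than infinities, and held-out transfers whose cell is unpopulated
in the training folds are excluded and counted, with the accounting
identity predicted + unpredictable = held-out maintained per fold.

Setting `comparison_mode = "uni_equals_1"` scores the same held-out data
against the independence model; on data with genuine universal-factor
correlation the observed twin rates then sit systematically above the
predictions — the diagnostic signature that motivates the model.

## Counseling tables

`build_prediction_table()` tabulates, for 1 up to `max_embryos` embryos
at one (LBR, UNI), the total delivery rate and the percentages of
deliveries that are multiples, twins, and triplets-or-more, and assigns
the multiples-risk band: green `[0, 10)`, yellow `[10, 20)`, red
`[20, 30)`, gray `≥ 30` percent. Banding always uses the unrounded
percentage; the print method rounds to whole percent for the clinic-style
view while the data frame keeps full precision. `max_embryos` defaults to
4, covering the transfer numbers seen in national registry summaries
without extrapolating. `build_clinic_tables()` maps a fitted rate table
to one such table per cell (fresh cells with the fresh UNI, frozen with
the frozen one), emitting an identifiability warning instead of a table
wherever a cell's rate exceeds the applicable UNI.
`simplified_reference_table()` produces the lookup grid for the
simplified mode at a single UNI, default 0.70 — a round value usable for
both cycle types — over a grid of average per-embryo rates.

```{r}
build_prediction_table(lbr = 0.35, uni = 0.70, max_embryos = 3)
```

## The synthetic clinic

No clinic-level transfer table is publicly deposited, so the package
carries its own generator, `simulate_clinic()`, which draws transfers
from the exact mechanism the model assumes. The default
`clinic_sim_config()` mirrors the cohort shape the method was developed
on: 684 transfers averaging 2.4 embryos each (mix 15%/30%/55% of 1/2/3
embryos), ages 25–44 weighted toward the mid-30s, four categories with
frozen cleavage the rarest (13%), true UNI 0.70 for both cycle types (the
simplified-mode value), and a rate surface (`default_lbr_curve()`) with
category bases 0.40/0.35/0.25/0.15 flat through age 34 then declining
linearly to a tenth of the base by 44 — bracketing the span from ~40%
young-group fresh blastocysts down to a few percent for older frozen
cleavage transfers. Fetal-heartbeat counts are reported equal to birth
counts: pregnancy loss between heartbeat and delivery, monozygotic
splitting, and donor cycles are not simulated, so tests passing on these
cohorts validate the estimation machinery under the model's own
assumptions — they cannot detect real-data departures such as
embryo-quality heterogeneity within a transfer or age effects on UNI
itself.

`uni_sample_size_study()` answers a planning question with this
generator: how many multiple-embryo transfers does a clinic need before
its UNI estimate is usefully precise? For each cohort size it simulates
two-embryo cohorts (rate 0.30, UNI 0.70 — typical of a blastocyst
program; the study's parameters are explicit assumptions), fits the rate
and UNI, bootstraps the 95% CI, and reports the mean half-width, which
empirically scales as $1/\sqrt{n}$. The half-width reaches ±0.05 at
roughly five thousand two-embryo transfers — far more than a single
mid-size clinic accrues in a few years, which is why pooling UNI across
subgroups (rather than fitting it per cell) is the default analysis
stance. `scripts/acceptance.R` reruns this study from scratch (grid
1,250–20,000 transfers, 200 replicates × 300 bootstrap resamples, a
Monte Carlo precision choice that keeps the mean half-widths stable to
about ±0.001) and reports the crossing size.

## Numerical and design notes

* All stochastic operations take explicit integer seeds and restore the
  caller's RNG state; derived seeds stay within 32-bit range.
* Grid search rather than smooth optimization for UNI: the likelihood is
  monotone-unimodal on the constrained interval, the answer is counselled
  to two decimals, and the grid makes the boundary diagnostics explicit.
  Halving the step perturbs the estimate by at most one step.
* `lbr = uni` is legal (conditional rate exactly 1; delivery rate equals
  UNI with all deliveries multiples at $n \ge 2$).
* Transfers at ages beyond the moving range (44+) have no cell;
  `fit_uni()` treats them as an error by default and drops them with a
  message under `on_missing_cell = "drop"` (the pipeline default in the
  CLI and cross-validation).
* Input CSVs are validated at the schema level (ages 18–50, counts
  consistent, categories legal) with row-numbered rejection reports;
  clinical exclusion criteria (gestational carriers, PGT, unusual freeze
  days) concern fields the schema does not carry, so inputs are expected
  to be pre-filtered to analyzable transfers.
* Test and example problem sizes (cohorts of 2,000–8,000 transfers,
  600–800 predictive simulations, 200–400 bootstrap resamples) were
  chosen so the full suite exercises every stochastic claim at
  comfortable Monte Carlo margins while running in about a minute.

## Limitations

The model represents dizygotic twinning only; UNI is assumed common
across ages and embryo counts within a cycle type; embryo morphology is
not a covariate (all embryos in a transfer share their cell's rate); and
estimates fitted to one clinic's data describe that clinic — portability
across clinics is an open empirical question, which is exactly why the
package fits rather than ships rate tables.
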