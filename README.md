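# uniplant

Tools for IVF clinics and reproductive-medicine researchers who need to
decide **how many embryos to transfer**: `uniplant` fits a clinic's own
embryo-transfer records to a *universal-factors* outcome model, validates
the fit by cross-validation, and turns it into counseling tables of
predicted delivery and multiple-gestation rates.

## The model

Embryos transferred together do not implant independently: transfer-level
("universal") conditions — endometrial receptivity, transfer technique,
culture conditions — either permit implantation or block every embryo at
once. The model has two parameter families:

* **LBR** — live birth rate per embryo: the marginal probability that one
  transferred embryo yields a live-born infant, estimated by least squares
  over the per-transfer equations `n_embryos × LBR = births`, within
  moving 5-year age groups (pooled ≤ 34, windows centered on 35–43) and
  four transfer categories (fresh/frozen × cleavage/blastocyst).
* **UNI** — universal factors fraction: the probability that conditions
  are favorable. With probability `1 − UNI` no embryo can implant; when
  favorable, each embryo delivers independently at the conditional rate
  `LBR / UNI`.

For a transfer of *n* embryos the number of live births *k* follows

    P(k ≥ 1) = UNI · PoissonBinomial_k(L₁/UNI, …, Lₙ/UNI)
    P(0)     = (1 − UNI) + UNI · Π(1 − Lᵢ/UNI)

so each embryo's marginal rate is exactly its LBR, while twins occur with
probability `L₁·L₂/UNI` — more often than independence predicts whenever
`UNI < 1`. UNI itself is fitted by maximum likelihood over the singleton
outcomes of multiple-embryo transfers, on a grid over `[max LBR, 1]`.

## Worked example

Clinic records are a flat CSV (one row per transfer: age at retrieval,
stage, cycle type, embryos transferred, live births). Here a synthetic
cohort stands in for them:

```r
library(uniplant)

records <- simulate_clinic(clinic_sim_config(n_transfers = 4000, seed = 7))
rates <- fit_lbr_table(records, B = 300, seed = 2)
head(as.data.frame(rates), 4)
#>   age_label      stage  cycle       lbr    ci_low   ci_high n_transfers n_embryos
#> 1      <=34   cleavage  fresh 0.2643857 0.2246844 0.3030277         297       727
#> 2      <=34 blastocyst  fresh 0.3766938 0.3467383 0.4055845         763      1825
#> 3      <=34   cleavage frozen 0.1439090 0.1111099 0.1748084         247       580
#> 4      <=34 blastocyst frozen 0.3257750 0.2995101 0.3581220         555      1332
```

Each row is one age-group × category cell: the fitted live birth rate per
embryo with its bootstrap 95% CI and the data volume behind it (the young
fresh-blastocyst cell here: 37.7% per embryo from 763 transfers). The
universal factors fraction is fitted from the multiple-embryo transfers,
separately per cycle type:

```r
fresh <- records[records$cycle_type == "fresh", ]
uni_fresh <- fit_uni(fresh, rates, on_missing_cell = "drop")
uni_fresh
#> Universal factors fraction (singleton likelihood, 1890 multiple-embryo transfers)
#>   UNI = 0.68
```

UNI = 0.68 means roughly a third of transfers face conditions under which
no embryo could implant; conditional on favorable conditions each embryo's
rate is `LBR/0.68`. The counseling table for the young fresh-blastocyst
cell:

```r
cell <- rates[rates$age_label == "<=34" & rates$stage == "blastocyst" &
                rates$cycle == "fresh", ]
build_prediction_table(cell$lbr, uni_fresh$value, max_embryos = 3)
#> Predicted transfer outcomes (LBR per embryo = 0.377, UNI = 0.68)
#>  embryos LBR % mult. % twins % trip. or >  band
#>        1 38%      0%      0%           0% green
#>        2 54%     38%     38%           0%  gray
#>        3 62%     64%     45%          19%  gray
```

Reading: one embryo delivers 38% of the time with no multiples risk
(green); a double transfer raises deliveries to 54% but 38% of those
deliveries are twins (gray, ≥ 30% multiples risk). The bands follow the
0–9 / 10–19 / 20–29 / ≥ 30% shading convention. `cross_validate()` checks
a fit against held-out data, and `simplified_reference_table()` produces
the hand-calculable lookup grid at UNI = 0.70.

A command-line interface wraps the same pipeline
(`exec/uniplant simulate | fit | predict | validate | power`).

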