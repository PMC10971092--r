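# iedina — item-explanatory higher-order DINA models

`iedina` is an R package for cognitive diagnosis modelling in which the
item parameters themselves are explained. It is aimed at psychometricians
and test developers who want to know not just *which* items have high
guessing or slipping rates, but *why* — by decomposing those parameters
into manifest item features (length, wording complexity, item format, ...).

## The models

The DINA measurement model scores person *j* on item *i* through the ideal
response η<sub>ji</sub> = ∏<sub>k</sub> α<sub>jk</sub><sup>q<sub>ik</sub></sup>:

> P(Y<sub>ji</sub> = 1 | η<sub>ji</sub>, g<sub>i</sub>, s<sub>i</sub>) =
> (1 − s<sub>i</sub>)<sup>η<sub>ji</sub></sup> g<sub>i</sub><sup>1 − η<sub>ji</sub></sup>,

with a higher-order trait driving attribute mastery,
P(α<sub>jk</sub> = 1 | θ<sub>j</sub>) = logit⁻¹(ξ<sub>k</sub>θ<sub>j</sub> + β<sub>k</sub>).
The item-explanatory extension links one item parameter to item features on
the logit scale,

> logit(g<sub>i</sub>) = γ<sub>0</sub> + Σ<sub>m</sub> γ<sub>m</sub> Z<sub>im</sub> ( + ε<sub>i</sub> ),

optionally with an item residual ε<sub>i</sub> ~ N(0, σ²<sub>ε</sub>)
absorbing unexplained variance. Five families are fitted by
Metropolis-within-Gibbs MCMC (`hodina`, `ie-g`, `ie-g-r`, `ie-s`,
`ie-s-r`), with exact 2^K profile enumeration, conjugate truncated-Beta
item updates under the identification constraint g < 1 − s, Gelman–Rubin
convergence checks, posterior predictive p-values, DIC, Wald tests of
feature coefficients, a two-step (fit-then-regress) alternative, an
item-text feature extractor with collinearity screening, a synthetic-data
simulator, and a parameter-recovery study driver. See
`vignettes/ie-hodina-methods.Rmd` for the full methods account.

## A worked example

Simulate a small higher-order DINA dataset whose guessing/slipping
parameters are driven by item features, fit the guessing-linked model, and
test the feature coefficients:

```r
library(iedina)

design <- sim_design(I = 20, J = 500, K = 2)
dat <- simulate_dataset(design, seed = 7)
dat
#> Synthetic higher-order DINA dataset: 500 persons x 20 items, 2 attributes
#>   true g in [ 0.033 , 0.384 ], true s in [ 0.031 , 0.401 ]
#>   item quality: 15 high / 5 low

fit <- fit_dina(dat$y, dat$q, "ie-g", features = dat$z,
                iter = 2000, burnin = 1000, seed = 1)
fit
#> Higher-order DINA fit, family: ie-g
#>    500 persons x 20 items, 2 attributes
#>    2 chains x 2000 iterations ( 1000 burn-in )
#>   max PSRF: 1.028 (converged)
#>   posterior-mean g in [ 0.049 , 0.282 ]; s in [ 0.029 , 0.334 ]

co <- subset(summary(fit), grepl("coef_g", parameter))
wald_test(co$mean, co$sd)[1:4, ]
#>     estimate         se          z            p significant
#> 1 -1.8914668 0.09066485 -20.862185 1.181498e-96        TRUE
#> 2  0.4192826 0.05719081   7.331293 2.279433e-13        TRUE
#> 3  0.1374083 0.06408403   2.144189 3.201771e-02        TRUE
#> 4  0.2084817 0.07339067   2.840711 4.501302e-03        TRUE
```

The first row is the intercept (the guessing logit when all features are
0); rows 2–4 are the slopes of the first three generating features, whose
true values are 0.6, 0.3, 0.3 — each flagged significant, with estimates
offset from the truth by the single 20-item realization (the recovery
driver quantifies exactly this). Classification accuracy against the
simulated truth:

```r
cls <- classify_profiles(fit)
pccr_accr(cls$profiles, dat$alpha)
#> $pccr
#> [1] 0.964
#>
#> $accr
#>    A1    A2
#> 0.974 0.988
```

96.4% of the 500 simulated persons are assigned their exact generating
attribute profile (chance level at K = 2 would be near 25%).

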