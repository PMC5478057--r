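# msrecap

Age-structured multistate capture–recapture modelling for populations in
which marked females move between two breeding colonies and between two
reproductive states.  The package was built around a long-term (13-year,
1989–2001) ring-recapture study of sympatric sibling mouse-eared bats
(*Myotis myotis* and *Myotis blythii*) at the Naters and Raron nursery
roosts in the Swiss Rhône valley, but the machinery — model notation,
likelihood, model selection, simulation — is generic.

## The model

Each marked female occupies one of four live states at every annual capture
occasion: 1/2 = not-yet-breeder in colony 1/2, 3/4 = experienced breeder in
colony 1/2; a fifth, explicit dead state absorbs the survival deficit so
every transition matrix is row-stochastic.  Between occasions a female
survives (first-year survival φ_juv in her first year, adult survival φ_ad
afterwards), may change colony (natal dispersal *n* in the first year,
breeding dispersal *b* later), and, if she has never bred, starts breeding
at attained age *a* with probability α_a (α₄ ≡ 1: no observed female
started later than age four).  Detection at an occasion happens with
recapture probability *p*, which may depend on colony, year, species and
breeding status, and is structurally 0 in 1994 when no field work took
place.  Observed capture histories are mutually exclusive outcomes of this
hidden Markov process, so the data are product-multinomial and the
likelihood of each history is computed by forward recursion conditional on
first release.  All probability parameters are estimated on the logit
scale under user-declared effect structures such as

```
phi(juv: year; ad: spec) psi(juv: .; ad: spec) p(Col*year+rep+spec) alpha(a3+spec)
```

Candidate models are compared by AIC (ΔAIC, Akaike weights) and parameters
can be model-averaged with Burnham–Anderson unconditional standard errors.
Derived life-history quantities include the mean age at first reproduction
`AFR = α₁ + Σₙ₌₂..₄ n·αₙ·Π_{i<n}(1−α_i)`, the further life expectancy at
age one `−1/ln(φ_ad)`, and the expected reproductive years
`life expectancy − (AFR − 1)`.

Because the original capture histories are not publicly deposited, the
package ships a simulator (`simulate_dataset()`, `myotis_config()`) that
reproduces the study design — occasions, skipped 1994 occasion, per-colony
cockchafer (pulse-resource) calendars, release totals of 430 and 849
females — so every stage of the pipeline is testable end to end.

## Worked example

```r
library(msrecap)

cfg <- myotis_config()                       # study design + generating rates
sim <- simulate_dataset(cfg$design, cfg$rates, seed = 1)
summary(sim)
#> Marked females       : blythii=430, myotis=849 (total 1279 )
#> Known age at marking : blythii=227, myotis=461
#> Colony of first capture:
#>          colony
#> species     N   R
#>   blythii 245 185
#>   myotis  178 671

# does the age-specific probability of first breeding differ by species?
mA <- ms_model(phi_juv = ".", phi_ad = "species", alpha = "a3+species",
               move_juv = ".", move_ad = "species", p = ".",
               fix = list(alpha1 = 0))
mB <- ms_model(phi_juv = ".", phi_ad = "species", alpha = "a3",
               move_juv = ".", move_ad = "species", p = ".",
               fix = list(alpha1 = 0))
fA <- ms_fit(mA, sim, starts = 2)
fB <- ms_fit(mB, sim, starts = 2)
rank_models(list(fA, fB), labels = c("alpha a3+species", "alpha a3"))
#> Model selection (2 models):
#>             model deviance npar  dAIC weight
#>  alpha a3+species  7437.29   13  0.00      1
#>          alpha a3  7524.66   12 85.37      0
```

The generating rates give the two species very different ages at first
breeding (α₂ = 0.33 vs 0.93), and dropping the species effect costs 85
AIC units.  The fitted age-specific probabilities recover the truth:

```r
tab <- predict(fA, "alpha")
tab[tab$colony == "N" & tab$interval == 1 & tab$cohort == "no" & tab$age %in% 2:3,
    c("age", "species", "estimate", "se")]
#>  age species estimate    se
#>    2 blythii    0.315 0.064
#>    3 blythii    0.687 0.090
#>    2  myotis    0.955 0.020
#>    3  myotis    0.990 0.007
```

The derived life-history summary on the published species-level rates:

```r
life_history_summary(c(blythii = 0.84, myotis = 0.80),
                     cbind(blythii = c(0, 0.33, 0.63, 1),
                           myotis = c(0, 0.93, 0.98, 1)),
                     phi_juv = c(blythii = 0.52, myotis = 0.52))
#>   species    afr phi_ad life_expectancy reproductive_years
#> 1 blythii 2.9179   0.84        5.735478           3.817578
#> 2  myotis 2.0714   0.80        4.481420           3.410020
#>   juvenile_survival_geomean
#> 1                      0.52
#> 2                      0.52
```

The lesser mouse-eared bat (*M. blythii*) starts breeding a year later but
lives longer, so the expected reproductive years of the two species end up
nearly equal — the life-history trade-off the study design was built to
measure.

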