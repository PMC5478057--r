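---
title: "Age-structured multistate capture-recapture: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-structured multistate capture-recapture: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msrecap)
```

## The process and observation model

`msrecap` models the annual fate of individually marked females that live
in one of two breeding colonies and are either experienced breeders or
not.  Four live states (1/2: not-yet-breeder in colony 1/2; 3/4: breeder
in colony 1/2) are augmented with an explicit dead state, so each of the
age-specific transition matrices is a proper 5 × 5 row-stochastic matrix
and the forward recursion is uniform.  Making death explicit, rather than
leaving it as a row deficit of a 4 × 4 matrix, is a deliberate design
choice: row-stochasticity becomes a testable invariant instead of an
implicit convention.

Three transition blocks cover the age structure:

* **age 0 → 1** (`juvenile_block()`): first-year apparent survival
  `phi_juv`, natal dispersal `n` between the colonies, and the
  probability `alpha[1]` of starting to breed at attained age 1;
* **attained ages 2–4** (`immature_block()`): adult survival `phi_ad`,
  breeding dispersal `b`, and `alpha[a]` at the attained age; rows 3–4 are
  the experienced-breeder rows of the same interval;
* **age 5 onward** (`experienced_block()`): breeder states only; this
  block also governs every interval of a female marked as an adult, whose
  exact age is unknown.

Having bred is absorbing: no transition returns from states 3/4 to 1/2,
and the data model refuses capture histories that violate this.

Two conventions here deserve a note because the standard matrix notation
is ambiguous about them.  First, `alpha` is indexed by the *attained*
age — the age reached at the end of the interval — so the 0 → 1 matrix
uses `alpha[1]` and the 3 → 4 matrix uses `alpha[4]`.  Second,
`alpha[4] = 1` is a structural constant (no female in the study was ever
observed to start breeding later than age four; without this bound the
last first-breeding probability is confounded with recapture).  With the
attained-age convention, fixing `alpha[4]` makes a separate "forced
breeding" 4 → 5 matrix redundant: after the age-4 transition every
survivor is a breeder, and the experienced block applies from age 5 on.

Covariates that vary over time resolve per interval *to the destination
year*: the interval from the capture season of year *t* to that of year
*t + 1* contains the spring cockchafer flight of year *t + 1*, so both
the survival and the first-breeding "cockchafer(time)" indicators use
year *t + 1*.  The cohort variant, "cockchafer(coh)", instead uses the
birth year of the female and is only meaningful for first-breeding
probabilities of known-age females.

## Likelihood and conditioning

Capture histories are mutually exclusive outcomes, so the observed
history counts are product-multinomial.  `history_nll()` evaluates one
history by the hidden-Markov forward recursion, conditioning on the first
release: the state distribution starts as a point mass on the state at
first capture, is propagated through the age-appropriate block each
interval, and is weighted at each later occasion by the detection
outcome — `p` at the observed state (collapsing the distribution) or
`1 - p` per live state when the female was not seen, with the dead state
carrying weight one.  There is no entry or recruitment modelling; the
model has no initial-state parameters, which mirrors conditioning on
release in classical multistate (Arnason–Schwarz) practice.

Recapture status follows the current latent state: states 1–2 use the
not-yet-breeder detection probability, states 3–4 the breeder one.
Females marked as adults are assigned to breeder states from marking on,
whatever their reproduction in the marking year, so they only inform
adult survival, breeding dispersal and breeder recapture.

The reported deviance is −2 × maximised log-likelihood without a
saturated-model constant.  Published deviances from capture–recapture
software include software-specific saturated terms, so absolute deviances
are not comparable across programs; all AIC differences and weights are
unaffected, which is why the model-selection layer is the comparison
surface.

A history that is *structurally* impossible under the model — for
instance a sighting at an occasion whose recapture probability is fixed
at zero — aborts the fit with a diagnostic listing the offending
individuals.  Silently dropping such rows would bias every estimate, and
a data error should be loud.

## Parameter coding

Effect structures per parameter family (`year`, `species`, `colony`,
`rep` status for recapture, `a2`/`a3` age classes for first breeding,
`cockchafer(time)`, `cockchafer(coh)`) are coded deterministically on the
logit scale: the first interactive (`*`) group becomes cell means, every
other term contributes treatment-coded offsets against a reference cell
(corner-point coding).  Additive effects are additive on the logit scale;
the source study does not state its link, and logit-additivity is the
standard choice in this model class.  Movement is always
direction-specific — `psi(juv: .)` is two constants (one per direction),
`psi(ad: spec)` crosses direction with species (four parameters) — since
the published movement estimates are direction-specific.

Parameters that the data cannot identify (the classic example is
first-year survival into the skipped 1994 occasion, confounded with the
zero recapture) are retained in the coding and flagged post hoc through
the rank of the Hessian, rather than removed a priori.  The published
parameter counts (e.g. 51 for the top model) depend on an undocumented
convention for counting confounded parameters, so parameter counts of the
full study models are not a reproduction target; the free-parameter count
of this package's coding for the top model is 48.

The candidate structures used in the study always keep the colony × year
interaction in the recapture model (one colony could not be sampled
normally in 2001).  The package does not hard-enforce that invariant,
because reduced designs — and the parameter-recovery studies below — use
constant recapture deliberately.

## Optimisation and uncertainty

Fitting maximises the likelihood with the PORT quasi-Newton routine
(`stats::nlminb`, relative tolerance 1e-10) from `starts` dispersed
initial points (the first at logit 0.5 for every parameter, the rest
uniform on (−2, 2) under a fixed per-fit seed).  A fit is flagged
`converged` when the optimizer reports success, the central-difference
gradient at the optimum is below 1e-3 relative to the NLL magnitude, and
the two best starts agree within 1e-4 in deviance.  The gradient
criterion is relative because an absolute 1e-8 norm is unattainable with
finite-difference derivatives on likelihoods of order 10³.

Standard errors come from the inverse of a finite-difference Hessian of
the NLL, mapped to the probability scale by the delta method.  When the
Hessian is singular the estimable subspace is inverted (eigenvalue
pseudo-inverse) and the rank is reported.  Estimates beyond |logit| > 10
are treated as boundary estimates and their SEs suppressed — a Wald SE at
the boundary is meaningless.

## Model selection and averaging

`rank_models()` computes `AIC = deviance + 2k`, ΔAIC and Akaike weights
over the full candidate set, sorting by ΔAIC with ties broken by fewer
parameters.  It accepts a plain deviance/parameter table so published
tables can be re-ranked without refitting.  `model_average()` keeps
models above a weight threshold (default 0.02, mirroring the study's
averaging rule), renormalises the weights, averages on the probability
scale, and reports the Burnham–Anderson unconditional standard error
`Σ w_i sqrt(se_i² + (θ_i − θ̄)²)`; the source cites "unconditional
standard errors" without a formula, and this is the standard form.
Whether the original weights were normalised over all 56 fitted models or
per displayed subset is unknowable from the publication; the package
always uses the full supplied set (weight *ratios* are invariant to that
choice, which is what the tests check against the printed weights).

## What the simulator emulates — and what it does not

`myotis_config()` reproduces the study conditions: 13 annual occasions
1989–2001 with the 1994 occasion skipped, two colonies, per-colony
cockchafer calendars (Naters 1990/1994/1998; Raron
1989/1992/1995/1998/2001, both areas in 1998), and releases totalling 430
lesser and 849 greater mouse-eared bat females of which 227 and 461 are
known-age juveniles.  The annual release numbers are unpublished, so the
schedule spreads each species' total uniformly over the marking years
1989–2000 (excluding 1994), split between colonies by the published
first-capture proportions (57% of *blythii* at Naters, 79% of *myotis* at
Raron).  Generating rates default to the published species-level
estimates: adult survival 0.84/0.80, first-year survival 0.52 (the
published geometric mean, held constant), first-breeding probabilities
(0, 0.33, 0.63, 1) and (0, 0.93, 0.98, 1), the published dispersal
probabilities, and constant recapture 0.7 (zero in 1994).  These values
were fixed once, from the publication, before any test was run.

Each simulated female consumes a pseudo-random stream derived from the
dataset seed and her index, so datasets are reproducible under partial
regeneration of the schedule.

The simulator deliberately omits features of real data: no individual
heterogeneity in survival or detection, no tag loss, no transience or
trap-dependence, no within-year processes, and year-constant first-year
survival where the real data show strong annual variation.  Passing
parameter-recovery tests therefore demonstrates the internal consistency
of generator, likelihood and optimizer — not robustness of the model to
the violations real bat data would bring.  The study's own
goodness-of-fit assessment of the general model came from external
software and is out of scope here.

## Numerical choices and degenerate inputs

* Probability parameters live on the logit scale; `logit()` refuses 0
  and 1 (a structurally zero or one cell is declared through
  `fix = list(...)`, not through the link).
* Dead-state entries are clamped at 0 against floating-point leakage of
  `1 − rowSums` (entries of order −1e-17 would otherwise inject sign
  errors into path probabilities).
* Histories with no occasion after release contribute zero
  log-likelihood (an empty product), and a dataset with no rows has
  deviance 0.
* Ties in AIC rank by parameter count; ties in both are left in input
  order.
* The fast grouped likelihood (histories grouped by species × age at
  marking × release occasion, duplicate observation rows collapsed with
  counts) is checked against the plain per-history recursion and against
  an exhaustive path-enumeration oracle in the test suite.

## Problem sizes used in validation

The parameter-recovery studies fit the generating model (constant
survival and recapture, `a3` first breeding with `alpha[1]` fixed at its
generating value 0, direction-specific dispersal) to 20 replicates per
species at the study's full release totals; recovery is judged within
three standard errors of the replicate mean.  The likelihood oracle
comparisons enumerate every valid observation sequence on designs of
three to five occasions under randomised rate sets.  Closed-form checks
use a 20-female adults-only design with perfect detection, where the
survival MLE must equal survivors/exposures.

## Known limitations

* Effect structures that share one additive term across the juvenile and
  adult survival families ("a2+spec"-style) are not representable —
  the two age classes are separate parameter families.  No published
  candidate model needs this form.
* Species-asymmetric structures written as per-species branches
  ("blythii: .; myotis: cockchafer") must be expressed through
  species × cockchafer interactions.
* No overdispersion (c-hat) adjustment, no Bayesian estimation, no
  random effects, and no individual covariates beyond
  species/colony/age/status.
* Averaged first-breeding probabilities feed the AFR formula on the
  probability scale; delta-method propagation into AFR is available but
  the published ±1.88 SE on one species' AFR is not a reproduction
  target.
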