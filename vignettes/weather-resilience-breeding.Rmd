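---
title: "Simulating selection for weather resilience in dairy small ruminants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating selection for weather resilience in dairy small ruminants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dairy goat and sheep production is sensitive to weather: an individual
animal's daily yield changes with ambient temperature, and the slope of
that relationship is itself heritable.  A breeding programme can
therefore select for *weather resilience* — but resilience is
genetically antagonistic to production level, so every percent of the
selection index spent on the slope is a percent not spent on yield.
`resilsim` is a forward stochastic simulator for quantifying that
trade-off: it propagates a closed nucleus across discrete generations
under the infinitesimal model and compares selection-index scenarios by
realized genetic gain, a standardized overall-progress statistic
(Index0) and economic profit under the current climate and under +1 °C
and +2 °C warming.

Two calibrated parameter sets ship with the package:

* `atlantic-goat` — a northern-European dairy goat programme (daily milk
  yield DMY, productive life Long, age at first kidding KA, mastitis
  incidence Mast).  Resilience is the slope of milk yield on daily
  temperature (kg/°C/day); because the Atlantic problem is weather
  *volatility* rather than sustained heat, the breeding objective is a
  slope of zero, and an alternative *stability* trait — the absolute
  value of the slope, with its own variance components — is also
  defined.
* `mediterranean-sheep` — a Spanish dairy sheep programme (milk, fat and
  protein yields, fertility).  Resilience is the slope of protein yield
  at heat-stress temperatures (g/°C/day); under sustained Mediterranean
  heat the objective is to push the slope toward positive values.
  Stability shares the slope's parameters, so absolute-mode runs reuse
  the slope trait with a stabilize-at-zero goal.

## The simulation model

**Base population.** For `n` founders (half of each sex), true breeding
values are drawn from MVN(0, **G**~0~) and environmental deviations
independently from MVN(0, **E**), where **G**~0~ and **E** are assembled
from the published per-trait variances and correlation matrices as
Σ~ij~ = ρ~ij~ √(σ²~i~ σ²~j~).  Continuous phenotypes are
base mean + TBV + deviation.  Published correlation estimates can be
jointly inconsistent after rounding; a matrix with a slightly negative
eigenvalue is repaired by clipping eigenvalues at zero and rescaling to
preserve the published variances (tolerance 1e−8), while a matrix whose
smallest eigenvalue is below −0.05 times the largest is rejected as a
data error.

**Genetic evaluation.** Breeding programmes rank animals on estimated,
not true, breeding values.  The simulator emulates an evaluation of
stated accuracy *r* per trait directly:

> EBV = *r* · TBV/σ~g~ + √(1 − *r*²) · z,  z ~ N(0, 1)

with noise independent across animals and traits, so the population
correlation between EBV and TBV converges to *r*.  Noise is re-drawn at
every generation (a repeated-evaluation programme).  This is the
simplest construction satisfying a stated accuracy; it deliberately
ignores error covariances between traits, for which no estimates are
available.

**Selection.** Within each generation EBVs are standardized (mean 0,
SD 1, population-SD convention), mapped to per-trait merits and combined
as index = Σ~k~ w~k~ merit~k~.  Merits encode the goal: +z to increase,
−z to decrease, and −|z − t~z~| for stabilizing goals.  The stabilizing
target t~z~ is re-anchored every generation:

> t~z~ = (target phenotype − current population mean) / (r σ~g~)

Re-anchoring matters.  A target fixed on the base-generation z scale
would exert the same directional pressure forever — the population would
overshoot the target and keep going.  With the tracking target the
pressure vanishes exactly when the mean sits on the target, which is
what stabilizing selection means; the goat milk-yield slope, stabilized
toward zero, settles at zero instead of diving past it.  The divisor
r σ~g~ is the SD of the EBV-based prediction of the genetic deviation,
i.e. the scale on which one z unit of selection moves the trait.

The best ⌈p·n⌉ animals of each sex are kept (goats: 30 % of males, 50 %
of females; sheep: 10 % and 50 %), ties broken by id so runs are
deterministic.

**Reproduction.** Parent pairs are drawn uniformly among selected
parents with remaining capacity (at most 100 offspring per sire and 7
per dam).  Offspring TBVs are the mid-parent mean plus a Mendelian
sampling deviation

> MS ~ MVN(0, 0.5 **G**~0~ (1 − F̄)),

where F̄ is the mean of the two parents' pedigree inbreeding
coefficients — the per-mating average, so a highly inbred pair transmits
less variation than the population average would suggest.  Environmental
deviations are fresh MVN(0, **E**) draws; offspring sexes alternate so
the split is exactly even.  No further variance re-inflation is applied:
the Bulmer-type erosion of genetic variance that selection induces
through the TBV recursion is left in place.

**Inbreeding.** Pedigree inbreeding is exact Wright/tabular-method
inbreeding, computed incrementally: the additive-relationship matrix is
carried only for each generation's selected parents (a few hundred
animals), which is sufficient both for offspring F (half the parents'
relationship) and for the next step of the recursion.  In the sheep
programme, fertility suffers linear inbreeding depression: the
continuous-scale phenotype is reduced by slope × F before thresholding.
No depression coefficient is published for this population; the packaged
value of 0.5 fertility-proportion per unit F is a round figure in the
range reported for fitness traits in small ruminants, chosen once and
not revisited.

**Binary traits.** Mastitis (goats) and fertility (sheep) are simulated
and selected on a continuous underlying scale with the published
variance components; recorded incidences are obtained by thresholding at
the fixed base-calibrated quantile (14 % mastitis, 42 % conception), so
selection response shows up as a change in incidence.  The published
fertility descriptives mix percent and proportion conventions; the
fixture stores fertility as a proportion in [0, 1].

## Scenario evaluation

**Index0** summarizes overall progress on everything except resilience:
each non-resilience trait's realized gain is standardized by its base
phenotypic SD, signed so the desirable direction is positive, weighted
by the *Base* scenario's weights, and summed.  A stabilizing trait
contributes its standardized reduction in distance to target,
w (|shift| − |Δ − shift|)/sd: an unchanged population scores zero and
landing on the target scores the maximum.  Gaining one phenotypic SD on
every desirable directional trait scores exactly 1.

**Profit** values realized gains at published economic weights (goats:
0.73 €/L milk, 0.055 €/day productive life, −0.16 € per month of kidding
age, −231 € per mastitis case; sheep: 0.73 €/kg milk, 0.072 €/g fat,
0.076 €/g protein, 137.6 € per lambing), with binary traits valued on
the incidence scale.  Warming enters through a loss term linear in the
temperature delta: L = mean slope × ΔT × climate price for actual-slope
resilience (the climate price is the milk price for goats, the protein
price for sheep), and L = −mean |slope| × ΔT × climate price for
stability, where any slope magnitude is a liability under increased
volatility.  At ΔT = 0 the slope is not priced (an option prices the
slope gain independently of warming); consequently profit differences
across ΔT are exactly linear.

**Scenario grids.** The packaged grids hold the production-trait weight
ratios of the Base index fixed (goats 5/31.25/18.75/45 over
DMY/Long/KA/Mast; sheep 43.75/21.875/21.875/12.5 over
DMY/DFY/DPY/Fert) while the resilience weight takes 0–40 % (goats) or
0–30 % (sheep); the goat stability family additionally includes variants
that pin milk yield at 14 % and split the remainder 20:12:44 over
Long/KA/Mast.  These reconstructions are anchored on the three index
weight vectors that are documented for these programmes
(4/25/15/36/20 and 14/20/12/44/10 for goats, 35/17.5/17.5/10/20 for
sheep); the full original grids were published only graphically, so
intermediate rows are the package's own interpolation under the
fixed-ratio rule.

## Reproducibility and problem sizes

Every replicate is seeded as `root_seed + replicate`, so a run is fully
reproducible and replicate seeds are shared across scenarios (common
random numbers, which sharpens scenario contrasts).  The packaged study
conditions are 1,000 animals per generation, 20 generations and 20
replicates per scenario — a single scenario runs in seconds.  The test
suite uses the full study conditions for the outcome-level checks and
smaller populations (40–60 animals, or single generations at
n = 20,000–50,000) for distributional and closed-form checks, sizes at
which Monte-Carlo error is far below the asserted tolerances.

## What the simulator does and does not emulate

The generator *is* the study design: parameters enter as published
means, variances, correlations and accuracies, and everything downstream
(selection response, inbreeding accumulation, profit ordering) is
emergent.  It does not emulate several features of real programmes:
overlapping generations and age structure, genomic evaluation, mate
allocation or optimal-contribution selection, seasonality, non-additive
inheritance beyond the linear fertility depression, or the derivation of
the resilience phenotype itself from weather and yield records (slopes
are simulated directly as traits).  Passing tests therefore demonstrate
internal consistency with quantitative-genetics theory — covariance
recovery, realized accuracies, the breeder's equation, tabular-method
inbreeding — not that any real population will realize the simulated
gains.

Two further caveats.  First, resilience trajectories depend strongly on
the between-trait correlation structure; with the packaged sheep
parameters the correlated decline of the slope under pure production
selection is modest (tenths of a g/°C/day over 20 generations), because
the printed production–slope correlations are small.  Second, under
drift alone the variance of a trait mean grows like t/(2N~e~), so
no-selection controls are judged against a drift-aware bound, not
against the base-population standard error.

## Known limitations

* The stability trait for goats needs a phenotypic mean and SD that were
  never published; the package derives them (0.047 ± 0.035 kg/°C/day)
  from the folded-normal distribution of the published slope, and labels
  them synthetic.
* EBV accuracy is treated as constant across generations even though
  selection erodes genetic variance, so realized within-generation
  accuracies drift slightly below nominal in late generations.
* Economic weights are held fixed across climates; re-deriving weights
  under warmed scenarios is out of scope.
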