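---
title: "Models and methods: quantitative genetics of a bivariate selection experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantitative genetics of a bivariate selection experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`qgsel` implements the complete quantitative-genetic analysis of a two-stage
family selection experiment on a pedigree-recorded fish population, where a
continuous trait (standard body length at 75 days, `Sdl`, mm) and a binary
threshold trait (maturity at 75 days, `Mat`) are selected jointly. This
vignette is the package's account of the underlying models, the estimation
choices, and what the test suite does and does not establish.

## The experimental design being modelled

Three lines are propagated in parallel from a common base population after
two generations of random mating: a Large line (the two largest mature fish
per sex are bred from each preselected family), a Small line (the two
smallest), and a Control line (random mature fish). Selection acts in two
stages every generation: among families at day 60 (10 of ~15 families kept,
on mean length, after discarding low-density tanks) and within families at
day 75 (truncation among mature fish only). Because immature fish can never
breed, all three lines also experience selection on maturity, and because
length and maturity are phenotypically correlated, the realized selection is
intrinsically bivariate. Pairs are assigned by a resampling optimizer that
minimizes the median prospective inbreeding coefficient of the offspring.

## Pedigree algebra

The additive relationship matrix **A** is built by the recursive tabular
method: `A_ii = 1 + F_i` with `F_i` the coancestry of the parents, and
`A_ij = (A_{j,s(i)} + A_{j,d(i)})/2`. Individuals with unknown parents are
founders, assumed unrelated and non-inbred. Inbreeding coefficients for
large pedigrees are computed without forming **A**, by the Meuwissen–Luo
`A = LDL'` accumulation, and the animal model consumes Henderson's sparse
**A**⁻¹ directly. A Monte-Carlo gene-dropping sampler (two distinct alleles
per founder, Mendelian transmission) provides an estimate of coancestry that
shares no code with the deterministic paths; the suite requires agreement
within three Monte-Carlo standard errors on small pedigrees.

The inbreeding effective size is reported from the linear approximation
`Ne = g / (2 * mean(F))`, i.e. an increment of `1/(2Ne)` per generation.
The compound form `1 - (1 - 1/2Ne)^g` differs only at the second decimal for
the inbreeding levels reached here; the linear form is what reproduces the
conventional rounded reports for this design (27, 33 and 35 for mean F of
0.11, 0.091 and 0.085 over six generations), and the test suite asserts the
reconciliation between the two forms explicitly.

`optimize_pairing()` scores `n_resamples` random candidate patterns (one
male and one female per pair, each candidate used at most once) by the
median prospective offspring inbreeding, with ties broken by the mean and
then by sampling order, so a seed makes the result reproducible. Sib pairs
are avoided through the optimization itself by default; `forbid_sibs` makes
them inadmissible. The count of resamples is configuration (default 10,000
for the standalone function; the experiment generator uses 200 per episode,
which on 20 + 20 candidates already finds a sib-free pattern essentially
always while keeping 200-replicate calibration studies affordable).

## Selection differentials and gradients

Effective differentials weight each breeder by its realized number of
surviving offspring. The among-family differential `S_a` is the
offspring-weighted mean of preselected family means minus the population
mean over *all* phenotyped fish (discarded families included — they are
phenotyped at day 75 precisely so that the population mean is unbiased).
The within-family differential `S_w` is the offspring-weighted mean
deviation of each breeder from its own family mean. With `t` the sib
phenotypic correlation (computed as the Pearson correlation over all ordered
within-family pairs), the expected responses are `h² S_a/(2t)` and
`h² S_w/(2(1-t))`, so the composite differential

> S = S_a / (2t) + S_w / (2(1−t))

predicts the response when multiplied by `h²`. Gradients are
**β** = **P**⁻¹**S** per line and generation, with maturity entering **P**
and **S** on the observed 0/1 scale (the latent probit scale is used only
inside the animal model and the predictions). Line-level gradients are
unweighted means over generations, reported with their SD.

Two degeneracies are handled explicitly rather than left to crash analyses:
a binary trait nearly fixed in a group makes `t` undefined or **P**
near-singular. `selection_summary()` clamps `t` into `[0.02, 0.98]` with a
warning and falls back to univariate gradients (`β = S/V_P` per trait) when
**P** cannot be inverted; the strict domain checks remain on the exported
single-purpose functions.

## Realized heritability by iterated GLS

For a selected line, the cumulative response relative to the Control line is
regressed through the origin on the cumulative composite differential. The
error covariance accounts for drift and sampling:

> V_ij = h² V_P (1/N + min(i,j)/Ne) + [i=j] V_P / N

The `min(i,j)` form is forced by symmetry: cumulative drift up to the
earlier of two generations is shared by both. Since V depends on `h²`, the
GLS is iterated from the OLS start until `|Δh²| < 1e-8` (convergence in a
handful of iterations in practice; 50 allowed). The estimate may be
negative — a response running against the differential — in which case the
drift term of V is floored at zero so V remains a covariance matrix while
the point estimate is reported as is. `Ne` defaults to 30, the
inbreeding-based estimate for this design; `N` is the phenotyped count per
generation (the constant drift term uses the first generation's count).

A caution that the package's own calibration quantifies: under bivariate
selection the univariate realized-h² estimand is *not* the base-population
h². With the default generator conditions (genetic correlation 0.6,
maturity ~90% and therefore under selection), the mean realized h² for a
true length h² of 0.30 is about 0.19–0.23 — correlated selection on the
maturity liability drags the length regression down. With maturity made
non-limiting the estimator recovers ≈ 0.28, the residual gap being the
Bulmer effect (selection-induced negative linkage disequilibrium shrinks the
usable additive variance within a few generations). The recovery test in
the acceptance suite therefore runs under the maturity-non-limiting
condition, where the estimand equals the nominal truth; the bivariate bias
is left visible in the default conditions because it is scientifically real
— it is the reason the bivariate animal model exists.

## The bivariate Gaussian–probit animal model

Each individual contributes

> y_ti = μ_t + f_t F_i + a_ti + u_{t,aq(i)} + g_{t,gen(i)} + e_ti

for traits t = length (Gaussian) and maturity (latent liability; the
observation is `1(y > 0)`). Random effects: breeding values with
cov(vec **a**) = **G** ⊗ **A** for all pedigree members (phenotyped or
not); aquarium effects (the rearing tank doubles as the full-sib family
identifier) with 2×2 covariance **AQ**; generation effects (8 levels, still
treated as random) with covariance **F**; residuals bivariate iid with
**E**, where `E[Mat,Mat] = 1` because a probit scale has no estimable
residual variance. The inbreeding coefficient enters as a fixed covariate
for both traits (full model only).

Fitting is single-site Gibbs with data augmentation, in compiled code:

1. **Liabilities**: truncated-normal draws from the residual conditional
   given the other trait (inverse-CDF-free rejection sampling, with Robert's
   exponential proposal in far tails). Missing values of either trait are
   imputed the same way without truncation. Draws beyond a configurable
   bound (default 12) are counted as divergent and reset to their
   conditional mean.
2. **Location effects**: intercepts and the inbreeding covariate jointly;
   breeding values individual-by-individual (jointly over traits) using the
   sparse **A**⁻¹ row; aquarium and generation levels one at a time.
3. **Components**: conditional inverse-Wishart updates, with prior
   `IW(ν = 2, Ψ)`. ν = 2 keeps the prior proper for two traits and denser
   near zero than ν = 3; Ψ defaults to `diag(phenotypic variance / 3)` per
   component (1 on the latent scale), configurable.
4. **Residual constraint**: an unconstrained residual matrix is drawn, then
   the binary dimension of the entire state (liabilities, effects, the Mat
   rows/columns of **G**, **AQ**, **F**) is rescaled so that
   `E[Mat,Mat] = 1` holds *exactly* in every stored draw (parameter
   expansion).
5. **Interweaving**: after the **G** update, the Cholesky factor of **G** is
   re-drawn in the non-centered parameterization `a = Ã L'` by independence
   Metropolis–Hastings (likelihood-exact Gaussian proposal, corrected by the
   IW prior and Cholesky Jacobian). This transfers variance between **G**
   and **E** in one move. It matters most when the split is weakly
   identified — in the extreme `A = I` case the split is *only*
   prior-identified and the posterior of h² is essentially the symmetric
   prior ridge; the interweaving roughly doubles the effective sample size
   per iteration there.

Default chain settings are desk-scale: 50,000 iterations, burn-in 5,000,
thinning 25, 4 chains, each chain seeded deterministically from the root
seed. Production-scale settings (e.g. 10⁶ iterations × 20 chains) are just
configuration. Summaries (2.5/50/97.5%) of components and of derived
quantities — `h²_t = G_tt / (G_tt + AQ_tt + E_tt)` and component
correlations — are computed per draw and pooled across chains, never from
summarized components. Diagnostics are Geyer initial-monotone ESS and
split-chain potential scale reduction (flagged above 1.1; reported as
unavailable with a single chain).

The model is fitted twice in the pipeline: a **full** scope (all data, with
the inbreeding covariate) describing the genetic architecture, and a
**predictive** scope restricted to the generations before the line split
plus the Control line afterwards, without the inbreeding covariate, so that
forecasts are independent of the selected lines' realized response.

## Trends, maternal effects, drift nulls

Genetic trends average breeding values per line × generation *within each
posterior draw*, then report the median and 95% support interval over draws
— the honest propagation of uncertainty. Heritable maternal effects `m` are
the per-draw OLS slope of the aquarium effect on the dam's breeding value
across aquaria (each tank maps to one dam), summarized as a posterior.

The drift null re-simulates neutral breeding values down the *observed*
pedigree, once per retained posterior **G** draw (subsampled to at most
5,000): founders `N(0, G)`, offspring centered on the midparent with
segregation covariance **G**/2. The envelope of line-mean breeding values
across replicates is the genetic space reachable by drift alone. The
segregation covariance is deliberately *not* shrunk by the parental
inbreeding correction `1 − (F_s + F_d)/2` — the uncorrected **G**/2 is the
conventional null for this analysis — but the corrected variant is
available behind `inbreeding_correction = TRUE`. A missing parent
contributes a fresh founder draw. Because the across-replicate variance of
a line mean grows by ≈ `V_G/Ne` per generation, regressing that variance on
generation (through the origin, from the line's first generation) gives a
drift-based `Ne = V_G / slope`, averaged over the two traits.

## Response prediction

Forecasts iterate Δ**μ** = **Gβ** on the scales where the infinitesimal
model is defensible: trait scale for length, latent probit scale for
maturity. Data-scale gradients are converted by the chain rule — the
maturity entry is multiplied by `φ(μ/√(1+v))/√(1+v)`, the derivative of the
data-scale mean `p = Φ(μ/√(1+v))` — and the Jacobian is re-evaluated at the
current mean each generation (a frozen-Jacobian mode exists for sensitivity
analysis). Each posterior **G** draw yields a trajectory; drift adds
`N(0, G/Ne)` per generation (default `Ne = 25`, the drift-based estimate
for this design). The extra latent variance `v` used in the conversions
defaults to the current draw's `V_G(Mat)` (plus the fixed residual 1);
aquarium and generation variances are treated as nuisance environment and
excluded by default, but a fixed `v` including them can be supplied —
which variances belong in the conversion is genuinely underdetermined, and
the choice is exposed rather than hidden.

## The experiment generator

`simulate_experiment()` creates the full design with known truth: ~54
founder families (unrelated, unrecorded parents), one recorded random-mating
generation (~56 pairs), allocation of the resulting families to three lines,
then six episodes of two-stage selection with optimized pairing. Phenotypes
are built additively from stored components (intercept, inbreeding
depression `f_t F_i`, breeding value, aquarium effect, generation effect,
residual), so `recombine_truth()` reproduces the tables bit-exactly —
an invariant the suite asserts. Family sizes are rounded normal (mean 15,
SD 5.8, floor 4); generation effects are drawn fresh per dataset and shared
across lines; maturity liability shares the full covariance structure with
length; the default liability intercept (2.4) puts ~90% of fish past the
threshold.

Default true components are realistic for a small laboratory fish: **G**
with `V_G(Sdl) = 0.86` mm², latent `V_G(Mat) = 0.51`, genetic correlation
0.6; residual `V_E(Sdl) = 3.34` with residual correlation ≈ 0.94; tank
variance 1.40/0.50; generation variance 1.05/1.53; inbreeding-depression
coefficients −6.78 mm and −10.21 probits per unit `F`. These place `h²(Sdl)`
at ≈ 0.15, mean length at 20 mm, and the realized inbreeding after six
episodes near 0.10 — i.e. the generator reproduces the design's published
summary statistics as emergent properties, not as inputs.

One deviation from a literal reading of the design is deliberate: a family
with fewer than the required mature fish per sex is normally skipped
(mirroring real attrition), but when skipping would leave a line with fewer
than `max(2, n_pairs/3)` candidates of a sex, shortfall families are
re-admitted with however many mature fish they have. Under the default
conditions the Small line can otherwise go extinct in a minority of runs —
through the genetic correlation, downward selection on length drags the
maturity liability down, inbreeding depression pushes the same way, and one
bad generation effect then leaves too few mature fish — whereas the real
protocol, which followed its theoretical pairing "as close as possible",
never lost a line.

The generator's maturity crash dynamics, family-size distribution and
density filtering emulate the recorded design, but several features of real
data are *not* represented: measurement error in length, sex-identification
errors in immature fish, non-genetic parental effects beyond the shared
tank, viability/fecundity selection beyond the density filter, and any
genotype-by-environment interaction. Passing the recovery tests therefore
shows the estimators are correct *under the infinitesimal model*, not that
real data obey it — indeed the mismatch between such predictions and the
real experiment's response is the scientific point of the original study.

## Numerical choices and problem sizes

* Truncated-normal sampling switches to Robert's exponential-rejection
  proposal beyond 0.45 SD into the tail; inverse-Wishart draws use the
  Bartlett construction on R's RNG so every result is reproducible from a
  single integer seed (chains and pipeline stages derive named sub-seeds).
* PSD square roots in the simulators use eigendecompositions with negative
  eigenvalues clamped at zero, so exactly-zero covariance matrices produce
  exactly degenerate draws.
* Ties in truncation selection are resolved by stable id order; ties in the
  pairing optimizer by median, then mean, then sampling order.
* The test and calibration runs use reduced but honest problem sizes chosen
  as the package's own desk-scale defaults: the full-design generator
  (~5,300 fish) for variance-component recovery (20 replicates, 12,000
  iterations each) and for the end-to-end benchmark quantities; 200
  two-line replicates for realized-h² calibration; 4 × 120,000 iterations
  for the prior-identified `A = I` case; 2,000 replicates for drift
  calibration on a 50-fish, 10-generation random-mating pedigree.

## Known limitations

* The sampler is single-site over individuals; for very deep pedigrees with
  few phenotypes per individual, mixing of breeding values is slower than a
  blocked (sparse-Cholesky) location update would be. The interweaving move
  compensates for the variance-split direction but not for local
  autocorrelation, so long chains remain advisable — as they were for the
  original analyses of this design.
* Two traits maximum; no dominance, no epistasis, no
  genotype-by-environment terms; REML/frequentist fitting is out of scope.
* The drift-Ne regression assumes variance grows linearly from the line's
  first generation; with very few generations the estimate is noisy, and
  the function refuses to report when the fitted slope is non-positive.
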