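---
title: "Indirect genetic effects and heritability under assortative mating: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect genetic effects and heritability under assortative mating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The phenotype model

`igeq` works with a quantitative phenotype shaped by three ingredients:

* **direct genetic effects (DGEs)** — effects of an individual's own alleles
  on their own phenotype, summed into the component
  $\Delta_{ij} = \sum_l \delta_l (g_{ijl} - 2 f_l)$;
* **parental indirect genetic effects (IGEs, "genetic nurture")** — effects
  of the *parents'* alleles on the offspring phenotype through the rearing
  environment, entering as $\eta_{p(i)} + \eta_{m(i)}$ with per-variant
  average parental effects $\eta_l$;
* a residual $\epsilon_{ij}$, so that
  $Y_{ij} = \Delta_{ij} + \eta_{p(i)} + \eta_{m(i)} + \epsilon_{ij}$.

Variants are bi-allelic with frequencies $f_l$ assumed constant across
generations, and segregate independently. Maternal-paternal IGE asymmetry is
absorbed into the residual; only the average parental IGE is modelled.

Under random mating the phenotypic variance decomposes as
$v_g + v_{e\sim g} + c_{ge} + \sigma^2_\epsilon$ with
$v_g = 2\sum_l \delta_l^2 f_l(1-f_l)$,
$v_{e\sim g} = 4\sum_l \eta_l^2 f_l(1-f_l)$ and
$c_{ge} = 4\sum_l \delta_l \eta_l f_l(1-f_l)$
(`randomMatingComponents()`). The genome-wide effect correlation
$r_{\delta\eta 0} = c_{ge}/\sqrt{2 v_g v_{e\sim g}}$ parameterizes how much
nurture "runs along" the same variants as direct effects.

## Assortative mating at equilibrium

Positive phenotypic matching of mates induces correlations between the
parental components, summarized by four numbers
(`EquilibriumCorrelations`): $r_\delta$ between parents' DGE components,
$r_\eta$ between their IGE components, and the cis/trans DGE-IGE
correlations $r_{\delta\eta}^{c}$, $r_{\delta\eta}^{\tau}$. After a
handful of generations the system approaches an equilibrium in which
(`equilibriumDecomposition()`):

$$v_g^{eq} = \frac{v_g}{1 - r_\delta},\qquad
  v_{e\sim g}^{eq} = \frac{1 + r_\eta}{1 - r_\eta}\, v_{e\sim g},\qquad
  c_{ge}^{eq} = (r_{\delta\eta}^{c} + r_{\delta\eta}^{\tau})
   \sqrt{\frac{2\, v_{e\sim g}\, v_g}{(1 - r_\eta)(1 - r_\delta)}}.$$

The first factor is the classical Crow-Felsenstein inflation; the other two
generalize it to nurtured phenotypes. Two heritabilities matter:
the equilibrium heritability $h^2_{eq} = v_g^{eq}/v_y^{eq}$, and the
"family-based" estimand $h^2_f = v_g/v_y^{eq} = (1 - r_\delta) h^2_{eq}$,
which is what twin ACE models, sibling realized-relatedness regression and
RDR estimate. `sibRegressionExpectation()` gives the expected slope
($h^2_f$) and intercept of the sib-regression, whose $r_\delta h^2_{eq}$
term shows why AM masquerades as shared environment.

### Resolving two ambiguous groupings

Two expressions in the published form of this theory admit more than one reading;
we resolved both by derivation and pinned the result on the forward
simulator (the tests treat the simulator as the authority):

* **The equilibrium covariance term.** If $r_{\delta\eta}^{c}$ and
  $r_{\delta\eta}^{\tau}$ are *bona fide correlations of equilibrium
  components* — which is what a simulation measures — then writing
  $\Delta_{\text{offspring}} = (\Delta_p + \Delta_m)/2 + \text{Mendelian
  noise}$ and using the component variances above forces the
  $\sqrt{(1-r_\eta)(1-r_\delta)}$ denominator shown, not the unrooted
  product. The simulator check (empirical $2\,\mathrm{Cov}(\Delta,
  \eta_p+\eta_m)$ at generation 20) discriminates sharply between the
  candidates. The same convention gives the alternative route
  `equilibriumCgeFromCge0()`:
  $c_{ge}^{eq} = c_{ge}\bigl(1 + 2 r_{\delta\eta}^{\tau} /
  (r_{\delta\eta 0}\sqrt{(1-r_\delta)(1-r_\eta)})\bigr)$, exact under the
  equilibrium identity $r_{\delta\eta}^{c} =
  r_{\delta\eta 0}\sqrt{(1-r_\delta)(1-r_\eta)} + r_{\delta\eta}^{\tau}$.
* **$r_\delta$ under primary phenotypic assortment.** Linear matching on
  the phenotype gives $\mathrm{Cov}(\Delta, Y) = v_g^{eq} + c_{ge}^{eq}/2$
  and hence `rdeltaPhenotypicAssortment()`:
  $r_\delta = h^2_{eq} r_Y (1 + c_{ge}^{eq}/(2 v_g^{eq}))^2$, reducing to
  the classic $h^2_{eq} r_Y$ without IGE-DGE covariance. The squared form
  matches the simulator; a ratio-style reading does not.

One further relation required correction: the NTC-to-direct-effect ratio of
an incomplete PGI must be
$\alpha_{PGI:k}/\delta_{PGI:k} = [(1+r_\delta)\alpha_\delta +
(1-\rho_k)]/(\rho_k (1+r_k))$. The $\rho_k$ in the denominator is forced by
the population-effect identity $\beta = \delta + (1+r_k)\alpha$ together
with $\delta/\beta = \rho_k/(1+(1+r_\delta)\alpha_\delta)$, and makes the
two $\alpha_\delta$ estimators exact mutual inverses of the two ratio
relations; a version without it is internally inconsistent.

## PGI analysis and the estimating equations

For a standardized PGI explaining a fraction $k$ of heritability under
random mating, AM alone shrinks the within-family (direct) effect relative
to the population effect by $\rho_k = 1 - (1-k) r_\delta$ (`rhoK()`), and
links the observed parental-PGI correlation to the component correlation by
$r_\delta = r_k/(k + (1-k) r_k)$ (`estimateRdelta()`). IGEs shift the
observed ratios away from these baselines through $\alpha_\delta$, the
average non-transmitted coefficient the *complete* DGE PGI would have,
$\alpha_\delta = c_{ge}^{eq}/(2 (1+r_\delta) v_g^{eq})$ (`trueDgeNtc()`),
whose phenotypic-variance contribution is
$v_{\eta:\delta} = 2(1+r_\delta)\alpha_\delta(1+\alpha_\delta) h^2_{eq}$.

`runTwoGenInference()` chains the estimating equations
$k \to r_\delta \to h^2_{eq} \to \rho_k \to \alpha_\delta \to
v_{\eta:\delta}$ from four observables: the two-generation regression
coefficients $(\hat\delta_k, \hat\alpha_k)$ (or the $\delta/\beta$ ratio),
$\hat r_k$, and an external $\hat h^2_f$. Design choices:

* **$\alpha_\delta$ estimator.** The NTC-ratio estimator (estimator 2) is
  the default because $\hat\alpha_k$ and $\hat\delta_k$ come from the same
  regression, so their sampling covariance is available; the
  $\delta/\beta$-ratio estimator (estimator 1) is used when only the ratio
  is published. On consistent inputs they coincide.
* **$k$ estimation.** $k = (1-r_k)\hat\delta_k^2/\hat h^2_f$, with optional
  sampling-error corrections $(1 - \hat z_f^{-2})(\hat\delta_k^2 -
  \mathrm{Var}(\hat\delta_k))$. Estimates are clipped to $[0,1]$ with a
  recorded flag rather than failing; a negative corrected numerator maps to
  $k = 0$.
* **Stability.** The equations are ratios of small quantities when
  $k$ is tiny; the pipeline records an `unstable_small_k` warning when
  $\hat k < 0.05$ or $k + (1-k) r_k < 0.05$. The threshold is our choice;
  instability near $k \approx 0.01$ is a documented property of the
  equations, not of the implementation.
* **Standard errors.** Delta method with a *numeric* Jacobian (central
  differences, per-coordinate step $\max(10^{-6}, 10^{-4}|x|)$), treating
  the regression-coefficient block, $\hat r_k$ and $\hat h^2_f$ as
  mutually independent (the heritability comes from an external study and
  $r_k$ from parents only). When $\hat r_k$'s SE is unavailable the
  default $(1-r_k^2)^2/n$ variance is used and flagged. The propagation is
  validated by Monte-Carlo calibration at the summary-statistic level: the
  mean delta-method SE of $\hat r_\delta$ tracks the replicate SD within a
  few percent when inputs are precise (test suite).

```{r example}
library(igeq)
runTwoGenInference(TwoGenInputs(
  ratioHat = 0.910, ratioSe = 0.009, rKHat = 0.106, rKSe = 0.020,
  h2fHat = 0.554, h2fSe = 0.044, kOverride = 0.452, kSe = 0.038))
```

## The forward simulator

`runSimulation()` implements the generative process the theory describes:

1. founders: genotypes $\mathrm{Binomial}(2, f_l)$ at 1000 variants with
   MAFs drawn with density $\propto 1/f$ on $[0.05, 0.5]$ (the spectrum of
   a constant-size random-mating population), random pairing;
2. effects $(\delta_l, \eta_l)$ bivariate standard normal with correlation
   $r_{\delta\eta 0} \in \{0, 0.5, 1\}$, then rescaled once so the founder
   offspring generation has $\mathrm{Var}(\Delta) = 0.5$ and
   $\mathrm{Var}(\eta_p + \eta_m) \in \{0, 0.125\}$, with
   $\sigma^2_\epsilon$ set so founder $\mathrm{Var}(Y) = 1$. The scaling
   constants are **frozen** thereafter — effect sizes stay fixed and all
   later variance growth is emergent from mating;
3. each generation: mates are rank-matched on $Z = Y + u$, with
   $\mathrm{Var}(u) = (1/r_Y - 1)\, v_y$ computed from the *current*
   parental generation's empirical variance, so the realized spousal
   correlation tracks $r_Y \in \{0, 0.25, 0.5, 0.75\}$; meiosis draws one
   allele per parent per variant independently (no linkage); each family
   has one male and one female offspring, guaranteeing balanced pools.

Truth tracking: each generation records empirical $v_g$, $v_{e\sim g}$,
$c_{ge}$, $\mathrm{Var}(Y)$, the four parental-component correlations
(sample correlations over mated pairs — no analytic recurrences), and the
realized spousal correlation. `buildPgi()` makes DGE or population-effect
PGIs with white weight noise at multiples $\{0, 1, 10, 100\}$ of the weight
variance, realizing $k \approx 1/(1+\text{multiple})$, and emits the
two-sibling family table the regression module consumes.

**Problem sizes.** The full study design is 30000 families for 20
generations of mating after the founder generation; the package's
`reduced` profile keeps all 1000 variants and all 20 generations but uses
3000 families, which we chose so that the whole 16-scenario grid runs in a
few minutes while Monte-Carlo error remains small. We deliberately did
*not* shorten the generation count: the variance components approach
equilibrium geometrically at rate $(1+r_\delta)/2$ per generation, so under
strong assortment ($r_Y = 0.75$, $r_\delta \approx 0.7$) a 12-generation
run is still visibly short of equilibrium while 20 generations is close.
Even at 20 generations the most extreme scenario
($r_{\delta\eta 0} = 1$, $r_Y = 0.75$, equilibrium variance $\approx 5$)
retains a small, seed-stable truncation offset between the equilibrium
prediction and the simulated variance; the corresponding agreement check in
the test suite documents this rather than hiding it.

**What the simulator does and does not emulate.** It reproduces Mendelian
trio structure, primary phenotypic assortment, genetic-nurture
confounding, and noisy PGI weights. It does not include linkage
disequilibrium, allele-frequency change, population stratification,
sibling-to-sibling IGEs, or realized-relatedness (IBD-segment) variation —
so passing tests validate the estimating equations under the model's own
assumptions, not robustness to stratified or LD-structured real data, and
the sib-regression results are covered analytically only.

## Degenerate inputs, ties, and other numerical choices

* Zero variances propagate zeros (e.g. the effect correlation is defined
  as 0 when either $v_g$ or $v_{e\sim g}$ is 0), so random-mating and
  no-IGE limits are first-class rather than errors.
* Rank matching breaks ties by the continuous matching noise itself;
  at $r_Y = 0$ pairing is an RNG permutation.
* PGI centering uses founder allele frequencies throughout (frequencies
  are treated as constant across generations; empirical drift is ignored).
* All PGIs in a family table are scaled by the *proband* PGI standard
  deviation — one common constant — because the coefficient identities
  assume parents and offspring share a scale; per-column standardization
  would distort $\beta = \delta + (1+r_k)\alpha$.
* Family-clustered (sandwich) covariance is the default for the
  two-generation regression because the simulator emits sibling pairs;
  `oneSibPerFamily = TRUE` reproduces independent-trio analysis.
* When both the ratio and the regression coefficients are supplied, their
  consistency under $\beta = \delta + (1+r_k)\alpha$ is checked to
  $10^{-6}$ and a mismatch is an error, not a silent preference.

## Limitations

* $h^2_f$ is always an input; the package does not estimate heritability
  from real relatedness data.
* The incomplete-PGI theory is derived under an equal-frequency,
  equal-effect subset model; its adequacy for noisy-weight PGIs is
  established by simulation (parameter recovery), not by algebra.
* Population-stratification confounding is outside the model; applying the
  pipeline to population-effect PGIs tests a null of "no IGEs or
  confounding beyond AM" rather than measuring IGEs.
* Delta-method SEs degrade together with the point estimates when
  $k \lesssim 0.05$; the pipeline warns but does not refuse.
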