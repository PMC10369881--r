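#' Construct random-mating variance components from parameters
#'
#' Builds a [RandomMatingComponents-class] object from the DGE-component
#' variance \code{vg}, the summed-parental-IGE variance \code{veg}, the
#' genome-wide DGE-IGE correlation \code{rDgIg0} and the residual variance,
#' setting \code{cge = rDgIg0 * sqrt(2 * vg * veg)}.
#'
#' @param vg DGE-component variance under random mating.
#' @param veg variance of the summed parental IGE component under random
#'   mating.
#' @param rDgIg0 genome-wide correlation between standardized DGEs and IGEs.
#' @param sigmaEps2 residual variance.
#' @return A [RandomMatingComponents-class] object.
#' @examples
#' RandomMatingComponents(vg = 0.5, veg = 0.125, rDgIg0 = 0.5,
#'                        sigmaEps2 = 0.2)
#' @export
RandomMatingComponents <- function(vg, veg, rDgIg0 = 0, sigmaEps2 = 0) {
  cge <- rDgIg0 * sqrt(2 * vg * veg)
  new("RandomMatingComponents",
      vg = vg, veg = veg, cge = cge, sigmaEps2 = sigmaEps2,
      rDgIg0 = rDgIg0, vy = vg + veg + cge + sigmaEps2)
}

#' Construct equilibrium correlations
#'
#' @param rDelta correlation between parents' DGE components.
#' @param rEta correlation between parents' IGE components.
#' @param rDeCis within-parent DGE-IGE correlation.
#' @param rDeTrans cross-parent DGE-IGE correlation.
#' @return An [EquilibriumCorrelations-class] object.
#' @examples
#' EquilibriumCorrelations(rDelta = 0.2)
#' @export
EquilibriumCorrelations <- function(rDelta = 0, rEta = 0,
                                    rDeCis = 0, rDeTrans = 0) {
  new("EquilibriumCorrelations", rDelta = rDelta, rEta = rEta,
      rDeCis = rDeCis, rDeTrans = rDeTrans)
}

#' Random-mating variance decomposition from per-variant effects
#'
#' Computes the random-mating variance components for a phenotype affected by
#' direct genetic effects (DGEs) and average parental indirect genetic
#' effects (IGEs) at L independently segregating bi-allelic variants:
#' \deqn{v_g = 2 \sum_l \delta_l^2 f_l (1 - f_l), \quad
#'       v_{e\sim g} = 4 \sum_l \eta_l^2 f_l (1 - f_l), \quad
#'       c_{ge} = 4 \sum_l \delta_l \eta_l f_l (1 - f_l).}
#' The genome-wide DGE-IGE correlation is recovered as
#' \code{rDgIg0 = cge / sqrt(2 vg veg)} (0 when either variance is 0).
#'
#' @param dgeEffects numeric, per-variant DGE sizes.
#' @param igeEffects numeric, per-variant average parental IGE sizes.
#' @param freqs numeric, per-variant allele frequencies in (0, 1).
#' @param sigmaEps2 residual variance.
#' @return A [RandomMatingComponents-class] object.
#' @examples
#' randomMatingComponents(1, 0, 0.5)  # vg = 0.5 for a single variant
#' @export
randomMatingComponents <- function(dgeEffects, igeEffects, freqs,
                                   sigmaEps2 = 0) {
  n <- length(freqs)
  if (length(dgeEffects) != n || length(igeEffects) != n) {
    stop("dgeEffects, igeEffects and freqs must have equal length")
  }
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)")
  }
  het <- freqs * (1 - freqs)
  vg <- 2 * sum(dgeEffects^2 * het)
  veg <- 4 * sum(igeEffects^2 * het)
  cge <- 4 * sum(dgeEffects * igeEffects * het)
  rDgIg0 <- if (vg > 0 && veg > 0) cge / sqrt(2 * vg * veg) else 0
  new("RandomMatingComponents",
      vg = vg, veg = veg, cge = cge, sigmaEps2 = sigmaEps2,
      rDgIg0 = rDgIg0, vy = vg + veg + cge + sigmaEps2)
}

#' Equilibrium variance decomposition under assortative mating
#'
#' Maps the random-mating components and the equilibrium correlations between
#' parents' DGE and IGE components to the equilibrium decomposition:
#' \deqn{v_g^{eq} = \frac{v_g}{1 - r_\delta}, \quad
#'       v_{e\sim g}^{eq} = \frac{1 + r_\eta}{1 - r_\eta} v_{e\sim g}, \quad
#'       c_{ge}^{eq} = (r_{\delta\eta}^{c} + r_{\delta\eta}^{\tau})
#'         \sqrt{\frac{2 v_{e\sim g} v_g}{(1 - r_\eta)(1 - r_\delta)}}.}
#' The covariance term uses the square root of the full product because
#' \code{rDeCis}/\code{rDeTrans} are correlations of the equilibrium
#' components, whose standard deviations are the random-mating ones inflated
#' by \code{1/sqrt(1 - rDelta)} and \code{1/sqrt(1 - rEta)}; this grouping is
#' pinned against the forward simulator in the test suite.
#'
#' @param rm A [RandomMatingComponents-class] object.
#' @param corr An [EquilibriumCorrelations-class] object (with
#'   \code{rDelta < 1}, \code{rEta < 1}).
#' @return An [EquilibriumComponents-class] object; \code{vyEq} is the sum of
#'   the three genetic terms and \code{rm@sigmaEps2}, \code{h2Eq = vgEq/vyEq},
#'   and \code{h2F = vg/vyEq}.
#' @examples
#' rm <- RandomMatingComponents(0.5, 0.125, 0.5, sigmaEps2 = 0.2)
#' equilibriumDecomposition(rm, EquilibriumCorrelations(rDelta = 0.2))
#' @export
equilibriumDecomposition <- function(rm, corr) {
  stopifnot(is(rm, "RandomMatingComponents"),
            is(corr, "EquilibriumCorrelations"))
  if (corr@rDelta >= 1 || corr@rEta >= 1) {
    stop("rDelta and rEta must be < 1")
  }
  vgEq <- rm@vg / (1 - corr@rDelta)
  vegEq <- rm@veg * (1 + corr@rEta) / (1 - corr@rEta)
  cgeEq <- if (rm@vg > 0 && rm@veg > 0) {
    (corr@rDeCis + corr@rDeTrans) *
      sqrt(2 * rm@veg * rm@vg / ((1 - corr@rEta) * (1 - corr@rDelta)))
  } else 0
  vyEq <- vgEq + vegEq + cgeEq + rm@sigmaEps2
  new("EquilibriumComponents",
      vgEq = vgEq, vegEq = vegEq, cgeEq = cgeEq, sigmaEps2 = rm@sigmaEps2,
      vyEq = vyEq, h2Eq = if (vyEq > 0) vgEq / vyEq else 0,
      h2F = if (vyEq > 0) rm@vg / vyEq else 0)
}

#' Equilibrium DGE-IGE covariance term via the random-mating covariance
#'
#' Alternative expression for the equilibrium covariance term in terms of the
#' random-mating covariance \code{cge} and the trans-parental correlation:
#' \deqn{c_{ge}^{eq} = c_{ge}\left(1 +
#'   \frac{2\, r_{\delta\eta}^{\tau}}
#'        {r_{\delta\eta 0}\sqrt{(1 - r_\delta)(1 - r_\eta)}}\right),}
#' valid when the genome-wide DGE-IGE correlation \code{rDgIg0} is nonzero.
#' Assortative mating increases the magnitude of this term whenever
#' \code{rDeTrans * rDgIg0 > 0}. At equilibrium the cis correlation satisfies
#' \code{rDeCis = rDgIg0 * sqrt((1 - rDelta)(1 - rEta)) + rDeTrans} (the
#' random-mating effect correlation diluted by the AM-inflated component
#' standard deviations, plus the AM-induced part), under which this route
#' agrees exactly with [equilibriumDecomposition()]'s covariance term; the
#' grouping is pinned against the forward simulator in the test suite.
#'
#' @inheritParams equilibriumDecomposition
#' @return numeric(1), the equilibrium covariance term.
#' @export
equilibriumCgeFromCge0 <- function(rm, corr) {
  stopifnot(is(rm, "RandomMatingComponents"),
            is(corr, "EquilibriumCorrelations"))
  if (rm@rDgIg0 == 0) {
    stop("rDgIg0 is zero: use equilibriumDecomposition() instead")
  }
  if (corr@rDelta >= 1 || corr@rEta >= 1) stop("rDelta and rEta must be < 1")
  rm@cge * (1 + 2 * corr@rDeTrans /
              (rm@rDgIg0 * sqrt((1 - corr@rDelta) * (1 - corr@rEta))))
}

#' Parental DGE-component correlation under primary phenotypic assortment
#'
#' Under primary phenotypic assortment (mates matched on the observed
#' phenotype, linear component-phenotype regression), the correlation between
#' parents' DGE components is
#' \deqn{r_\delta = h^2_{eq}\, r_Y \left(1 +
#'   \frac{c_{ge}^{eq}}{2 v_g^{eq}}\right)^2,}
#' which reduces to the classic \code{rDelta = h2Eq * rY} when the DGE and
#' IGE components are uncorrelated at equilibrium. The squared grouping
#' follows from \code{Cov(Delta, Y) = vgEq + cgeEq/2} under linear matching
#' and is pinned against the forward simulator in the test suite.
#'
#' @param h2Eq equilibrium heritability.
#' @param rY spousal phenotypic correlation.
#' @param cgeEq equilibrium DGE-IGE covariance term.
#' @param vgEq equilibrium DGE-component variance (> 0).
#' @return numeric(1), the implied \code{rDelta}.
#' @examples
#' rdeltaPhenotypicAssortment(h2Eq = 0.5, rY = 0.5)  # classic 0.25
#' @export
rdeltaPhenotypicAssortment <- function(h2Eq, rY, cgeEq = 0, vgEq = 1) {
  if (vgEq <= 0) stop("vgEq must be > 0")
  h2Eq * rY * (1 + cgeEq / (2 * vgEq))^2
}

#' Expected sib-regression slope and intercept
#'
#' Expectation of the regression of the sibling phenotype cross-product
#' (scaled by \code{vyEq}) on realized identity-by-descent relatedness:
#' slope \code{vg/vyEq} (the family-based heritability estimand \code{h2F})
#' and intercept
#' \code{rDelta * h2Eq + (vegEq + cgeEq + residCov)/vyEq}. Under assortative
#' mating the intercept is positive even with no shared sibling environment,
#' so naive readings overstate shared-environment variance; subtracting
#' \code{rDelta/(1 - rDelta) * h2F} recovers the shared-environment part.
#'
#' @param rm A [RandomMatingComponents-class] object.
#' @param eq The paired [EquilibriumComponents-class] object.
#' @param corr An [EquilibriumCorrelations-class] object.
#' @param residCov expected residual covariance between siblings.
#' @return A [SibRegressionExpectation-class] object.
#' @export
sibRegressionExpectation <- function(rm, eq, corr, residCov = 0) {
  stopifnot(is(rm, "RandomMatingComponents"),
            is(eq, "EquilibriumComponents"),
            is(corr, "EquilibriumCorrelations"))
  if (eq@vyEq <= 0) stop("vyEq must be > 0")
  slope <- rm@vg / eq@vyEq
  intercept <- corr@rDelta * eq@h2Eq +
    (eq@vegEq + eq@cgeEq + residCov) / eq@vyEq
  new("SibRegressionExpectation",
      slope = slope, intercept = intercept, residCov = residCov)
}

#' Equilibrium heritability from the family-based estimand
#'
#' Inflates a family-based heritability estimate (twin ACE, sib-regression,
#' RDR — all of which estimate \code{h2F = vg/vyEq}) by the assortative-mating
#' correction factor: \code{h2Eq = h2F / (1 - rDelta)}.
#'
#' @param h2F family-based heritability estimand.
#' @param rDelta correlation between parents' DGE components (< 1).
#' @return numeric(1), equilibrium heritability.
#' @examples
#' h2eqFromH2f(0.554, 0.208)
#' @export
h2eqFromH2f <- function(h2F, rDelta) {
  if (any(rDelta >= 1)) stop("rDelta must be < 1")
  h2F / (1 - rDelta)
}

#' Flat named-list view of a component object
#'
#' Returns the numeric fields of a component/correlation/coefficient object
#' as a flat named list with snake_case keys, the serialization used by the
#' JSON outputs and the simulator's per-generation summary table.
#'
#' @param x a [RandomMatingComponents-class], [EquilibriumCorrelations-class],
#'   [EquilibriumComponents-class] or [PGICoefficients-class] object.
#' @return named list of numeric scalars.
#' @export
setGeneric("asFlatList", function(x) standardGeneric("asFlatList"))

#' @rdname asFlatList
#' @export
setMethod("asFlatList", "RandomMatingComponents", function(x) {
  list(vg = x@vg, ve_g = x@veg, cge = x@cge, sigma_eps2 = x@sigmaEps2,
       r_dg_ig_0 = x@rDgIg0, vy = x@vy)
})

#' @rdname asFlatList
#' @export
setMethod("asFlatList", "EquilibriumCorrelations", function(x) {
  list(r_delta = x@rDelta, r_eta = x@rEta,
       r_de_cis = x@rDeCis, r_de_trans = x@rDeTrans)
})

#' @rdname asFlatList
#' @export
setMethod("asFlatList", "EquilibriumComponents", function(x) {
  list(vg_eq = x@vgEq, ve_g_eq = x@vegEq, cge_eq = x@cgeEq,
       sigma_eps2 = x@sigmaEps2, vy_eq = x@vyEq, h2_eq = x@h2Eq,
       h2_f = x@h2F)
})

#' @rdname asFlatList
#' @export
setMethod("asFlatList", "PGICoefficients", function(x) {
  list(delta_pgi = x@deltaPgi, alpha_pgi = x@alphaPgi, beta_pgi = x@betaPgi,
       r_k = x@rK, k = x@k)
})

setMethod("show", "RandomMatingComponents", function(object) {
  cat("Random-mating variance components\n")
  cat(sprintf("  vg = %.4g  ve_g = %.4g  cge = %.4g  sigma_eps2 = %.4g\n",
              object@vg, object@veg, object@cge, object@sigmaEps2))
  cat(sprintf("  r_dg_ig_0 = %.4g  vy = %.4g\n", object@rDgIg0, object@vy))
})

setMethod("show", "EquilibriumCorrelations", function(object) {
  cat("Equilibrium parental-component correlations\n")
  cat(sprintf("  r_delta = %.4g  r_eta = %.4g  r_de_cis = %.4g  r_de_trans = %.4g\n",
              object@rDelta, object@rEta, object@rDeCis, object@rDeTrans))
})

setMethod("show", "EquilibriumComponents", function(object) {
  cat("Equilibrium variance components\n")
  cat(sprintf("  vg_eq = %.4g  ve_g_eq = %.4g  cge_eq = %.4g  sigma_eps2 = %.4g\n",
              object@vgEq, object@vegEq, object@cgeEq, object@sigmaEps2))
  cat(sprintf("  vy_eq = %.4g  h2_eq = %.4g  h2_f = %.4g\n",
              object@vyEq, object@h2Eq, object@h2F))
})

setMethod("show", "SibRegressionExpectation", function(object) {
  cat("Expected sib-regression on realized relatedness\n")
  cat(sprintf("  slope (h2_f) = %.4g  intercept = %.4g  resid_cov = %.4g\n",
              object@slope, object@intercept, object@residCov))
})
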