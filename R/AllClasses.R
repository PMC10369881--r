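#' @import methods
NULL

#' Random-mating variance components
#'
#' Container for the variance decomposition of a phenotype affected by direct
#' genetic effects (DGEs) and parental indirect genetic effects (IGEs) in a
#' random-mating population: \code{vy = vg + veg + cge + sigmaEps2}, where
#' \code{vg} is the variance of the DGE component, \code{veg} the variance of
#' the summed parental IGE component, \code{cge} twice the covariance between
#' the two, and \code{sigmaEps2} the residual variance. \code{rDgIg0} is the
#' genome-wide correlation between standardized DGEs and IGEs, tied to the
#' covariance term by \code{cge = rDgIg0 * sqrt(2 * vg * veg)}.
#'
#' @slot vg numeric(1), random-mating DGE-component variance.
#' @slot veg numeric(1), random-mating variance of the summed parental IGE
#'   component.
#' @slot cge numeric(1), twice the DGE/summed-IGE covariance.
#' @slot sigmaEps2 numeric(1), residual variance.
#' @slot rDgIg0 numeric(1), genome-wide DGE-IGE correlation.
#' @slot vy numeric(1), total phenotypic variance (sum of the four terms).
#' @exportClass RandomMatingComponents
setClass("RandomMatingComponents",
  representation(
    vg = "numeric", veg = "numeric", cge = "numeric",
    sigmaEps2 = "numeric", rDgIg0 = "numeric", vy = "numeric"
  )
)

setValidity("RandomMatingComponents", function(object) {
  msg <- character()
  for (s in c("vg", "veg", "cge", "sigmaEps2", "rDgIg0", "vy")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) {
      msg <- c(msg, sprintf("slot '%s' must be a finite numeric scalar", s))
    }
  }
  if (length(msg)) return(msg)
  if (object@vg < 0) msg <- c(msg, "vg must be >= 0")
  if (object@veg < 0) msg <- c(msg, "veg must be >= 0")
  if (object@sigmaEps2 < 0) msg <- c(msg, "sigmaEps2 must be >= 0")
  if (abs(object@rDgIg0) > 1 + 1e-8) msg <- c(msg, "|rDgIg0| must be <= 1")
  if (object@cge^2 > 2 * object@vg * object@veg + 1e-8) {
    msg <- c(msg, "cge^2 must be <= 2 * vg * veg (Cauchy-Schwarz)")
  }
  tot <- object@vg + object@veg + object@cge + object@sigmaEps2
  if (abs(tot - object@vy) > 1e-6 * max(1, abs(tot))) {
    msg <- c(msg, "vy must equal vg + veg + cge + sigmaEps2")
  }
  if (length(msg)) msg else TRUE
})

#' Equilibrium correlations between parents' genetic-effect components
#'
#' Correlations among the four parental components (paternal/maternal DGE and
#' IGE components) at assortative-mating equilibrium: \code{rDelta} between
#' parents' DGE components, \code{rEta} between parents' IGE components,
#' \code{rDeCis} between DGE and IGE components within a parent, and
#' \code{rDeTrans} between one parent's DGE component and the other's IGE
#' component.
#'
#' @slot rDelta numeric(1), between-parent DGE correlation.
#' @slot rEta numeric(1), between-parent IGE correlation.
#' @slot rDeCis numeric(1), within-parent (cis) DGE-IGE correlation.
#' @slot rDeTrans numeric(1), cross-parent (trans) DGE-IGE correlation.
#' @exportClass EquilibriumCorrelations
setClass("EquilibriumCorrelations",
  representation(
    rDelta = "numeric", rEta = "numeric",
    rDeCis = "numeric", rDeTrans = "numeric"
  )
)

setValidity("EquilibriumCorrelations", function(object) {
  msg <- character()
  for (s in c("rDelta", "rEta", "rDeCis", "rDeTrans")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) {
      msg <- c(msg, sprintf("slot '%s' must be a finite numeric scalar", s))
    } else if (abs(v) > 1 + 1e-8) {
      msg <- c(msg, sprintf("slot '%s' must lie in [-1, 1]", s))
    }
  }
  if (length(msg)) return(msg)
  # implied correlation matrix of (Delta_p, Delta_m, eta_p, eta_m)
  R <- correlationMatrix4(object)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    msg <- c(msg, "implied 4x4 correlation matrix is not positive semi-definite")
  }
  if (length(msg)) msg else TRUE
})

# 4x4 correlation matrix of (Delta_p, Delta_m, eta_p, eta_m)
correlationMatrix4 <- function(corr) {
  rd <- corr@rDelta; re <- corr@rEta
  rc <- corr@rDeCis; rt <- corr@rDeTrans
  matrix(c(
    1, rd, rc, rt,
    rd, 1, rt, rc,
    rc, rt, 1, re,
    rt, rc, re, 1
  ), 4, 4, byrow = TRUE)
}

#' Equilibrium variance components
#'
#' The phenotypic-variance decomposition at assortative-mating equilibrium:
#' \code{vyEq = vgEq + vegEq + cgeEq + sigmaEps2}. \code{h2Eq = vgEq/vyEq} is
#' the equilibrium heritability and \code{h2F = vg/vyEq} is the family-based
#' heritability estimand (the quantity estimated by twin ACE, sib-regression
#' and relatedness-disequilibrium regression), related by
#' \code{h2F = (1 - rDelta) * h2Eq}.
#'
#' @slot vgEq numeric(1), equilibrium DGE-component variance.
#' @slot vegEq numeric(1), equilibrium summed-parental-IGE variance.
#' @slot cgeEq numeric(1), equilibrium twice-covariance term.
#' @slot sigmaEps2 numeric(1), residual variance (unchanged by AM).
#' @slot vyEq numeric(1), equilibrium phenotypic variance.
#' @slot h2Eq numeric(1), equilibrium heritability.
#' @slot h2F numeric(1), family-based heritability estimand.
#' @exportClass EquilibriumComponents
setClass("EquilibriumComponents",
  representation(
    vgEq = "numeric", vegEq = "numeric", cgeEq = "numeric",
    sigmaEps2 = "numeric", vyEq = "numeric", h2Eq = "numeric", h2F = "numeric"
  )
)

setValidity("EquilibriumComponents", function(object) {
  msg <- character()
  tot <- object@vgEq + object@vegEq + object@cgeEq + object@sigmaEps2
  if (abs(tot - object@vyEq) > 1e-6 * max(1, abs(tot))) {
    msg <- c(msg, "vyEq must equal vgEq + vegEq + cgeEq + sigmaEps2")
  }
  if (object@h2Eq < -1e-8 || object@h2Eq > 1 + 1e-8) {
    msg <- c(msg, "h2Eq must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Expected sibling phenotype-product regression on realized relatedness
#'
#' Expectations for the regression of the sibling phenotype cross-product
#' (scaled by the equilibrium phenotypic variance) on realized
#' identity-by-descent relatedness. The slope is the family-based heritability
#' estimand \code{h2F = vg/vyEq}; under assortative mating the intercept picks
#' up a term \code{rDelta * h2Eq} even with no shared environment.
#'
#' @slot slope numeric(1), expected slope (\code{vg/vyEq}).
#' @slot intercept numeric(1), expected intercept.
#' @slot residCov numeric(1), residual sibling covariance used.
#' @exportClass SibRegressionExpectation
setClass("SibRegressionExpectation",
  representation(slope = "numeric", intercept = "numeric", residCov = "numeric")
)

#' Polygenic-index weight set
#'
#' Per-variant weights and allele frequencies defining an (unstandardized) PGI
#' \code{sum_l w_l (g_l - 2 f_l)}, plus the standardizing constant
#' \code{norm = sqrt(Var(PGI))} under random mating.
#'
#' @slot weights numeric, per-variant weights.
#' @slot freqs numeric, per-variant allele frequencies in (0, 1).
#' @slot norm numeric(1), random-mating standard deviation of the raw PGI.
#' @slot kind character(1), one of "dge", "ige", "population", "custom".
#' @exportClass PGIWeights
setClass("PGIWeights",
  representation(weights = "numeric", freqs = "numeric",
                 norm = "numeric", kind = "character")
)

setValidity("PGIWeights", function(object) {
  msg <- character()
  if (length(object@weights) != length(object@freqs)) {
    msg <- c(msg, "weights and freqs must have equal length")
  }
  if (any(object@freqs <= 0 | object@freqs >= 1)) {
    msg <- c(msg, "freqs must lie strictly in (0, 1)")
  }
  if (!object@kind %in% c("dge", "ige", "population", "custom")) {
    msg <- c(msg, "kind must be one of dge, ige, population, custom")
  }
  if (any(object@weights != 0) && !(object@norm > 0)) {
    msg <- c(msg, "norm must be > 0 when any weight is nonzero")
  }
  if (length(msg)) msg else TRUE
})

#' Expected PGI regression coefficients
#'
#' Expected coefficients for a standardized PGI: the direct effect
#' \code{deltaPgi}, the average non-transmitted coefficient \code{alphaPgi},
#' the population effect \code{betaPgi}, the correlation between parents'
#' PGIs \code{rK}, and the fraction \code{k} of heritability the PGI would
#' explain in a random-mating population. At equilibrium,
#' \code{betaPgi = deltaPgi + (1 + rK) * alphaPgi}.
#'
#' @slot deltaPgi numeric(1).
#' @slot alphaPgi numeric(1).
#' @slot betaPgi numeric(1).
#' @slot rK numeric(1).
#' @slot k numeric(1), NA when not determined.
#' @exportClass PGICoefficients
setClass("PGICoefficients",
  representation(deltaPgi = "numeric", alphaPgi = "numeric",
                 betaPgi = "numeric", rK = "numeric", k = "numeric")
)

#' Inputs to the two-generation estimating-equation pipeline
#'
#' Summary-level inputs: the two-generation regression coefficients (direct
#' effect \code{deltaHat}, average NTC \code{alphaHat}, and their sampling
#' covariance), or alternatively the direct-to-population-effect ratio
#' \code{ratioHat}; the correlation between parents' PGIs \code{rKHat}; and a
#' family-based heritability estimate \code{h2fHat}. \code{kOverride}
#' optionally supplies the fraction of heritability the PGI would explain
#' under random mating instead of estimating it from \code{deltaHat}.
#' Absent optional fields are \code{NA}.
#'
#' @slot deltaHat,deltaSe numeric(1).
#' @slot alphaHat,alphaSe numeric(1).
#' @slot deltaAlphaCov numeric(1), sampling covariance of (deltaHat, alphaHat).
#' @slot ratioHat,ratioSe numeric(1), estimated delta/beta ratio.
#' @slot rKHat,rKSe numeric(1).
#' @slot h2fHat,h2fSe numeric(1).
#' @slot nFamilies numeric(1), used for default SE formulas; NA if unknown.
#' @slot kOverride,kSe numeric(1).
#' @exportClass TwoGenInputs
setClass("TwoGenInputs",
  representation(
    deltaHat = "numeric", deltaSe = "numeric",
    alphaHat = "numeric", alphaSe = "numeric",
    deltaAlphaCov = "numeric",
    ratioHat = "numeric", ratioSe = "numeric",
    rKHat = "numeric", rKSe = "numeric",
    h2fHat = "numeric", h2fSe = "numeric",
    nFamilies = "numeric",
    kOverride = "numeric", kSe = "numeric"
  )
)

setValidity("TwoGenInputs", function(object) {
  msg <- character()
  ses <- c(object@deltaSe, object@alphaSe, object@ratioSe, object@rKSe,
           object@h2fSe, object@kSe)
  if (any(ses < 0, na.rm = TRUE)) msg <- c(msg, "standard errors must be >= 0")
  if (is.na(object@rKHat) || abs(object@rKHat) >= 1) {
    msg <- c(msg, "rKHat must be supplied and lie in (-1, 1)")
  }
  if (is.na(object@h2fHat)) msg <- c(msg, "h2fHat must be supplied")
  haveDelta <- !is.na(object@deltaHat)
  haveRatioK <- !is.na(object@ratioHat) && !is.na(object@kOverride)
  if (!haveDelta && !haveRatioK) {
    msg <- c(msg, "need deltaHat, or ratioHat together with kOverride")
  }
  if (length(msg)) msg else TRUE
})

#' Outputs of the two-generation estimating-equation pipeline
#'
#' Point estimates and delta-method standard errors for \code{k},
#' \code{r_delta}, \code{h2_eq}, \code{rho_k}, \code{alpha_delta} and
#' \code{v_eta_delta}, the implied population effect \code{betaHat}, which
#' alpha-delta estimator was used, and any warnings raised during estimation
#' (k clipping, instability).
#'
#' @slot estimates named numeric vector of point estimates.
#' @slot ses named numeric vector of delta-method standard errors.
#' @slot betaHat numeric(1), implied population effect; NA in ratio mode.
#' @slot methodAlpha integer(1), 1 or 2.
#' @slot warnings character vector.
#' @exportClass TwoGenEstimates
setClass("TwoGenEstimates",
  representation(estimates = "numeric", ses = "numeric",
                 betaHat = "numeric", methodAlpha = "integer",
                 warnings = "character")
)

#' Per-family phenotype and PGI table
#'
#' A validated wrapper around a data.frame with one row per phenotyped
#' offspring and columns \code{FID} (family), \code{IID} (individual),
#' \code{phenotype}, \code{pgi_proband}, \code{pgi_father},
#' \code{pgi_mother}, and optionally \code{sex}. Siblings share \code{FID}
#' and parental PGIs; all PGIs are on one common (possibly unstandardized)
#' scale.
#'
#' @slot data data.frame as described.
#' @exportClass FamilyPGIDataset
setClass("FamilyPGIDataset", representation(data = "data.frame"))

setValidity("FamilyPGIDataset", function(object) {
  msg <- character()
  need <- c("FID", "IID", "phenotype", "pgi_proband", "pgi_father", "pgi_mother")
  missing <- setdiff(need, names(object@data))
  if (length(missing)) {
    msg <- c(msg, paste("missing columns:", paste(missing, collapse = ", ")))
  } else {
    num <- c("phenotype", "pgi_proband", "pgi_father", "pgi_mother")
    bad <- num[!vapply(object@data[num], is.numeric, logical(1))]
    if (length(bad)) {
      msg <- c(msg, paste("non-numeric columns:", paste(bad, collapse = ", ")))
    }
    if (length(unique(object@data$FID)) < 2L) {
      msg <- c(msg, "need at least 2 distinct families")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the forward-in-time assortative-mating simulation. Defaults
#' are the study conditions: 30000 families, 1000 causal variants with minor
#' allele frequencies drawn with density proportional to 1/f on
#' \code{mafRange}, a DGE component explaining \code{vg0} = 0.5 of the
#' founder-generation phenotypic variance, a summed parental IGE component
#' explaining \code{veg0} (0 or 0.125), effect correlation \code{rDgIg0},
#' spousal phenotypic correlation \code{rY}, and 20 generations of mating
#' after the random-mating founder generation.
#'
#' @slot nFamilies integer(1).
#' @slot nVariants integer(1).
#' @slot mafRange numeric(2).
#' @slot vg0,veg0,rDgIg0,rY numeric(1).
#' @slot nGenerations integer(1).
#' @slot seed integer(1).
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nFamilies = "integer", nVariants = "integer", mafRange = "numeric",
    vg0 = "numeric", veg0 = "numeric", rDgIg0 = "numeric", rY = "numeric",
    nGenerations = "integer", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nFamilies < 2L) msg <- c(msg, "nFamilies must be >= 2")
  if (object@nVariants < 1L) msg <- c(msg, "nVariants must be >= 1")
  lo <- object@mafRange[1]; hi <- object@mafRange[2]
  if (!(lo > 0 && lo < hi && hi <= 0.5)) {
    msg <- c(msg, "mafRange must satisfy 0 < lo < hi <= 0.5")
  }
  if (object@rY < 0 || object@rY >= 1) msg <- c(msg, "rY must lie in [0, 1)")
  if (abs(object@rDgIg0) > 1) msg <- c(msg, "|rDgIg0| must be <= 1")
  cge0 <- object@rDgIg0 * sqrt(2 * object@vg0 * object@veg0)
  if (object@vg0 + object@veg0 + cge0 >= 1) {
    msg <- c(msg, "vg0 + veg0 + cge0 must be < 1 so that sigmaEps2 > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated population state (one generation)
#'
#' Genotypes, true effect sizes, phenotype components and pedigree links for
#' one offspring generation of the forward simulation, together with the
#' frozen founder-generation scaling constants.
#'
#' @slot generation integer(1), 1 = founder-produced random-mating generation.
#' @slot freqs numeric, founder allele frequencies.
#' @slot delta,eta numeric, per-variant DGE and average parental IGE sizes
#'   (on the frozen phenotype scale).
#' @slot sigmaEps2 numeric(1), residual variance (frozen).
#' @slot geno integer matrix, (2 * nFamilies) x L offspring dosages; rows
#'   ordered by family with the male sibling first.
#' @slot family integer, family index per offspring row.
#' @slot sex character, "M"/"F" per offspring row.
#' @slot fatherGeno,motherGeno integer matrices, nFamilies x L.
#' @slot compDelta numeric, offspring DGE component.
#' @slot compEtaPar numeric, per-family summed parental IGE component.
#' @slot y numeric, offspring phenotypes.
#' @slot fatherY,motherY numeric, parental phenotypes.
#' @slot fatherDelta,motherDelta,fatherEta,motherEta numeric, parental DGE and
#'   (single-parent) IGE components.
#' @exportClass Population
setClass("Population",
  representation(
    generation = "integer", freqs = "numeric",
    delta = "numeric", eta = "numeric", sigmaEps2 = "numeric",
    geno = "matrix", family = "integer", sex = "character",
    fatherGeno = "matrix", motherGeno = "matrix",
    compDelta = "numeric", compEtaPar = "numeric", y = "numeric",
    fatherY = "numeric", motherY = "numeric",
    fatherDelta = "numeric", motherDelta = "numeric",
    fatherEta = "numeric", motherEta = "numeric"
  )
)

#' Simulated PGI description
#'
#' Weight construction used for a simulated PGI: DGE weights or population
#' (DGE + IGE) weights, plus white estimation noise whose variance is
#' \code{noiseMultiple} times the variance of the noise-free weights.
#' \code{k} is the realized fraction of heritability the PGI would explain in
#' a random-mating population, computed from the weights, effects and founder
#' frequencies.
#'
#' @slot kind character(1), "dge" or "population".
#' @slot noiseMultiple numeric(1).
#' @slot k numeric(1), realized k.
#' @slot weights numeric, the noisy per-variant weights.
#' @exportClass SimPGI
setClass("SimPGI",
  representation(kind = "character", noiseMultiple = "numeric",
                 k = "numeric", weights = "numeric")
)
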