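#' Construct a PGI weight set
#'
#' @param weights per-variant weights of the unstandardized PGI.
#' @param freqs per-variant allele frequencies in (0, 1).
#' @param kind label: "dge", "ige", "population" or "custom".
#' @return A [PGIWeights-class] object with \code{norm} set to the
#'   random-mating standard deviation \code{sqrt(sum(w^2 * 2 f (1 - f)))}.
#' @examples
#' pgiWeights(c(1, -0.5), c(0.3, 0.4), kind = "custom")
#' @export
pgiWeights <- function(weights, freqs, kind = "custom") {
  norm <- sqrt(sum(weights^2 * 2 * freqs * (1 - freqs)))
  new("PGIWeights", weights = weights, freqs = freqs, norm = norm,
      kind = kind)
}

#' Expected PGI regression coefficients under random mating
#'
#' For a standardized PGI with weights \code{w}, the expected direct effect,
#' average non-transmitted coefficient (NTC) and population effect in a
#' random-mating population are ratio-of-sums expressions:
#' \deqn{\delta_{PGI} = \frac{\sum_l w_l \delta_l 2 f_l (1-f_l)}
#'   {\sqrt{\sum_l w_l^2 2 f_l (1-f_l)}},}
#' with \eqn{\alpha_{PGI}} using the IGEs \eqn{\eta_l} and
#' \eqn{\beta_{PGI}} the population effects \eqn{\beta_l = \delta_l + \eta_l}.
#' Under random mating the parental-PGI correlation is 0.
#'
#' @param w A [PGIWeights-class] object.
#' @param dgeEffects per-variant DGE sizes.
#' @param igeEffects per-variant average parental IGE sizes.
#' @param h2 optional random-mating heritability used to fill in
#'   \code{k = deltaPgi^2 / h2}; \code{k} is NA when not supplied.
#' @return A [PGICoefficients-class] object.
#' @examples
#' f <- rep(0.5, 2)
#' w <- pgiWeights(c(1, 1), f, kind = "dge")
#' randomMatingCoefficients(w, dgeEffects = c(1, 1), igeEffects = c(0, 0))
#' @export
randomMatingCoefficients <- function(w, dgeEffects, igeEffects, h2 = NA_real_) {
  stopifnot(is(w, "PGIWeights"))
  n <- length(w@weights)
  if (length(dgeEffects) != n || length(igeEffects) != n) {
    stop("effect vectors must match the weight vector length")
  }
  if (all(w@weights == 0)) stop("all-zero weight vector")
  het2 <- 2 * w@freqs * (1 - w@freqs)
  deltaPgi <- sum(w@weights * dgeEffects * het2) / w@norm
  alphaPgi <- sum(w@weights * igeEffects * het2) / w@norm
  betaPgi <- sum(w@weights * (dgeEffects + igeEffects) * het2) / w@norm
  k <- if (is.na(h2)) NA_real_ else deltaPgi^2 / h2
  new("PGICoefficients", deltaPgi = deltaPgi, alphaPgi = alphaPgi,
      betaPgi = betaPgi, rK = 0, k = k)
}

#' Average NTC of the true DGE PGI at equilibrium
#'
#' At assortative-mating equilibrium, a two-generation regression of the
#' phenotype on the (unstandardized) true DGE component and the summed
#' parental DGE component has direct effect 1 and average NTC
#' \deqn{\alpha_\delta = \frac{c_{ge}^{eq}}{2 (1 + r_\delta) v_g^{eq}},}
#' nonzero only when IGEs are present and the equilibrium cis+trans DGE-IGE
#' correlations do not cancel. The standardized-PGI variant is
#' \code{alphaDelta * sqrt(vgEq)}.
#'
#' @param rm A [RandomMatingComponents-class] object.
#' @param corr An [EquilibriumCorrelations-class] object.
#' @param eq The paired [EquilibriumComponents-class] object.
#' @return A list with \code{alphaDelta} and the standardized
#'   \code{alphaDeltaStd}.
#' @export
trueDgeNtc <- function(rm, corr, eq) {
  stopifnot(is(rm, "RandomMatingComponents"),
            is(corr, "EquilibriumCorrelations"),
            is(eq, "EquilibriumComponents"))
  if (eq@vgEq <= 0) stop("vgEq must be > 0")
  alphaDelta <- eq@cgeEq / (2 * (1 + corr@rDelta) * eq@vgEq)
  list(alphaDelta = alphaDelta, alphaDeltaStd = alphaDelta * sqrt(eq@vgEq))
}

#' Variance explained by the true DGE PGI and its parental component
#'
#' The proportion of phenotypic variance explained by joint regression on the
#' offspring and parental true-DGE PGIs at equilibrium is
#' \code{(1 + 2 (1 + rDelta) alphaDelta (1 + alphaDelta)) * h2Eq}; the excess
#' over \code{h2Eq} is the contribution of parental IGEs,
#' \code{vEtaDelta = 2 (1 + rDelta) alphaDelta (1 + alphaDelta) h2Eq}.
#'
#' @param h2Eq equilibrium heritability.
#' @param rDelta correlation between parents' DGE components.
#' @param alphaDelta average NTC of the true DGE PGI.
#' @return A list with \code{proportion} and \code{vEtaDelta}.
#' @export
trueDgeVarianceExplained <- function(h2Eq, rDelta, alphaDelta) {
  if (abs(rDelta) >= 1) stop("|rDelta| must be < 1")
  proportion <- (1 + 2 * (1 + rDelta) * alphaDelta * (1 + alphaDelta)) * h2Eq
  list(proportion = proportion, vEtaDelta = proportion - h2Eq)
}

#' Equilibrium R-squared of an incomplete DGE PGI
#'
#' Phenotypic variance explained at equilibrium by a PGI that would explain a
#' fraction \code{k} of the heritability under random mating (no IGEs):
#' \deqn{R^2_{eq} = k\, h^2_{eq} \left(1 +
#'   \frac{(1 - k) r_\delta}{1 + r_k}\right).}
#' Assortative mating inflates the R-squared because the PGI becomes
#' correlated with the DGE component it does not tag; the inflation vanishes
#' as \code{k} approaches 1 or \code{rDelta} approaches 0.
#'
#' @param k fraction of heritability explained under random mating, in
#'   \code{[0, 1]}.
#' @param rDelta correlation between parents' DGE components.
#' @param rK correlation between parents' PGIs (\code{1 + rK > 0}).
#' @param h2Eq equilibrium heritability.
#' @return numeric(1).
#' @export
equilibriumR2 <- function(k, rDelta, rK, h2Eq) {
  stopifnot(all(k >= 0 & k <= 1), all(1 + rK > 0))
  k * h2Eq * (1 + (1 - k) * rDelta / (1 + rK))
}

#' Direct-to-population-effect ratio expected from assortative mating alone
#'
#' Without IGEs, the expected ratio between direct and population effects of
#' a PGI explaining a fraction \code{k} of heritability under random mating
#' is \code{rho_k = 1 - (1 - k) * rDelta}, the baseline "shrinkage" of PGI
#' effects within-family attributable purely to AM. The single-variant limit
#' \code{k -> 0} gives \code{1 - rDelta}.
#'
#' @inheritParams equilibriumR2
#' @return numeric, same length as the inputs after recycling.
#' @examples
#' rhoK(0.452, 0.2078)
#' @export
rhoK <- function(k, rDelta) {
  stopifnot(all(k >= 0 & k <= 1), all(abs(rDelta) <= 1))
  1 - (1 - k) * rDelta
}

#' Direct-to-population-effect ratio in the presence of IGEs
#'
#' With IGEs, the expected ratio becomes
#' \code{rho_k / (1 + (1 + rDelta) * alphaDelta)}: observed shrinkage beyond
#' the AM-only baseline \code{rho_k} indicates an IGE component positively
#' correlated with the DGE component.
#'
#' @param rho AM-only ratio \code{rho_k}.
#' @param rDelta correlation between parents' DGE components.
#' @param alphaDelta average NTC of the true DGE PGI.
#' @return numeric(1).
#' @export
ratioWithIge <- function(rho, rDelta, alphaDelta) {
  denom <- 1 + (1 + rDelta) * alphaDelta
  if (any(denom == 0)) stop("1 + (1 + rDelta) * alphaDelta must be nonzero")
  rho / denom
}

#' Expected NTC-to-direct-effect ratio
#'
#' The average NTC of an incomplete DGE PGI decomposes into an AM-induced
#' part and an IGE part:
#' \deqn{\frac{\alpha_{PGI:k}}{\delta_{PGI:k}} =
#'   \frac{(1 + r_\delta)\alpha_\delta + (1 - \rho_k)}{\rho_k (1 + r_k)}.}
#' The \eqn{\rho_k} in the denominator makes this the exact consequence of
#' the population-effect identity \code{beta = delta + (1 + rK) alpha}
#' together with \code{delta/beta = rho_k / (1 + (1 + rDelta) alphaDelta)},
#' and the exact algebraic inverse of [estimateAlphaDelta2()] (note
#' \code{rho_k (1 + r_k) = rho_k + k r_delta} when \code{r_k} is consistent
#' with \code{(k, r_delta)}).
#'
#' @param alphaDelta average NTC of the true DGE PGI.
#' @param rDelta correlation between parents' DGE components.
#' @param rho AM-only direct-to-population ratio \code{rho_k}.
#' @param rK correlation between parents' PGIs (\code{1 + rK > 0}).
#' @return numeric(1).
#' @export
ntcRatio <- function(alphaDelta, rDelta, rho, rK) {
  stopifnot(all(1 + rK > 0), all(rho > 0))
  ((1 + rDelta) * alphaDelta + (1 - rho)) / (rho * (1 + rK))
}

#' Parental-PGI correlation implied by the parental DGE-component correlation
#'
#' Inverts the estimating relation between the observed-PGI correlation and
#' the DGE-component correlation:
#' \code{rK = k * rDelta / (1 - (1 - k) * rDelta)}. Round-trips exactly with
#' [estimateRdelta()]; \code{rK <= rDelta} with equality at \code{k = 1}.
#'
#' @inheritParams rhoK
#' @return numeric(1).
#' @examples
#' rkFromRdelta(0.452, 0.20781)
#' @export
rkFromRdelta <- function(k, rDelta) {
  denom <- 1 - (1 - k) * rDelta
  if (any(denom <= 0)) stop("(1 - k) * rDelta must be < 1")
  k * rDelta / denom
}

setMethod("show", "PGICoefficients", function(object) {
  cat("Expected PGI regression coefficients\n")
  cat(sprintf("  delta = %.4g  alpha (NTC) = %.4g  beta = %.4g\n",
              object@deltaPgi, object@alphaPgi, object@betaPgi))
  cat(sprintf("  r_k = %.4g  k = %.4g\n", object@rK, object@k))
})

setMethod("show", "PGIWeights", function(object) {
  cat(sprintf("PGI weight set (%s): %d variants, norm = %.4g\n",
              object@kind, length(object@weights), object@norm))
})
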