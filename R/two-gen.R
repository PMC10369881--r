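#' Assemble inputs for the two-generation inference pipeline
#'
#' Convenience constructor for [TwoGenInputs-class]. Supply either the
#' two-generation regression coefficients (\code{deltaHat}, \code{alphaHat})
#' or the direct-to-population-effect ratio (\code{ratioHat}) together with
#' \code{kOverride}; \code{rKHat} and \code{h2fHat} are always required.
#'
#' @param deltaHat,deltaSe estimated PGI direct effect and its SE.
#' @param alphaHat,alphaSe estimated average NTC and its SE.
#' @param deltaAlphaCov sampling covariance of (deltaHat, alphaHat).
#' @param ratioHat,ratioSe estimated delta/beta ratio and its SE.
#' @param rKHat,rKSe estimated parental-PGI correlation and its SE; when
#'   \code{rKSe} is NA and \code{nFamilies} is given, the default
#'   \code{sqrt((1 - rK^2)^2 / nFamilies)} is used.
#' @param h2fHat,h2fSe family-based heritability estimate and its SE.
#' @param nFamilies number of families behind \code{rKHat}.
#' @param kOverride,kSe externally supplied k and its SE.
#' @return A validated [TwoGenInputs-class] object.
#' @examples
#' TwoGenInputs(ratioHat = 0.910, rKHat = 0.106, h2fHat = 0.554,
#'              kOverride = 0.452)
#' @export
TwoGenInputs <- function(deltaHat = NA_real_, deltaSe = NA_real_,
                         alphaHat = NA_real_, alphaSe = NA_real_,
                         deltaAlphaCov = NA_real_,
                         ratioHat = NA_real_, ratioSe = NA_real_,
                         rKHat = NA_real_, rKSe = NA_real_,
                         h2fHat = NA_real_, h2fSe = NA_real_,
                         nFamilies = NA_real_,
                         kOverride = NA_real_, kSe = NA_real_) {
  new("TwoGenInputs",
      deltaHat = deltaHat, deltaSe = deltaSe,
      alphaHat = alphaHat, alphaSe = alphaSe,
      deltaAlphaCov = deltaAlphaCov,
      ratioHat = ratioHat, ratioSe = ratioSe,
      rKHat = rKHat, rKSe = rKSe,
      h2fHat = h2fHat, h2fSe = h2fSe,
      nFamilies = nFamilies, kOverride = kOverride, kSe = kSe)
}

#' Estimate the fraction of heritability a PGI would explain at random mating
#'
#' Plain estimator \code{k = (1 - rK) * delta^2 / h2f}, or the bias-corrected
#' form \code{k = (1 - rK) * (1 - zf^-2) * (delta^2 - Var(delta)) / h2f} with
#' \code{zf = h2f / SE(h2f)}. The corrections vanish when \code{varDelta = 0}
#' and \code{seH2f = 0}. The estimate is clipped to \code{[0, 1]} and a
#' \code{clipped} flag returned; a negative corrected numerator yields
#' \code{k = 0} with the flag set.
#'
#' @param deltaHat estimated PGI direct effect (standardized scale).
#' @param rK parental-PGI correlation.
#' @param h2f family-based heritability estimate (> 0).
#' @param varDelta sampling variance of \code{deltaHat}.
#' @param seH2f standard error of \code{h2f}.
#' @param biasCorrect apply the sampling-error corrections.
#' @return list with \code{k} (clipped), \code{kRaw} and \code{clipped}.
#' @export
estimateK <- function(deltaHat, rK, h2f, varDelta = 0, seH2f = 0,
                      biasCorrect = TRUE) {
  if (h2f <= 0) stop("h2f must be > 0")
  if (biasCorrect) {
    zfinv2 <- if (seH2f > 0) (seH2f / h2f)^2 else 0
    kRaw <- (1 - rK) * (1 - zfinv2) * (deltaHat^2 - varDelta) / h2f
  } else {
    kRaw <- (1 - rK) * deltaHat^2 / h2f
  }
  k <- min(max(kRaw, 0), 1)
  list(k = k, kRaw = kRaw, clipped = (k != kRaw))
}

#' Estimate the parental DGE-component correlation
#'
#' \code{rDelta = rK / (k + (1 - k) * rK)}. Consistent when the inputs are;
#' unstable when the denominator is small (many downstream terms are ratios
#' of noisy parameters), which is reported via the \code{unstable} flag.
#'
#' @param k fraction of heritability explained at random mating.
#' @param rK parental-PGI correlation.
#' @param stabilityThreshold denominator below which the estimate is flagged.
#' @return list with \code{rDelta}, \code{denominator} and \code{unstable}.
#' @examples
#' estimateRdelta(0.452, 0.106)$rDelta  # height: 0.208
#' @export
estimateRdelta <- function(k, rK, stabilityThreshold = 0.05) {
  denom <- k + (1 - k) * rK
  if (denom <= 0) stop("k + (1 - k) * rK must be > 0")
  list(rDelta = rK / denom, denominator = denom,
       unstable = denom < stabilityThreshold)
}

#' Ratio-based estimator of the true-DGE-PGI NTC
#'
#' Estimator 1, from the observed direct-to-population-effect ratio:
#' \code{alphaDelta = (rho - ratio) / (ratio * (1 + rDelta))}. Zero when the
#' observed ratio equals the AM-only prediction \code{rho}; positive when
#' observed shrinkage exceeds it.
#'
#' @param rho AM-only ratio prediction \code{rho_k}.
#' @param ratio observed delta/beta ratio (nonzero).
#' @param rDelta parental DGE-component correlation.
#' @return numeric(1).
#' @export
estimateAlphaDelta1 <- function(rho, ratio, rDelta) {
  if (any(ratio == 0)) stop("ratio must be nonzero")
  (rho - ratio) / (ratio * (1 + rDelta))
}

#' NTC-ratio-based estimator of the true-DGE-PGI NTC
#'
#' Estimator 2, from the NTC-to-direct-effect ratio of the same regression:
#' \code{alphaDelta = ((rho + k * rDelta) * ntcRatio - (1 - rho)) /
#' (1 + rDelta)}. Preferred by default because \code{alphaHat} and
#' \code{deltaHat} come from the same regression, making their sampling
#' covariance available.
#'
#' @param rho AM-only ratio prediction \code{rho_k}.
#' @param k fraction of heritability explained at random mating.
#' @param rDelta parental DGE-component correlation.
#' @param ntcRatioHat observed \code{alphaHat / deltaHat}.
#' @return numeric(1).
#' @export
estimateAlphaDelta2 <- function(rho, k, rDelta, ntcRatioHat) {
  ((rho + k * rDelta) * ntcRatioHat - (1 - rho)) / (1 + rDelta)
}

#' Estimate the IGE contribution to phenotypic variance
#'
#' \code{vEtaDelta = 2 * (1 + rDelta) * alphaDelta * (1 + alphaDelta) * h2Eq},
#' the proportion of phenotypic variance contributed by the IGE component
#' correlated with the DGE component.
#'
#' @param alphaDelta average NTC of the true DGE PGI.
#' @param rDelta parental DGE-component correlation.
#' @param h2Eq equilibrium heritability.
#' @return numeric(1).
#' @export
estimateVEtaDelta <- function(alphaDelta, rDelta, h2Eq) {
  2 * (1 + rDelta) * alphaDelta * (1 + alphaDelta) * h2Eq
}

#' Delta-method standard errors for a smooth map
#'
#' Propagates an input covariance matrix through a (possibly non-linear) map
#' using a numeric Jacobian: \code{SE = sqrt(diag(J Sigma J'))} with \code{J}
#' computed by central finite differences with per-coordinate step
#' \code{max(1e-6, 1e-4 * |x|)}.
#'
#' @param fn function mapping a numeric vector to a numeric vector.
#' @param x point at which to linearize.
#' @param sigma input covariance matrix (positive semi-definite).
#' @return list with \code{se} (per-output SEs), \code{jacobian} and the
#'   output covariance \code{cov}.
#' @export
deltaMethodSE <- function(fn, x, sigma) {
  p <- length(x)
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == p)) stop("sigma must be a p x p matrix")
  if (any(!is.finite(sigma))) stop("sigma contains non-finite entries")
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("sigma must be positive semi-definite")
  }
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), p)
  for (j in seq_len(p)) {
    h <- max(1e-6, 1e-4 * abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  V <- J %*% sigma %*% t(J)
  list(se = sqrt(pmax(diag(V), 0)), jacobian = J, cov = V)
}

paramNames <- c("k", "r_delta", "h2_eq", "rho_k", "alpha_delta", "v_eta_delta")

# Pure pipeline map used both for point estimates and the numeric Jacobian.
# mode "regression": x = (delta, alpha, rk, h2f [, k]); fixed carries
#   varDelta, zf-related seH2f and whether k comes from x.
# mode "ratio": x = (ratio, rk, h2f, k).
twoGenMap <- function(x, mode, kFromInput, varDelta = 0, seH2f = 0) {
  if (mode == "regression") {
    delta <- x[1]; alpha <- x[2]; rk <- x[3]; h2f <- x[4]
    k <- if (kFromInput) x[5] else {
      estimateK(delta, rk, h2f, varDelta = varDelta, seH2f = seH2f)$kRaw
    }
    rd <- rk / (k + (1 - k) * rk)
    h2eq <- h2f / (1 - rd)
    rho <- 1 - (1 - k) * rd
    ad <- estimateAlphaDelta2(rho, k, rd, alpha / delta)
  } else if (mode == "ratio") {
    ratio <- x[1]; rk <- x[2]; h2f <- x[3]; k <- x[4]
    rd <- rk / (k + (1 - k) * rk)
    h2eq <- h2f / (1 - rd)
    rho <- 1 - (1 - k) * rd
    ad <- estimateAlphaDelta1(rho, ratio, rd)
  } else { # ratio_delta: k estimated from delta
    ratio <- x[1]; delta <- x[2]; rk <- x[3]; h2f <- x[4]
    k <- estimateK(delta, rk, h2f, varDelta = varDelta, seH2f = seH2f)$kRaw
    rd <- rk / (k + (1 - k) * rk)
    h2eq <- h2f / (1 - rd)
    rho <- 1 - (1 - k) * rd
    ad <- estimateAlphaDelta1(rho, ratio, rd)
  }
  v <- estimateVEtaDelta(ad, rd, h2eq)
  c(k = unname(k), r_delta = unname(rd), h2_eq = unname(h2eq),
    rho_k = unname(rho), alpha_delta = unname(ad), v_eta_delta = unname(v))
}

#' Run the two-generation estimating-equation pipeline
#'
#' Executes the full inference chain: estimate \code{k} (unless overridden),
#' then \code{r_delta}, the equilibrium heritability
#' \code{h2_eq = h2f/(1 - r_delta)}, the AM-only ratio \code{rho_k}, the
#' true-DGE-PGI NTC \code{alpha_delta} (estimator 2 from the regression
#' coefficients by default, estimator 1 when only the delta/beta ratio is
#' available) and the IGE variance contribution \code{v_eta_delta}.
#' Delta-method standard errors are propagated through the whole map with a
#' numeric Jacobian, treating the regression-coefficient block, \code{rK} and
#' \code{h2f} as mutually independent. A stability warning is recorded when
#' the estimated \code{k} (or the denominator of the \code{r_delta} equation)
#' falls below 0.05, where the ratio-heavy estimating equations become
#' unstable.
#'
#' @param inputs A [TwoGenInputs-class] object.
#' @param alphaEstimator force estimator 1 or 2; default picks 2 when the
#'   regression coefficients are available, else 1.
#' @param biasCorrectK apply the sampling-error correction when estimating k.
#' @return A [TwoGenEstimates-class] object.
#' @examples
#' est <- runTwoGenInference(TwoGenInputs(ratioHat = 0.910, ratioSe = 0.009,
#'   rKHat = 0.106, rKSe = 0.020, h2fHat = 0.554, h2fSe = 0.044,
#'   kOverride = 0.452, kSe = 0.038))
#' estimates(est)
#' @export
runTwoGenInference <- function(inputs, alphaEstimator = NULL,
                               biasCorrectK = TRUE) {
  stopifnot(is(inputs, "TwoGenInputs"))
  validObject(inputs)
  warningsOut <- character()

  haveReg <- !is.na(inputs@deltaHat) && !is.na(inputs@alphaHat)
  haveRatio <- !is.na(inputs@ratioHat)
  if (is.null(alphaEstimator)) alphaEstimator <- if (haveReg) 2L else 1L
  alphaEstimator <- as.integer(alphaEstimator)
  if (alphaEstimator == 2L && !haveReg) {
    stop("estimator 2 needs deltaHat and alphaHat")
  }
  if (alphaEstimator == 1L && !haveRatio) {
    stop("estimator 1 needs ratioHat")
  }

  # population-effect identity consistency when both routes supplied
  betaHat <- NA_real_
  if (haveReg) {
    betaHat <- inputs@deltaHat + (1 + inputs@rKHat) * inputs@alphaHat
    if (haveRatio &&
        abs(inputs@ratioHat - inputs@deltaHat / betaHat) > 1e-6) {
      stop("ratioHat inconsistent with deltaHat/(deltaHat + (1 + rK) alphaHat)")
    }
  }

  rkVar <- if (!is.na(inputs@rKSe)) inputs@rKSe^2 else {
    if (is.na(inputs@nFamilies)) {
      stop("need rKSe or nFamilies for the default rK variance")
    }
    warningsOut <- c(warningsOut, "rk_se_default")
    (1 - inputs@rKHat^2)^2 / inputs@nFamilies
  }
  h2fVar <- if (!is.na(inputs@h2fSe)) inputs@h2fSe^2 else 0
  seH2f <- if (!is.na(inputs@h2fSe)) inputs@h2fSe else 0

  kFromInput <- !is.na(inputs@kOverride)

  if (alphaEstimator == 2L) {
    varDelta <- if (!is.na(inputs@deltaSe)) inputs@deltaSe^2 else 0
    if (!biasCorrectK) varDelta <- 0
    x <- c(inputs@deltaHat, inputs@alphaHat, inputs@rKHat, inputs@h2fHat)
    dav <- if (!is.na(inputs@deltaAlphaCov)) inputs@deltaAlphaCov else 0
    alphaVar <- if (!is.na(inputs@alphaSe)) inputs@alphaSe^2 else 0
    sigma <- diag(c(varDelta, alphaVar, rkVar, h2fVar))
    sigma[1, 2] <- sigma[2, 1] <- dav
    if (kFromInput) {
      x <- c(x, inputs@kOverride)
      kv <- if (!is.na(inputs@kSe)) inputs@kSe^2 else 0
      sigma <- rbind(cbind(sigma, 0), 0)
      sigma[5, 5] <- kv
    }
    fn <- function(z) twoGenMap(z, "regression", kFromInput,
                                varDelta = if (biasCorrectK) varDelta else 0,
                                seH2f = if (biasCorrectK) seH2f else 0)
  } else {
    ratioVar <- if (!is.na(inputs@ratioSe)) inputs@ratioSe^2 else 0
    if (kFromInput) {
      x <- c(inputs@ratioHat, inputs@rKHat, inputs@h2fHat, inputs@kOverride)
      sigma <- diag(c(ratioVar, rkVar, h2fVar,
                      if (!is.na(inputs@kSe)) inputs@kSe^2 else 0))
      fn <- function(z) twoGenMap(z, "ratio", TRUE)
    } else {
      if (is.na(inputs@deltaHat)) stop("estimator 1 needs kOverride or deltaHat")
      varDelta <- if (!is.na(inputs@deltaSe) && biasCorrectK)
        inputs@deltaSe^2 else 0
      x <- c(inputs@ratioHat, inputs@deltaHat, inputs@rKHat, inputs@h2fHat)
      sigma <- diag(c(ratioVar, varDelta, rkVar, h2fVar))
      fn <- function(z) twoGenMap(z, "ratio_delta", FALSE,
                                  varDelta = varDelta,
                                  seH2f = if (biasCorrectK) seH2f else 0)
    }
  }

  est <- fn(x)

  # k clipping on the point estimate (Jacobian uses the unclipped map)
  if (est["k"] < 0 || est["k"] > 1) {
    warningsOut <- c(warningsOut, "k_clipped")
    kClip <- min(max(est["k"], 0), 1)
    if (!kFromInput) {
      # re-run the downstream chain at the clipped k
      if (alphaEstimator == 2L) {
        est <- twoGenMap(c(x[1:4], kClip), "regression", TRUE)
      } else {
        est <- twoGenMap(c(x[1], x[3], x[4], kClip), "ratio", TRUE)
      }
    } else {
      est["k"] <- kClip
    }
  }

  dm <- deltaMethodSE(fn, x, sigma)
  ses <- dm$se
  names(ses) <- paramNames

  denom <- est["k"] + (1 - est["k"]) * inputs@rKHat
  if (est["k"] < 0.05 || denom < 0.05) {
    warningsOut <- c(warningsOut, "unstable_small_k")
  }

  new("TwoGenEstimates", estimates = est, ses = ses, betaHat = betaHat,
      methodAlpha = alphaEstimator, warnings = unique(warningsOut))
}

#' @describeIn TwoGenEstimates-class point estimates as a named vector.
#' @param object a \code{TwoGenEstimates} object.
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @export
setMethod("estimates", "TwoGenEstimates", function(object) object@estimates)

#' @describeIn TwoGenEstimates-class delta-method standard errors as a named
#'   vector.
#' @export
setGeneric("standardErrors",
           function(object) standardGeneric("standardErrors"))

#' @export
setMethod("standardErrors", "TwoGenEstimates",
          function(object) object@ses)

#' @describeIn TwoGenEstimates-class warnings recorded during estimation.
#' @export
setGeneric("estimationWarnings",
           function(object) standardGeneric("estimationWarnings"))

#' @export
setMethod("estimationWarnings", "TwoGenEstimates",
          function(object) object@warnings)

setMethod("show", "TwoGenEstimates", function(object) {
  cat("Two-generation PGI inference (alpha-delta estimator",
      object@methodAlpha, ")\n")
  tab <- data.frame(estimate = round(object@estimates, 4),
                    se = round(object@ses, 4))
  rownames(tab) <- names(object@estimates)
  print(tab)
  if (length(object@warnings)) {
    cat("warnings:", paste(object@warnings, collapse = ", "), "\n")
  }
})

setMethod("show", "TwoGenInputs", function(object) {
  cat("Two-generation inference inputs\n")
  fmt <- function(v, s) {
    if (is.na(v)) "NA" else sprintf("%.4g (SE %s)", v,
                                    if (is.na(s)) "NA" else sprintf("%.4g", s))
  }
  cat("  delta =", fmt(object@deltaHat, object@deltaSe),
      " alpha =", fmt(object@alphaHat, object@alphaSe), "\n")
  cat("  ratio =", fmt(object@ratioHat, object@ratioSe),
      " rk =", fmt(object@rKHat, object@rKSe),
      " h2f =", fmt(object@h2fHat, object@h2fSe),
      " k =", fmt(object@kOverride, object@kSe), "\n")
})
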