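#' Construct a per-family phenotype/PGI dataset
#'
#' @param data data.frame with columns \code{FID}, \code{IID},
#'   \code{phenotype}, \code{pgi_proband}, \code{pgi_father},
#'   \code{pgi_mother} and optionally \code{sex}. Rows with missing
#'   phenotype or PGI values are dropped (listwise deletion) with a message.
#' @return A validated [FamilyPGIDataset-class] object.
#' @export
FamilyPGIDataset <- function(data) {
  need <- c("phenotype", "pgi_proband", "pgi_father", "pgi_mother")
  if (all(need %in% names(data))) {
    keep <- stats::complete.cases(data[need])
    if (!all(keep)) {
      message(sum(!keep), " rows with missing values dropped")
      data <- data[keep, , drop = FALSE]
    }
  }
  new("FamilyPGIDataset", data = data)
}

#' @describeIn FamilyPGIDataset-class the underlying data.frame.
#' @param x a \code{FamilyPGIDataset}.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "FamilyPGIDataset", function(x, ...) x@data)

#' @describeIn FamilyPGIDataset-class number of distinct families.
#' @param object a \code{FamilyPGIDataset}.
#' @export
setGeneric("nFamilies", function(object) standardGeneric("nFamilies"))

#' @export
setMethod("nFamilies", "FamilyPGIDataset",
          function(object) length(unique(object@data$FID)))

setMethod("show", "FamilyPGIDataset", function(object) {
  cat(sprintf("FamilyPGIDataset: %d individuals in %d families\n",
              nrow(object@data), nFamilies(object)))
})

#' Standardize a family PGI dataset onto the analysis scale
#'
#' Scales the phenotype to mean 0 and variance 1, and mean-centres all three
#' PGIs after dividing each by the proband-PGI standard deviation. A single
#' scaling constant keeps parent and offspring PGIs on one common scale, so
#' that the regression coefficients obey the population-effect identity
#' \code{beta = delta + (1 + rK) * alpha}; per-column standardization would
#' break it. At equilibrium the parental-sum PGI then has variance about
#' \code{2 * (1 + rK)}.
#'
#' @param dataset A [FamilyPGIDataset-class] object.
#' @return list with \code{dataset} (standardized) and \code{report}
#'   (means/SDs used).
#' @export
standardizeFamilies <- function(dataset) {
  stopifnot(is(dataset, "FamilyPGIDataset"))
  d <- dataset@data
  sdY <- stats::sd(d$phenotype)
  sdP <- stats::sd(d$pgi_proband)
  if (!(sdY > 0) || !(sdP > 0)) {
    stop("phenotype and proband PGI must have nonzero variance")
  }
  report <- list(phenotype_mean = mean(d$phenotype), phenotype_sd = sdY,
                 pgi_scale = sdP,
                 pgi_proband_mean = mean(d$pgi_proband / sdP),
                 pgi_father_mean = mean(d$pgi_father / sdP),
                 pgi_mother_mean = mean(d$pgi_mother / sdP),
                 n = nrow(d))
  d$phenotype <- (d$phenotype - report$phenotype_mean) / sdY
  d$pgi_proband <- d$pgi_proband / sdP - report$pgi_proband_mean
  d$pgi_father <- d$pgi_father / sdP - report$pgi_father_mean
  d$pgi_mother <- d$pgi_mother / sdP - report$pgi_mother_mean
  list(dataset = new("FamilyPGIDataset", data = d), report = report)
}

#' Two-generation PGI regression
#'
#' OLS of the standardized phenotype on the standardized proband PGI and the
#' parental-sum PGI (father + mother on the common scale), returning the
#' direct effect \code{deltaHat}, the average NTC \code{alphaHat} and their
#' family-clustered (cluster-robust) sampling covariance — siblings share
#' family environment and parental PGIs, so classical OLS covariance would be
#' anti-conservative.
#'
#' @param dataset A [FamilyPGIDataset-class] object.
#' @param standardize standardize first via [standardizeFamilies()].
#' @param oneSibPerFamily keep only the first sibling per family
#'   (independent-trio analysis).
#' @return list with \code{deltaHat}, \code{alphaHat}, \code{vcov} (2x2),
#'   \code{nIndividuals}, \code{nFamilies}, and the fitted \code{lm} object.
#' @export
fitTwoGen <- function(dataset, standardize = TRUE, oneSibPerFamily = FALSE) {
  stopifnot(is(dataset, "FamilyPGIDataset"))
  if (standardize) dataset <- standardizeFamilies(dataset)$dataset
  d <- dataset@data
  if (oneSibPerFamily) d <- d[!duplicated(d$FID), , drop = FALSE]
  d$pgi_par <- d$pgi_father + d$pgi_mother
  fit <- stats::lm(phenotype ~ pgi_proband + pgi_par, data = d)
  if (any(!is.finite(stats::coef(fit))) || fit$rank < 3L) {
    stop("design matrix is rank deficient (proband PGI collinear with parental sum?)")
  }
  V <- sandwich::vcovCL(fit, cluster = d$FID)[2:3, 2:3]
  co <- stats::coef(fit)
  list(deltaHat = unname(co["pgi_proband"]), alphaHat = unname(co["pgi_par"]),
       vcov = V, nIndividuals = nrow(d), nFamilies = length(unique(d$FID)),
       fit = fit)
}

#' Population-effect PGI regression
#'
#' OLS of the standardized phenotype on the standardized proband PGI alone,
#' returning the population effect \code{betaHat} with a family-clustered
#' standard error.
#'
#' @inheritParams fitTwoGen
#' @return list with \code{betaHat}, \code{se}, \code{nIndividuals},
#'   \code{nFamilies}, and the fitted \code{lm} object.
#' @export
fitPopulation <- function(dataset, standardize = TRUE,
                          oneSibPerFamily = FALSE) {
  stopifnot(is(dataset, "FamilyPGIDataset"))
  if (standardize) dataset <- standardizeFamilies(dataset)$dataset
  d <- dataset@data
  if (oneSibPerFamily) d <- d[!duplicated(d$FID), , drop = FALSE]
  fit <- stats::lm(phenotype ~ pgi_proband, data = d)
  se <- sqrt(sandwich::vcovCL(fit, cluster = d$FID)[2, 2])
  list(betaHat = unname(stats::coef(fit)["pgi_proband"]), se = se,
       nIndividuals = nrow(d), nFamilies = length(unique(d$FID)), fit = fit)
}

#' Correlation between parents' PGIs
#'
#' Pearson correlation between paternal and maternal PGIs over unique
#' families (siblings deduplicated, as they share parental PGIs), with the
#' default standard error \code{(1 - r^2) / sqrt(n - 1)}.
#'
#' @param dataset A [FamilyPGIDataset-class] object with at least 3 distinct
#'   families.
#' @return list with \code{rK}, \code{se} and \code{nFamilies}.
#' @export
parentalPgiCorrelation <- function(dataset) {
  stopifnot(is(dataset, "FamilyPGIDataset"))
  d <- dataset@data[!duplicated(dataset@data$FID), , drop = FALSE]
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 distinct families")
  r <- stats::cor(d$pgi_father, d$pgi_mother)
  list(rK = r, se = (1 - r^2) / sqrt(n - 1), nFamilies = n)
}

#' Compute PGIs from a genotype matrix and per-variant weights
#'
#' Raw (unstandardized) PGI values \code{sum_l w_l (g_l - 2 f_l)} for an
#' additive-coded genotype matrix (individuals x variants, dosages 0/1/2).
#'
#' @param geno numeric/integer matrix, individuals x variants.
#' @param weights per-variant weights.
#' @param freqs per-variant allele frequencies used for centering.
#' @return numeric vector of raw PGI values.
#' @export
pgiFromGenotypes <- function(geno, weights, freqs) {
  if (ncol(geno) != length(weights) || ncol(geno) != length(freqs)) {
    stop("weights and freqs must match the number of genotype columns")
  }
  drop(geno %*% weights) - sum(2 * freqs * weights)
}

#' Summary-level inference from an individual-level dataset
#'
#' Runs the two-generation and parental-correlation analyses on a family PGI
#' dataset and feeds the results, together with an external family-based
#' heritability estimate, into [runTwoGenInference()].
#'
#' @param dataset A [FamilyPGIDataset-class] object.
#' @param h2f family-based heritability estimate.
#' @param h2fSe its standard error (0 treats \code{h2f} as known).
#' @param kOverride optional externally supplied k (with \code{kSe}).
#' @param kSe SE of \code{kOverride}.
#' @param oneSibPerFamily passed to [fitTwoGen()].
#' @param ... passed to [runTwoGenInference()].
#' @return A [TwoGenEstimates-class] object.
#' @export
inferFromDataset <- function(dataset, h2f, h2fSe = 0, kOverride = NA_real_,
                             kSe = NA_real_, oneSibPerFamily = FALSE, ...) {
  reg <- fitTwoGen(dataset, oneSibPerFamily = oneSibPerFamily)
  rk <- parentalPgiCorrelation(dataset)
  inputs <- TwoGenInputs(
    deltaHat = reg$deltaHat, deltaSe = sqrt(reg$vcov[1, 1]),
    alphaHat = reg$alphaHat, alphaSe = sqrt(reg$vcov[2, 2]),
    deltaAlphaCov = reg$vcov[1, 2],
    rKHat = rk$rK, rKSe = rk$se,
    h2fHat = h2f, h2fSe = h2fSe,
    nFamilies = reg$nFamilies,
    kOverride = kOverride, kSe = kSe)
  runTwoGenInference(inputs, ...)
}
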