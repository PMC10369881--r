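#' Simulation configuration constructor
#'
#' Builds a [SimConfig-class]. The \code{"paper"} profile is the full-scale
#' study design (30000 families, 20 generations of mating after the
#' random-mating founder generation); the \code{"reduced"} profile scales
#' down the number of families (3000) but keeps the full 20 generations,
#' because approach to the equilibrium variance is geometric at rate
#' \code{(1 + rDelta)/2} per generation and is still incomplete after ~12
#' generations under strong assortment.
#'
#' @param nFamilies,nVariants,mafRange,vg0,veg0,rDgIg0,rY,nGenerations,seed
#'   see [SimConfig-class]; unset values default per \code{profile}.
#' @param profile "paper" or "reduced".
#' @return A validated [SimConfig-class] object.
#' @examples
#' simConfig(rY = 0.5, veg0 = 0.125, rDgIg0 = 0.5, seed = 1,
#'           profile = "reduced")
#' @export
simConfig <- function(nFamilies = NULL, nVariants = 1000,
                      mafRange = c(0.05, 0.5), vg0 = 0.5, veg0 = 0.125,
                      rDgIg0 = 0.5, rY = 0.5, nGenerations = NULL,
                      seed = 1L, profile = c("paper", "reduced")) {
  profile <- match.arg(profile)
  if (is.null(nFamilies)) {
    nFamilies <- if (profile == "paper") 30000L else 3000L
  }
  if (is.null(nGenerations)) nGenerations <- 20L
  new("SimConfig",
      nFamilies = as.integer(nFamilies), nVariants = as.integer(nVariants),
      mafRange = as.numeric(mafRange), vg0 = vg0, veg0 = veg0,
      rDgIg0 = rDgIg0, rY = rY, nGenerations = as.integer(nGenerations),
      seed = as.integer(seed))
}

#' Draw minor allele frequencies with density proportional to 1/f
#'
#' Inverse-CDF sampling of the 1/f frequency spectrum expected for a
#' random-mating population of constant effective size:
#' \code{f = lo * (hi/lo)^u} with \code{u ~ Uniform(0, 1)} (log-uniform on
#' \code{[lo, hi]}).
#'
#' @param nVariants number of draws.
#' @param mafRange numeric(2), \code{0 < lo < hi <= 0.5}.
#' @return numeric vector of frequencies.
#' @export
drawMafs <- function(nVariants, mafRange = c(0.05, 0.5)) {
  lo <- mafRange[1]; hi <- mafRange[2]
  if (!(lo > 0 && lo < hi && hi <= 0.5)) {
    stop("mafRange must satisfy 0 < lo < hi <= 0.5")
  }
  lo * (hi / lo)^stats::runif(nVariants)
}

#' Draw per-variant DGE and IGE sizes
#'
#' Bivariate standard normal pairs with correlation \code{rDgIg0}; at
#' \code{rDgIg0 = 1} the IGEs equal the DGEs exactly.
#'
#' @param nVariants number of variants.
#' @param rDgIg0 effect correlation in \code{[-1, 1]}.
#' @return list with \code{delta} and \code{eta}.
#' @export
drawEffects <- function(nVariants, rDgIg0 = 0) {
  stopifnot(abs(rDgIg0) <= 1)
  delta <- stats::rnorm(nVariants)
  eta <- if (abs(rDgIg0) == 1) {
    rDgIg0 * delta
  } else {
    rDgIg0 * delta + sqrt(1 - rDgIg0^2) * stats::rnorm(nVariants)
  }
  list(delta = delta, eta = eta)
}

# one gamete per parent row: transmitted allele count per variant
gameteFrom <- function(G) {
  het <- G == 1L
  out <- (G == 2L) + (het & matrix(stats::runif(length(G)) < 0.5,
                                   nrow(G), ncol(G)))
  storage.mode(out) <- "integer"
  out
}

#' Simulate meiosis for paired parents
#'
#' Each offspring receives, per variant, one allele sampled uniformly from
#' each parent's two alleles, independently across variants and offspring
#' (independent segregation, no linkage).
#'
#' @param fatherGeno,motherGeno integer matrices (families x variants) of
#'   additive dosages 0/1/2.
#' @param nOffspring offspring per family.
#' @return integer matrix of (families * nOffspring) x variants dosages,
#'   rows grouped by family.
#' @export
meiosis <- function(fatherGeno, motherGeno, nOffspring = 2L) {
  stopifnot(all(dim(fatherGeno) == dim(motherGeno)))
  n <- nrow(fatherGeno)
  out <- matrix(0L, n * nOffspring, ncol(fatherGeno))
  idx <- function(j) seq.int(j, by = nOffspring, length.out = n)
  for (j in seq_len(nOffspring)) {
    out[idx(j), ] <- gameteFrom(fatherGeno) + gameteFrom(motherGeno)
  }
  out
}

#' Rank-match mates on a noisy phenotype
#'
#' Implements primary phenotypic assortment: each individual's matching score
#' is \code{Z = Y + u} with \code{u ~ Normal(0, (1/rY - 1) * vy)}, where
#' \code{vy} is the empirical phenotypic variance of the current parental
#' generation; males and females are sorted by Z and paired by rank, which
#' yields a realized spousal phenotypic correlation close to \code{rY}.
#' \code{rY = 0} pairs uniformly at random.
#'
#' @param yMale,yFemale phenotypes of the male and female mating pools
#'   (equal lengths).
#' @param rY target spousal phenotypic correlation in \code{[0, 1)}.
#' @return list of index vectors \code{father} and \code{mother}: pair i
#'   consists of male \code{father[i]} and female \code{mother[i]}.
#' @export
mateAssortative <- function(yMale, yFemale, rY) {
  n <- length(yMale)
  stopifnot(length(yFemale) == n)
  if (rY < 0 || rY >= 1) stop("rY must lie in [0, 1)")
  if (rY == 0) {
    return(list(father = sample.int(n), mother = seq_len(n)))
  }
  vy <- stats::var(c(yMale, yFemale))
  sdAm <- sqrt((1 / rY - 1) * vy)
  zM <- yMale + stats::rnorm(n, 0, sdAm)
  zF <- yFemale + stats::rnorm(n, 0, sdAm)
  list(father = order(zM), mother = order(zF))
}

# raw (unscaled) component sums
rawComponent <- function(geno, effects, freqs) {
  drop(geno %*% effects) - 2 * sum(freqs * effects)
}

#' Assemble phenotypes for an offspring generation
#'
#' Computes the DGE component from offspring genotypes and the summed
#' parental IGE component from the paired parental genotypes, using the
#' frozen founder-generation scaling (effects are already on the phenotype
#' scale), draws residuals \code{Normal(0, sigmaEps2)} and forms
#' \code{Y = Delta + eta_p + eta_m + eps}.
#'
#' @param geno offspring dosage matrix (2 sibs per family, rows grouped by
#'   family).
#' @param fatherGeno,motherGeno parental dosage matrices.
#' @param freqs founder allele frequencies.
#' @param delta,eta per-variant effects on the phenotype scale.
#' @param sigmaEps2 residual variance.
#' @return list with \code{compDelta}, \code{compEtaPar} (per family),
#'   \code{y}.
#' @export
assemblePhenotypes <- function(geno, fatherGeno, motherGeno, freqs,
                               delta, eta, sigmaEps2) {
  compDelta <- rawComponent(geno, delta, freqs)
  compEtaPar <- rawComponent(fatherGeno, eta, freqs) +
    rawComponent(motherGeno, eta, freqs)
  nSib <- nrow(geno) / nrow(fatherGeno)
  eps <- stats::rnorm(length(compDelta), 0, sqrt(sigmaEps2))
  y <- compDelta + rep(compEtaPar, each = nSib) + eps
  list(compDelta = compDelta, compEtaPar = compEtaPar, y = y)
}

newGenerationPopulation <- function(generation, freqs, delta, eta, sigmaEps2,
                                    fatherGeno, motherGeno, fatherY, motherY,
                                    geno = NULL) {
  if (is.null(geno)) geno <- meiosis(fatherGeno, motherGeno, 2L)
  n <- nrow(fatherGeno)
  comp <- assemblePhenotypes(geno, fatherGeno, motherGeno, freqs, delta, eta,
                             sigmaEps2)
  new("Population",
      generation = as.integer(generation), freqs = freqs,
      delta = delta, eta = eta, sigmaEps2 = sigmaEps2,
      geno = geno, family = rep(seq_len(n), each = 2L),
      sex = rep(c("M", "F"), n),
      fatherGeno = fatherGeno, motherGeno = motherGeno,
      compDelta = comp$compDelta, compEtaPar = comp$compEtaPar, y = comp$y,
      fatherY = fatherY, motherY = motherY,
      fatherDelta = drop(fatherGeno %*% delta) - 2 * sum(freqs * delta),
      motherDelta = drop(motherGeno %*% delta) - 2 * sum(freqs * delta),
      fatherEta = drop(fatherGeno %*% eta) - 2 * sum(freqs * eta),
      motherEta = drop(motherGeno %*% eta) - 2 * sum(freqs * eta))
}

corOrZero <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
}

#' Per-generation summary of the simulated truth
#'
#' Empirical variance components of the offspring generation and sample
#' correlations among the paired parents' DGE and IGE components.
#'
#' @param pop A [Population-class] object.
#' @return One-row data.frame with columns \code{generation}, \code{vg},
#'   \code{ve_g}, \code{cge}, \code{vy}, \code{r_delta}, \code{r_eta},
#'   \code{r_de_cis}, \code{r_de_trans}, \code{r_y_realized}.
#' @export
generationSummary <- function(pop) {
  stopifnot(is(pop, "Population"))
  etaPerSib <- rep(pop@compEtaPar, each = 2L)
  ryr <- if (all(is.na(pop@fatherY))) NA_real_ else
    stats::cor(pop@fatherY, pop@motherY)
  data.frame(
    generation = pop@generation,
    vg = stats::var(pop@compDelta),
    ve_g = stats::var(pop@compEtaPar),
    cge = 2 * stats::cov(pop@compDelta, etaPerSib),
    vy = stats::var(pop@y),
    r_delta = corOrZero(pop@fatherDelta, pop@motherDelta),
    r_eta = corOrZero(pop@fatherEta, pop@motherEta),
    r_de_cis = (corOrZero(pop@fatherDelta, pop@fatherEta) +
                  corOrZero(pop@motherDelta, pop@motherEta)) / 2,
    r_de_trans = (corOrZero(pop@fatherDelta, pop@motherEta) +
                    corOrZero(pop@motherDelta, pop@fatherEta)) / 2,
    r_y_realized = ryr)
}

#' Run the forward-in-time assortative-mating simulation
#'
#' Simulates founders (genotypes Binomial(2, f), random pairing), produces
#' the random-mating first offspring generation, computes the scaling that
#' puts the DGE component at variance \code{vg0} and the summed parental IGE
#' component at \code{veg0} in that generation (constants are then frozen so
#' effect sizes stay fixed and variance growth under AM is emergent), sets
#' \code{sigmaEps2 = 1 - (vg0 + veg0 + rDgIg0 * sqrt(2 vg0 veg0))} so the
#' founder-generation phenotypic variance is about 1, and then iterates
#' mate -> meiose -> assemble for \code{nGenerations} further generations.
#' Fully reproducible given \code{cfg@seed}.
#'
#' @param cfg A [SimConfig-class] object.
#' @return list with \code{population} (the final [Population-class], whose
#'   parental slots hold the penultimate generation), \code{summary}
#'   (one row per offspring generation), and \code{config}.
#' @export
runSimulation <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@nFamilies
  L <- cfg@nVariants

  freqs <- drawMafs(L, cfg@mafRange)
  eff <- drawEffects(L, cfg@rDgIg0)

  founderGeno <- function() {
    g <- matrix(stats::rbinom(n * L, 2L, rep(freqs, each = n)), n, L)
    storage.mode(g) <- "integer"
    g
  }
  fatherGeno <- founderGeno()
  motherGeno <- founderGeno()

  # first offspring generation; scaling computed on it, frozen thereafter
  geno1 <- meiosis(fatherGeno, motherGeno, 2L)
  vDelta <- stats::var(rawComponent(geno1, eff$delta, freqs))
  vEtaPar <- stats::var(rawComponent(fatherGeno, eff$eta, freqs) +
                          rawComponent(motherGeno, eff$eta, freqs))
  delta <- eff$delta * sqrt(cfg@vg0 / vDelta)
  eta <- if (cfg@veg0 > 0) eff$eta * sqrt(cfg@veg0 / vEtaPar) else
    rep(0, L)
  cge0 <- cfg@rDgIg0 * sqrt(2 * cfg@vg0 * cfg@veg0)
  sigmaEps2 <- 1 - (cfg@vg0 + cfg@veg0 + cge0)
  if (sigmaEps2 <= 0) stop("sigmaEps2 <= 0: reduce the genetic variances")

  pop <- newGenerationPopulation(1L, freqs, delta, eta, sigmaEps2,
                                 fatherGeno, motherGeno,
                                 rep(NA_real_, n), rep(NA_real_, n),
                                 geno = geno1)
  summaries <- vector("list", cfg@nGenerations + 1L)
  summaries[[1L]] <- generationSummary(pop)

  for (g in seq_len(cfg@nGenerations)) {
    males <- pop@sex == "M"
    females <- pop@sex == "F"
    pairs <- mateAssortative(pop@y[males], pop@y[females], cfg@rY)
    mg <- pop@geno[males, , drop = FALSE]
    fg <- pop@geno[females, , drop = FALSE]
    yM <- pop@y[males]; yF <- pop@y[females]
    pop <- newGenerationPopulation(
      pop@generation + 1L, freqs, delta, eta, sigmaEps2,
      fatherGeno = mg[pairs$father, , drop = FALSE],
      motherGeno = fg[pairs$mother, , drop = FALSE],
      fatherY = yM[pairs$father], motherY = yF[pairs$mother])
    summaries[[g + 1L]] <- generationSummary(pop)
  }

  list(population = pop, summary = do.call(rbind, summaries), config = cfg)
}

#' Build a simulated PGI and the per-family analysis dataset
#'
#' Constructs PGI weights as the true DGEs (kind "dge") or true population
#' effects DGE + IGE (kind "population"), plus white noise with variance
#' \code{noiseMultiple} times the variance of the noise-free weights
#' (emulating estimation error; the realized fraction of heritability
#' explained under random mating is about \code{1/(1 + noiseMultiple)} for a
#' DGE PGI). Proband PGIs come from the offspring genotypes and parental PGIs
#' from the paired parental genotypes, all centred with the founder allele
#' frequencies and left on the common raw scale (standardization is the
#' regression step's job).
#'
#' @param pop A [Population-class] object (final generation of
#'   [runSimulation()]).
#' @param kind "dge" or "population".
#' @param noiseMultiple noise-variance multiple (0, 1, 10, 100, ...).
#' @return list with \code{pgi} (a [SimPGI-class]; its \code{k} is the
#'   realized fraction of heritability the PGI would explain under random
#'   mating) and \code{dataset} (a [FamilyPGIDataset-class] with two siblings
#'   per family).
#' @export
buildPgi <- function(pop, kind = c("dge", "population"), noiseMultiple = 0) {
  stopifnot(is(pop, "Population"))
  kind <- match.arg(kind)
  base <- if (kind == "dge") pop@delta else pop@delta + pop@eta
  noise <- if (noiseMultiple > 0) {
    stats::rnorm(length(base), 0, sqrt(noiseMultiple * stats::var(base)))
  } else 0
  w <- base + noise

  het2 <- 2 * pop@freqs * (1 - pop@freqs)
  num <- sum(w * pop@delta * het2)
  k <- num^2 / (sum(w^2 * het2) * sum(pop@delta^2 * het2))

  proband <- pgiFromGenotypes(pop@geno, w, pop@freqs)
  father <- pgiFromGenotypes(pop@fatherGeno, w, pop@freqs)
  mother <- pgiFromGenotypes(pop@motherGeno, w, pop@freqs)

  d <- data.frame(
    FID = pop@family,
    IID = paste(pop@family, rep(1:2, length.out = length(pop@family)),
                sep = "_"),
    phenotype = pop@y,
    pgi_proband = proband,
    pgi_father = father[pop@family],
    pgi_mother = mother[pop@family],
    sex = pop@sex,
    stringsAsFactors = FALSE)

  list(pgi = new("SimPGI", kind = kind, noiseMultiple = noiseMultiple,
                 k = k, weights = w),
       dataset = FamilyPGIDataset(d))
}

setMethod("show", "Population", function(object) {
  cat(sprintf(
    "Population: generation %d, %d families, %d variants, Var(Y) = %.3f\n",
    object@generation, nrow(object@fatherGeno), ncol(object@geno),
    stats::var(object@y)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d families, %d variants, vg0 = %.3g, veg0 = %.3g, rDgIg0 = %.3g, rY = %.3g, %d generations, seed %d\n",
    object@nFamilies, object@nVariants, object@vg0, object@veg0,
    object@rDgIg0, object@rY, object@nGenerations, object@seed))
})

setMethod("show", "SimPGI", function(object) {
  cat(sprintf("Simulated %s PGI: noise multiple %.3g, realized k = %.3f\n",
              object@kind, object@noiseMultiple, object@k))
})
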