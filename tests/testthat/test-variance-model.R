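test_that("random-mating decomposition matches the closed-form sums", {
  # single variant: vg = 2 * 1 * 0.25 = 0.5
  rm1 <- randomMatingComponents(1, 0, 0.5)
  expect_equal(rm1@vg, 0.5)
  expect_equal(rm1@veg, 0)
  expect_equal(rm1@cge, 0)
  expect_equal(rm1@rDgIg0, 0)

  # zero DGEs: vg = cge = 0 regardless of IGEs
  rm0 <- randomMatingComponents(c(0, 0), c(1, 2), c(0.2, 0.3))
  expect_equal(rm0@vg, 0)
  expect_equal(rm0@cge, 0)

  # multi-variant sums against direct evaluation
  set.seed(1)
  d <- rnorm(50); e <- rnorm(50); f <- runif(50, 0.05, 0.5)
  rm <- randomMatingComponents(d, e, f, sigmaEps2 = 0.3)
  het <- f * (1 - f)
  expect_equal(rm@vg, 2 * sum(d^2 * het))
  expect_equal(rm@veg, 4 * sum(e^2 * het))
  expect_equal(rm@cge, 4 * sum(d * e * het))
  expect_equal(rm@vy, rm@vg + rm@veg + rm@cge + rm@sigmaEps2)
  expect_equal(rm@rDgIg0, rm@cge / sqrt(2 * rm@vg * rm@veg))

  expect_error(randomMatingComponents(1:2, 1:2, 0.5), "length")
  expect_error(randomMatingComponents(1, 1, 1.2), "frequencies")
})

test_that("scaled-effect parameterization reproduces the study constants", {
  # cge = r * sqrt(2 vg veg) at vg = 0.5, veg = 0.125
  expect_equal(RandomMatingComponents(0.5, 0.125, 0.5)@cge, 0.5 * sqrt(0.125))
  expect_equal(round(RandomMatingComponents(0.5, 0.125, 0.5)@cge, 3), 0.177)
  expect_equal(round(RandomMatingComponents(0.5, 0.125, 1)@cge, 3), 0.354)
  expect_equal(RandomMatingComponents(0.5, 0.125, 0)@cge, 0)
})

test_that("equilibrium decomposition has correct limits and monotonicity", {
  rm <- RandomMatingComponents(0.5, 0.125, 0.5, sigmaEps2 = 0.2)

  # zero correlations: equilibrium = random mating (except cge via corr = 0)
  eq0 <- equilibriumDecomposition(rm, EquilibriumCorrelations())
  expect_equal(eq0@vgEq, rm@vg)
  expect_equal(eq0@vegEq, rm@veg)
  expect_equal(eq0@cgeEq, 0)

  # Crow-Felsenstein limit: no IGEs, single-factor inflation
  rmNoIge <- RandomMatingComponents(0.5, 0, 0, sigmaEps2 = 0.5)
  eqCF <- equilibriumDecomposition(rmNoIge,
                                   EquilibriumCorrelations(rDelta = 0.5))
  expect_equal(eqCF@vgEq, 1.0)
  expect_equal(eqCF@cgeEq, 0)
  expect_equal(eqCF@h2F, (1 - 0.5) * eqCF@h2Eq)

  # vy_eq is the component sum; h2 identity holds generally
  corr <- EquilibriumCorrelations(0.3, 0.2, 0.25, 0.15)
  eq <- equilibriumDecomposition(rm, corr)
  expect_equal(eq@vyEq, eq@vgEq + eq@vegEq + eq@cgeEq + rm@sigmaEps2)
  expect_equal(eq@h2F, (1 - corr@rDelta) * eq@h2Eq)

  # strict monotonicity of vgEq in rDelta and vegEq in rEta
  rds <- seq(0, 0.8, by = 0.1)
  vgs <- vapply(rds, function(r) {
    equilibriumDecomposition(rm, EquilibriumCorrelations(rDelta = r))@vgEq
  }, numeric(1))
  expect_true(all(diff(vgs) > 0))
  vegs <- vapply(rds, function(r) {
    equilibriumDecomposition(rm, EquilibriumCorrelations(rEta = r))@vegEq
  }, numeric(1))
  expect_true(all(diff(vegs) > 0))

  expect_error(equilibriumDecomposition(rm, EquilibriumCorrelations(rDelta = 1)),
               "< 1")
})

test_that("alternative covariance-term route agrees on consistent inputs", {
  rm <- RandomMatingComponents(0.5, 0.125, 0.5, sigmaEps2 = 0.2)
  # consistency: cis correlation implied by the random-mating correlation
  # plus the AM-induced trans part (equilibrium-correlation convention)
  rd <- 0.3; re <- 0.2; rt <- 0.15
  rc <- rm@rDgIg0 * sqrt((1 - rd) * (1 - re)) + rt
  corr <- EquilibriumCorrelations(rd, re, rc, rt)
  expect_equal(equilibriumCgeFromCge0(rm, corr),
               equilibriumDecomposition(rm, corr)@cgeEq,
               tolerance = 1e-12)

  # no AM, no trans correlation: reduces to the random-mating covariance
  corr0 <- EquilibriumCorrelations(0, 0, rm@rDgIg0, 0)
  expect_equal(equilibriumCgeFromCge0(rm, corr0), rm@cge)

  # stated arithmetic: factor 1 + 2 rt / (r0 sqrt((1-rd)(1-re)))
  rm1 <- RandomMatingComponents(0.5, 0.125, 1, sigmaEps2 = 0.1)
  corr1 <- EquilibriumCorrelations(0.25, 0.25, 0, 0.25)
  expect_equal(equilibriumCgeFromCge0(rm1, corr1), rm1@cge * (1 + 0.5 / 0.75))

  rm0 <- RandomMatingComponents(0.5, 0.125, 0, sigmaEps2 = 0.1)
  expect_error(equilibriumCgeFromCge0(rm0, corr1), "rDgIg0")
})

test_that("phenotypic-assortment rdelta reduces to the classic result", {
  expect_equal(rdeltaPhenotypicAssortment(0.5, 0.5), 0.25)
  expect_equal(rdeltaPhenotypicAssortment(0.7, 0), 0)
  # with positively correlated components the induced correlation is larger
  expect_gt(rdeltaPhenotypicAssortment(0.5, 0.5, cgeEq = 0.2, vgEq = 1), 0.25)
  expect_error(rdeltaPhenotypicAssortment(0.5, 0.5, vgEq = 0), "vgEq")
})

test_that("sib-regression expectations expose the AM intercept bias", {
  # no AM, no IGE, no shared residual: slope = h2, intercept = 0
  rm <- RandomMatingComponents(0.5, 0, 0, sigmaEps2 = 0.5)
  eq <- equilibriumDecomposition(rm, EquilibriumCorrelations())
  sib <- sibRegressionExpectation(rm, eq, EquilibriumCorrelations())
  expect_equal(sib@slope, 0.5)
  expect_equal(sib@intercept, 0)

  # AM without IGEs: intercept = rDelta * h2Eq despite no shared environment
  corr <- EquilibriumCorrelations(rDelta = 0.4)
  eqAM <- equilibriumDecomposition(rm, corr)
  sibAM <- sibRegressionExpectation(rm, eqAM, corr)
  expect_gt(sibAM@intercept, 0)
  expect_equal(sibAM@intercept, 0.4 * eqAM@h2Eq)

  # correction identity: rDelta * h2Eq = rDelta/(1 - rDelta) * h2F
  expect_equal(sibAM@intercept - 0.4 / (1 - 0.4) * eqAM@h2F, 0,
               tolerance = 1e-12)

  # general intercept recovers the shared components after the correction
  rm2 <- RandomMatingComponents(0.5, 0.125, 0.5, sigmaEps2 = 0.19822)
  corr2 <- EquilibriumCorrelations(0.3, 0.2, 0.4, 0.2)
  eq2 <- equilibriumDecomposition(rm2, corr2)
  sib2 <- sibRegressionExpectation(rm2, eq2, corr2, residCov = 0.05)
  expect_equal(sib2@intercept - corr2@rDelta / (1 - corr2@rDelta) * eq2@h2F,
               (eq2@vegEq + eq2@cgeEq + 0.05) / eq2@vyEq,
               tolerance = 1e-12)
})

test_that("family-based heritability inflates correctly to equilibrium", {
  expect_equal(round(h2eqFromH2f(0.554, 0.2078099), 3), 0.699)
  expect_equal(h2eqFromH2f(0.6, 0), 0.6)
  # twin-column chain: rdelta from k = 0.346, rk = 0.106
  rd <- estimateRdelta(0.346, 0.106)$rDelta
  expect_equal(round(h2eqFromH2f(0.729, rd), 3), 0.979)
  expect_error(h2eqFromH2f(0.5, 1), "rDelta")
})

test_that("component objects validate and serialize to flat lists", {
  rm <- RandomMatingComponents(0.5, 0.125, 0.5, sigmaEps2 = 0.2)
  fl <- asFlatList(rm)
  expect_named(fl, c("vg", "ve_g", "cge", "sigma_eps2", "r_dg_ig_0", "vy"))
  expect_equal(fl$vy, rm@vy)

  # Cauchy-Schwarz violation rejected
  expect_error(new("RandomMatingComponents", vg = 0.5, veg = 0.125,
                   cge = 1, sigmaEps2 = 0, rDgIg0 = 0.5, vy = 1.625),
               "Cauchy")
  # non-PSD correlation structure rejected
  expect_error(EquilibriumCorrelations(0.9, -0.9, 0.9, 0.9),
               "positive semi-definite")
})
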