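test_that("k estimator applies and drops its bias corrections correctly", {
  # corrections vanish with exact inputs
  plain <- estimateK(0.5293, 0.106, 0.554)
  expect_equal(plain$k, (1 - 0.106) * 0.5293^2 / 0.554)
  expect_false(plain$clipped)
  expect_equal(estimateK(0.5293, 0.106, 0.554, varDelta = 0, seH2f = 0)$k,
               estimateK(0.5293, 0.106, 0.554, biasCorrect = FALSE)$k)
  # algebraic inversion of the plain estimator against the printed k
  deltaHat <- sqrt(0.452 * 0.554 / (1 - 0.106))
  expect_equal(round(estimateK(deltaHat, 0.106, 0.554)$k, 3), 0.452)
  # corrected estimator shrinks k for noisy inputs
  corr <- estimateK(0.5293, 0.106, 0.554, varDelta = 0.01^2, seH2f = 0.044)
  expect_lt(corr$k, plain$k)
  # negative corrected numerator clips to zero with a flag
  zero <- estimateK(0.005, 0.1, 0.5, varDelta = 0.01^2)
  expect_equal(zero$k, 0)
  expect_true(zero$clipped)
  # k above 1 clips with a flag
  one <- estimateK(1.2, 0, 0.5)
  expect_equal(one$k, 1)
  expect_true(one$clipped)
  expect_error(estimateK(0.5, 0.1, 0), "h2f")
})

test_that("rdelta estimating equation matches the printed chains", {
  expect_equal(round(estimateRdelta(0.452, 0.106)$rDelta, 3), 0.208)
  expect_equal(round(estimateRdelta(0.069, 0.175)$rDelta, 3), 0.755)
  expect_equal(estimateRdelta(0.7, 0)$rDelta, 0)
  expect_equal(estimateRdelta(1, 0.3)$rDelta, 0.3)
  expect_true(estimateRdelta(0.01, 0.02)$unstable)
  expect_false(estimateRdelta(0.5, 0.1)$unstable)
  expect_error(estimateRdelta(0, 0), "> 0")
})

test_that("alpha-delta estimators reproduce the printed values and agree", {
  # height RDR: ratio route
  rd <- estimateRdelta(0.452, 0.106)$rDelta
  rho <- rhoK(0.452, rd)
  expect_equal(round(estimateAlphaDelta1(rho, 0.910, rd), 3), -0.022)
  expect_equal(estimateAlphaDelta1(rho, rho, rd), 0)

  # EA: estimator 2 with alpha/delta implied by the ratio via the
  # population-effect identity gives the same answer as estimator 1
  rdEa <- estimateRdelta(0.069, 0.175)$rDelta
  rhoEa <- rhoK(0.069, rdEa)
  ntcHat <- (1 / 0.556 - 1) / (1 + 0.175)
  expect_equal(round(estimateAlphaDelta2(rhoEa, 0.069, rdEa, ntcHat), 3),
               -0.265)
  expect_equal(estimateAlphaDelta2(rhoEa, 0.069, rdEa, ntcHat),
               estimateAlphaDelta1(rhoEa, 0.556, rdEa), tolerance = 1e-6)

  # AM-only NTC ratio maps to zero
  k <- 0.5; rd0 <- 0.3; rho0 <- rhoK(k, rd0)
  expect_equal(estimateAlphaDelta2(rho0, k, rd0,
                                   (1 - rho0) / (rho0 + k * rd0)), 0,
               tolerance = 1e-12)

  # paired noisy replicates: the two estimators nearly coincide
  set.seed(11)
  diffs <- replicate(300, {
    d <- rnorm(1, 0.55, 0.01); a <- rnorm(1, 0.03, 0.007)
    rk <- rnorm(1, 0.2, 0.01); h2f <- rnorm(1, 0.45, 0.03)
    kk <- estimateK(d, rk, h2f)$k
    rdd <- estimateRdelta(kk, rk)$rDelta
    rr <- rhoK(kk, rdd)
    beta <- d + (1 + rk) * a
    abs(estimateAlphaDelta1(rr, d / beta, rdd) -
          estimateAlphaDelta2(rr, kk, rdd, a / d))
  })
  expect_lt(mean(diffs), 0.01)
})

test_that("v_eta_delta matches the published inference-chain values", {
  expect_equal(estimateVEtaDelta(0, 0.3, 0.7), 0)
  rd <- estimateRdelta(0.452, 0.106)$rDelta
  ad <- estimateAlphaDelta1(rhoK(0.452, rd), 0.910, rd)
  expect_equal(round(estimateVEtaDelta(ad, rd, 0.554 / (1 - rd)), 3), -0.036)
  rdEa <- estimateRdelta(0.069, 0.175)$rDelta
  adEa <- estimateAlphaDelta1(rhoK(0.069, rdEa), 0.556, rdEa)
  expect_equal(round(estimateVEtaDelta(adEa, rdEa, 0.400 / (1 - rdEa)), 3),
               -1.114)
})

test_that("delta-method machinery is exact on linear maps and guards inputs", {
  A <- matrix(c(1, 2, 0, -1, 0.5, 3), 3, 2)
  S <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  dm <- deltaMethodSE(function(x) drop(A %*% x), c(1, 2), S)
  expect_equal(dm$se, sqrt(diag(A %*% S %*% t(A))), tolerance = 1e-6)
  # zero input covariance propagates to zero output SEs
  dm0 <- deltaMethodSE(function(x) c(x[1]^2, exp(x[2])), c(1, 1),
                       matrix(0, 2, 2))
  expect_equal(dm0$se, c(0, 0))
  expect_error(deltaMethodSE(identity, c(1, 2), matrix(c(1, 2, 2, 1), 2)),
               "semi-definite")
  expect_error(deltaMethodSE(identity, c(1, 2), diag(3)), "p x p")
})

test_that("full pipeline reproduces the published inference chains", {
  # height, RDR heritability input (ratio route with supplied k)
  h <- runTwoGenInference(TwoGenInputs(
    ratioHat = 0.910, ratioSe = 0.009, rKHat = 0.106, rKSe = 0.020,
    h2fHat = 0.554, h2fSe = 0.044, kOverride = 0.452, kSe = 0.038))
  e <- estimates(h)
  expect_equal(round(unname(e["r_delta"]), 3), 0.208)
  expect_equal(round(unname(e["h2_eq"]), 3), 0.699)
  expect_equal(round(unname(e["rho_k"]), 3), 0.886)
  expect_equal(round(unname(e["alpha_delta"]), 3), -0.022)
  expect_equal(round(unname(e["v_eta_delta"]), 3), -0.036)
  expect_equal(h@methodAlpha, 1L)
  # SEs propagate to plausible magnitudes (nonzero, same order as printed)
  s <- standardErrors(h)
  expect_true(all(s[c("r_delta", "h2_eq", "alpha_delta")] > 0))
  expect_lt(abs(s[["r_delta"]] - 0.041) / 0.041, 0.5)

  # educational attainment chain
  ea <- runTwoGenInference(TwoGenInputs(
    ratioHat = 0.556, ratioSe = 0.020, rKHat = 0.175, rKSe = 0.020,
    h2fHat = 0.400, h2fSe = 0.024, kOverride = 0.069, kSe = 0.007))
  ee <- estimates(ea)
  expect_equal(round(unname(ee["r_delta"]), 3), 0.755)
  expect_equal(round(unname(ee["alpha_delta"]), 3), -0.265)
  expect_equal(round(unname(ee["v_eta_delta"]), 3), -1.114)

  # regression-coefficient route: delta/alpha consistent with the height
  # ratio reproduce the same chain via estimator 2
  delta <- 0.5293; beta <- delta / 0.910
  alpha <- (beta - delta) / (1 + 0.106)
  reg <- runTwoGenInference(TwoGenInputs(
    deltaHat = delta, deltaSe = 0, alphaHat = alpha, alphaSe = 0,
    rKHat = 0.106, rKSe = 0.020, h2fHat = 0.554, h2fSe = 0.044),
    biasCorrectK = FALSE)
  expect_equal(reg@methodAlpha, 2L)
  expect_equal(round(unname(estimates(reg)["r_delta"]), 3), 0.208)
  expect_equal(round(unname(estimates(reg)["alpha_delta"]), 3), -0.022)
  expect_equal(reg@betaHat, beta)

  # inconsistent ratio vs regression coefficients is an error
  expect_error(runTwoGenInference(TwoGenInputs(
    deltaHat = delta, alphaHat = alpha, ratioHat = 0.8,
    rKHat = 0.106, h2fHat = 0.554)), "inconsistent")
})

test_that("pipeline flags instability at very small k", {
  est <- runTwoGenInference(TwoGenInputs(
    ratioHat = 0.5, ratioSe = 0.02, rKHat = 0.02, rKSe = 0.01,
    h2fHat = 0.5, h2fSe = 0.03, kOverride = 0.01, kSe = 0.005))
  expect_true("unstable_small_k" %in% estimationWarnings(est))
  # and k clipping is reported when the corrected numerator goes negative
  clip <- runTwoGenInference(TwoGenInputs(
    deltaHat = 0.01, deltaSe = 0.02, alphaHat = 0.02, alphaSe = 0.01,
    rKHat = 0.1, rKSe = 0.01, h2fHat = 0.5, h2fSe = 0.03))
  expect_true("k_clipped" %in% estimationWarnings(clip))
})

test_that("delta-method SEs calibrate against summary-level replicates", {
  set.seed(5)
  delta0 <- 0.55; alpha0 <- 0.05; rk0 <- 0.20; h2f0 <- 0.47
  seD <- 0.010; seA <- 0.007; covDA <- -0.3 * seD * seA
  seRk <- (1 - rk0^2) / sqrt(10000); seH <- 0.04
  ch <- chol(matrix(c(seD^2, covDA, covDA, seA^2), 2))
  R <- 500
  est <- matrix(NA_real_, R, 6); ses <- matrix(NA_real_, R, 6)
  for (r in seq_len(R)) {
    da <- c(delta0, alpha0) + drop(rnorm(2) %*% ch)
    out <- runTwoGenInference(TwoGenInputs(
      deltaHat = da[1], deltaSe = seD, alphaHat = da[2], alphaSe = seA,
      deltaAlphaCov = covDA, rKHat = rnorm(1, rk0, seRk), rKSe = seRk,
      h2fHat = rnorm(1, h2f0, seH), h2fSe = seH))
    est[r, ] <- estimates(out); ses[r, ] <- standardErrors(out)
  }
  colnames(est) <- colnames(ses) <- names(estimates(out))
  for (p in c("r_delta", "h2_eq", "alpha_delta")) {
    expect_lt(abs(mean(ses[, p]) / sd(est[, p]) - 1), 0.15)
  }
})

test_that("null inference covers zero IGEs at nominal rates", {
  # AM present, no IGEs: alpha_delta and v_eta_delta within 2 SE of zero in
  # at least 93% of summary-level replicates
  set.seed(6)
  k0 <- 0.5; rd0 <- 0.28
  rk0 <- rkFromRdelta(k0, rd0); rho0 <- rhoK(k0, rd0)
  h2eq0 <- 0.57; h2f0 <- (1 - rd0) * h2eq0
  delta0 <- sqrt(k0 * h2f0 / (1 - rk0))
  alpha0 <- delta0 * (1 - rho0) / (rho0 * (1 + rk0))
  seD <- 0.012; seA <- 0.008
  seRk <- (1 - rk0^2) / sqrt(8000); seH <- 0.015
  cover <- replicate(400, {
    out <- runTwoGenInference(TwoGenInputs(
      deltaHat = rnorm(1, delta0, seD), deltaSe = seD,
      alphaHat = rnorm(1, alpha0, seA), alphaSe = seA,
      rKHat = rnorm(1, rk0, seRk), rKSe = seRk,
      h2fHat = rnorm(1, h2f0, seH), h2fSe = seH))
    e <- estimates(out); s <- standardErrors(out)
    c(abs(e["alpha_delta"]) <= 2 * s["alpha_delta"],
      abs(e["v_eta_delta"]) <= 2 * s["v_eta_delta"])
  })
  expect_gte(mean(cover[1, ]), 0.93)
  expect_gte(mean(cover[2, ]), 0.93)
})
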