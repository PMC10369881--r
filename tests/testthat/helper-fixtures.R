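# Synthetic trio data with exact Mendelian PGI structure (no genotypes):
# parents' PGIs are unit-variance with correlation rk; each sibling's PGI is
# the midparent value plus segregation noise of variance (1 - rk)/2, so
# offspring PGI variance equals the parental variance (equilibrium).
# Phenotype: Y = delta * pgi + alpha * (pgi_f + pgi_m) + e.
makeTrioData <- function(nFam, delta = 0.5, alpha = 0, rk = 0,
                         sibs = 2L, residSd = NULL, famSd = 0) {
  f <- stats::rnorm(nFam)
  m <- rk * f + sqrt(1 - rk^2) * stats::rnorm(nFam)
  rows <- rep(seq_len(nFam), each = sibs)
  pgi <- (f[rows] + m[rows]) / 2 +
    stats::rnorm(nFam * sibs, 0, sqrt((1 - rk) / 2))
  lin <- delta * pgi + alpha * (f[rows] + m[rows])
  if (is.null(residSd)) residSd <- sqrt(max(1 - stats::var(lin), 0.1))
  y <- lin + stats::rnorm(nFam * sibs, 0, residSd) +
    stats::rnorm(nFam, 0, famSd)[rows]
  FamilyPGIDataset(data.frame(
    FID = rows,
    IID = paste(rows, rep(seq_len(sibs), nFam), sep = "_"),
    phenotype = y, pgi_proband = pgi,
    pgi_father = f[rows], pgi_mother = m[rows],
    stringsAsFactors = FALSE))
}

# the 16 simulation study conditions
scenarioGrid <- function() {
  g <- expand.grid(veg0 = c(0, 0.125), rDgIg0 = c(0, 0.5, 1),
                   rY = c(0, 0.25, 0.5, 0.75))
  g[!(g$veg0 == 0 & g$rDgIg0 != 0), , drop = FALSE]
}

# simulated truth of the final generation
simTruth <- function(pop) {
  rd <- stats::cor(pop@fatherDelta, pop@motherDelta)
  vgEq <- stats::var(pop@compDelta)
  vy <- stats::var(pop@y)
  h2eq <- vgEq / vy
  cgeEq <- 2 * stats::cov(pop@compDelta, rep(pop@compEtaPar, each = 2))
  ad <- cgeEq / (2 * (1 + rd) * vgEq)
  c(r_delta = rd, h2_eq = h2eq, alpha_delta = ad,
    v_eta_delta = 2 * (1 + rd) * ad * (1 + ad) * h2eq)
}

# run the 16 reduced-scale scenario simulations once per test session
.scenarioCache <- new.env(parent = emptyenv())
acceptanceScenarios <- function() {
  if (!is.null(.scenarioCache$sims)) return(.scenarioCache$sims)
  grid <- scenarioGrid()
  sims <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- simConfig(veg0 = grid$veg0[i], rDgIg0 = grid$rDgIg0[i],
                     rY = grid$rY[i], seed = 100L + i, profile = "reduced")
    runSimulation(cfg)
  })
  .scenarioCache$sims <- sims
  sims
}
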