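#' Agreement between the equilibrium decomposition and simulated truth
#'
#' Evaluates the equilibrium phenotypic-variance decomposition with the
#' correlations measured among the final generation's mated parents and
#' compares it with the empirical phenotypic variance of the final offspring
#' generation; also compares the Crow-Felsenstein prediction
#' \code{vg0/(1 - rDelta)} with the empirical DGE-component variance. Both
#' differences come with Monte-Carlo standard errors from a family-block
#' (delete-a-group) jackknife, which recomputes measured correlations,
#' predictions and empirical variances on each leave-one-block-out subset
#' and therefore accounts for the sampling noise shared between prediction
#' and observation.
#'
#' @param sim result of [runSimulation()].
#' @param nBlocks number of jackknife blocks over families.
#' @return list with \code{vy} (prediction, empirical, difference, se) and
#'   \code{vgEq} (same for the DGE-component variance), plus the measured
#'   correlations.
#' @export
equilibriumAgreement <- function(sim, nBlocks = 30L) {
  pop <- sim$population
  cfg <- sim$config
  stopifnot(is(pop, "Population"), is(cfg, "SimConfig"))
  n <- nrow(pop@fatherGeno)
  vg0 <- cfg@vg0; veg0 <- cfg@veg0
  cge0 <- cfg@rDgIg0 * sqrt(2 * vg0 * veg0)
  sigmaEps2 <- 1 - (vg0 + veg0 + cge0)

  statFor <- function(fam) {
    fd <- pop@fatherDelta[fam]; md <- pop@motherDelta[fam]
    fe <- pop@fatherEta[fam]; me <- pop@motherEta[fam]
    rd <- corOrZero(fd, md)
    re <- corOrZero(fe, me)
    rc <- (corOrZero(fd, fe) + corOrZero(md, me)) / 2
    rt <- (corOrZero(fd, me) + corOrZero(md, fe)) / 2
    rows <- rep((fam - 1L) * 2L, each = 2L) + c(1L, 2L)
    vyEmp <- stats::var(pop@y[rows])
    vgEmp <- stats::var(pop@compDelta[rows])
    vyPred <- vg0 / (1 - rd) + veg0 * (1 + re) / (1 - re) +
      (if (veg0 > 0) (rc + rt) * sqrt(2 * veg0 * vg0 / ((1 - re) * (1 - rd)))
       else 0) + sigmaEps2
    c(vyPred = vyPred, vyEmp = vyEmp, vyDiff = vyPred - vyEmp,
      vgPred = vg0 / (1 - rd), vgEmp = vgEmp,
      vgDiff = vg0 / (1 - rd) - vgEmp,
      r_delta = rd, r_eta = re, r_de_cis = rc, r_de_trans = rt)
  }

  full <- statFor(seq_len(n))
  blocks <- cut(seq_len(n), nBlocks, labels = FALSE)
  jack <- vapply(seq_len(nBlocks),
                 function(b) statFor(which(blocks != b))[c("vyDiff", "vgDiff")],
                 numeric(2))
  jackSe <- function(v) sqrt((nBlocks - 1) / nBlocks * sum((v - mean(v))^2))

  list(
    vy = list(predicted = unname(full["vyPred"]),
              empirical = unname(full["vyEmp"]),
              difference = unname(full["vyDiff"]),
              se = jackSe(jack["vyDiff", ])),
    vgEq = list(predicted = unname(full["vgPred"]),
                empirical = unname(full["vgEmp"]),
                difference = unname(full["vgDiff"]),
                se = jackSe(jack["vgDiff", ])),
    correlations = as.list(full[c("r_delta", "r_eta", "r_de_cis",
                                  "r_de_trans")]))
}
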