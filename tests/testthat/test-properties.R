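# distributional properties of the fitted model, checked by simulation

test_that("stronger spatial mixing in the truth raises the phi posterior", {
  nPairs <- 10L
  wins <- 0L
  for (r in seq_len(nPairs)) {
    fits <- lapply(c(0.1, 0.9), function(phiTrue) {
      sim <- simulatePanel(simulationConfig(
        nCountries = 25, years = 2000:2009, graphKind = "lattice",
        trueBeta = rep(0, 6),
        trueHyper = list(tauE = 150, tauS = 1, phi = phiTrue,
                         tauTheta = 2e4, tauDelta = 180),
        seed = 500L + 7L * r + round(phiTrue)))
      mod <- buildModel(sim$panel, sim$graph, modelSpec("M0s"))
      suppressWarnings(fitMCMC(mod, nIter = 700L, nWarmup = 300L,
                               nChains = 1L, seed = r))
    })
    phiMeans <- vapply(fits, function(f) mean(f@draws$hyper[, "phi"]), 0)
    wins <- wins + (phiMeans[2L] > phiMeans[1L])
  }
  expect_gte(wins, 9L)
})

test_that("posterior error variance tracks the true noise level", {
  # On a complete panel the exchangeable interaction and the Gaussian error
  # are indistinguishable cell-level effects: only their variance sum is
  # likelihood-identified.  sigma_e^2 itself is therefore tracked on the
  # variant without the interaction term, and the identified total on the
  # full model.
  fits <- lapply(c(50, 150, 400), function(tauTrue) {
    sim <- simulatePanel(simulationConfig(
      nCountries = 16, years = 2000:2011,
      trueHyper = list(tauE = tauTrue, tauS = 5, phi = 0.5,
                       tauTheta = 2e4, tauDelta = 1e4),
      seed = 900L + tauTrue))
    mod <- buildModel(sim$panel, sim$graph,
                      modelSpec("M1s", effects = c("spatial", "temporal")))
    modFull <- buildModel(sim$panel, sim$graph, modelSpec("M1s"))
    list(noInt = suppressWarnings(fitMCMC(mod, nIter = 700L, nWarmup = 300L,
                                          nChains = 1L, seed = 5L)),
         full = suppressWarnings(fitMCMC(modFull, nIter = 700L,
                                         nWarmup = 300L, nChains = 1L,
                                         seed = 5L)))
  })
  sigma2 <- vapply(fits, function(f)
    mean(1 / f$noInt@draws$hyper[, "tau_e"]), 0)
  expect_true(all(diff(sigma2) < 0))
  total <- vapply(fits, function(f)
    mean(1 / f$full@draws$hyper[, "tau_e"] +
           1 / f$full@draws$hyper[, "tau_delta"]), 0)
  expect_true(all(diff(total) < 0))
})

test_that("local trends pick up an injected country-specific slope", {
  # a country whose interaction term carries an extra linear slope should
  # show a recovered local trend with the right sign
  nRep <- 10L
  hits <- 0L
  for (r in seq_len(nRep)) {
    sim <- simulatePanel(simulationConfig(
      nCountries = 16, years = 2000:2011, trueBeta = rep(0, 6),
      trueHyper = list(tauE = 150, tauS = 5, phi = 0.5, tauTheta = 2e4,
                       tauDelta = 180), seed = 700L + r))
    y <- outcomeMatrix(sim$panel)
    slope <- 0.08 * (seq_len(12L) - 6.5)           # +0.08 gap years / year
    y["C001", ] <- y["C001", ] + slope
    panel <- GapPanel(y, countryIds(sim$panel), panelYears(sim$panel),
                      covariates = covariateMatrices(sim$panel),
                      region = panelRegions(sim$panel))
    mod <- buildModel(panel, sim$graph, modelSpec("M0s"))
    fit <- suppressWarnings(fitMCMC(mod, nIter = 600L, nWarmup = 250L,
                                    nChains = 1L, seed = r))
    lt <- localTemporalTrend(fit, "C001")
    fitSlope <- stats::coef(stats::lm(lt$mean ~ lt$year))[2L]
    hits <- hits + (fitSlope > 0)
  }
  expect_gte(hits, 9L)
})

test_that("credible bands tighten as the interaction precision grows", {
  widths <- vapply(c(30, 3000), function(tauD) {
    sim <- simulatePanel(simulationConfig(
      nCountries = 16, years = 2000:2011,
      trueHyper = list(tauE = 150, tauS = 5, phi = 0.5, tauTheta = 2e4,
                       tauDelta = tauD), seed = 800L + tauD))
    mod <- buildModel(sim$panel, sim$graph, modelSpec("M1s"))
    fit <- suppressWarnings(fitMCMC(mod, nIter = 600L, nWarmup = 250L,
                                    nChains = 1L, seed = 9L))
    lt <- localTemporalTrend(fit, "C005")
    mean(lt$q97.5 - lt$q2.5)
  }, 0)
  expect_lt(widths[2L], widths[1L])
})
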