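test_that("model assembly counts the latent field and expands regions", {
  sim <- simulatePanel(simulationConfig(nCountries = 4, years = 2000:2002,
                                        regionCount = 2, seed = 1))
  # intercept + s (4) + theta (3) + delta (12); no covariates under M0s
  m0 <- buildModel(sim$panel, sim$graph, modelSpec("M0s"))
  expect_equal(latentDimension(m0), 1L + 4L + 3L + 12L)

  sim6 <- simulatePanel(simulationConfig(nCountries = 12, years = 2000:2002,
                                         regionCount = 6, seed = 2))
  m2 <- buildModel(sim6$panel, sim6$graph, modelSpec("M2s"))
  # two exposure coefficients per region plus four shared confounders
  expect_equal(ncol(m2@design$F), 2L * 6L + 4L)
  expect_equal(sum(grepl("^pwpm25:", colnames(m2@design$F))), 6L)

  # a zero covariate cell must be rejected by name under the log transform
  simBad <- simulatePanel(simulationConfig(nCountries = 4, years = 2000:2002,
                                           regionCount = 2, seed = 3))
  SummarizedExperiment::assays(simBad$panel)$poverty[2L, 1L] <- 0
  expect_error(buildModel(simBad$panel, simBad$graph, modelSpec("M1s")),
               "poverty.*C002.*2000")

  # mismatched country sets
  g2 <- simulateGraph(5, "lattice")
  expect_error(buildModel(sim$panel, g2, modelSpec("M0s")), "differ")
})

test_that("degenerate intercept model reproduces its closed-form posterior", {
  set.seed(42)
  n <- 20L; tauE <- 150
  y <- stats::rnorm(n, 5, sd = 1 / sqrt(tauE))
  panel <- GapPanel(matrix(y, n, 1L), sprintf("C%03d", 1:n), 2000L)
  graph <- buildGraph(countryIds(panel))
  mod <- buildModel(panel, graph,
                    modelSpec("M0s", effects = character(),
                              priors = list(alphaPrec = 0),
                              fixedTauE = tauE))
  fit <- fitMCMC(mod, nIter = 2500L, nWarmup = 500L, nChains = 1L, seed = 7L)
  a <- fit@draws$alpha
  postSd <- 1 / sqrt(n * tauE)
  expect_lt(abs(mean(a) - mean(y)), 3 * postSd / sqrt(length(a)))
  expect_equal(stats::var(a), postSd^2, tolerance = 0.1)
})

test_that("sampling is reproducible for a fixed seed and configuration", {
  f1 <- quickFit(nCountries = 9, years = 2000:2005, nIter = 120, nWarmup = 40)
  f2 <- quickFit(nCountries = 9, years = 2000:2005, nIter = 120, nWarmup = 40)
  expect_identical(f1$fit@draws, f2$fit@draws)
  expect_identical(f1$fit@pointwiseLogLik, f2$fit@pointwiseLogLik)
})

test_that("posterior draws satisfy the identifiability constraints", {
  f <- quickFit(nCountries = 9, years = 2000:2006, nIter = 200, nWarmup = 80)
  th <- f$fit@draws$theta
  de <- f$fit@draws$delta
  expect_lt(max(abs(rowSums(th))), 1e-10)
  expect_lt(max(abs(rowSums(de))), 1e-10)
  # structured BYM2 part sums to zero within each component (one lattice comp)
  expect_lt(max(abs(rowSums(f$fit@draws$u))), 1e-7)
  # decomposition is exact: s = (sqrt(phi) u + sqrt(1-phi) v)/sqrt(tau_s)
  hy <- f$fit@draws$hyper
  sRec <- (sqrt(hy[, "phi"]) * f$fit@draws$u +
           sqrt(1 - hy[, "phi"]) * f$fit@draws$v) / sqrt(hy[, "tau_s"])
  expect_equal(sRec, f$fit@draws$s, tolerance = 1e-8)
})

test_that("posterior summaries use equal-tailed intervals and flag zero", {
  K <- 100L
  ll <- matrix(stats::dnorm(c(1, 2), log = TRUE), K, 2L, byrow = TRUE)
  fit <- handFit(y = c(1, 2), ll = ll, tauE = 1, muMean = c(1, 2),
                 extraDraws = list(alpha = rep(3.5, K)))
  sm <- posteriorSummary(fit, "alpha")
  expect_equal(sm$mean, 3.5)
  expect_equal(sm$q2.5, 3.5)
  expect_equal(sm$q97.5, 3.5)
  expect_true(sm$significant)

  fit2 <- handFit(y = c(1, 2), ll = ll, tauE = 1, muMean = c(1, 2),
                  extraDraws = list(alpha = as.numeric(1:100)))
  sm2 <- posteriorSummary(fit2, "alpha")
  expect_equal(sm2$mean, 50.5)
  expect_equal(sm2$q2.5, unname(stats::quantile(1:100, 0.025)))
  expect_error(posteriorSummary(fit2, "nonsense"), "unknown quantity")
})

test_that("spatiotemporal decompositions are consistent with the draws", {
  f <- quickFit(nCountries = 9, years = 2000:2006, nIter = 250, nWarmup = 100)
  fit <- f$fit
  yr <- 2003L; t <- yr - 1999L
  comb <- combinedSpatialEffect(fit, yr)
  manual <- fit@draws$s[, 2L] + fit@draws$theta[, t] +
    fit@draws$delta[, (t - 1L) * 9L + 2L]
  expect_equal(comb$mean[2L], mean(manual))
  expect_equal(comb$q2.5[2L], unname(stats::quantile(manual, 0.025)))
  expect_error(combinedSpatialEffect(fit, 1950), "outside")

  lt <- localTemporalTrend(fit, "C003")
  manual3 <- fit@draws$theta[, 5L] + fit@draws$delta[, 4L * 9L + 3L]
  expect_equal(lt$mean[5L], mean(manual3))
  expect_error(localTemporalTrend(fit, "nowhere"), "unknown country")

  ot <- overallTemporalTrend(fit)
  expect_equal(ot$mean, colMeans(fit@draws$theta))
  expect_lt(abs(sum(ot$mean)), 1e-10)
})

test_that("missing outcomes are masked from the likelihood and imputed", {
  sim <- simulatePanel(simulationConfig(nCountries = 9, years = 2000:2007,
                                        missingRate = 0.15, seed = 21))
  nMis <- sum(is.na(outcomeMatrix(sim$panel)))
  expect_gt(nMis, 0L)
  mod <- buildModel(sim$panel, sim$graph, modelSpec("M1s"))
  expect_equal(length(mod@design$y), 72L - nMis)
  fit <- suppressWarnings(fitMCMC(mod, nIter = 150L, nWarmup = 50L,
                                  nChains = 1L, seed = 2L))
  expect_equal(ncol(fit@pointwiseLogLik), 72L - nMis)
})
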