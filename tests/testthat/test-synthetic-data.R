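test_that("simulated lattices have the expected grid structure", {
  expect_equal(nEdges(simulateGraph(9, "lattice")), 12L)   # 3x3: 2*3*2
  expect_equal(nEdges(simulateGraph(4, "lattice")), 4L)    # 2x2
  g1 <- simulateGraph(20, "random_geometric", seed = 3L)
  g2 <- simulateGraph(20, "random_geometric", seed = 3L)
  expect_identical(graphEdges(g1), graphEdges(g2))
  # geometric graphs are stitched to a single component
  expect_equal(max(componentLabels(icarPrecision(g1))), 1L)
  expect_error(simulateGraph(0), "positive")
})

test_that("BYM2 draws respect the mixing limits and constraints", {
  g <- simulateGraph(9, "lattice")
  ic <- icarPrecision(g)
  d0 <- simulateBYM2(g, tauS = 4, phi = 0, seed = 2L, icar = ic)
  expect_equal(d0$s, d0$v / 2)   # pure unstructured limit
  d1 <- simulateBYM2(g, tauS = 1, phi = 1, seed = 2L, icar = ic)
  expect_equal(d1$s, d1$u)
  expect_lt(abs(mean(d1$u)), 1e-8)  # per-component sum-to-zero (connected)
  expect_error(simulateBYM2(g, 1, 1.2), "phi")
})

test_that("phi = 0 draws have marginal variance 1/tau_s", {
  g <- simulateGraph(4, "lattice")
  ic <- icarPrecision(g)
  draws <- vapply(1:10000,
                  function(i) simulateBYM2(g, 2, 0, seed = i, icar = ic)$s[1L],
                  0)
  expect_equal(stats::var(draws), 1 / 2, tolerance = 0.05)
})

test_that("structured draws match the scaled generalized-inverse covariance", {
  g <- buildGraph(c("A", "B", "C"), cbind(c("A", "A", "B"), c("B", "C", "C")))
  ic <- icarPrecision(g)
  S <- vapply(1:20000,
              function(i) simulateBYM2(g, 1, 1, seed = i, icar = ic)$s,
              numeric(3))
  emp <- stats::cov(t(S))
  # oracle: dense generalized inverse rescaled by the K3 factor 2/9
  Gor <- MASS::ginv(as.matrix(icarQ(ic))) / (2 / 9)
  expect_equal(emp, Gor, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("temporal trend draws are centred random walks", {
  th <- simulateTemporalTrend(40, tauTheta = 1e12, seed = 1L)
  expect_true(all(abs(th) < 1e-4))
  th2 <- simulateTemporalTrend(25, tauTheta = 3, seed = 2L)
  expect_lt(abs(sum(th2)), 1e-10)
  diffs <- unlist(lapply(1:5000, function(i)
    diff(simulateTemporalTrend(10, tauTheta = 5, seed = i))))
  expect_equal(stats::var(diffs), 1 / 5, tolerance = 0.05)
  expect_error(simulateTemporalTrend(2, 1, order = 2), "at least")
})

test_that("interaction draws are centred and have the right variance", {
  d <- simulateInteraction(100, 100, tauDelta = 1e12, seed = 1L)
  expect_true(all(abs(d) < 1e-4))
  d2 <- simulateInteraction(100, 100, tauDelta = 4, seed = 3L)
  expect_equal(mean(d2), 0)
  expect_equal(stats::var(as.vector(d2)), 1 / 4, tolerance = 0.05)
})

test_that("panel simulation composes the generative model exactly", {
  # noise-free null: every effect degenerate, no covariate contribution
  cfgNull <- simulationConfig(
    nCountries = 9, years = 2000:2004, trueBeta = rep(0, 6),
    trueHyper = list(tauE = 1e12, tauS = 1e12, phi = 0.5, tauTheta = 1e12,
                     tauDelta = 1e12), alpha = 4.8, seed = 5)
  simNull <- simulatePanel(cfgNull)
  expect_true(all(abs(outcomeMatrix(simNull$panel) - 4.8) < 1e-4))

  # reconstruction: with tau_e huge, y equals the structural part exactly
  cfg <- simulationConfig(
    nCountries = 12, years = 2000:2007,
    trueHyper = list(tauE = 1e12, tauS = 5, phi = 0.5, tauTheta = 100,
                     tauDelta = 50), seed = 6)
  sim <- simulatePanel(cfg)
  tr <- sim$truth
  covs <- covariateMatrices(sim$panel)
  lp <- Reduce(`+`, Map(function(b, x) b * log(x), as.list(tr$betas), covs))
  recon <- tr$alpha + outer(tr$s, rep(1, 8)) + outer(rep(1, 12), tr$theta) +
    tr$delta + lp
  expect_true(all(abs(outcomeMatrix(sim$panel) - recon) < 1e-4))

  # determinism
  sim2 <- simulatePanel(cfg)
  expect_identical(outcomeMatrix(sim$panel), outcomeMatrix(sim2$panel))
  expect_identical(sim$truth, sim2$truth)

  # covariates strictly positive so the log transform is always defined
  expect_true(all(vapply(covs, function(m) all(m > 0), TRUE)))

  # validation errors carry the offending field
  expect_error(simulationConfig(nCountries = 0), "nCountries")
  expect_error(simulationConfig(trueHyper = list(tauE = -1, tauS = 1,
                                                 phi = 0.5, tauTheta = 1,
                                                 tauDelta = 1)), "trueHyper")
})

test_that("region-specific truth overrides the exposure coefficients", {
  cfg <- simulationConfig(
    nCountries = 10, years = 2000:2005, regionCount = 2,
    regionBetas = list(pwpm25 = c(0.2, -0.3), urbanpop = c(0.1, 0.1)),
    trueHyper = list(tauE = 1e12, tauS = 1e10, phi = 0.5, tauTheta = 1e10,
                     tauDelta = 1e10), seed = 9)
  sim <- simulatePanel(cfg)
  tr <- sim$truth
  covs <- covariateMatrices(sim$panel)
  b1 <- ifelse(tr$region == "R01", 0.2, -0.3)
  lp <- b1 * log(covs$pwpm25) + 0.1 * log(covs$urbanpop) +
    Reduce(`+`, Map(function(b, x) b * log(x),
                    as.list(tr$betas[3:6]), covs[3:6]))
  expect_true(all(abs(outcomeMatrix(sim$panel) - (tr$alpha + lp)) < 1e-3))
})

test_that("exposure grids tile the requested zones deterministically", {
  g <- simulateExposureGrids(1, c(2, 2), seed = 1)
  expect_true(all(g$zones == 1L))
  expect_true(all(g$pm > 0))
  expect_true(all(g$pop >= 0 & g$pop == round(g$pop)))

  g2 <- simulateExposureGrids(4, c(6, 5), seed = 2)
  expect_identical(g2, simulateExposureGrids(4, c(6, 5), seed = 2))
  expect_setequal(unique(as.vector(g2$zones)), 1:4)
  perZone <- tapply(as.vector(g2$pop), as.vector(g2$zones), sum)
  expect_equal(sum(perZone), sum(g2$pop))  # partition conserves population

  expect_error(simulateExposureGrids(10, c(3, 3)), "too small")
})
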