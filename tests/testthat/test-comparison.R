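test_that("DIC and WAIC match hand calculation on a small draw table", {
  # 3 draws x 2 observations with known mu per draw and fixed tau_e
  y <- c(1.0, 2.0)
  tauE <- 4
  mus <- rbind(c(0.8, 2.1), c(1.1, 1.9), c(1.0, 2.2))
  ll <- t(apply(mus, 1L, function(mu)
    stats::dnorm(y, mu, 1 / sqrt(tauE), log = TRUE)))
  ll <- rbind(ll, ll, ll, ll)            # >= 10 draws for the estimators
  mus4 <- mus[rep(1:3, 4L), ]
  muMean <- colMeans(mus4)
  fit <- handFit(y, ll, tauE, muMean)

  # hand-computed DIC (plug-in at posterior means of mu and tau_e)
  dBar <- mean(-2 * rowSums(ll))
  dHat <- -2 * sum(stats::dnorm(y, muMean, 1 / sqrt(tauE), log = TRUE))
  dic <- computeDIC(fit)
  expect_equal(dic$dic, dBar + (dBar - dHat), tolerance = 1e-10)
  expect_equal(dic$pD, dBar - dHat, tolerance = 1e-10)

  # hand-computed WAIC (log-mean-exp lpd, variance penalty)
  lpd <- log(colMeans(exp(ll)))
  pw <- apply(ll, 2L, stats::var)
  waic <- computeWAIC(fit)
  expect_equal(waic$waic, -2 * sum(lpd - pw), tolerance = 1e-10)
  expect_equal(waic$pWAIC, sum(pw), tolerance = 1e-10)
})

test_that("identical draws give zero effective parameters", {
  y <- c(0.5, 1.5, 2.5)
  ll1 <- stats::dnorm(y, 1.2, 1, log = TRUE)
  ll <- matrix(ll1, 12L, 3L, byrow = TRUE)
  fit <- handFit(y, ll, tauE = 1, muMean = rep(1.2, 3L))
  expect_equal(computeDIC(fit)$pD, 0, tolerance = 1e-10)
  expect_equal(computeDIC(fit)$dic, -2 * sum(ll1), tolerance = 1e-10)
  w <- computeWAIC(fit)
  expect_equal(w$pWAIC, 0, tolerance = 1e-10)
  expect_equal(w$waic, -2 * sum(ll1), tolerance = 1e-10)
})

test_that("WAIC is invariant to duplicating every draw", {
  set.seed(8)
  ll <- matrix(stats::rnorm(20 * 4, -1, 0.3), 20L, 4L)
  y <- stats::rnorm(4)
  f1 <- handFit(y, ll, 1, rep(0, 4L))
  f2 <- handFit(y, rbind(ll, ll), 1, rep(0, 4L))
  w1 <- computeWAIC(f1); w2 <- computeWAIC(f2)
  # lpd is unchanged; the variance penalty only changes by the n-1 divisor
  expect_equal(w1$waic, w2$waic, tolerance = 0.05)
  pwExact1 <- apply(ll, 2L, function(c) mean((c - mean(c))^2))
  pwExact2 <- apply(rbind(ll, ll), 2L,
                    function(c) mean((c - mean(c))^2))
  expect_equal(pwExact1, pwExact2, tolerance = 1e-12)
})

test_that("stable log-sum-exp agrees with direct computation when safe", {
  set.seed(9)
  ll <- matrix(stats::rnorm(40, -2, 0.5), 10L, 4L)
  expect_equal(stgap:::logMeanExpCols(ll), log(colMeans(exp(ll))),
               tolerance = 1e-12)
  # and survives scales that underflow naively
  llBig <- ll - 800
  expect_true(all(is.finite(stgap:::logMeanExpCols(llBig))))
  expect_equal(stgap:::logMeanExpCols(llBig), log(colMeans(exp(ll))) - 800,
               tolerance = 1e-12)
})

test_that("model ranking is ascending with stable ties and guarded inputs", {
  sc <- data.frame(model = c("a", "b"), dic = c(-90, -140), pD = c(3, 4),
                   waic = c(-100, -150), pWAIC = c(3, 4), nObs = c(50, 50))
  out <- compareModels(sc)
  expect_equal(out$model, c("b", "a"))
  expect_equal(out$dWAIC, c(0, 50))

  tie <- data.frame(model = c("x", "y"), dic = c(1, 1), pD = c(0, 0),
                    waic = c(5, 5), pWAIC = c(0, 0), nObs = c(10, 10))
  expect_equal(compareModels(tie)$model, c("x", "y"))

  bad <- data.frame(model = c("x", "y"), dic = c(1, 1), pD = c(0, 0),
                    waic = c(5, 5), pWAIC = c(0, 0), nObs = c(10, 12))
  expect_error(compareModels(bad), "different observation")
  expect_error(compareModels(sc[1, ]), "at least two")
})

test_that("effective-parameter estimates are non-negative on real fits", {
  f <- quickFit(nCountries = 9, years = 2000:2005, nIter = 250, nWarmup = 100)
  sc <- fitScore(f$fit)
  expect_gte(sc$pWAIC, 0)
  expect_true(is.finite(sc$dic) && is.finite(sc$waic))
  expect_equal(sc$nObs, 9L * 6L)
})
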