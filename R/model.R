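#' Create a model specification
#'
#' @param variant `"M0s"` (random effects only), `"M1s"` (adds the six global
#'   log-covariate coefficients) or `"M2s"` (pwPM2.5 and urbanization
#'   coefficients vary by region).
#' @param trendOrder random-walk order of the temporal trend (1 or 2).
#' @param effects random-effect terms to include; defaults to all of
#'   `"spatial"` (BYM2), `"temporal"` (random-walk trend) and `"interaction"`
#'   (exchangeable space-time term).  Dropping terms yields reduced models,
#'   e.g. a no-spatial variant for model comparison, or a pure fixed-effect
#'   model whose posterior is available in closed form.
#' @param logCovariates log-transform covariates (they enter as `ln x`).
#' @param logOutcome model `log(y)` instead of `y` (off by default; the
#'   observation model reads `y_it ~ Normal(mu_it, 1/tau_e)`).
#' @param priors named list: `alphaPrec` and `betaPrec` are Gaussian prior
#'   precisions for the intercept and coefficients (default `1e-6`, i.e.
#'   `Normal(0, 1000^2)`); `tauShape`, `tauRate` are the Gamma prior
#'   parameters shared by all precision hyperparameters (default
#'   `Gamma(1, 5e-5)`); the BYM2 mixing parameter has a `Uniform(0, 1)`
#'   prior.
#' @param fixedTauE if finite, hold the error precision fixed (used by the
#'   closed-form validation model).
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(variant = c("M1s", "M0s", "M2s"), trendOrder = 1L,
                      effects = c("spatial", "temporal", "interaction"),
                      logCovariates = TRUE, logOutcome = FALSE,
                      priors = list(), fixedTauE = NA_real_) {
  variant <- match.arg(variant)
  pr <- utils::modifyList(
    list(alphaPrec = 1e-6, betaPrec = 1e-6, tauShape = 1, tauRate = 5e-5),
    priors)
  new("ModelSpec", variant = variant, trendOrder = as.integer(trendOrder),
      effects = effects, logCovariates = logCovariates,
      logOutcome = logOutcome, priors = pr, fixedTauE = as.numeric(fixedTauE))
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@variant,
      sprintf("(RW%d trend; effects: %s)\n", object@trendOrder,
              paste(object@effects, collapse = "+")))
})

# random-walk penalty matrix of given order (improper prior precision of theta)
rwPenalty <- function(T, order = 1L) {
  D <- diff(diag(T), differences = order)
  forceSymmetric(Matrix(crossprod(D), sparse = TRUE))
}

#' Assemble the model state for a panel and graph
#'
#' Builds every design structure the sampler needs: the observation map from
#' the latent field `(alpha, beta, s, theta, delta)` to the observed cells,
#' the fixed-effect design (covariates log-transformed and centred; under
#' `"M2s"` the pwPM2.5 and urbanization columns are expanded into one column
#' per region), the eigendecomposition of the scaled structured BYM2
#' covariance, and the random-walk penalty.  Cells with a missing outcome but
#' complete covariates are tracked separately for imputation; cells with
#' missing covariates are excluded from the likelihood.
#'
#' @param panel a [GapPanel-class]; its country set must equal the graph's
#'   node set.
#' @param graph an [AdjacencyGraph-class].
#' @param spec a [ModelSpec-class].
#' @return a [GapModel-class].
#' @export
buildModel <- function(panel, graph, spec = modelSpec()) {
  stopifnot(is(panel, "GapPanel"), is(graph, "AdjacencyGraph"),
            is(spec, "ModelSpec"))
  countries <- countryIds(panel)
  years <- panelYears(panel)
  if (!setequal(countries, graphNodes(graph)))
    stop("panel country set and graph node set differ")
  # reorder graph nodes to panel order
  perm <- match(countries, graphNodes(graph))
  e <- graphEdges(graph)
  relabel <- match(seq_len(nNodes(graph)), perm)
  graph <- buildGraph(countries,
                      if (nrow(e)) matrix(countries[relabel[e]], ncol = 2L)
                      else NULL)
  n <- length(countries); T <- length(years); nT <- n * T
  region <- panelRegions(panel)
  if (spec@variant == "M2s" && is.null(region))
    stop("variant 'M2s' requires per-country region labels")
  y <- outcomeMatrix(panel)
  if (spec@logOutcome) {
    if (any(is.finite(y) & y <= 0))
      stop("log outcome requested but outcome has non-positive values")
    y <- log(y)
  }
  covs <- covariateMatrices(panel)
  p <- 0L; Xcols <- list()
  if (spec@variant %in% c("M1s", "M2s")) {
    missing <- setdiff(gapCovariateNames(), names(covs))
    if (length(missing))
      stop("variant '", spec@variant, "' needs covariates: ",
           paste(missing, collapse = ", "))
    covs <- covs[gapCovariateNames()]
    if (spec@logCovariates) {
      for (cv in names(covs)) {
        bad <- which(is.finite(covs[[cv]]) & covs[[cv]] <= 0, arr.ind = TRUE)
        if (nrow(bad))
          stop(sprintf(
            "covariate '%s' is non-positive for country %s, year %s; %s",
            cv, countries[bad[1L, 1L]], years[bad[1L, 2L]],
            "log transform undefined"))
        covs[[cv]] <- log(covs[[cv]])
      }
    }
  }
  covOk <- matrix(TRUE, n, T)
  if (length(covs) && spec@variant != "M0s")
    for (cv in gapCovariateNames()) covOk <- covOk & is.finite(covs[[cv]])
  obs <- which(is.finite(y) & covOk)          # column-major cell indices
  mis <- which(!is.finite(y) & covOk)
  if (!length(obs)) stop("no usable observations")
  obsI <- (obs - 1L) %% n + 1L
  obsT <- (obs - 1L) %/% n + 1L
  buildF <- function(cells, ci, ct) {
    if (spec@variant == "M0s") return(matrix(numeric(), length(cells), 0L))
    base <- vapply(gapCovariateNames(),
                   function(cv) covs[[cv]][cells], numeric(length(cells)))
    base <- matrix(base, ncol = 6L,
                   dimnames = list(NULL, gapCovariateNames()))
    base <- sweep(base, 2L, centers, "-")
    if (spec@variant == "M1s") return(base)
    regs <- sort(unique(region))
    Fm <- matrix(0, length(cells), 2L * length(regs) + 4L)
    cn <- character(ncol(Fm))
    k <- 0L
    for (cv in c("pwpm25", "urbanpop")) for (r in regs) {
      k <- k + 1L
      Fm[, k] <- base[, cv] * (region[ci] == r)
      cn[k] <- paste0(cv, ":", r)
    }
    for (cv in gapCovariateNames()[3:6]) {
      k <- k + 1L
      Fm[, k] <- base[, cv]
      cn[k] <- cv
    }
    colnames(Fm) <- cn
    Fm
  }
  centers <- if (spec@variant == "M0s") NULL else
    vapply(gapCovariateNames(), function(cv) mean(covs[[cv]][obs]), 0)
  Fobs <- buildF(obs, obsI, obsT)
  Fmis <- buildF(mis, (mis - 1L) %% n + 1L, (mis - 1L) %/% n + 1L)
  p <- ncol(Fobs)
  useS <- "spatial" %in% spec@effects
  useT <- "temporal" %in% spec@effects
  useD <- "interaction" %in% spec@effects
  off <- list(alpha = 1L, beta = if (p) 1L + seq_len(p) else integer())
  m <- 1L + p
  if (useS) { off$s <- m + seq_len(n); m <- m + n }
  if (useT) { off$theta <- m + seq_len(T); m <- m + T }
  if (useD) { off$delta <- m + seq_len(nT); m <- m + nT }
  designRows <- function(Fm, ci, ct, cells) {
    N <- length(cells)
    ii <- rep(seq_len(N), 1L + p + useS + useT + useD)
    jj <- rep(1L, N); xx <- rep(1, N)
    if (p) { jj <- c(jj, rep(off$beta, each = N)); xx <- c(xx, as.vector(Fm)) }
    if (useS) { jj <- c(jj, off$s[ci]); xx <- c(xx, rep(1, N)) }
    if (useT) { jj <- c(jj, off$theta[ct]); xx <- c(xx, rep(1, N)) }
    if (useD) { jj <- c(jj, off$delta[cells]); xx <- c(xx, rep(1, N)) }
    sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, m))
  }
  A <- designRows(Fobs, obsI, obsT, obs)
  Amis <- if (length(mis))
    designRows(Fmis, (mis - 1L) %% n + 1L, (mis - 1L) %/% n + 1L, mis)
  else NULL
  icar <- icarPrecision(graph)
  Egam <- NULL
  if (useS) {
    G <- scaledStructuredCovariance(icar)
    eg <- eigen(G, symmetric = TRUE)
    Egam <- list(E = eg$vectors, gamma = pmax(eg$values, 0))
  }
  design <- list(
    y = y[obs], A = A, AtA = forceSymmetric(crossprod(A)),
    Aty = drop(as.matrix(crossprod(A, y[obs]))),
    F = Fobs, obs = obs, obsI = obsI, obsT = obsT, mis = mis, Amis = Amis,
    E = Egam$E, gamma = Egam$gamma, icar = icar,
    RT = if (useT) rwPenalty(T, spec@trendOrder) else NULL,
    layout = list(m = m, p = p, n = n, T = T, nT = nT, off = off,
                  useS = useS, useT = useT, useD = useD),
    betaNames = colnames(Fobs), centers = centers)
  new("GapModel", spec = spec, graph = graph, countries = countries,
      years = years, region = if (is.null(region)) character() else region,
      design = design)
}

setMethod("show", "GapModel", function(object) {
  d <- object@design$layout
  cat("GapModel:", object@spec@variant, "-", length(object@countries),
      "countries x", length(object@years), "years;",
      length(object@design$y), "observed cells; latent dimension", d$m, "\n")
})

#' @describeIn buildModel total latent-field dimension of a built model.
#' @param model a `GapModel`.
#' @export
latentDimension <- function(model) model@design$layout$m

#' Fit a spatiotemporal gap model by MCMC
#'
#' Metropolis-within-Gibbs over the latent Gaussian field and its
#' hyperparameters:
#' \enumerate{
#'   \item a joint Gaussian update of `(alpha, beta, s, theta, delta)` by a
#'     sparse Cholesky solve of the full conditional, followed by exact
#'     projection onto the sum-to-zero constraints (`sum(theta) = 0`,
#'     `sum(delta) = 0`; the structured spatial part is sum-to-zero per
#'     component by construction);
#'   \item conjugate Gamma updates for `tau_e`, `tau_theta`, `tau_delta` and
#'     the BYM2 marginal precision `tau_s`;
#'   \item an adaptive Metropolis update for the BYM2 mixing parameter `phi`
#'     on the logit scale, tuned during warm-up towards a 30-45% acceptance
#'     rate;
#'   \item predictive imputation of missing outcomes each sweep.
#' }
#' Pointwise Gaussian log-likelihood terms are recorded for every kept draw,
#' so WAIC and DIC can be computed afterwards.  When the model includes the
#' exchangeable interaction, that cell-level effect is integrated out of the
#' recorded density analytically (variance `1/tau_e + 1/tau_delta`): the two
#' terms are exchangeable iid cell effects in the likelihood, so only their
#' variance total is identified, and marginalizing keeps the information
#' criteria invariant to the arbitrary split between them.  The structured/unstructured
#' decomposition `(u, v)` of the BYM2 effect is drawn from its exact
#' conditional per kept draw.
#'
#' @param model a [GapModel-class] from [buildModel()].
#' @param nIter iterations per chain (including warm-up).
#' @param nWarmup warm-up iterations discarded per chain.
#' @param nChains number of independent chains.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param thin keep every `thin`-th post-warm-up draw.
#' @param rhatWarn warn when split-chain potential scale reduction of the
#'   intercept, coefficients or hyperparameters exceeds this threshold.
#' @return a [GapFit-class].
#' @export
fitMCMC <- function(model, nIter = 5000L, nWarmup = 2000L, nChains = 2L,
                    seed = 42L, thin = 1L, rhatWarn = 1.05) {
  stopifnot(is(model, "GapModel"))
  if (nWarmup < 0 || nIter <= nWarmup)
    stop("need nIter > nWarmup >= 0")
  d <- model@design; L <- d$layout; pr <- model@spec@priors
  n <- L$n; T <- L$T; nT <- L$nT; p <- L$p; m <- L$m
  N <- length(d$y)
  fixedTauE <- model@spec@fixedTauE
  aTau <- pr$tauShape; bTau <- pr$tauRate
  rwRank <- if (L$useT) T - model@spec@trendOrder else 0L
  # constraint matrix (columns = constraints) for conditioning by kriging
  Ct <- NULL
  if (L$useT || L$useD) {
    cols <- list()
    if (L$useT) cols$theta <- L$off$theta
    if (L$useD) cols$delta <- L$off$delta
    Ct <- sparseMatrix(i = unlist(cols),
                       j = rep(seq_along(cols), lengths(cols)),
                       x = 1, dims = c(m, length(cols)))
  }
  priorFixed <- c(pr$alphaPrec, rep(pr$betaPrec, p))
  ## fixed sparsity pattern of the posterior precision: prior blocks + AtA.
  ## values are rewritten in place each sweep, so no per-iteration assembly.
  symm <- function(i, j, x) {
    keep <- i <= j
    sparseMatrix(i = i[keep], j = j[keep], x = x[keep], dims = c(m, m),
                 symmetric = TRUE)
  }
  comps <- list(fix = symm(seq_len(1L + p), seq_len(1L + p),
                           pmax(priorFixed, 1e-300)))
  if (L$useS) {
    ij <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
    comps$s <- symm(L$off$s[ij[, 1L]], L$off$s[ij[, 2L]],
                    rep(1, nrow(ij)))
    sLocal <- ij   # local (row, col) of each s-block entry, in pattern order
  }
  if (L$useT) {
    rt <- as(as(d$RT, "generalMatrix"), "TsparseMatrix")
    comps$rt <- symm(L$off$theta[rt@i + 1L], L$off$theta[rt@j + 1L], rt@x)
  }
  if (L$useD) comps$del <- symm(L$off$delta, L$off$delta, rep(1, nT))
  comps$ata <- forceSymmetric(d$AtA)
  Qtemplate <- Reduce(`+`, comps)
  patKey <- function(M) {
    M <- as(M, "CsparseMatrix")
    list(key = rep(seq_len(m), diff(M@p)) * as.numeric(m) + M@i,
         x = M@x)
  }
  tKey <- patKey(Qtemplate)
  maps <- lapply(comps, function(M) {
    k <- patKey(M)
    list(idx = match(k$key, tKey$key), x0 = k$x)
  })
  if (L$useS) {
    # entry order of the s block within comps$s (column-major upper triangle)
    sOrd <- order(sLocal[, 2L], sLocal[, 1L])
    sRow <- sLocal[sOrd, 1L]; sCol <- sLocal[sOrd, 2L]
  }
  nnzQ <- length(Qtemplate@x)
  tDiagIdx <- which(rep(seq_len(m), diff(Qtemplate@p)) == Qtemplate@i + 1L)
  nKeep <- length(seq.int(nWarmup + 1L, nIter, by = thin))
  chains <- vector("list", nChains)
  accAll <- numeric(nChains)
  for (ch in seq_len(nChains)) {
    set.seed(seed + ch - 1L)
    tauE <- if (is.finite(fixedTauE)) fixedTauE else
      1 / max(stats::var(d$y), 1e-8)
    tauS <- 1; phi <- 0.5; tauTheta <- 100; tauDelta <- 100
    lstep <- 0; accN <- 0L; accDen <- 0L
    keep <- list(alpha = numeric(nKeep),
                 beta = matrix(0, nKeep, p),
                 s = matrix(0, nKeep, n), theta = matrix(0, nKeep, T),
                 delta = if (L$useD) matrix(0, nKeep, nT) else matrix(0, nKeep, 0L),
                 hyper = matrix(0, nKeep, 5L,
                                dimnames = list(NULL, c("tau_e", "tau_s", "phi",
                                                        "tau_theta", "tau_delta"))),
                 ll = matrix(0, nKeep, N),
                 ymis = matrix(0, nKeep, length(d$mis)))
    muSum <- numeric(N); krow <- 0L
    w <- phi * d$gamma + (1 - phi)   # BYM2 covariance eigenvalues at phi
    for (it in seq_len(nIter)) {
      ## (i) joint Gaussian update of the latent field
      qx <- numeric(nnzQ)
      qx[maps$fix$idx] <- maps$fix$x0
      if (L$useS) {
        Pphi <- d$E %*% (t(d$E) * (1 / w))
        Pphi <- (Pphi + t(Pphi)) / 2
        qx[maps$s$idx] <- qx[maps$s$idx] + tauS * Pphi[cbind(sRow, sCol)]
      }
      if (L$useT) qx[maps$rt$idx] <- qx[maps$rt$idx] + tauTheta * maps$rt$x0
      if (L$useD) qx[maps$del$idx] <- qx[maps$del$idx] + tauDelta
      qx[maps$ata$idx] <- qx[maps$ata$idx] + tauE * maps$ata$x0
      Q <- Qtemplate; Q@x <- qx
      chQ <- tryCatch(Cholesky(Q, LDL = FALSE, perm = TRUE),
                      error = function(e) NULL)
      if (is.null(chQ)) {
        # ill-conditioned state (e.g. extreme hyperparameter draw): retry
        # with a tiny ridge before giving up with diagnostics
        qx[tDiagIdx] <- qx[tDiagIdx] * (1 + 1e-8) + 1e-10 * max(qx)
        Q@x <- qx
        chQ <- tryCatch(Cholesky(Q, LDL = FALSE, perm = TRUE),
                        error = function(e)
                          stop("latent-field solve failed at iteration ", it,
                               " (tau_e=", signif(tauE, 4), ", tau_s=",
                               signif(tauS, 4), ", phi=", signif(phi, 4),
                               "): ", conditionMessage(e), call. = FALSE))
      }
      b <- tauE * d$Aty
      mu <- drop(as.matrix(solve(chQ, b)))
      z <- stats::rnorm(m)
      x <- mu + drop(as.matrix(solve(chQ, solve(chQ, z, system = "Lt"),
                                     system = "Pt")))
      if (!is.null(Ct)) {
        W <- as.matrix(solve(chQ, Ct))
        S <- as.matrix(crossprod(Ct, W))
        x <- x - drop(W %*% solve(S, drop(crossprod(Ct, x))))
      }
      alpha <- x[1L]
      beta <- if (p) x[L$off$beta] else numeric()
      s <- if (L$useS) x[L$off$s] else numeric(n)
      theta <- if (L$useT) x[L$off$theta] else numeric(T)
      delta <- if (L$useD) x[L$off$delta] else numeric(0L)
      muObs <- drop(as.matrix(d$A %*% x))
      resid <- d$y - muObs
      ## (ii) conjugate gamma updates
      if (!is.finite(fixedTauE))
        tauE <- stats::rgamma(1L, aTau + N / 2, rate = bTau + sum(resid^2) / 2)
      if (L$useT) {
        qTh <- drop(theta %*% as.matrix(d$RT %*% theta))
        tauTheta <- stats::rgamma(1L, aTau + rwRank / 2, rate = bTau + qTh / 2)
      }
      if (L$useD)
        tauDelta <- stats::rgamma(1L, aTau + (nT - 1) / 2,
                                  rate = bTau + sum(delta^2) / 2)
      if (L$useS) {
        st <- drop(crossprod(d$E, s))
        qS <- sum(st^2 / w)
        tauS <- stats::rgamma(1L, aTau + n / 2, rate = bTau + qS / 2)
        ## (iii) Metropolis update of phi on the logit scale
        lphi <- stats::qlogis(phi)
        ## support truncated to logit(phi) in [-9.2, 9.2]: at phi -> 1 the
        ## BYM2 prior precision grows like 1/(1-phi) and destroys
        ## conditioning; proposals outside are rejected
        lprop <- lphi + exp(lstep) * stats::rnorm(1L)
        phiProp <- stats::plogis(lprop)
        wProp <- phiProp * d$gamma + (1 - phiProp)
        logTarget <- function(wv, ph)
          -0.5 * sum(log(wv)) - tauS / 2 * sum(st^2 / wv) +
            log(ph) + log1p(-ph)
        logA <- if (abs(lprop) > 9.2) -Inf else
          logTarget(wProp, phiProp) - logTarget(w, phi)
        accDen <- accDen + 1L
        if (is.finite(logA) && log(stats::runif(1L)) < logA) {
          phi <- phiProp; w <- wProp; accN <- accN + 1L
        }
        if (it <= nWarmup) {
          accProb <- if (is.finite(logA)) min(1, exp(logA)) else 0
          lstep <- lstep + (accProb - 0.375) / it^0.6
        }
      }
      ## record
      if (it > nWarmup && (it - nWarmup - 1L) %% thin == 0L) {
        krow <- krow + 1L
        keep$alpha[krow] <- alpha
        if (p) keep$beta[krow, ] <- beta
        keep$s[krow, ] <- s
        keep$theta[krow, ] <- theta
        if (L$useD) keep$delta[krow, ] <- delta
        keep$hyper[krow, ] <- c(tauE, tauS, phi, tauTheta, tauDelta)
        ## pointwise log-likelihood for WAIC/DIC.  The exchangeable
        ## interaction is an iid cell-level Gaussian, exchangeable with the
        ## observation error in the likelihood: only 1/tau_e + 1/tau_delta is
        ## identified.  It is therefore integrated out analytically, making
        ## the recorded density depend only on identified quantities.
        if (L$useD) {
          muMarg <- muObs - delta[d$obs]
          keep$ll[krow, ] <- stats::dnorm(d$y, muMarg,
                                          sqrt(1 / tauE + 1 / tauDelta),
                                          log = TRUE)
          muSum <- muSum + muMarg
        } else {
          keep$ll[krow, ] <- stats::dnorm(d$y, muObs, 1 / sqrt(tauE),
                                          log = TRUE)
          muSum <- muSum + muObs
        }
        ## predictive imputation of cells with missing outcome
        if (length(d$mis))
          keep$ymis[krow, ] <- drop(as.matrix(d$Amis %*% x)) +
            stats::rnorm(length(d$mis), sd = 1 / sqrt(tauE))
      }
    }
    keep$muSum <- muSum
    keep$acc <- if (accDen) accN / accDen else NA_real_
    chains[[ch]] <- keep
    accAll[ch] <- keep$acc
  }
  draws <- list(
    alpha = unlist(lapply(chains, `[[`, "alpha")),
    beta = do.call(rbind, lapply(chains, `[[`, "beta")),
    s = do.call(rbind, lapply(chains, `[[`, "s")),
    theta = do.call(rbind, lapply(chains, `[[`, "theta")),
    delta = do.call(rbind, lapply(chains, `[[`, "delta")),
    ymis = do.call(rbind, lapply(chains, `[[`, "ymis")),
    hyper = do.call(rbind, lapply(chains, `[[`, "hyper")))
  colnames(draws$beta) <- d$betaNames
  ll <- do.call(rbind, lapply(chains, `[[`, "ll"))
  muMean <- Reduce(`+`, lapply(chains, `[[`, "muSum")) / (nKeep * nChains)
  ## exact conditional draw of the structured/unstructured split (u, v)
  K <- length(draws$alpha)
  draws$u <- matrix(0, K, n); draws$v <- matrix(0, K, n)
  if (L$useS) {
    stAll <- draws$s %*% d$E
    for (j in seq_len(K)) {
      tauSj <- draws$hyper[j, "tau_s"]; phij <- draws$hyper[j, "phi"]
      a <- sqrt(phij / tauSj); c2 <- (1 - phij) / tauSj
      denom <- a^2 * d$gamma + c2
      ut <- a * d$gamma * stAll[j, ] / denom +
        sqrt(d$gamma * c2 / denom) * stats::rnorm(n)
      u <- drop(d$E %*% ut)
      draws$u[j, ] <- u
      draws$v[j, ] <- (draws$s[j, ] - a * u) / sqrt(c2)
    }
  }
  rhat <- splitRhat(chains, p)
  meta <- list(seed = seed, nChains = nChains, nIter = nIter,
               nWarmup = nWarmup, thin = thin, keptPerChain = nKeep,
               acceptanceRate = accAll, rhat = rhat,
               priors = pr, fixedTauE = fixedTauE)
  if (any(is.finite(rhat) & rhat > rhatWarn))
    warning("split-chain Rhat above ", rhatWarn, " for: ",
            paste(names(rhat)[is.finite(rhat) & rhat > rhatWarn],
                  collapse = ", "), call. = FALSE)
  new("GapFit", model = model, draws = draws, pointwiseLogLik = ll,
      muMean = muMean, meta = meta)
}

# split-chain potential scale reduction for scalar summaries
splitRhat <- function(chains, p) {
  pull <- function(getter) {
    halves <- list()
    for (ch in chains) {
      v <- getter(ch)
      h <- length(v) %/% 2L
      if (h < 2L) return(NA_real_)
      halves <- c(halves, list(v[seq_len(h)], v[h + seq_len(h)]))
    }
    mns <- vapply(halves, mean, 0); vrs <- vapply(halves, stats::var, 0)
    nh <- length(halves[[1L]])
    B <- nh * stats::var(mns); W <- mean(vrs)
    if (W <= 0) return(1)
    sqrt(((nh - 1) / nh * W + B / nh) / W)
  }
  out <- c(alpha = pull(function(ch) ch$alpha))
  if (p)
    for (k in seq_len(p))
      out[paste0("beta.", k)] <- pull(function(ch) ch$beta[, k])
  for (h in colnames(chains[[1L]]$hyper))
    out[h] <- pull(function(ch) ch$hyper[, h])
  out
}

setMethod("show", "GapFit", function(object) {
  K <- length(object@draws$alpha)
  cat("GapFit:", object@model@spec@variant, "-", K, "draws (",
      object@meta$nChains, "chain(s) x", object@meta$keptPerChain, ")\n")
  cat("  phi acceptance rate:",
      paste(signif(object@meta$acceptanceRate, 3), collapse = ", "), "\n")
  rh <- object@meta$rhat
  cat("  max split-chain Rhat:", signif(max(rh[is.finite(rh)], 1), 4), "\n")
})

#' @describeIn fitMCMC number of kept posterior draws in a fit.
#' @param fit a `GapFit`.
#' @export
nDraws <- function(fit) length(fit@draws$alpha)
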