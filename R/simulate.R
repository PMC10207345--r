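#' Simulate a spatial adjacency graph
#'
#' Stand-in geographies for the country map: a trimmed square lattice
#' (connected by construction) or a random geometric graph on the unit square
#' (patched to be connected by linking nearest points across components).
#'
#' @param n number of nodes (countries).
#' @param kind `"lattice"` or `"random_geometric"`.
#' @param seed integer RNG seed; the result is deterministic given
#'   `(n, kind, seed)`.
#' @return an [AdjacencyGraph-class] with nodes `C001, C002, ...`.
#' @examples
#' nEdges(simulateGraph(9, "lattice"))  # 3x3 grid: 12 edges
#' @export
simulateGraph <- function(n, kind = c("lattice", "random_geometric"),
                          seed = 1L) {
  kind <- match.arg(kind)
  if (n < 1) stop("'n' must be a positive integer")
  nodes <- sprintf("C%03d", seq_len(n))
  if (kind == "lattice") {
    nr <- max(1L, floor(sqrt(n)))
    nc <- ceiling(n / nr)
    cellRow <- (seq_len(n) - 1L) %/% nc + 1L
    cellCol <- (seq_len(n) - 1L) %% nc + 1L
    right <- which(cellCol < nc & seq_len(n) + 1L <= n)
    down <- which(seq_len(n) + nc <= n)
    em <- rbind(cbind(right, right + 1L), cbind(down, down + nc))
    return(buildGraph(nodes, matrix(nodes[em], ncol = 2L)))
  }
  set.seed(seed)
  xy <- cbind(stats::runif(n), stats::runif(n))
  r <- sqrt(2.2 / max(n, 2))
  d <- as.matrix(stats::dist(xy))
  adj <- d <= r & upper.tri(d)
  em <- which(adj, arr.ind = TRUE)
  g <- buildGraph(nodes, matrix(nodes[em], ncol = 2L))
  # stitch components together through their closest node pairs
  repeat {
    comp <- componentLabels(icarPrecision(g))
    if (max(comp) == 1L || n == 1L) break
    other <- comp != comp[1L]
    dsub <- d[!other, other, drop = FALSE]
    ij <- which(dsub == min(dsub), arr.ind = TRUE)[1L, ]
    a <- which(!other)[ij[1L]]; b <- which(other)[ij[2L]]
    g <- buildGraph(nodes, rbind(matrix(nodes[graphEdges(g)], ncol = 2L),
                                 c(nodes[a], nodes[b])))
  }
  g
}

#' Simulate a BYM2 spatial effect
#'
#' Draws `s = (sqrt(phi) * u + sqrt(1 - phi) * v) / sqrt(tauS)` where `u` is
#' the scaled structured (ICAR) component — drawn from the sum-to-zero
#' constrained generalized inverse of the ICAR precision, rescaled so its
#' geometric-mean marginal variance is 1 — and `v` is i.i.d. standard normal.
#' Under this scaling the marginal variance of `s` is approximately
#' `1 / tauS`, apportioned by the mixing parameter `phi`.
#'
#' @param graph an [AdjacencyGraph-class].
#' @param tauS marginal precision (> 0).
#' @param phi mixing parameter in `[0, 1]` (share of structured variance).
#' @param seed integer RNG seed.
#' @param icar optionally, a precomputed [icarPrecision()] of `graph`.
#' @return list with numeric vectors `s`, `u`, `v` (per node).
#' @export
simulateBYM2 <- function(graph, tauS, phi, seed = 1L, icar = NULL) {
  if (phi < 0 || phi > 1) stop("'phi' must lie in [0, 1]")
  if (tauS <= 0) stop("'tauS' must be positive")
  if (is.null(icar)) icar <- icarPrecision(graph)
  G <- scaledStructuredCovariance(icar)
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  set.seed(seed)
  u <- drop(eg$vectors %*% (sqrt(lam) * stats::rnorm(length(lam))))
  v <- stats::rnorm(nNodes(graph))
  s <- (sqrt(phi) * u + sqrt(1 - phi) * v) / sqrt(tauS)
  list(s = s, u = u, v = v)
}

#' Simulate the overall temporal trend
#'
#' A random walk of order 1 (default) or 2 with increment precision
#' `tauTheta`, centred to sum to zero over the study years (the constraint
#' under which the trend is identified next to the intercept).
#'
#' @param nYears number of years `T` (at least `order + 1`).
#' @param tauTheta precision of the random-walk increments.
#' @param order random-walk order, 1 or 2.
#' @param seed integer RNG seed.
#' @return numeric vector of length `nYears` summing to zero.
#' @export
simulateTemporalTrend <- function(nYears, tauTheta, order = 1L, seed = 1L) {
  if (!order %in% c(1L, 2L)) stop("'order' must be 1 or 2")
  if (nYears < order + 1L) stop("'nYears' must be at least order + 1")
  if (tauTheta <= 0) stop("'tauTheta' must be positive")
  set.seed(seed)
  z <- stats::rnorm(nYears - order, sd = 1 / sqrt(tauTheta))
  theta <- if (order == 1L) cumsum(c(0, z)) else cumsum(cumsum(c(0, 0, z)))
  theta - mean(theta)
}

#' Simulate the space-time interaction
#'
#' Exchangeable (Type I) interaction: i.i.d. `Normal(0, 1/tauDelta)` entries,
#' centred to overall zero mean.
#'
#' @param n number of countries; @param nYears number of years.
#' @param tauDelta interaction precision.
#' @param seed integer RNG seed.
#' @return `n x nYears` numeric matrix with overall mean zero.
#' @export
simulateInteraction <- function(n, nYears, tauDelta, seed = 1L) {
  if (n < 1 || nYears < 1) stop("'n' and 'nYears' must be positive")
  if (tauDelta <= 0) stop("'tauDelta' must be positive")
  set.seed(seed)
  d <- matrix(stats::rnorm(n * nYears, sd = 1 / sqrt(tauDelta)), n, nYears)
  d - mean(d)
}

whoRegionNames <- function(k) {
  who <- c("Africa", "Americas", "EasternMediterranean", "Europe",
           "SouthEastAsia", "WesternPacific")
  if (k == 6L) who else sprintf("R%02d", seq_len(k))
}

#' Simulation configuration
#'
#' Bundles and validates the ground truth of a synthetic country-by-year
#' panel.  Defaults emulate the study conditions of the global gender-gap
#' analysis: a 1960-2018 panel, fixed-effect coefficients with the
#' sign/magnitude pattern of the global fit
#' (`beta = (0.034, 0.251, -0.012, -0.061, 0.419, 0.076)` on the log-covariate
#' scale), and hyperparameters `tau_e = 150`, `tau_s = 5`, `phi = 0.5`,
#' `tau_theta = 2e4`, `tau_delta = 180`.
#'
#' @param nCountries number of countries.
#' @param years integer year range (default `1960:2018`); must span >= 3.
#' @param graphKind `"lattice"` or `"random_geometric"`.
#' @param trueBeta numeric length-6 vector of fixed-effect coefficients in the
#'   order of [gapCovariateNames()].
#' @param regionBetas optional list with numeric per-region vectors `pwpm25`
#'   and `urbanpop` (length `regionCount`) overriding the first two
#'   coefficients region by region (region-specific-coefficient truth).
#' @param trueHyper named list `tauE`, `tauS`, `phi`, `tauTheta`, `tauDelta`.
#' @param regionCount number of regions partitioning the countries (default 6,
#'   labelled with the WHO region names).
#' @param alpha intercept (overall outcome level before covariates).
#' @param covariateMeanlog,covariateSdlog length-6 log-normal parameters of the
#'   strictly positive covariates.
#' @param covariateCor common-factor correlation in `[0, 1)` inducing mild
#'   positive cross-correlation between log covariates (0 = independent).
#' @param missingRate MCAR missingness rate applied to the outcome.
#' @param trendOrder random-walk order of the simulated trend.
#' @param seed integer RNG seed.
#' @return validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nCountries = 60L,
                             years = 1960:2018,
                             graphKind = c("lattice", "random_geometric"),
                             trueBeta = c(0.034, 0.251, -0.012, -0.061,
                                          0.419, 0.076),
                             regionBetas = NULL,
                             trueHyper = list(tauE = 150, tauS = 5, phi = 0.5,
                                              tauTheta = 2e4, tauDelta = 180),
                             regionCount = 6L,
                             alpha = -3.0,
                             covariateMeanlog = log(c(25, 50, 10, 45, 2800, 150)),
                             covariateSdlog = c(0.5, 0.3, 0.8, 0.3, 0.15, 0.5),
                             covariateCor = 0,
                             missingRate = 0,
                             trendOrder = 1L,
                             seed = 1L) {
  graphKind <- match.arg(graphKind)
  if (nCountries < 1) stop("invalid 'nCountries'")
  if (length(years) < 3) stop("invalid 'years': span must be at least 3")
  if (length(trueBeta) != 6) stop("invalid 'trueBeta': need 6 coefficients")
  hy <- trueHyper
  need <- c("tauE", "tauS", "phi", "tauTheta", "tauDelta")
  if (!all(need %in% names(hy))) stop("invalid 'trueHyper': need ", paste(need, collapse = ", "))
  prec <- unlist(hy[c("tauE", "tauS", "tauTheta", "tauDelta")])
  if (any(prec <= 0)) stop("invalid 'trueHyper': precisions must be positive")
  if (hy$phi < 0 || hy$phi > 1) stop("invalid 'trueHyper': phi must be in [0, 1]")
  if (regionCount < 1 || regionCount > nCountries) stop("invalid 'regionCount'")
  if (!is.null(regionBetas)) {
    if (!all(c("pwpm25", "urbanpop") %in% names(regionBetas)))
      stop("invalid 'regionBetas': need vectors 'pwpm25' and 'urbanpop'")
    if (any(lengths(regionBetas[c("pwpm25", "urbanpop")]) != regionCount))
      stop("invalid 'regionBetas': need one coefficient per region")
  }
  if (length(covariateMeanlog) != 6 || length(covariateSdlog) != 6)
    stop("invalid covariate log-normal parameters: need length 6")
  if (covariateCor < 0 || covariateCor >= 1) stop("invalid 'covariateCor'")
  if (missingRate < 0 || missingRate >= 1) stop("invalid 'missingRate'")
  structure(list(nCountries = as.integer(nCountries), years = as.integer(years),
                 graphKind = graphKind, trueBeta = trueBeta,
                 regionBetas = regionBetas, trueHyper = hy,
                 regionCount = as.integer(regionCount), alpha = alpha,
                 covariateMeanlog = covariateMeanlog,
                 covariateSdlog = covariateSdlog, covariateCor = covariateCor,
                 missingRate = missingRate, trendOrder = as.integer(trendOrder),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a country-by-year panel with known ground truth
#'
#' Composes the generative model: strictly positive log-normal covariates,
#' BYM2 spatial effect on a simulated graph, random-walk temporal trend,
#' exchangeable space-time interaction, and Gaussian observation noise:
#' `y_it = alpha + s_i + theta_t + delta_it + sum_k beta_k * ln(x_k,it) + e_it`.
#' When `regionBetas` is set, the pwPM2.5 and urbanization coefficients vary
#' by region (the region-specific-coefficient structure).
#'
#' @param config a [simulationConfig()].
#' @return list with elements `panel` (a [GapPanel-class] carrying region
#'   labels), `graph` (the [AdjacencyGraph-class]), and `truth` (list of
#'   `alpha`, `s`, `u`, `v`, `theta`, `delta`, `betas`, `regionBetas`,
#'   `hyper`, `region`).  The truth is also stored in
#'   `S4Vectors::metadata(panel)$truth`.
#' @examples
#' sim <- simulatePanel(simulationConfig(nCountries = 9, years = 2000:2004))
#' sim$panel
#' @export
simulatePanel <- function(config = simulationConfig()) {
  if (!inherits(config, "SimulationConfig"))
    config <- do.call(simulationConfig, config)
  n <- config$nCountries; yrs <- config$years; T <- length(yrs)
  hy <- config$trueHyper
  graph <- simulateGraph(n, config$graphKind, seed = config$seed)
  icar <- icarPrecision(graph)
  sp <- simulateBYM2(graph, hy$tauS, hy$phi, seed = config$seed + 1L,
                     icar = icar)
  theta <- simulateTemporalTrend(T, hy$tauTheta, order = config$trendOrder,
                                 seed = config$seed + 2L)
  delta <- simulateInteraction(n, T, hy$tauDelta, seed = config$seed + 3L)
  # contiguous blocks of roughly equal size, in node order
  region <- whoRegionNames(config$regionCount)[
    ceiling(seq_len(n) / (n / config$regionCount))]
  set.seed(config$seed + 4L)
  covs <- list()
  common <- matrix(stats::rnorm(n * T), n, T)
  rho <- config$covariateCor
  for (k in seq_len(6)) {
    z <- sqrt(rho) * common + sqrt(1 - rho) * matrix(stats::rnorm(n * T), n, T)
    covs[[gapCovariateNames()[k]]] <-
      exp(config$covariateMeanlog[k] + config$covariateSdlog[k] * z)
  }
  beta <- config$trueBeta
  lp <- matrix(0, n, T)
  for (k in seq_len(6)) {
    bk <- matrix(beta[k], n, T)
    if (k <= 2 && !is.null(config$regionBetas)) {
      key <- gapCovariateNames()[k]
      bk <- matrix(config$regionBetas[[key]][match(region, whoRegionNames(config$regionCount))],
                   n, T)
    }
    lp <- lp + bk * log(covs[[k]])
  }
  y <- config$alpha + outer(sp$s, rep(1, T)) + outer(rep(1, n), theta) +
    delta + lp + matrix(stats::rnorm(n * T, sd = 1 / sqrt(hy$tauE)), n, T)
  if (config$missingRate > 0)
    y[matrix(stats::runif(n * T) < config$missingRate, n, T)] <- NA
  panel <- GapPanel(y, graphNodes(graph), yrs, covariates = covs,
                    region = region)
  truth <- list(alpha = config$alpha, s = sp$s, u = sp$u, v = sp$v,
                theta = theta, delta = delta, betas = beta,
                regionBetas = config$regionBetas, hyper = hy, region = region)
  metadata(panel)$truth <- truth
  list(panel = panel, graph = graph, truth = truth)
}

#' Simulate exposure grids
#'
#' Plain-matrix fixtures for the population-weighted exposure statistic: a
#' positive pollutant concentration grid, a non-negative integer population
#' grid, and a zone-id grid tiling the cells into `nZones` contiguous
#' (row-major) zones.
#'
#' @param nZones number of zones; every zone receives at least one cell.
#' @param gridShape integer `(rows, cols)`.
#' @param seed integer RNG seed.
#' @return list of matrices `pm`, `pop`, `zones` (integer zone ids).
#' @export
simulateExposureGrids <- function(nZones, gridShape = c(10L, 10L), seed = 1L) {
  nr <- gridShape[1L]; nc <- gridShape[2L]
  if (nr * nc < nZones) stop("grid too small: fewer cells than zones")
  if (nZones < 1) stop("'nZones' must be positive")
  set.seed(seed)
  pm <- matrix(stats::rlnorm(nr * nc, log(20), 0.6), nr, nc)
  pop <- matrix(stats::rpois(nr * nc, 120), nr, nc)
  zones <- matrix(sort(rep_len(seq_len(nZones), nr * nc)), nr, nc, byrow = TRUE)
  list(pm = pm, pop = pop, zones = zones)
}
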