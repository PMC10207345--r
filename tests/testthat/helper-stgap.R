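# shared fixtures and independent oracles (built in code, no stored data)

# random sparse graph, possibly with isolated nodes
randomGraph <- function(n, pEdge = 0.15, seed = 1L) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < pEdge
  buildGraph(nodes, matrix(nodes[pairs[keep, , drop = FALSE]], ncol = 2L))
}

# independent oracle for the constrained generalized inverse: MASS::ginv on
# the dense component matrix (its null space is the component constant)
ginvDiagOracle <- function(Qdense) diag(MASS::ginv(Qdense))

# per-component BYM2 scaling factors via the MASS::ginv oracle
kappaOracle <- function(graph) {
  ic <- icarPrecision(graph)
  comp <- componentLabels(ic)
  Q <- as.matrix(icarQ(ic))
  vapply(seq_len(max(comp)), function(k) {
    idx <- which(comp == k)
    if (length(idx) < 2L) return(1)
    exp(mean(log(ginvDiagOracle(Q[idx, idx, drop = FALSE]))))
  }, numeric(1))
}

# tiny panel with explicit values, no covariates
tinyPanel <- function(n = 3L, T = 4L, y = NULL, region = NULL) {
  if (is.null(y)) y <- matrix(seq_len(n * T), n, T)
  GapPanel(y, sprintf("C%03d", seq_len(n)), 2000L + seq_len(T) - 1L,
           region = region)
}

# hand-assembled GapFit over a real (degenerate) model, for testing the
# summary and information-criterion arithmetic on known draw tables
handFit <- function(y, ll, tauE, muMean, extraDraws = list()) {
  n <- length(y)
  panel <- GapPanel(matrix(y, n, 1L), sprintf("C%03d", seq_len(n)), 2000L)
  graph <- buildGraph(countryIds(panel))
  model <- buildModel(panel, graph,
                      modelSpec(variant = "M0s", effects = character()))
  K <- nrow(ll)
  draws <- utils::modifyList(list(
    alpha = rep(0, K), beta = matrix(0, K, 0L),
    s = matrix(0, K, n), theta = matrix(0, K, 1L),
    delta = matrix(0, K, 0L),
    u = matrix(0, K, n), v = matrix(0, K, n),
    hyper = matrix(rep(c(tauE, 1, 0.5, 1, 1), each = K), K, 5L,
                   dimnames = list(NULL, c("tau_e", "tau_s", "phi",
                                           "tau_theta", "tau_delta")))),
    extraDraws)
  new("GapFit", model = model, draws = draws, pointwiseLogLik = ll,
      muMean = muMean, meta = list())
}

# short MCMC run on a simulated panel, for structural tests
quickFit <- function(nCountries = 16L, years = 2000:2009, variant = "M1s",
                     seed = 11L, nIter = 400L, nWarmup = 150L, ...) {
  sim <- simulatePanel(simulationConfig(nCountries = nCountries,
                                        years = years, seed = seed, ...))
  mod <- buildModel(sim$panel, sim$graph, modelSpec(variant = variant))
  fit <- suppressWarnings(
    fitMCMC(mod, nIter = nIter, nWarmup = nWarmup, nChains = 1L, seed = seed))
  list(sim = sim, model = mod, fit = fit)
}
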