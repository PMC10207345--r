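#' @import methods
#' @importFrom Matrix Matrix Cholesky sparseMatrix crossprod t
#'   forceSymmetric solve rowSums colSums
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowData colData assays<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Undirected country adjacency graph
#'
#' Holds the neighbourhood structure of the spatial units (countries) that
#' drives the intrinsic CAR precision of the BYM2 spatial effect.  Edges are
#' stored once, as pairs `(i, j)` with `i < j`; the structure is symmetric by
#' construction and self-loops are rejected.
#'
#' @slot nodes character vector of unique node labels, in a stable order.
#' @slot edges two-column integer matrix of node indices, one row per
#'   undirected edge, each row satisfying `i < j`.
#'
#' @seealso [buildGraph()], [icarPrecision()], [simulateGraph()]
#' @export
setClass("AdjacencyGraph",
  representation(nodes = "character", edges = "matrix"))

setValidity("AdjacencyGraph", function(object) {
  n <- length(object@nodes)
  e <- object@edges
  if (anyDuplicated(object@nodes)) return("node labels must be unique")
  if (!is.numeric(e) || ncol(e) != 2L) return("edges must be a 2-column matrix")
  if (nrow(e)) {
    if (any(e != round(e)) || any(e < 1) || any(e > n))
      return("edge indices must be integers in [1, n_nodes]")
    if (any(e[, 1L] == e[, 2L])) return("self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L])) return("edges must be stored with i < j")
    if (anyDuplicated(e)) return("duplicate edges")
  }
  TRUE
})

#' Intrinsic CAR precision structure
#'
#' The ICAR precision matrix `Q = D - A` (degree matrix minus adjacency) of an
#' [AdjacencyGraph-class], together with its connected-component labels and the
#' per-component BYM2 scaling factors (the geometric-mean marginal variance of
#' the constrained generalized inverse; 1 for singleton components).
#'
#' @slot Q symmetric sparse precision matrix with zero row sums.
#' @slot componentLabels integer component label per node (1-based).
#' @slot scalingFactors numeric, one positive scaling factor per component.
#'
#' @seealso [icarPrecision()], [bym2ScalingFactor()]
#' @export
setClass("IcarPrecision",
  representation(Q = "Matrix", componentLabels = "integer",
                 scalingFactors = "numeric"))

setValidity("IcarPrecision", function(object) {
  n <- nrow(object@Q)
  if (length(object@componentLabels) != n)
    return("componentLabels length must equal nrow(Q)")
  k <- max(object@componentLabels, 0L)
  if (length(object@scalingFactors) != k)
    return("need one scaling factor per component")
  if (any(object@scalingFactors <= 0)) return("scaling factors must be positive")
  if (max(abs(Matrix::rowSums(object@Q))) > 1e-10)
    return("ICAR precision rows must sum to zero")
  TRUE
})

#' Country-by-year panel container
#'
#' A `GapPanel` is a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with countries as rows and years as columns.  The outcome (gender gap in
#' life expectancy, or a gender-specific life expectancy) lives in assay
#' `"y"`; each covariate (pwPM2.5, urban population share, poverty gap,
#' female primary education share, calorie supply, smoking death rate) is a
#' further assay.  `rowData(x)$region` carries the region label used by the
#' region-specific coefficient model.  Missing cells are `NA`.
#'
#' @seealso [GapPanel()], [readPanel()], [simulatePanel()]
#' @export
setClass("GapPanel", contains = "SummarizedExperiment")

setValidity("GapPanel", function(object) {
  if (!"y" %in% assayNames(object)) return("assay 'y' (outcome) is required")
  covs <- intersect(assayNames(object), gapCovariateNames())
  for (cv in covs) {
    m <- assay(object, cv)
    if (any(is.finite(m) & m <= 0))
      return(sprintf("covariate '%s' must be strictly positive where observed", cv))
  }
  yrs <- panelYears(object)
  if (length(yrs) && any(diff(yrs) <= 0)) return("years must be increasing")
  TRUE
})

#' Model specification
#'
#' Declares which model variant to fit and with which structural options.
#' Variants follow the naming used for nested spatiotemporal regressions of
#' the gender gap: `"M0s"` has no covariates (intercept + spatial + temporal +
#' interaction random effects); `"M1s"` adds the six log-transformed
#' covariates with global coefficients; `"M2s"` lets the two exposure
#' coefficients (pwPM2.5 and urbanization) vary by region.
#'
#' @slot variant `"M0s"`, `"M1s"` or `"M2s"`.
#' @slot trendOrder random-walk order of the temporal trend (1 or 2).
#' @slot effects character subset of `c("spatial", "temporal", "interaction")`;
#'   random-effect terms included in the linear predictor.
#' @slot logCovariates logical; natural-log transform the covariates (default).
#' @slot logOutcome logical; model `log(y)` instead of `y`.
#' @slot priors named list of prior settings (see [modelSpec()]).
#' @slot fixedTauE numeric; if finite, the Gaussian error precision is held
#'   fixed at this value instead of being sampled.
#'
#' @seealso [modelSpec()], [buildModel()]
#' @export
setClass("ModelSpec",
  representation(variant = "character", trendOrder = "integer",
                 effects = "character", logCovariates = "logical",
                 logOutcome = "logical", priors = "list",
                 fixedTauE = "numeric"))

setValidity("ModelSpec", function(object) {
  if (!object@variant %in% c("M0s", "M1s", "M2s")) return("unknown variant")
  if (!object@trendOrder %in% c(1L, 2L)) return("trendOrder must be 1 or 2")
  if (!all(object@effects %in% c("spatial", "temporal", "interaction")))
    return("effects must be a subset of spatial/temporal/interaction")
  pr <- object@priors
  need <- c("alphaPrec", "betaPrec", "tauShape", "tauRate")
  if (!all(need %in% names(pr))) return("priors must name alphaPrec, betaPrec, tauShape, tauRate")
  if (pr$tauShape <= 0 || pr$tauRate <= 0) return("gamma prior parameters must be positive")
  if (pr$alphaPrec < 0 || pr$betaPrec < 0) return("prior precisions must be non-negative")
  TRUE
})

#' Assembled model state
#'
#' Internal design structures produced by [buildModel()]: the observation map
#' from the latent field to the observed cells, the fixed-effect design on the
#' (centred) log scale, the scaled generalized inverse of the ICAR precision in
#' eigen form, and the random-walk penalty of the temporal trend.  Users
#' normally pass this straight to [fitMCMC()].
#'
#' @slot spec the [ModelSpec-class] used.
#' @slot graph the [AdjacencyGraph-class], reordered to panel country order.
#' @slot countries,years labels of the panel axes.
#' @slot region per-country region labels (may be empty).
#' @slot design list of internal design objects (observation indices, sparse
#'   design matrix, eigendecomposition of the scaled structured covariance,
#'   trend penalty, latent-field layout).
#'
#' @export
setClass("GapModel",
  representation(spec = "ModelSpec", graph = "AdjacencyGraph",
                 countries = "character", years = "integer",
                 region = "character", design = "list"))

#' Posterior sample from a spatiotemporal gap model
#'
#' Holds the post-warm-up MCMC draws of every latent quantity and
#' hyperparameter, the draws-by-observations pointwise log-likelihood matrix
#' used for WAIC/DIC, and sampler metadata (seed, chains, acceptance rates,
#' split-chain potential scale reduction).
#'
#' @slot model the [GapModel-class] that was fitted.
#' @slot draws named list of draw arrays: `alpha` (vector), `beta`
#'   (draws x p), `s`, `u`, `v` (draws x n), `theta` (draws x T), `delta`
#'   (draws x nT), `hyper` (draws x 5: tau_e, tau_s, phi, tau_theta,
#'   tau_delta).
#' @slot pointwiseLogLik draws x observations matrix of Gaussian
#'   log-likelihood terms at observed cells.
#' @slot muMean posterior-mean linear predictor at observed cells.
#' @slot meta list: seed, chains, iterations, acceptance rates, rhat, timing.
#'
#' @seealso [fitMCMC()], [posteriorSummary()], [computeWAIC()]
#' @export
setClass("GapFit",
  representation(model = "GapModel", draws = "list",
                 pointwiseLogLik = "matrix", muMean = "numeric", meta = "list"))

setValidity("GapFit", function(object) {
  if (!length(object@draws$alpha)) return("no draws stored")
  if (nrow(object@pointwiseLogLik) != length(object@draws$alpha))
    return("pointwiseLogLik rows must match number of draws")
  if (any(!is.finite(object@pointwiseLogLik)))
    return("pointwise log-likelihood must be finite")
  TRUE
})
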