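logMeanExpCols <- function(ll) {
  m <- apply(ll, 2L, max)
  m + log(colMeans(exp(sweep(ll, 2L, m, "-"))))
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `pD = Dbar - Dhat`, where `Dbar` is the posterior
#' mean deviance (`-2 x` log-likelihood) over the kept draws and `Dhat` is the
#' plug-in deviance at the posterior means of the linear predictor and of the
#' observation variance (Spiegelhalter form).  The likelihood matches the one
#' recorded per draw by [fitMCMC()]: when the model includes the exchangeable
#' space-time interaction, that cell-level effect is integrated out and the
#' observation variance is the identified total `1/tau_e + 1/tau_delta`;
#' otherwise the variance is `1/tau_e` at the posterior mean of `tau_e`.
#'
#' @param fit a [GapFit-class] with at least 10 draws.
#' @return list with `dic`, `pD`, `nObs`.
#' @seealso [computeWAIC()], [compareModels()]
#' @export
computeDIC <- function(fit) {
  stopifnot(is(fit, "GapFit"))
  ll <- fit@pointwiseLogLik
  if (nrow(ll) < 10L) stop("need at least 10 draws for DIC")
  dBar <- mean(-2 * rowSums(ll))
  hy <- fit@draws$hyper
  sd2hat <- if (fit@model@design$layout$useD)
    mean(1 / hy[, "tau_e"] + 1 / hy[, "tau_delta"])
  else 1 / mean(hy[, "tau_e"])
  dHat <- -2 * sum(stats::dnorm(fit@model@design$y, fit@muMean,
                                sqrt(sd2hat), log = TRUE))
  pD <- dBar - dHat
  list(dic = dBar + pD, pD = pD, nObs = ncol(ll))
}

#' Widely applicable information criterion
#'
#' `WAIC = -2 * sum_i (lpd_i - pWAIC_i)` with `lpd_i` the log of the
#' posterior-mean pointwise likelihood (computed by a stable
#' log-sum-exp) and `pWAIC_i = var_draws(log p(y_i | draw))`, the variance
#' form of the effective-parameter penalty.
#'
#' @param fit a [GapFit-class] with at least 10 draws.
#' @return list with `waic`, `pWAIC`, `nObs`.
#' @export
computeWAIC <- function(fit) {
  stopifnot(is(fit, "GapFit"))
  ll <- fit@pointwiseLogLik
  if (nrow(ll) < 10L) stop("need at least 10 draws for WAIC")
  lpd <- logMeanExpCols(ll)
  pw <- apply(ll, 2L, stats::var)
  list(waic = -2 * sum(lpd - pw), pWAIC = sum(pw), nObs = ncol(ll))
}

#' Goodness-of-fit scores of a fit
#'
#' @param fit a [GapFit-class].
#' @return one-row data.frame with `dic`, `pD`, `waic`, `pWAIC`, `nObs`.
#' @export
fitScore <- function(fit) {
  d <- computeDIC(fit); w <- computeWAIC(fit)
  data.frame(dic = d$dic, pD = d$pD, waic = w$waic, pWAIC = w$pWAIC,
             nObs = d$nObs)
}

#' Rank models by information criteria
#'
#' Orders fits (or precomputed score rows) by WAIC, smaller is better, with
#' deltas relative to the best model.  All scores must refer to the same
#' observations; ties keep input order.
#'
#' @param scores a named list of [GapFit-class] objects, or a data.frame of
#'   [fitScore()] rows with a `model` column.
#' @return data.frame `(model, dic, pD, waic, pWAIC, dWAIC)` sorted by WAIC.
#' @export
compareModels <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    labels <- names(scores)
    if (is.null(labels)) labels <- paste0("model", seq_along(scores))
    scores <- cbind(model = labels,
                    do.call(rbind, lapply(scores, fitScore)))
  }
  if (nrow(scores) < 2L) stop("need at least two models to compare")
  if (length(unique(scores$nObs)) > 1L)
    stop("models were scored on different observation sets")
  ord <- order(scores$waic)   # stable for ties
  out <- scores[ord, , drop = FALSE]
  out$dWAIC <- out$waic - out$waic[1L]
  rownames(out) <- NULL
  out
}
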