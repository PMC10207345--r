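defaultQuantities <- function(fit) {
  c("alpha", colnames(fit@draws$beta),
    c("tau_e", "tau_s", "phi", "tau_theta", "tau_delta"))
}

# map quantity names onto a draws matrix (columns = quantities)
drawsMatrix <- function(fit, quantities) {
  d <- fit@draws
  model <- fit@model
  K <- length(d$alpha)
  out <- matrix(0, K, length(quantities), dimnames = list(NULL, quantities))
  hyperNames <- colnames(d$hyper)
  for (q in quantities) {
    if (q == "alpha") { out[, q] <- d$alpha; next }
    if (q %in% colnames(d$beta)) { out[, q] <- d$beta[, q]; next }
    if (q %in% hyperNames) { out[, q] <- d$hyper[, q]; next }
    if (q == "sigma2_e") { out[, q] <- 1 / d$hyper[, "tau_e"]; next }
    mm <- regmatches(q, regexec("^(s|theta|delta)\\[(.+)\\]$", q))[[1L]]
    if (length(mm)) {
      what <- mm[2L]; key <- mm[3L]
      if (what == "s") {
        i <- match(key, model@countries)
        if (!is.na(i)) { out[, q] <- d$s[, i]; next }
      } else if (what == "theta") {
        t <- match(as.integer(key), model@years)
        if (!is.na(t)) { out[, q] <- d$theta[, t]; next }
      } else {
        ij <- strsplit(key, ",", fixed = TRUE)[[1L]]
        i <- match(trimws(ij[1L]), model@countries)
        t <- match(as.integer(trimws(ij[2L])), model@years)
        if (!is.na(i) && !is.na(t) && ncol(d$delta)) {
          out[, q] <- d$delta[, (t - 1L) * length(model@countries) + i]; next
        }
      }
    }
    stop("unknown quantity: '", q, "'")
  }
  out
}

summariseDraws <- function(mat) {
  qs <- apply(mat, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 7)
  data.frame(quantity = colnames(mat),
             mean = colMeans(mat),
             q2.5 = qs[1L, ], q97.5 = qs[2L, ],
             significant = qs[1L, ] > 0 | qs[2L, ] < 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior summary table
#'
#' Posterior mean and equal-tailed 95% credible interval (linear-interpolation
#' quantiles) for named quantities, with a significance flag set when the
#' interval excludes zero (the asterisk convention of coefficient tables).
#'
#' Recognized names: `"alpha"`, any fixed-effect column name (e.g.
#' `"pwpm25"`, or `"pwpm25:Europe"` for region-specific fits), the
#' hyperparameters `"tau_e"`, `"tau_s"`, `"phi"`, `"tau_theta"`,
#' `"tau_delta"`, `"sigma2_e"`, and indexed effects `"s[country]"`,
#' `"theta[year]"`, `"delta[country,year]"`.
#'
#' @param fit a [GapFit-class].
#' @param quantities character vector of quantity names; defaults to the
#'   intercept, all fixed effects and all hyperparameters.
#' @return data.frame with columns `quantity`, `mean`, `q2.5`, `q97.5`,
#'   `significant`.
#' @export
posteriorSummary <- function(fit, quantities = NULL) {
  stopifnot(is(fit, "GapFit"))
  if (is.null(quantities)) quantities <- defaultQuantities(fit)
  summariseDraws(drawsMatrix(fit, quantities))
}

deltaSlice <- function(fit, tIdx) {
  n <- length(fit@model@countries)
  if (ncol(fit@draws$delta))
    fit@draws$delta[, (tIdx - 1L) * n + seq_len(n), drop = FALSE]
  else matrix(0, nDraws(fit), n)
}

#' Combined spatial effect at a given year
#'
#' Per-country posterior summary of `s_i + theta_t + delta_it`, the
#' spatiotemporal deviation of country `i` in year `t` from the overall level
#' `alpha`: positive values mean the country sits above the overall level
#' that year.
#'
#' @param fit a [GapFit-class].
#' @param year a year within the fitted panel range.
#' @return data.frame with columns `country`, `mean`, `q2.5`, `q97.5`,
#'   `significant`.
#' @export
combinedSpatialEffect <- function(fit, year) {
  stopifnot(is(fit, "GapFit"))
  t <- match(as.integer(year), fit@model@years)
  if (is.na(t)) stop("year ", year, " outside the fitted panel range")
  comb <- fit@draws$s + deltaSlice(fit, t) + fit@draws$theta[, t]
  colnames(comb) <- fit@model@countries
  out <- summariseDraws(comb)
  names(out)[1L] <- "country"
  out
}

#' Country-specific temporal trend
#'
#' Per-year posterior summary of `theta_t + delta_it` for one country: the
#' country's own temporal trajectory (shared trend plus its space-time
#' deviation), with an equal-tailed 95% band.
#'
#' @param fit a [GapFit-class].
#' @param country a country id present in the fitted panel.
#' @return data.frame with columns `year`, `mean`, `q2.5`, `q97.5`.
#' @export
localTemporalTrend <- function(fit, country) {
  stopifnot(is(fit, "GapFit"))
  i <- match(country, fit@model@countries)
  if (is.na(i)) stop("unknown country: '", country, "'")
  n <- length(fit@model@countries)
  T <- length(fit@model@years)
  idx <- (seq_len(T) - 1L) * n + i
  tr <- fit@draws$theta +
    (if (ncol(fit@draws$delta)) fit@draws$delta[, idx, drop = FALSE] else 0)
  colnames(tr) <- fit@model@years
  out <- summariseDraws(tr)
  data.frame(year = fit@model@years, mean = out$mean,
             q2.5 = out$q2.5, q97.5 = out$q97.5)
}

#' Overall temporal trend
#'
#' Per-year posterior summary of the shared trend `theta_t` (posterior mean
#' and equal-tailed 95% band).  The trend is identified under a sum-to-zero
#' constraint over the study years.
#'
#' @param fit a [GapFit-class].
#' @return data.frame with columns `year`, `mean`, `q2.5`, `q97.5`.
#' @export
overallTemporalTrend <- function(fit) {
  stopifnot(is(fit, "GapFit"))
  tr <- fit@draws$theta
  colnames(tr) <- fit@model@years
  out <- summariseDraws(tr)
  data.frame(year = fit@model@years, mean = out$mean,
             q2.5 = out$q2.5, q97.5 = out$q97.5)
}
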