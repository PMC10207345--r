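movingAverage <- function(x, window = 5L) {
  half <- window %/% 2L
  T <- length(x)
  vapply(seq_len(T), function(t) {
    w <- x[max(1L, t - half):min(T, t + half)]
    mean(w, na.rm = TRUE)
  }, 0)
}

theilSenSlope <- function(values, years) {
  ok <- is.finite(values)
  v <- values[ok]; y <- years[ok]
  ij <- utils::combn(length(v), 2L)
  stats::median((v[ij[2L, ]] - v[ij[1L, ]]) / (y[ij[2L, ]] - y[ij[1L, ]]))
}

#' Classify a country trajectory
#'
#' Operationalizes the descriptive trend taxonomy of country trajectories:
#' the series is smoothed with a centred moving average (window
#' `window`); the country is labelled `"peak"` (increase-then-decrease) when
#' the smoothed maximum lies at least `edgeMargin` years inside both ends of
#' the record and the raw rise (peak minus first value) and raw fall (peak
#' minus last value) both reach `epsilon`; otherwise the label is
#' `"increasing"` or `"decreasing"` by the sign of the Theil-Sen slope.  The
#' peak value reported is the raw series value at the smoothed argmax year.
#'
#' The window (5 years), edge margin (3 years) and threshold (0.25 years of
#' gap) are tunable parameters of this operationalization, not estimated
#' quantities.
#'
#' @param values per-year series (e.g. a country's gender gap); `NA` allowed.
#' @param years matching integer years.
#' @param window centred moving-average window (odd).
#' @param edgeMargin minimum distance (years) of the peak from either end.
#' @param epsilon minimum raw rise and fall (same unit as `values`).
#' @return list with `label` (`"peak"`, `"increasing"` or `"decreasing"`),
#'   `peakYear` and `peakValue` (`NA` unless `label == "peak"`), and
#'   `slope` (Theil-Sen slope per decade).
#' @examples
#' classifyTrend(c(1, 2, 3, 4, 5, 4, 3, 2, 1), 2000:2008)$label  # "peak"
#' @export
classifyTrend <- function(values, years, window = 5L, edgeMargin = 3L,
                          epsilon = 0.25) {
  if (length(values) != length(years)) stop("values/years length mismatch")
  ok <- is.finite(values)
  if (sum(ok) < 7L) stop("need at least 7 non-missing observations")
  sm <- movingAverage(values, window)
  cand <- which(ok)
  peakIdx <- cand[which.max(sm[cand])]
  slope <- 10 * theilSenSlope(values, years)
  isPeak <- (years[peakIdx] - min(years[ok]) >= edgeMargin) &&
    (max(years[ok]) - years[peakIdx] >= edgeMargin) &&
    (values[peakIdx] - values[cand[1L]] >= epsilon) &&
    (values[peakIdx] - values[cand[length(cand)]] >= epsilon)
  if (isPeak)
    list(label = "peak", peakYear = years[peakIdx],
         peakValue = values[peakIdx], slope = slope)
  else
    list(label = if (slope >= 0) "increasing" else "decreasing",
         peakYear = NA_integer_, peakValue = NA_real_, slope = slope)
}

#' Classify every country in a panel
#'
#' @param panel a [GapPanel-class].
#' @param ... passed to [classifyTrend()].
#' @return data.frame `(country, label, peakYear, peakValue, slope)`.
#' @export
classifyPanelTrends <- function(panel, ...) {
  y <- outcomeMatrix(panel)
  rows <- lapply(seq_len(nrow(y)), function(i) {
    cl <- classifyTrend(y[i, ], panelYears(panel), ...)
    data.frame(country = countryIds(panel)[i], label = cl$label,
               peakYear = cl$peakYear, peakValue = cl$peakValue,
               slope = cl$slope, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-region average series
#'
#' Unweighted mean of the outcome over the countries of each region, year by
#' year, ignoring missing values; the number of contributing countries is
#' reported per cell.  Regions with no mapped country are omitted with a
#' warning.
#'
#' @param panel a [GapPanel-class].
#' @param regionMap optional named character vector `country -> region`;
#'   defaults to the panel's own region labels.  Every panel country must be
#'   mapped.
#' @return data.frame `(region, year, mean, n)`.
#' @export
regionAverage <- function(panel, regionMap = NULL) {
  if (is.null(regionMap)) {
    reg <- panelRegions(panel)
    if (is.null(reg)) stop("panel has no region labels and no 'regionMap' given")
  } else {
    reg <- unname(regionMap[countryIds(panel)])
    if (anyNA(reg))
      stop("unmapped countries: ",
           paste(countryIds(panel)[is.na(reg)], collapse = ", "))
  }
  y <- outcomeMatrix(panel)
  regions <- sort(unique(reg))
  empty <- setdiff(unique(regionMap), reg)
  if (length(empty))
    warning("region(s) with zero countries omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  out <- lapply(regions, function(r) {
    sub <- y[reg == r, , drop = FALSE]
    data.frame(region = r, year = panelYears(panel),
               mean = colMeans(sub, na.rm = TRUE),
               n = colSums(is.finite(sub)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$mean[out$n == 0L] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Table of countries with a trajectory peak
#'
#' @param classifications output of [classifyPanelTrends()] (or a compatible
#'   data.frame).
#' @return the `"peak"`-labelled rows sorted by peak value, descending.
#' @export
peakValueTable <- function(classifications) {
  pk <- classifications[classifications$label == "peak", , drop = FALSE]
  pk <- pk[order(-pk$peakValue), c("country", "peakYear", "peakValue")]
  rownames(pk) <- NULL
  pk
}
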