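#' Population-weighted exposure mean per zone
#'
#' For each zone, computes `sum(pm_i * pop_i) / sum(pop_i)` over the zone's
#' grid cells: the population-weighted mean pollutant concentration
#' (pwPM2.5 when the pollutant grid is fine particulate matter).  Cells with
#' a missing zone id are ignored.  Cells with positive population but missing
#' pollutant value are excluded from both numerator and denominator, and the
#' population fraction actually covered is reported.  A zone whose covered
#' population is zero yields `NA` with a warning, never a silent zero.
#'
#' Accumulation is in double precision and fixed row-major order, so results
#' are bit-reproducible.
#'
#' @param pm numeric matrix of pollutant concentration per cell (ug/m3).
#' @param pop numeric matrix of population counts per cell (>= 0).
#' @param zones matrix of zone ids per cell (integer or character; `NA` =
#'   outside any zone).  All three matrices must share their shape.
#' @return data.frame with one row per zone: `zone`, `value` (the
#'   population-weighted mean), `coverage` (covered-population fraction).
#' @examples
#' pm <- matrix(c(10, 20), 1); pop <- matrix(c(1, 3), 1)
#' populationWeightedMean(pm, pop, matrix(c("A", "A"), 1))$value  # 17.5
#' @export
populationWeightedMean <- function(pm, pop, zones) {
  pm <- as.matrix(pm); pop <- as.matrix(pop); zones <- as.matrix(zones)
  if (!all(dim(pm) == dim(pop)) || !all(dim(pm) == dim(zones)))
    stop("'pm', 'pop' and 'zones' must have identical shapes")
  if (any(pop < 0, na.rm = TRUE)) stop("'pop' must be non-negative")
  if (any(is.finite(pm) & pm < 0 & !is.na(zones)))
    stop("'pm' must be non-negative where a zone is defined")
  # row-major cell order
  ord <- order(row(pm), col(pm))
  z <- as.vector(zones)[ord]; x <- as.vector(pm)[ord]; w <- as.vector(pop)[ord]
  keep <- !is.na(z)
  z <- z[keep]; x <- x[keep]; w <- w[keep]
  w[is.na(w)] <- 0
  zoneIds <- unique(z)
  val <- cov <- numeric(length(zoneIds))
  for (k in seq_along(zoneIds)) {
    cells <- z == zoneIds[k]
    xi <- x[cells]; wi <- w[cells]
    ok <- !is.na(xi)
    totPop <- sum(wi)
    covPop <- sum(wi[ok])
    cov[k] <- if (totPop > 0) covPop / totPop else 0
    if (covPop > 0) {
      val[k] <- sum(xi[ok] * wi[ok]) / covPop
    } else {
      val[k] <- NA_real_
      warning("zone '", zoneIds[k], "' has zero covered population; ",
              "exposure set to NA", call. = FALSE)
    }
  }
  data.frame(zone = zoneIds, value = val, coverage = cov,
             stringsAsFactors = FALSE)
}

#' Attach exposure values to a panel
#'
#' Joins per-zone, per-year exposure values (e.g. the output of
#' [populationWeightedMean()] computed for several years) onto the panel's
#' `pwpm25` covariate.  Zone ids are matched against country ids; unmatched
#' panel cells are left missing, and exposure entries for countries absent
#' from the panel are skipped with a warning.
#'
#' @param panel a [GapPanel-class].
#' @param exposures data.frame with columns `zone` (country id), `year`, and
#'   `value`.  Duplicate `(zone, year)` keys are an error.
#' @return the panel with its `pwpm25` assay filled at matched cells.
#' @export
attachExposure <- function(panel, exposures) {
  stopifnot(is(panel, "GapPanel"))
  if (!all(c("zone", "year", "value") %in% names(exposures)))
    stop("'exposures' needs columns zone, year, value")
  if (nrow(exposures) == 0) return(panel)
  key <- paste(exposures$zone, exposures$year)
  if (anyDuplicated(key))
    stop("duplicate (zone, year) keys in 'exposures': ",
         key[anyDuplicated(key)])
  cur <- covariateMatrices(panel)[["pwpm25"]]
  if (is.null(cur))
    cur <- matrix(NA_real_, nrow(panel), ncol(panel),
                  dimnames = dimnames(outcomeMatrix(panel)))
  i <- match(as.character(exposures$zone), countryIds(panel))
  j <- match(as.integer(exposures$year), panelYears(panel))
  drop <- is.na(i) | is.na(j)
  if (any(drop))
    warning(sum(drop), " exposure entr(y/ies) for countries/years absent ",
            "from the panel were skipped", call. = FALSE)
  cur[cbind(i[!drop], j[!drop])] <- exposures$value[!drop]
  assays(panel)$pwpm25 <- cur
  validObject(panel)
  panel
}

#' Read / write a whitespace-delimited grid
#'
#' Plain-text matrix format for exposure grids: one grid row per line, values
#' separated by whitespace, `NA` for missing, `#` comment lines allowed.
#'
#' @param path file path.
#' @return [readGridTxt()] returns a numeric matrix.
#' @export
readGridTxt <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(strsplit(lines, "[[:space:]]+"), function(v) {
    v[v == "NA"] <- NA_character_
    as.numeric(v)
  })
  if (length(unique(lengths(rows))) > 1) stop("ragged grid rows in ", path)
  do.call(rbind, rows)
}

#' @rdname readGridTxt
#' @param grid numeric matrix to write.
#' @export
writeGridTxt <- function(grid, path) {
  writeLines(apply(as.matrix(grid), 1L, paste, collapse = " "), path)
  invisible(path)
}
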