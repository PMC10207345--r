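#' @importClassesFrom Matrix Matrix
NULL

#' Canonical covariate names
#'
#' The six covariates of the gap regression, in model order: population-
#' weighted PM2.5 (ug/m3), urban population share (%), poverty gap index,
#' female primary education share (%), calorie supply (kcal/capita/day), and
#' smoking death rate (per 100,000).
#'
#' @return character vector of assay/column names.
#' @export
gapCovariateNames <- function() {
  c("pwpm25", "urbanpop", "poverty", "education", "calories", "smoking")
}

#' Construct a country-by-year panel
#'
#' @param y numeric country x year outcome matrix (e.g. the gender gap in life
#'   expectancy, in years); `NA` marks missing cells.
#' @param countries character vector of country identifiers (row labels).
#' @param years integer vector of calendar years (column labels).
#' @param covariates named list of country x year matrices; names must come
#'   from [gapCovariateNames()].  Values must be strictly positive where
#'   observed, so the log transform of the regression is always defined.
#' @param region optional per-country region label (length `nrow(y)`).
#'
#' @return a [GapPanel-class] object.
#' @examples
#' p <- GapPanel(matrix(rnorm(6, 5), 2, 3), c("A", "B"), 2000:2002)
#' dim(p)
#' @export
GapPanel <- function(y, countries = rownames(y), years = colnames(y),
                     covariates = list(), region = NULL) {
  y <- as.matrix(y)
  if (is.null(countries)) stop("country labels are required")
  if (is.null(years)) stop("year labels are required")
  countries <- as.character(countries)
  years <- as.integer(years)
  if (length(countries) != nrow(y) || length(years) != ncol(y))
    stop("dimensions of 'y' do not match countries/years")
  dimnames(y) <- list(countries, years)
  bad <- setdiff(names(covariates), gapCovariateNames())
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  covariates <- lapply(covariates, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == dim(y))) stop("covariate dimensions must match 'y'")
    dimnames(m) <- dimnames(y)
    m
  })
  rd <- DataFrame(row.names = countries)
  if (!is.null(region)) {
    if (length(region) != length(countries))
      stop("'region' must have one label per country")
    rd$region <- as.character(region)
  }
  se <- SummarizedExperiment(
    assays = c(list(y = y), covariates),
    rowData = rd,
    colData = DataFrame(year = years, row.names = as.character(years)))
  new("GapPanel", se)
}

#' @describeIn GapPanel country identifiers (row labels) of a panel.
#' @param x a `GapPanel`.
#' @export
countryIds <- function(x) rownames(x)

#' @describeIn GapPanel calendar years (column labels) of a panel.
#' @export
panelYears <- function(x) as.integer(colData(x)$year)

#' @describeIn GapPanel per-country region labels, or `NULL` when absent.
#' @export
panelRegions <- function(x) {
  rd <- rowData(x)
  if ("region" %in% colnames(rd)) as.character(rd$region) else NULL
}

#' @describeIn GapPanel the outcome matrix (assay `"y"`).
#' @export
outcomeMatrix <- function(x) assay(x, "y")

#' @describeIn GapPanel the named list of covariate matrices present.
#' @export
covariateMatrices <- function(x) {
  covs <- intersect(assayNames(x), gapCovariateNames())
  stats::setNames(lapply(covs, function(cv) assay(x, cv)), covs)
}

setMethod("show", "GapPanel", function(object) {
  cat("GapPanel:", nrow(object), "countries x", ncol(object), "years",
      sprintf("(%d-%d)\n", min(panelYears(object)), max(panelYears(object))))
  cat("  covariates:", paste(names(covariateMatrices(object)), collapse = ", "),
      "\n")
  reg <- panelRegions(object)
  if (!is.null(reg))
    cat("  regions:", paste(sort(unique(reg)), collapse = ", "), "\n")
  nmis <- sum(is.na(outcomeMatrix(object)))
  cat("  missing outcome cells:", nmis, "of", length(outcomeMatrix(object)), "\n")
})
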