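#' Read a country-year panel CSV
#'
#' Long format, one row per country-year.  Required columns: `country_id`,
#' `year`, and at least one of `ggle`, `le_m`, `le_f`; optional columns: the
#' covariates of [gapCovariateNames()] and `region`.  Missing values are
#' empty fields or `NA`.  The table is rectangularized to the full
#' country-by-year lattice (all years between the observed minimum and
#' maximum) with explicit missing cells.  When `ggle` is absent (or missing
#' in a row) but both life-expectancy columns are present, it is backfilled
#' as `le_f - le_m` (the gender gap is female minus male life expectancy).
#'
#' @param path CSV file path; `#` comment lines are skipped.
#' @param outcome which column becomes the panel outcome: `"ggle"` (default),
#'   `"le_m"` or `"le_f"`.
#' @return a [GapPanel-class].
#' @export
readPanel <- function(path, outcome = c("ggle", "le_m", "le_f")) {
  outcome <- match.arg(outcome)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (!all(c("country_id", "year") %in% names(df)))
    stop("panel CSV needs 'country_id' and 'year' columns")
  if (!any(c("ggle", "le_m", "le_f") %in% names(df)))
    stop("panel CSV needs at least one of 'ggle', 'le_m', 'le_f'")
  numCols <- intersect(names(df), c("year", "ggle", "le_m", "le_f",
                                    gapCovariateNames()))
  for (cc in numCols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(conv))
      if (length(bad))
        stop("non-numeric value in column '", cc, "', row ", bad[1L],
             ": '", v[bad[1L]], "'")
      df[[cc]] <- conv
    }
  }
  key <- paste(df$country_id, df$year)
  if (anyDuplicated(key))
    stop("duplicate (country, year) row: ", key[anyDuplicated(key)])
  if (!"ggle" %in% names(df)) df$ggle <- NA_real_
  if (all(c("le_m", "le_f") %in% names(df))) {
    fill <- is.na(df$ggle) & !is.na(df$le_f) & !is.na(df$le_m)
    df$ggle[fill] <- df$le_f[fill] - df$le_m[fill]
  }
  countries <- sort(unique(as.character(df$country_id)))
  years <- seq(min(df$year), max(df$year))
  i <- match(as.character(df$country_id), countries)
  j <- match(df$year, years)
  toMat <- function(col) {
    m <- matrix(NA_real_, length(countries), length(years))
    if (col %in% names(df)) m[cbind(i, j)] <- df[[col]]
    m
  }
  y <- toMat(outcome)
  covs <- Filter(function(m) any(is.finite(m)),
                 stats::setNames(lapply(gapCovariateNames(), toMat),
                                 gapCovariateNames()))
  region <- NULL
  if ("region" %in% names(df)) {
    rg <- tapply(as.character(df$region), i, function(v) {
      v <- unique(v[!is.na(v)]); if (length(v)) v[1L] else NA_character_
    })
    region <- as.character(rg[as.character(seq_along(countries))])
  }
  GapPanel(y, countries, years, covariates = covs, region = region)
}

#' Write a panel to CSV
#'
#' Long format, countries and years in sorted order, missing values as empty
#' fields; the inverse of [readPanel()] for finite values and missing
#' markers.
#'
#' @param panel a [GapPanel-class].
#' @param path output file path.
#' @param header optional character vector of comment lines (each written
#'   with a leading `#`).
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path, header = character()) {
  y <- outcomeMatrix(panel)
  covs <- covariateMatrices(panel)
  reg <- panelRegions(panel)
  df <- data.frame(
    country_id = rep(countryIds(panel), times = ncol(y)),
    year = rep(panelYears(panel), each = nrow(y)),
    ggle = as.vector(y), stringsAsFactors = FALSE)
  for (cv in names(covs)) df[[cv]] <- as.vector(covs[[cv]])
  if (!is.null(reg)) df$region <- rep(reg, times = ncol(y))
  df <- df[order(df$country_id, df$year), ]
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read a posterior summary table
#'
#' CSV with columns `(quantity, mean, q2.5, q97.5, significant)`; numeric
#' values carry 12 significant digits so the table round-trips losslessly at
#' that precision.
#'
#' @param summary a non-empty [posteriorSummary()] data.frame.
#' @param path file path.
#' @param header optional `#`-prefixed comment lines.
#' @return `path` invisibly; [readSummaries()] returns the data.frame.
#' @export
writeSummaries <- function(summary, path, header = character()) {
  if (!NROW(summary)) stop("empty summary table")
  need <- c("quantity", "mean", "q2.5", "q97.5", "significant")
  if (!all(need %in% names(summary)))
    stop("summary must have columns: ", paste(need, collapse = ", "))
  out <- summary[, need]
  for (cc in c("mean", "q2.5", "q97.5"))
    out[[cc]] <- formatC(out[[cc]], digits = 12, format = "g")
  out$significant <- tolower(as.character(out$significant))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSummaries
#' @export
readSummaries <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$significant <- df$significant == "true"
  df
}

# tiny deterministic polynomial hash of a config for output stamping
configHash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the simulate-fit-summarize-compare-trends pipeline
#'
#' Executes the requested stages in order on one output directory.  Every
#' artifact is stamped with the package version, the seed and a config hash;
#' rerunning with the same config reproduces bit-identical outputs.
#'
#' @param config named list (or path to a YAML file holding one) with fields:
#'   `outDir` (required), `seed` (default 1), `stages` (default
#'   `c("simulate", "fit", "summarize", "trends")`; `"compare"` available
#'   when `models` has length > 1), `simulation` (list passed to
#'   [simulationConfig()]), `panel`/`graph`/`regions` (input paths, used
#'   instead of simulation when given), `models` (character vector of
#'   variants, default `"M1s"`), `sampler` (list: `nIter`, `nWarmup`,
#'   `nChains`, `thin`).
#' @return the output directory path, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outDir)) stop("config needs 'outDir'")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  if (is.null(stages)) {
    stages <- c("simulate", "fit", "summarize", "trends")
    if (length(config$models) > 1L) stages <- c(stages, "compare")
  }
  models <- if (is.null(config$models)) "M1s" else config$models
  hash <- configHash(config[setdiff(names(config), "outDir")])
  stamp <- c(sprintf("stgap %s", as.character(utils::packageVersion("stgap"))),
             sprintf("seed=%d config=%s", seed, hash))
  ## validate inputs before any compute
  for (f in intersect(c("panel", "graph", "regions"), names(config)))
    if (!file.exists(config[[f]]))
      stop("input file for '", f, "' not found: ", config[[f]])
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  outPath <- function(...) file.path(config$outDir, ...)
  logLines <- c(paste0("# ", stamp), paste("stages:", paste(stages, collapse = " ")))
  panel <- NULL; graph <- NULL
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if ("simulate" %in% stages) {
    runStage("simulate", {
      simCfg <- do.call(simulationConfig,
                        utils::modifyList(list(seed = seed),
                                          as.list(config$simulation)))
      sim <- simulatePanel(simCfg)
      panel <- sim$panel; graph <- sim$graph
      writePanel(panel, outPath("panel.csv"), header = stamp)
      writeEdgeList(graph, outPath("edges.txt"))
    })
  } else {
    runStage("load", {
      if (is.null(config$panel)) stop("no panel input and no simulate stage")
      panel <- readPanel(config$panel)
      graph <- readEdgeList(config$graph, countryIds(panel))
    })
  }
  fits <- list()
  if ("fit" %in% stages) {
    sa <- utils::modifyList(list(nIter = 2000L, nWarmup = 800L, nChains = 1L,
                                 thin = 1L), as.list(config$sampler))
    for (v in models) {
      runStage("fit", {
        mod <- buildModel(panel, graph, modelSpec(variant = v))
        fits[[v]] <- fitMCMC(mod, nIter = sa$nIter, nWarmup = sa$nWarmup,
                              nChains = sa$nChains, seed = seed,
                              thin = sa$thin)
        logLines <- c(logLines,
                       sprintf("fit %s: seed=%d acceptance=%s", v, seed,
                               paste(signif(fits[[v]]@meta$acceptanceRate, 4),
                                     collapse = ",")))
      })
    }
  }
  if ("summarize" %in% stages) {
    runStage("summarize", {
      if (!length(fits)) stop("nothing fitted to summarize")
      for (v in names(fits))
        writeSummaries(posteriorSummary(fits[[v]]),
                       outPath(sprintf("summaries_%s.csv", v)),
                       header = stamp)
    })
  }
  if ("compare" %in% stages) {
    runStage("compare", {
      if (length(fits) < 2L) stop("comparison needs at least two fitted models")
      cmp <- compareModels(fits)
      con <- file(outPath("comparison.csv"), "w")
      writeLines(paste0("# ", stamp), con)
      utils::write.csv(cmp, con, row.names = FALSE)
      close(con)
    })
  }
  if ("trends" %in% stages) {
    runStage("trends", {
      cls <- classifyPanelTrends(panel)
      con <- file(outPath("trends.csv"), "w")
      writeLines(paste0("# ", stamp), con)
      utils::write.csv(cls, con, row.names = FALSE, na = "")
      close(con)
    })
  }
  writeLines(logLines, outPath("run_log.txt"))
  invisible(config$outDir)
}
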