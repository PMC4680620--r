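## Shared plumbing: TSV / YAML / JSON readers and writers with schema
## validation, plus the run manifest. TSV dialect: tab-separated, header row,
## '.' decimal, no quoting. Numeric columns are written with 17 significant
## digits so write/read round-trips are exact.

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write / read a nucleus table as TSV
#'
#' Columns: \code{nucleus_id}, \code{x_ap}, \code{dv_index}, then one column
#' per gene. Reading validates the schema and reports offending row numbers;
#' missing columns, non-numeric expression values and duplicated
#' \code{(x_ap, dv_index)} pairs are errors.
#'
#' @param table a [NucleusTable-class].
#' @param path file path.
#' @return \code{readNucleusTable()} returns a [NucleusTable-class];
#'   \code{writeNucleusTable()} returns \code{path} invisibly.
#' @export
writeNucleusTable <- function(table, path) {
  stopifnot(is(table, "NucleusTable"))
  expr <- SummarizedExperiment::assay(table, "expression")
  df <- data.frame(nucleus_id = table$nucleus_id,
                   x_ap = .fmtNum(apPosition(table)),
                   dv_index = dvIndex(table),
                   check.names = FALSE)
  for (g in rownames(expr)) df[[g]] <- .fmtNum(expr[g, ])
  lines <- c(paste(colnames(df), collapse = "\t"),
             do.call(paste, c(unname(as.list(df)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeNucleusTable
#' @export
readNucleusTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(read.delim(path, check.names = FALSE,
                            colClasses = "character"),
                 error = function(e) stop("cannot parse '", path,
                                          "' as a TSV table: ",
                                          conditionMessage(e)))
  need <- c("nucleus_id", "x_ap", "dv_index")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  geneCols <- setdiff(colnames(df), need)
  if (!length(geneCols))
    stop("table schema error: no gene expression columns")
  if (!nrow(df)) stop("table schema error: no data rows")

  asNum <- function(col, what) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !df[[col]] %in% c("NA", ""))
    if (length(bad))
      stop(sprintf("table schema error: non-numeric %s in column '%s', row(s) %s",
                   what, col, paste(utils::head(bad, 5L), collapse = ", ")))
    v
  }
  xAP <- asNum("x_ap", "position")
  dv <- asNum("dv_index", "index")
  dup <- which(duplicated(paste(xAP, dv)))
  if (length(dup))
    stop("table schema error: duplicate (x_ap, dv_index) at row(s) ",
         paste(utils::head(dup, 5L), collapse = ", "))
  expr <- t(vapply(setNames(geneCols, geneCols),
                   function(g) asNum(g, "expression"),
                   numeric(nrow(df))))
  NucleusTable(expr, xAP = xAP, dvIndex = dv, nucleusId = df$nucleus_id)
}

#' Write a strategy realization as TSV
#'
#' Columns \code{cell_index}, \code{x}, \code{value}.
#'
#' @param realization a [ProfileRealization-class].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeRealization <- function(realization, path) {
  stopifnot(is(realization, "ProfileRealization"))
  lines <- c("cell_index\tx\tvalue",
             paste(seq_along(realization@positions),
                   .fmtNum(realization@positions),
                   .fmtNum(realization@values), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## YAML configuration readers
## ---------------------------------------------------------------------------

#' Read model specifications from YAML
#'
#' \code{readGradientSpec()} expects keys \code{L, cMax, sigma0, nCells};
#' \code{readStrategyParams()} expects \code{gradient:}, \code{readout:}
#' (\code{eta0, gain, shape, nEff}) and \code{strategy};
#' \code{readEmbryoSpec()} expects \code{nAP, nDV, roi} and a \code{genes:}
#' list whose entries carry \code{type: sigmoid} (\code{midpoint, width,
#' direction, amplitude, sd}) or \code{type: stripes} (\code{centers, widths,
#' amplitudes, sd}).
#'
#' @param path YAML file path.
#' @return the corresponding validated S4 object.
#' @export
readGradientSpec <- function(path) {
  y <- yaml::read_yaml(path)
  GradientSpec(L = y$L, cMax = y$cMax, sigma0 = y$sigma0, nCells = y$nCells)
}

#' @rdname readGradientSpec
#' @export
readStrategyParams <- function(path) {
  y <- yaml::read_yaml(path)
  r <- y$readout
  StrategyParams(
    gradient = GradientSpec(L = y$gradient$L, cMax = y$gradient$cMax,
                            sigma0 = y$gradient$sigma0,
                            nCells = y$gradient$nCells),
    readout = ReadoutSpec(eta0 = r$eta0,
                          gain = if (is.null(r$gain)) 1 else r$gain,
                          shape = if (is.null(r$shape)) "linear" else r$shape,
                          nEff = if (is.null(r$nEff)) 1 else r$nEff),
    strategy = y$strategy)
}

#' @rdname readGradientSpec
#' @export
readEmbryoSpec <- function(path) {
  y <- yaml::read_yaml(path)
  genes <- lapply(names(y$genes), function(nm) {
    g <- y$genes[[nm]]
    if (identical(g$type, "sigmoid"))
      sigmoidGene(nm, midpoint = g$midpoint, width = g$width,
                  direction = g$direction,
                  amplitude = if (is.null(g$amplitude)) 1 else g$amplitude,
                  sd = if (is.null(g$sd)) 0.05 else g$sd)
    else if (identical(g$type, "stripes"))
      stripeGene(nm, centers = unlist(g$centers),
                 widths = unlist(g$widths),
                 amplitudes = if (is.null(g$amplitudes)) 1
                              else unlist(g$amplitudes),
                 sd = if (is.null(g$sd)) 0.1 else g$sd)
    else stop("unknown gene type for '", nm, "'")
  })
  names(genes) <- names(y$genes)
  EmbryoSpec(genes = genes,
             nAP = if (is.null(y$nAP)) 100L else y$nAP,
             nDV = if (is.null(y$nDV)) 12L else y$nDV,
             roi = if (is.null(y$roi)) c(0.37, 0.47) else unlist(y$roi))
}

## ---------------------------------------------------------------------------
## JSON reports and run manifests
## ---------------------------------------------------------------------------

## JSON has no Inf/NaN; encode them as explicit string sentinels and restore
## them on read.
.encodeSentinels <- function(x) {
  if (is.list(x)) return(lapply(x, .encodeSentinels))
  if (is.numeric(x) && any(!is.finite(x) & !is.na(x))) {
    x <- as.list(x)
    lapply(x, function(v) {
      if (is.nan(v)) "NaN"
      else if (is.infinite(v)) if (v > 0) "Inf" else "-Inf"
      else v
    })
  } else x
}

.decodeSentinels <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .decodeSentinels)
    if (length(x) && is.null(names(x))) {
      isNum <- vapply(x, function(v) length(v) == 1L &&
        (is.numeric(v) ||
         (is.character(v) && v %in% c("Inf", "-Inf", "NaN"))), logical(1))
      isLgl <- vapply(x, function(v) length(v) == 1L && is.logical(v),
                      logical(1))
      if (all(isNum)) {
        return(vapply(x, function(v) {
          if (identical(v, "Inf")) Inf
          else if (identical(v, "-Inf")) -Inf
          else if (identical(v, "NaN")) NaN
          else as.numeric(v)
        }, numeric(1)))
      }
      if (all(isLgl)) return(vapply(x, identity, logical(1)))
    }
    x
  } else x
}

#' Write / read an analysis report as JSON
#'
#' Serializes a [runPipeline()] report (or any nested list of numerics,
#' strings and data frames) with deterministic key ordering and fixed float
#' precision, so identical runs produce byte-identical files. Non-finite
#' values are written as the explicit string sentinels \code{"Inf"},
#' \code{"-Inf"}, \code{"NaN"}.
#'
#' @param report a named list.
#' @param path file path.
#' @return \code{readReport()} returns the report list (numeric vectors
#'   restored, data frames as lists of columns);
#'   \code{writeReport()} returns \code{path} invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is.list(report))
  json <- jsonlite::toJSON(.encodeSentinels(report), digits = I(10),
                           auto_unbox = TRUE, pretty = TRUE, null = "null",
                           dataframe = "columns", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  .decodeSentinels(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                      simplifyVector = FALSE))
}

#' Write a run manifest
#'
#' Every pipeline output directory gets exactly one manifest recording the
#' configuration (and its MD5 hash), the seed, the package version, a
#' timestamp and the list of files the run produced. All data artifacts of a
#' run are byte-identical across reruns with equal config and seed; the
#' manifest's timestamp is the one field that is not.
#'
#' @param dir output directory.
#' @param config the configuration list used.
#' @param seed the integer seed used.
#' @param files character, output file names.
#' @return the manifest path, invisibly.
#' @export
writeManifest <- function(dir, config, seed, files) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = I(10)),
             tmp)
  manifest <- list(
    package = "accinfo",
    version = as.character(utils::packageVersion("accinfo")),
    configHash = unname(tools::md5sum(tmp)),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(files))
  path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             path)
  invisible(path)
}
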