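# CSV / JSON interfaces. All tabular artifacts are CSV with a header row and
# subject_id as the first column where rows are subjects; matrices carry
# row/column labels; metadata travels in JSON sidecars.

#' Write a subjects-by-variables matrix as CSV
#'
#' @param m numeric matrix, subjects in rows
#' @param path output file
#' @param subjectIds character vector of subject identifiers; generated when
#'   NULL
#' @return the path, invisibly
#' @export
writeSubjectMatrix <- function(m, path, subjectIds = NULL) {
  m <- as.matrix(m)
  if (is.null(subjectIds))
    subjectIds <- if (!is.null(rownames(m))) rownames(m)
      else sprintf("sub-%06d", seq_len(nrow(m)))
  df <- data.frame(subject_id = subjectIds, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a subjects-by-variables matrix from CSV
#'
#' Expects subject_id as the first column; returns the numeric matrix with
#' subject ids as rownames.
#'
#' @param path CSV file written by \code{\link{writeSubjectMatrix}}
#' @return numeric matrix
#' @export
readSubjectMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a labelled square matrix (e.g. a TPDM) as CSV
#'
#' @param m square matrix with dimnames
#' @param path output file
#' @return the path, invisibly
#' @export
writeSquareMatrix <- function(m, path) {
  df <- data.frame(variable = if (is.null(rownames(m)))
    paste0("v", seq_len(nrow(m))) else rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a normative model as JSON
#'
#' The basis spec, posterior weights and covariance, variances and warp
#' parameters round-trip losslessly (numbers are written at full precision).
#'
#' @param fit a \linkS4class{NormativeModel}
#' @param path JSON file
#' @return \code{writeNormativeModel}: the path, invisibly;
#'   \code{readNormativeModel}: the restored model
#' @export
writeNormativeModel <- function(fit, path) {
  obj <- list(basisSpec = fit@basisSpec, weights = fit@weights,
              weightCov = fit@weightCov, noiseVariance = fit@noiseVariance,
              priorPrecision = fit@priorPrecision, warp = fit@warp,
              trainSummary = fit@trainSummary,
              logEvidence = fit@logEvidence)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeNormativeModel
#' @export
readNormativeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- obj$basisSpec
  spec$degree <- as.integer(spec$degree)
  if (is.null(spec$siteLevels)) spec$siteLevels <- character(0)
  warp <- if (length(obj$warp)) as.list(obj$warp) else list()
  new("NormativeModel", basisSpec = spec, weights = as.numeric(obj$weights),
      weightCov = as.matrix(obj$weightCov),
      noiseVariance = obj$noiseVariance,
      priorPrecision = obj$priorPrecision, warp = warp,
      trainSummary = as.list(obj$trainSummary),
      logEvidence = obj$logEvidence)
}

#' Write a synthetic dataset with a JSON sidecar
#'
#' Writes covariates, response/z-score matrices and phenotypes as CSV, plus
#' a sidecar recording the seed, the generating spec and the generator
#' version, so a dataset is reproducible from its sidecar alone.
#'
#' @param dir output directory (created if needed)
#' @param covariates covariate data.frame (or NULL)
#' @param values response or z-score matrix (or NULL)
#' @param phenotypes phenotype data.frame (or NULL)
#' @param spec the generating spec (any JSON-serializable list)
#' @param seed the seed used
#' @return named character vector of written paths, invisibly
#' @export
writeSyntheticData <- function(dir, covariates = NULL, values = NULL,
                               phenotypes = NULL, spec = list(),
                               seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  ids <- if (!is.null(covariates)) covariates$subject_id else NULL
  if (!is.null(covariates)) {
    p <- file.path(dir, "covariates.csv")
    utils::write.csv(covariates, p, row.names = FALSE)
    paths["covariates"] <- p
  }
  if (!is.null(values)) {
    p <- file.path(dir, "values.csv")
    writeSubjectMatrix(values, p, subjectIds = ids)
    paths["values"] <- p
  }
  if (!is.null(phenotypes)) {
    p <- file.path(dir, "phenotypes.csv")
    df <- if (!is.null(ids))
      cbind(data.frame(subject_id = ids), phenotypes) else phenotypes
    utils::write.csv(df, p, row.names = FALSE)
    paths["phenotypes"] <- p
  }
  sidecar <- file.path(dir, "generator.json")
  jsonlite::write_json(
    list(seed = seed, spec = spec,
         generator = paste0("extremeNorm ",
                            as.character(utils::packageVersion("extremeNorm")))),
    sidecar, digits = NA, auto_unbox = TRUE)
  paths["sidecar"] <- sidecar
  invisible(paths)
}
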