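# End-to-end orchestration: normative fits -> deviation matrix -> marginal
# Frechet transform -> polar threshold -> TPDM -> extreme PCA -> behavioral
# associations, with every intermediate artifact written to disk and a
# manifest carrying checksums, the seed and the configuration.

pipelineDefaults <- function() {
  list(trainFraction = 0.1, warp = FALSE, quantile = 0.95,
       normalization = "unit", nComponents = 2L, scoreMap = "log",
       alpha = 0.05, seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Fails fast — before any computation — on missing input paths, split
#' fractions outside (0, 1), or an absent input block. A config must supply
#' either a \code{synthetic} block, a \code{zscores} path (normative stage
#' skipped), or \code{covariates} + \code{idps} paths.
#'
#' @param config named list (or path to a JSON/YAML file) with optional
#'   fields \code{synthetic}, \code{covariates}, \code{idps},
#'   \code{zscores}, \code{phenotypes}, \code{outputDir} and the tuning
#'   fields of \code{\link{runPipeline}}
#' @return the completed config list (defaults filled in)
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the yaml package is required to read YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- pipelineDefaults()
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (config$trainFraction <= 0 || config$trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  if (config$quantile <= 0 || config$quantile >= 1)
    stop("quantile must be in (0, 1)")
  if (!config$normalization %in% c("unit", "printed"))
    stop("normalization must be 'unit' or 'printed'")
  if (!config$scoreMap %in% c("log", "raw"))
    stop("scoreMap must be 'log' or 'raw'")
  hasSynthetic <- !is.null(config$synthetic)
  hasZ <- !is.null(config$zscores)
  hasRaw <- !is.null(config$covariates) && !is.null(config$idps)
  if (!hasSynthetic && !hasZ && !hasRaw)
    stop("config must supply a 'synthetic' block, a 'zscores' path, or ",
         "'covariates' + 'idps' paths")
  for (f in c("covariates", "idps", "zscores", "phenotypes")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("input path for '", f, "' does not exist: ", config[[f]])
  }
  if (is.null(config$outputDir)) stop("config must supply 'outputDir'")
  config
}

# stage: synthetic generation (deviation matrix route)
pipelineSynthetic <- function(config) {
  syn <- config$synthetic
  B <- syn$B
  if (!is.matrix(B)) B <- do.call(rbind, lapply(B, unlist))
  B <- checkMaxLinearB(B)
  n <- checkCount(syn$nSubjects, "nSubjects", min = 10L)
  z <- simulateTailZ(n, B, seed = config$seed)
  phen <- NULL
  if (!is.null(syn$phenotypes)) {
    # plant effects on the true extreme components so end-to-end recovery
    # is checkable: scores from the oracle eigenbasis of B B'
    basisTrue <- extremePCA(B %*% t(B))
    xs <- toPseudoFrechet(z)
    sTrue <- projectScores(xs, basisTrue,
                           nComponents = config$nComponents,
                           map = config$scoreMap)
    planted <- syn$phenotypes$planted %||% list()
    if (is.data.frame(planted))  # JSON configs deserialize to a data.frame
      planted <- lapply(seq_len(nrow(planted)),
                        function(i) as.list(planted[i, ]))
    phen <- simulatePhenotypes(
      sTrue, nNull = syn$phenotypes$nNull %||% 0L,
      planted = planted, seed = config$seed + 1)
  }
  list(z = z, phenotypes = phen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the extreme normative modeling pipeline
#'
#' Executes the six stages in order — normative fits, deviation matrix,
#' marginal Frechet transform, polar thresholding, TPDM + extreme PCA, and
#' behavioral associations — writing every intermediate artifact under
#' \code{config$outputDir} and returning (and writing) a manifest listing
#' each file with its MD5 checksum, the seed, and the configuration. The
#' same config and seed reproduce byte-identical artifacts. A stage failure
#' aborts with the stage name; artifacts written before the failure are
#' retained for debugging.
#'
#' @param config see \code{\link{validatePipelineConfig}}; tuning fields:
#'   \code{trainFraction} (default 0.1), \code{warp} (FALSE),
#'   \code{quantile} (0.95 radial threshold), \code{normalization}
#'   ("unit" or "printed"), \code{nComponents} (2), \code{scoreMap}
#'   ("log" or "raw"), \code{alpha} (0.05), \code{seed}
#' @return the manifest, invisibly (list with \code{files}, \code{seed},
#'   \code{config}, \code{summary})
#' @export
runPipeline <- function(config) {
  config <- validatePipelineConfig(config)
  outDir <- config$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  summary <- list()
  emit <- function(name, writer) {
    path <- file.path(outDir, name)
    writer(path)
    files[[name]] <<- path
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  phenotypes <- NULL
  if (!is.null(config$synthetic)) {
    syn <- stage("synthetic", pipelineSynthetic(config))
    z <- syn$z
    phenotypes <- syn$phenotypes
    emit("zscores.csv", function(p) writeSubjectMatrix(z, p))
    if (!is.null(phenotypes))
      emit("phenotypes.csv", function(p)
        utils::write.csv(phenotypes, p, row.names = FALSE))
  } else if (!is.null(config$zscores)) {
    z <- stage("input", readSubjectMatrix(config$zscores))
  } else {
    values <- stage("input", readSubjectMatrix(config$idps))
    covariates <- stage("input",
      utils::read.csv(config$covariates, stringsAsFactors = FALSE))
    fits <- stage("normative", fitNormativeAll(
      values, covariates, trainFraction = config$trainFraction,
      warp = config$warp, seed = config$seed))
    z <- fits$z
    drop <- !fits$metrics$qcPass
    if (any(drop)) {
      message("QC excluded variable(s): ",
              paste(fits$metrics$variable[drop], collapse = ", "))
      z <- z[, !drop, drop = FALSE]
    }
    summary$normativeMetrics <- fits$metrics
    emit("normative_metrics.csv", function(p)
      utils::write.csv(fits$metrics, p, row.names = FALSE))
    emit("zscores.csv", function(p) writeSubjectMatrix(z, p))
  }
  if (is.null(phenotypes) && !is.null(config$phenotypes))
    phenotypes <- utils::read.csv(config$phenotypes,
                                  stringsAsFactors = FALSE)

  xs <- stage("marginal-transform", toPseudoFrechet(z))
  polar <- stage("polar-threshold",
                 polarDecompose(xs, quantile = config$quantile))
  tpdm <- stage("tpdm", estimateTPDM(polar, mode = config$normalization))
  emit("tpdm.csv", function(p) writeSquareMatrix(tpdm@matrix, p))
  basis <- stage("extreme-pca", extremePCA(tpdm))
  lc <- loadingsContributions(basis, nComponents = config$nComponents)
  emit("scale_proportions.csv", function(p)
    utils::write.csv(data.frame(component = seq_along(basis@values),
                                scale = basis@values,
                                proportion = basis@proportions),
                     p, row.names = FALSE))
  emit("loadings.csv", function(p) writeSquareMatrix(lc$loadings, p))
  emit("contributions.csv", function(p)
    writeSquareMatrix(lc$contributions, p))
  scores <- stage("scores", projectScores(xs, basis,
                                          nComponents = config$nComponents,
                                          map = config$scoreMap))
  emit("extreme_scores.csv", function(p) writeSubjectMatrix(scores, p))
  summary$radialThreshold <- polar@radialThreshold
  summary$nExceedances <- polar@nExceedances
  summary$scaleProportions <- basis@proportions[seq_len(config$nComponents)]

  if (!is.null(phenotypes)) {
    phenNum <- phenotypes[, vapply(phenotypes, is.numeric, logical(1)),
                          drop = FALSE]
    assoc <- stage("association", associateComponents(
      scores, phenNum, alpha = config$alpha,
      nComponents = config$nComponents))
    emit("associations.csv", function(p)
      utils::write.csv(assoc, p, row.names = FALSE))
    for (l in seq_len(config$nComponents))
      emit(sprintf("manhattan_epc%d.csv", l), function(p)
        utils::write.csv(manhattanTable(assoc, l), p, row.names = FALSE))
    summary$nBonferroniSignificant <- sum(assoc$bonferroniSignificant)
  }

  manifest <- list(
    files = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    seed = config$seed,
    config = config[setdiff(names(config), "outputDir")],
    version = as.character(utils::packageVersion("extremeNorm")),
    summary = summary)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(manifest)
}
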