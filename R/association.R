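# Brain-behavior screening: correlate component scores against behavioral
# phenotypes with Spearman (continuous/ordinal) or point-biserial (binary)
# correlation, Bonferroni-corrected across phenotypes and components, plus
# the comparator analyses: standard correlation PCA and the |z| > cutoff
# deviation count score.

#' Associate component scores with behavioral phenotypes
#'
#' For every (phenotype, component) pair up to \code{nComponents}, computes a
#' point-biserial correlation (Pearson against the 0/1 code) when the
#' phenotype has exactly two distinct non-missing values, and a Spearman rank
#' correlation otherwise (multi-level unordered categoricals are rank
#' correlations on the codes, with a warning left to the caller's category
#' map). Observations are pairwise-complete. The family-wise Bonferroni
#' threshold is \code{alpha / m} with \code{m = nTested * nComponents}.
#' Spearman p-values use the t approximation, or the exact null distribution
#' for fewer than 50 untied observations.
#'
#' Phenotypes with fewer than 3 non-missing values, or constant ones, are
#' skipped and reported in the \code{"skipped"} attribute.
#'
#' @param scores subjects-by-components numeric matrix
#' @param phenotypes data.frame of numeric phenotype columns, aligned with
#'   \code{scores} by row
#' @param alpha family-wise error level (default 0.05)
#' @param nComponents number of leading score columns to test (default all)
#' @param categories optional named character vector mapping phenotype names
#'   to category labels
#' @return data.frame with columns \code{phenotype}, \code{category},
#'   \code{component}, \code{testType}, \code{correlation}, \code{pValue},
#'   \code{negLog10P}, \code{bonferroniSignificant}, \code{nUsed}, sorted by
#'   descending \code{negLog10P}; attributes \code{m}, \code{bonferroniP}
#'   (the per-test threshold) and \code{skipped}
#' @export
associateComponents <- function(scores, phenotypes, alpha = 0.05,
                                nComponents = ncol(as.matrix(scores)),
                                categories = NULL) {
  scores <- as.matrix(scores)
  L <- checkCount(nComponents, "nComponents")
  if (L > ncol(scores)) stop("nComponents exceeds the score columns")
  stopifnot(nrow(phenotypes) == nrow(scores))
  skipped <- character(0)
  rows <- vector("list", 0L)
  tested <- 0L
  for (ph in names(phenotypes)) {
    p <- phenotypes[[ph]]
    ok <- is.finite(p)
    vals <- unique(p[ok])
    if (sum(ok) < 3L || length(vals) < 2L) {
      skipped <- c(skipped, ph)
      next
    }
    tested <- tested + 1L
    binary <- length(vals) == 2L
    for (l in seq_len(L)) {
      use <- ok & is.finite(scores[, l])
      nUsed <- sum(use)
      if (binary) {
        ct <- cor.test(scores[use, l], as.numeric(p[use]))
        type <- "point_biserial"
      } else {
        exact <- nUsed < 50L && !anyDuplicated(p[use]) &&
          !anyDuplicated(scores[use, l])
        ct <- suppressWarnings(
          cor.test(scores[use, l], p[use], method = "spearman",
                   exact = exact))
        type <- "spearman"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = ph,
        category = if (!is.null(categories) && ph %in% names(categories))
          unname(categories[ph]) else NA_character_,
        component = l, testType = type,
        correlation = unname(ct$estimate), pValue = ct$p.value,
        nUsed = nUsed, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no testable phenotypes")
  m <- tested * L
  tab$pValue <- pmax(tab$pValue, .Machine$double.xmin)  # keep -log10 finite
  tab$negLog10P <- -log10(tab$pValue)
  tab$bonferroniSignificant <- tab$pValue <= alpha / m
  tab <- tab[order(-tab$negLog10P), ]
  rownames(tab) <- NULL
  attr(tab, "m") <- m
  attr(tab, "bonferroniP") <- alpha / m
  attr(tab, "skipped") <- skipped
  tab
}

#' Aggregate associations per phenotype
#'
#' Per-phenotype summary keeping the most significant component result (the
#' reported p is therefore the maximum significance across the leading
#' components).
#'
#' @param tab an association table from \code{\link{associateComponents}}
#' @return data.frame with one row per phenotype, sorted by significance
#' @export
aggregateAssociations <- function(tab) {
  sp <- split(tab, tab$phenotype)
  out <- do.call(rbind, lapply(sp, function(d) d[which.max(d$negLog10P), ]))
  out <- out[order(-out$negLog10P), ]
  rownames(out) <- NULL
  out
}

#' Manhattan-ready table for one component
#'
#' Per-phenotype rows for a given component in input order, with the
#' Bonferroni threshold as a constant column, ready to plot.
#'
#' @param tab an association table from \code{\link{associateComponents}}
#' @param component component index
#' @return data.frame with columns \code{phenotype}, \code{category},
#'   \code{negLog10P} and \code{thresholdLine}
#' @export
manhattanTable <- function(tab, component = 1L) {
  d <- tab[tab$component == component, ]
  data.frame(phenotype = d$phenotype, category = d$category,
             negLog10P = d$negLog10P,
             thresholdLine = -log10(attr(tab, "bonferroniP")))
}

#' Standard correlation PCA comparator
#'
#' Eigendecomposition of the Pearson correlation matrix of the deviation
#' scores — the bulk-dependence comparator to extreme PCA, in the same
#' output layout. Scores are projections of the standardized data.
#'
#' @param z subjects-by-variables deviation matrix or
#'   \linkS4class{DeviationExperiment}
#' @param nComponents number of leading components to score (default 2)
#' @return list with \code{values}, \code{vectors}, \code{proportions}
#'   (eigenvalues over D), \code{loadings} (u * sqrt(lambda)) and
#'   \code{scores}
#' @export
standardPCA <- function(z, nComponents = 2L) {
  if (is(z, "DeviationExperiment")) z <- deviationMatrix(z)
  z <- as.matrix(z)
  if (ncol(z) < 2L) stop("at least 2 variables are required")
  L <- checkCount(nComponents, "nComponents")
  sds <- apply(z, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(z)[sds == 0], collapse = ", "))
  R <- cor(z)
  e <- eigen(R, symmetric = TRUE)
  u <- e$vectors
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  rownames(u) <- colnames(z)
  scores <- scale(z) %*% u[, seq_len(L), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(L))
  list(values = e$values, vectors = u,
       proportions = e$values / sum(e$values),
       loadings = sweep(u, 2, sqrt(pmax(e$values, 0)), `*`),
       scores = scores)
}

#' Deviation count scores
#'
#' The simple comparator: per subject, the number of variables with
#' z > cutoff, z < -cutoff, and their sum (default cutoff 1.96, i.e. the
#' two-sided 5\% normal tail).
#'
#' @param z subjects-by-variables deviation matrix or
#'   \linkS4class{DeviationExperiment}
#' @param cutoff positive threshold on |z| (default 1.96)
#' @return data.frame with columns \code{nPositive}, \code{nNegative},
#'   \code{nTotal}, one row per subject
#' @export
deviationCounts <- function(z, cutoff = 1.96) {
  if (is(z, "DeviationExperiment")) z <- deviationMatrix(z)
  z <- as.matrix(z)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive number")
  pos <- rowSums(z > cutoff)
  neg <- rowSums(z < -cutoff)
  data.frame(nPositive = pos, nNegative = neg, nTotal = pos + neg)
}
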