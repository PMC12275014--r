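# Multivariate tail dependence: marginal standardization to common tail
# index alpha = 2, polar decomposition with a radial threshold, the tail
# pairwise dependence matrix (TPDM), and its eigendecomposition into
# extreme principal components.

#' Rank-based Frechet marginal transform
#'
#' Standardizes every column of a deviation matrix to a common heavy tail.
#' Per column, the empirical CDF is estimated by mid-ranks,
#' F-hat = rank/(n+1) (so F-hat < 1 always), and mapped through the
#' Frechet(alpha = 2) quantile function x = (-log F-hat)^(-1/2), whose CDF is
#' exp(-x^-2). The transform is strictly monotone per column, so the copula
#' — and with it all tail dependence — is untouched while the margins become
#' regularly varying with tail index 2.
#'
#' Rows containing missing values are dropped (complete-case) with a message,
#' since the polar decomposition needs full vectors.
#'
#' @param z numeric matrix of deviation scores, subjects by variables, or a
#'   \linkS4class{DeviationExperiment}
#' @return a \linkS4class{PseudoFrechet}
#' @examples
#' z <- matrix(rnorm(200), 100, 2)
#' x <- toPseudoFrechet(z)
#' range(pseudoFrechetValues(x))
#' @export
toPseudoFrechet <- function(z) {
  if (is(z, "DeviationExperiment")) z <- deviationMatrix(z)
  z <- as.matrix(z)
  if (is.null(colnames(z))) colnames(z) <- paste0("v", seq_len(ncol(z)))
  cc <- complete.cases(z)
  if (!all(cc)) {
    message(sum(!cc), " rows with missing values dropped (complete-case)")
    z <- z[cc, , drop = FALSE]
  }
  n <- nrow(z)
  x <- matrix(NA_real_, n, ncol(z), dimnames = dimnames(z))
  for (j in seq_len(ncol(z))) {
    nd <- length(unique(z[, j]))
    if (nd == 1L)
      stop("column '", colnames(z)[j], "' is constant and cannot be ",
           "rank-transformed")
    if (nd < 20L)
      warning("column '", colnames(z)[j], "' has only ", nd,
              " distinct values")
    fhat <- rank(z[, j], ties.method = "average") / (n + 1)
    x[, j] <- (-log(fhat))^(-1 / 2)
  }
  new("PseudoFrechet", values = x, alpha = 2, sourceColumns = colnames(z))
}

#' Polar decomposition and radial thresholding
#'
#' Writes each pseudo-Frechet row as r * omega with r the L2 norm and omega
#' on the unit sphere, and sets the radial threshold r0 at the empirical
#' \code{quantile} of r (default 0.95). Observations with r > r0 are the
#' multivariate extremes used for TPDM estimation.
#'
#' @param x a \linkS4class{PseudoFrechet} (or a positive matrix)
#' @param quantile radial quantile for the threshold, in (0, 1); default 0.95
#' @return a \linkS4class{PolarDecomposition}
#' @export
polarDecompose <- function(x, quantile = 0.95) {
  v <- if (is(x, "PseudoFrechet")) x@values else as.matrix(x)
  if (any(v <= 0)) stop("polar decomposition expects positive values")
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  r <- sqrt(rowSums(v^2))
  omega <- v / r
  r0 <- unname(stats::quantile(r, quantile))
  mask <- r > r0
  nexc <- sum(mask)
  if (nexc < 20L)
    warning("only ", nexc, " radial exceedances above r0")
  new("PolarDecomposition", radius = r, angles = omega,
      radialThreshold = r0, quantile = quantile, exceedanceMask = mask,
      nExceedances = as.integer(nexc))
}

#' Estimate the tail pairwise dependence matrix
#'
#' Empirical second moments of the angular components over radial
#' exceedances:
#' \code{sigma_ij = const * mean(omega_i * omega_j | r > r0)}.
#' In \code{"printed"} mode the constant is 2 (the trace is then exactly 2);
#' in \code{"unit"} mode (default) it is the dimension D, so that unit-scale
#' Frechet(2) margins give a unit diagonal and the trace is exactly D. The
#' two modes differ by the scalar D/2 only and share all eigenstructure.
#'
#' @param polar a \linkS4class{PolarDecomposition}
#' @param mode \code{"unit"} or \code{"printed"}
#' @return a \linkS4class{TPDM}
#' @examples
#' z <- simulateTailZ(2000, B = rbind(c(1, 0), c(0.8, 0.6)), seed = 1)
#' tp <- estimateTPDM(polarDecompose(toPseudoFrechet(z)))
#' tpdmMatrix(tp)   # converges to B %*% t(B) as n grows
#' @export
estimateTPDM <- function(polar, mode = c("unit", "printed")) {
  mode <- match.arg(mode)
  stopifnot(is(polar, "PolarDecomposition"))
  if (polar@nExceedances < 1L) stop("no radial exceedances")
  w <- polar@angles[polar@exceedanceMask, , drop = FALSE]
  d <- ncol(w)
  const <- if (mode == "printed") 2 else d
  m <- const * crossprod(w) / nrow(w)
  m <- (m + t(m)) / 2
  new("TPDM", matrix = m, mode = mode,
      radialThreshold = polar@radialThreshold,
      nExceedances = polar@nExceedances, quantile = polar@quantile)
}

#' Extreme principal components of a TPDM
#'
#' Eigendecomposition of the tail pairwise dependence matrix. Eigenvalues
#' ("scales") are sorted descending and reported with their scale
#' proportions; eigenvector signs follow the convention that each vector's
#' largest-magnitude entry is positive. Because the two TPDM normalization
#' modes differ by a positive scalar, eigenvectors and proportions are
#' identical across modes.
#'
#' @param tpdm a \linkS4class{TPDM} or a symmetric positive semidefinite
#'   matrix
#' @return an \linkS4class{ExtremeEigenBasis}
#' @export
extremePCA <- function(tpdm) {
  m <- if (is(tpdm, "TPDM")) tpdm@matrix else as.matrix(tpdm)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("extremePCA requires a symmetric matrix")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  u <- e$vectors
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  rownames(u) <- rownames(m)
  new("ExtremeEigenBasis", values = e$values, vectors = u,
      proportions = e$values / sum(e$values))
}

#' Loadings and contributions of extreme components
#'
#' Per-variable weights of the leading \code{L} extreme components. In
#' \code{"printed"} mode the loading is f_l = u_l * lambda_l and the
#' contribution of variable d is c_dl = f_dl^2 / lambda_l. The
#' \code{"conventional"} mode uses f_l = u_l * sqrt(lambda_l), under which
#' the contributions of a component sum to 1. An average-contribution
#' reference value (1/D) is returned for ranking displays.
#'
#' @param basis an \linkS4class{ExtremeEigenBasis}
#' @param nComponents number of leading components L (default all)
#' @param mode \code{"printed"} or \code{"conventional"}
#' @return list with matrices \code{loadings} and \code{contributions}
#'   (variables by components) and scalar \code{averageContribution}
#' @export
loadingsContributions <- function(basis, nComponents = length(basis@values),
                                  mode = c("printed", "conventional")) {
  mode <- match.arg(mode)
  L <- checkCount(nComponents, "nComponents")
  d <- nrow(basis@vectors)
  if (L > d) stop("nComponents exceeds the number of variables")
  lam <- basis@values[seq_len(L)]
  u <- basis@vectors[, seq_len(L), drop = FALSE]
  f <- if (mode == "printed") sweep(u, 2, lam, `*`)
       else sweep(u, 2, sqrt(pmax(lam, 0)), `*`)
  cmat <- matrix(0, d, L, dimnames = dimnames(f))
  pos <- lam > 0
  if (any(!pos))
    warning("zero eigenvalue(s); their contributions are defined as 0")
  cmat[, pos] <- sweep(f[, pos, drop = FALSE]^2, 2, lam[pos], `/`)
  colnames(f) <- colnames(cmat) <- paste0("EPC", seq_len(L))
  list(loadings = f, contributions = cmat, averageContribution = 1 / d)
}

#' Subject-level extreme component scores
#'
#' Projects pseudo-Frechet observations onto the leading \code{L}
#' eigenvectors. The default pre-map takes logs column-wise first (mapping
#' the positive half-line onto the real line); \code{map = "raw"} projects
#' the pseudo-Frechet values directly. The convention used is recorded as an
#' attribute, since subject-level extreme-PC scores are a reporting
#' convention rather than part of the tail model.
#'
#' @param x a \linkS4class{PseudoFrechet}
#' @param basis an \linkS4class{ExtremeEigenBasis}
#' @param nComponents number of leading components L
#' @param map \code{"log"} (default) or \code{"raw"}
#' @return subjects-by-L score matrix with attribute \code{"map"}
#' @export
projectScores <- function(x, basis, nComponents = 2L,
                          map = c("log", "raw")) {
  map <- match.arg(map)
  stopifnot(is(x, "PseudoFrechet"), is(basis, "ExtremeEigenBasis"))
  L <- checkCount(nComponents, "nComponents")
  d <- nrow(basis@vectors)
  if (ncol(x@values) != d)
    stop("column count of x does not match the eigenbasis dimension")
  if (L > d) stop("nComponents exceeds the number of variables")
  v <- if (map == "log") log(x@values) else x@values
  s <- v %*% basis@vectors[, seq_len(L), drop = FALSE]
  colnames(s) <- paste0("EPC", seq_len(L))
  attr(s, "map") <- map
  s
}
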