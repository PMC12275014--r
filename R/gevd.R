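# Generalized extreme value distribution and block-maxima fitting.
#
#   G(z) = exp(-(1 + xi * (z - mu)/sigma)^(-1/xi)),
# with the Gumbel limit exp(-exp(-(z - mu)/sigma)) as xi -> 0.

#' Generalized extreme value distribution functions
#'
#' CDF and quantile function of the GEVD with location \code{loc}, scale
#' \code{scale} and shape \code{shape}; the Gumbel limit is used for
#' \code{|shape| < 1e-6}.
#'
#' @param z quantiles
#' @param p probabilities in (0, 1)
#' @param loc location mu
#' @param scale positive scale sigma
#' @param shape shape xi
#' @return probabilities (\code{pgevd}) or quantiles (\code{qgevd})
#' @examples
#' pgevd(0, 0, 1, 0)  # exp(-1), the Gumbel CDF at its location
#' @export
pgevd <- function(z, loc, scale, shape) {
  stopifnot(scale > 0)
  s <- (z - loc) / scale
  if (abs(shape) < .XI_EPS) return(exp(-exp(-s)))
  arg <- 1 + shape * s
  ifelse(arg <= 0, if (shape > 0) 0 else 1,
         exp(-exp((-1 / shape) * log(pmax(arg, 1e-300)))))
}

#' @rdname pgevd
#' @export
qgevd <- function(p, loc, scale, shape) {
  stopifnot(scale > 0)
  if (any(p <= 0 | p >= 1)) stop("probabilities must be in (0, 1)")
  if (abs(shape) < .XI_EPS) return(loc - scale * log(-log(p)))
  loc + scale * expm1(-shape * log(-log(p))) / shape
}

gevdNegLogLik <- function(par, x) {
  mu <- par[1]; sigma <- par[2]; xi <- par[3]
  if (!is.finite(sigma) || sigma <= 0) return(Inf)
  s <- (x - mu) / sigma
  n <- length(x)
  if (abs(xi) < .XI_EPS)
    return(n * log(sigma) + sum(s) + sum(exp(-s)))
  arg <- 1 + xi * s
  if (any(arg <= 0)) return(Inf)
  n * log(sigma) + (1 / xi + 1) * sum(log(arg)) + sum(arg^(-1 / xi))
}

#' Fit a generalized extreme value distribution to block maxima
#'
#' Collapses \code{z} to per-block maxima according to \code{blocks} and fits
#' the GEVD by maximum likelihood (Gumbel moment start, shape restricted to
#' (-0.5, 1]). Standard errors come from the inverse observed information.
#'
#' @param z numeric vector of values
#' @param blocks block label per value (factor-like); each block contributes
#'   its maximum
#' @param minBlocks warn when fewer blocks than this are available
#'   (default 20)
#' @return a \linkS4class{GEVDFit}
#' @examples
#' set.seed(1)
#' z <- rnorm(5000)
#' fitGEVD(z, blocks = rep(1:50, each = 100))
#' @export
fitGEVD <- function(z, blocks, minBlocks = 20L) {
  stopifnot(length(z) == length(blocks))
  keep <- is.finite(z)
  x <- tapply(z[keep], blocks[keep], max)
  x <- as.numeric(x[!is.na(x)])
  if (length(x) < 2L) stop("at least two non-empty blocks are required")
  if (length(x) < minBlocks)
    warning(sprintf("only %d blocks; GEVD asymptotics may be poor", length(x)))
  # Gumbel method-of-moments start
  s0 <- sqrt(6 * var(x)) / pi
  m0 <- mean(x) - 0.5772157 * s0
  nll <- function(par) {  # (mu, log sigma, xi)
    xi <- par[3]
    if (xi <= -0.5 || xi > 1) return(1e10)
    v <- gevdNegLogLik(c(par[1], exp(par[2]), xi), x)
    if (!is.finite(v)) 1e10 else v
  }
  fit <- optim(c(m0, log(s0), 0.05), nll, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-12))
  if (fit$convergence != 0)
    stop("GEVD maximum-likelihood optimization did not converge")
  mu <- fit$par[1]; sigma <- exp(fit$par[2]); xi <- fit$par[3]
  hess <- try(optimHess(c(mu, sigma, xi), gevdNegLogLik, x = x),
              silent = TRUE)
  se <- c(location = NA_real_, scale = NA_real_, shape = NA_real_)
  if (!inherits(hess, "try-error")) {
    vc <- try(solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc) > 0))
      se[] <- sqrt(diag(vc))
  }
  new("GEVDFit", location = mu, scale = sigma, shape = xi, se = se,
      nBlocks = length(x), logLik = -fit$value)
}
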