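# internal helpers

# sample skewness (g1) and excess kurtosis (g2)
sampleSkewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}

sampleKurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2 - 3
}

# seed scoping: run expr under a seed without clobbering the caller's RNG
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

checkCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

#' Angle between two directions
#'
#' Sign-invariant angle between two vectors, in degrees. Used to compare
#' estimated leading directions (extreme or standard principal components)
#' with planted or comparator directions.
#'
#' @param u,v numeric vectors of equal length
#' @return angle in degrees, in [0, 90]
#' @export
angleBetween <- function(u, v) {
  cosang <- abs(sum(u * v)) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(min(1, cosang)) * 180 / pi
}
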