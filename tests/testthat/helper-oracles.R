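# Shared fixtures and small oracles used across test files.

# the two-variable max-linear spec whose TPDM is exactly [[1, .8], [.8, 1]]
B_ORACLE <- rbind(c(1, 0), c(0.8, 0.6))

# Monte-Carlo standard errors of the first four moments of a standard
# normal sample of size n (mean, variance, skewness, excess kurtosis)
momentSE <- function(n) {
  c(mean = 1 / sqrt(n), var = sqrt(2 / n),
    skew = sqrt(6 / n), kurt = sqrt(24 / n))
}

# full TPDM pipeline from a z matrix
tpdmFromZ <- function(z, quantile = 0.95, mode = "unit") {
  estimateTPDM(polarDecompose(toPseudoFrechet(z), quantile = quantile),
               mode = mode)
}
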