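# Exact null distribution of the Kendall concordance count between a fixed
# template (possibly with tied values) and a uniformly random permutation of
# distinct data values.  The number of discordant pairs among the
# template-comparable pairs follows the Gaussian-multinomial distribution
# over the template's tie-group sizes; coefficients are built by sequential
# Gaussian-binomial convolution, normalised to probabilities as we go so
# that large series lengths do not overflow.

# probability vector over 0..(m*n) discordances for merging a block of n new
# elements into m old ones: Gaussian binomial [m+n, n]_q / choose(m+n, n)
.qbinomProb <- function(m, n) {
  # start from polynomial 1, multiply by (1-q^(m+i)), divide by (1-q^i)
  deg <- m * n
  coef <- c(1, rep(0, deg))
  for (i in seq_len(n)) {
    # multiply by (1 - q^(m+i)) -- guaranteed exact cancellation later
    d <- m + i
    if (d <= deg) coef[(d + 1):(deg + 1)] <-
        coef[(d + 1):(deg + 1)] - coef[1:(deg + 1 - d)]
    # divide by (1 - q^i): s[j] = c[j] + s[j - i]
    if (i <= deg) for (j in (i + 1):(deg + 1))
      coef[j] <- coef[j] + coef[j - i]
  }
  coef / sum(coef)
}

#' Exact Kendall concordance null for a tied template
#'
#' Returns the exact probability distribution of the number of
#' \emph{discordant} pairs between a fixed template with tie-group sizes
#' \code{groupSizes} and a uniformly random permutation of distinct data
#' values, over the template-comparable pairs only.
#'
#' @param groupSizes integer sizes of the template's tie groups (in
#'   ascending template order; the order does not affect the null).
#' @return numeric vector \code{p}; \code{p[d + 1]} is the probability of
#'   exactly \code{d} discordances, \code{d = 0, ..., Dtot}.
#' @export
kendallExactNull <- function(groupSizes) {
  groupSizes <- as.integer(groupSizes)
  stopifnot(all(groupSizes >= 1))
  acc <- 1
  nAcc <- groupSizes[1]
  for (a in seq_along(groupSizes)[-1]) {
    blk <- .qbinomProb(nAcc, groupSizes[a])
    acc <- stats::convolve(acc, rev(blk), type = "open")
    acc[acc < 0] <- 0  # FFT jitter
    acc <- acc / sum(acc)
    nAcc <- nAcc + groupSizes[a]
  }
  if (length(acc) == 1) acc <- 1
  acc
}

# concordance/discordance counts of x against template u over pairs where u
# differs; pairs with tied x contribute to neither count
.concordance <- function(x, u) {
  n <- length(x)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  su <- sign(u[ij[, 2]] - u[ij[, 1]])
  sx <- sign(x[ij[, 2]] - x[ij[, 1]])
  keep <- su != 0
  s <- sx[keep] * su[keep]
  c(conc = sum(s > 0), disc = sum(s < 0), comparable = sum(keep))
}

# exact tail p-value P(C >= c_obs) for template u (null cached per tie
# signature in the calling environment if provided)
.jtkTailP <- function(x, u, nullCache = NULL) {
  cc <- .concordance(x, u)
  sizes <- sort(as.integer(table(u)))
  key <- paste(sizes, collapse = ",")
  nul <- if (!is.null(nullCache) && !is.null(nullCache[[key]]))
    nullCache[[key]]
  else {
    nn <- kendallExactNull(sizes)
    if (!is.null(nullCache)) nullCache[[key]] <- nn
    nn
  }
  dTot <- length(nul) - 1L
  # C = dTot - D when x has no ties; with x ties C_obs is smaller, which
  # only makes the tail probability conservative
  dMax <- dTot - cc[["conc"]]  # largest D compatible with observing >= conc
  sum(nul[seq_len(dMax + 1L)])
}
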