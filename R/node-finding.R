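#' Amplitude-variability ("regulator") score of a trace
#'
#' The population standard deviation of the base-10 logarithm of the
#' mean-normalised expression profile.  Scaling the whole trace by a
#' positive constant leaves the score unchanged.
#'
#' @param trace strictly positive numeric vector.
#' @param pseudocount optional nonnegative value added to every point
#'   before taking logs (off by default); without it, any value <= 0 is a
#'   domain error.
#' @return nonnegative scalar.
#' @export
regulatorScore <- function(trace, pseudocount = 0) {
  trace <- trace + pseudocount
  if (any(trace <= 0))
    stop("trace has values <= 0; the log-amplitude score requires positive ",
         "expression (consider the documented 'pseudocount' option)",
         call. = FALSE)
  lg <- log10(trace / mean(trace))
  sqrt(mean((lg - mean(lg))^2))  # population (divide-by-T) convention
}

#' Empirical amplitude p-value against resampled curves
#'
#' Generates \code{nR} random curves by picking, independently at each
#' time point, the value at that time of a curve drawn uniformly from the
#' whole dataset, and returns the fraction whose regulator score strictly
#' exceeds the score of \code{gene}.
#'
#' @param gene gene name present in \code{tss}.
#' @param tss a \linkS4class{TimeSeriesSet}.
#' @param nR number of random curves (>= 1).
#' @param pseudocount forwarded to \code{\link{regulatorScore}}.
#' @return empirical p-value in [0, 1] (0 is attainable and best).
#' @export
empiricalPReg <- function(gene, tss, nR = 1000, pseudocount = 0) {
  stopifnot(is(tss, "TimeSeriesSet"), nR >= 1)
  v <- tss@values
  if (!gene %in% rownames(v)) stop("unknown gene: ", gene)
  target <- regulatorScore(v[gene, ], pseudocount)
  nT <- ncol(v)
  picks <- matrix(sample.int(nrow(v), nR * nT, replace = TRUE), nR, nT)
  exceed <- 0L
  for (r in seq_len(nR)) {
    rc <- v[cbind(picks[r, ], seq_len(nT))]
    if (regulatorScore(rc, pseudocount) > target) exceed <- exceed + 1L
  }
  exceed / nR
}

#' Cosine templates for the periodicity score
#'
#' One template per (period, phase) pair, sampled on the measurement grid:
#' \code{cos(2*pi*(t - phase)/period)}.  Phases default to one sampling
#' step apart across a full period, which includes the anti-phase
#' templates, so matching is two-sided through the phase grid.
#'
#' @param times sampling times.
#' @param periods numeric vector of candidate periods (no hidden default;
#'   supply via configuration).
#' @param phases optional explicit phase offsets; default derives a grid
#'   from the median sampling interval.
#' @return list of numeric template vectors.
#' @export
jtkTemplates <- function(times, periods, phases = NULL) {
  stopifnot(length(periods) >= 1, all(periods > 0))
  out <- list()
  for (p in periods) {
    ph <- if (is.null(phases)) {
      dt <- median(diff(times))
      seq(0, p - dt / 2, by = dt)
    } else phases
    for (f in ph) out[[length(out) + 1L]] <- cos(2 * pi * (times - f) / p)
  }
  out
}

#' Exact-null periodicity p-value (Kendall tau vs. sinusoid templates)
#'
#' For each template the pairwise up/down pattern of the trace is compared
#' with the template's (Kendall concordance); the best concordance is
#' converted to an exact p-value under the permutation null (honouring
#' template ties) and Bonferroni-multiplied by the number of templates.
#'
#' @param trace numeric vector (>= 3 points).
#' @param times sampling times.
#' @param periods candidate periods, see \code{\link{jtkTemplates}}.
#' @param phases optional phase grid.
#' @return adjusted p-value in (0, 1].
#' @export
jtkPValue <- function(trace, times, periods, phases = NULL) {
  if (length(trace) < 3) stop("need at least 3 time points")
  if (max(trace) == min(trace)) {
    warning("constant trace: tau undefined, returning p = 1")
    return(1)
  }
  tpl <- jtkTemplates(times, periods, phases)
  cache <- new.env(parent = emptyenv())
  p <- vapply(tpl, function(u) .jtkTailP(trace, u, cache), 0)
  min(1, length(tpl) * min(p))
}

#' Combined periodicity-amplitude node score
#'
#' \code{pReg * pPer * (1 + (pReg/0.001)^2) * (1 + (pPer/0.001)^2)}; lower
#' is better, and the quadratic factors accentuate profiles that are
#' simultaneously highly periodic and highly variable in amplitude.
#'
#' @param pReg empirical amplitude p-value in [0, 1].
#' @param pPer adjusted periodicity p-value in (0, 1].
#' @return nonnegative score (vectorised).
#' @export
dlxjtkScore <- function(pReg, pPer) {
  stopifnot(all(pReg >= 0 & pReg <= 1), all(pPer > 0 & pPer <= 1))
  pReg * pPer * (1 + (pReg / 0.001)^2) * (1 + (pPer / 0.001)^2)
}

#' Score all genes of a dataset for core-oscillator candidacy
#'
#' @param tss a \linkS4class{TimeSeriesSet}.
#' @param nR random-curve count for the amplitude p-value.
#' @param periods candidate periods for the periodicity score.
#' @param phases optional phase grid.
#' @param pseudocount forwarded to \code{\link{regulatorScore}}.
#' @return data.frame with columns gene, p_reg, p_per, dlxjtk.
#' @export
nodeScores <- function(tss, nR, periods, phases = NULL, pseudocount = 0) {
  genes <- geneNames(tss)
  pr <- vapply(genes, function(g) empiricalPReg(g, tss, nR, pseudocount), 0)
  pp <- vapply(genes, function(g)
    jtkPValue(tss@values[g, ], tss@times, periods, phases), 0)
  data.frame(gene = genes, p_reg = pr, p_per = pp,
             dlxjtk = dlxjtkScore(pr, pp), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rank genes by the combined node score
#'
#' @param scores data.frame from \code{\link{nodeScores}}.
#' @param topK optional truncation passed on to edge finding.
#' @return a \linkS4class{RankingTable} (ascending score, lower = better).
#' @export
rankNodes <- function(scores, topK = NULL) {
  stopifnot(nrow(scores) >= 1)
  it <- data.frame(item = scores$gene, score = scores$dlxjtk,
                   p_reg = scores$p_reg, p_per = scores$p_per,
                   stringsAsFactors = FALSE)
  rt <- rankingTable(it, "lower_is_better")
  if (!is.null(topK)) {
    rt@items <- rt@items[rt@items$rank <= topK, , drop = FALSE]
  }
  rt
}
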