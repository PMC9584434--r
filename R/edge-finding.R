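# Bayesian ranking of single-edge Hill regulation models (the "local"
# stage): every allowed (target, source, sign) hypothesis is fit as a
# one-dimensional Hill ODE driven by the interpolated regulator trace, and
# model evidence is computed by Laplace approximation around the optimum.

#' Right-hand side of the single-edge Hill model
#'
#' \code{dG/dt = gamma - beta * G + F(H)} with
#' \code{F = alpha * H^n / (k^n + H^n)} for activation and
#' \code{F = alpha * k^n / (k^n + H^n)} for repression.
#'
#' @param G current target level.
#' @param H current regulator level (>= 0).
#' @param sign \code{"activation"} or \code{"repression"}.
#' @param params named numeric vector/list with \code{alpha}, \code{beta},
#'   \code{gamma}, \code{k}, \code{n}.
#' @return the derivative (vectorised over \code{G}, \code{H}).
#' @export
hillRhs <- function(G, H, sign = c("activation", "repression"), params) {
  sign <- match.arg(sign)
  H <- pmax(H, 0)  # guard against interpolation round-off below zero
  p <- as.list(params)
  f <- if (sign == "activation")
    p$alpha * H^p$n / (p$k^p$n + H^p$n)
  else
    p$alpha * p$k^p$n / (p$k^p$n + H^p$n)
  p$gamma - p$beta * G + f
}

#' Predict a target trace from a regulator under the Hill model
#'
#' Integrates the single-edge model with the regulator linearly
#' interpolated between samples, starting from the observed initial
#' target value, using a fixed-step classical Runge-Kutta scheme with
#' \code{nSub} substeps per sampling interval.
#'
#' @param regulatorTrace regulator values on \code{times}.
#' @param times strictly increasing sampling times.
#' @param sign \code{"activation"} or \code{"repression"}.
#' @param params model parameters, see \code{\link{hillRhs}}.
#' @param initialValue target value at \code{times[1]}.
#' @param nSub integration substeps per sampling interval.
#' @return predicted target values at \code{times}.
#' @export
predictTarget <- function(regulatorTrace, times, sign, params, initialValue,
                          nSub = 4L) {
  stopifnot(length(regulatorTrace) == length(times), nSub >= 1)
  nT <- length(times)
  out <- numeric(nT)
  out[1] <- g <- initialValue
  for (i in seq_len(nT - 1L)) {
    h <- (times[i + 1L] - times[i]) / nSub
    h0 <- regulatorTrace[i]
    slope <- (regulatorTrace[i + 1L] - regulatorTrace[i]) / (times[i + 1L] - times[i])
    for (s in seq_len(nSub)) {
      tA <- (s - 1L) * h
      hA <- h0 + slope * tA
      hM <- h0 + slope * (tA + h / 2)
      hB <- h0 + slope * (tA + h)
      k1 <- hillRhs(g, hA, sign, params)
      k2 <- hillRhs(g + h / 2 * k1, hM, sign, params)
      k3 <- hillRhs(g + h / 2 * k2, hM, sign, params)
      k4 <- hillRhs(g + h * k3, hB, sign, params)
      g <- g + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (!is.finite(g))
      stop("integration diverged at parameter point (",
           paste(signif(unlist(params), 4), collapse = ", "), ")")
    out[i + 1L] <- g
  }
  out
}

# hand-inlined fixed-step RK4 used inside optimisation loops (identical
# scheme to predictTarget, without per-call argument marshalling)
.predictFast <- function(reg, times, act, a, b, gm, k, n, g0, nSub) {
  nT <- length(times)
  kn <- k^n
  out <- numeric(nT)
  out[1] <- g <- g0
  # interpolation round-off can push a zero regulator slightly negative,
  # which a fractional Hill exponent cannot absorb
  f <- if (act) function(H) { hn <- max(H, 0)^n; a * hn / (kn + hn) }
  else function(H) a * kn / (kn + max(H, 0)^n)
  # explicit RK4 needs beta * h below its stability limit (~2.8)
  maxDt <- max(diff(times))
  nSub <- max(nSub, ceiling(b * maxDt / 2))
  for (i in seq_len(nT - 1L)) {
    dt <- times[i + 1L] - times[i]
    h <- dt / nSub
    h0 <- reg[i]
    sl <- (reg[i + 1L] - reg[i]) / dt
    for (s in seq_len(nSub)) {
      tA <- (s - 1L) * h
      fA <- f(h0 + sl * tA)
      fM <- f(h0 + sl * (tA + h / 2))
      fB <- f(h0 + sl * (tA + h))
      k1 <- gm - b * g + fA
      k2 <- gm - b * (g + h / 2 * k1) + fM
      k3 <- gm - b * (g + h / 2 * k2) + fM
      k4 <- gm - b * (g + h * k3) + fB
      g <- g + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (!is.finite(g)) return(NULL)
    out[i + 1L] <- g
  }
  out
}

#' Parameter box bounds for edge-model fitting
#'
#' Positive box bounds scaled to the data: the half-max constant spans
#' the regulator's observed range, production rates are bounded by
#' decay-consistent levels of the target, and the Hill exponent lies in
#' [1, 10].
#'
#' @param targetTrace observed target values.
#' @param regulatorTrace observed regulator values.
#' @return list with \code{lower} and \code{upper} named vectors over
#'   (alpha, beta, gamma, k, n).
#' @export
edgeFitBounds <- function(targetTrace, regulatorTrace) {
  rmax <- max(regulatorTrace)
  rmin <- min(regulatorTrace)
  if (rmax <= 0) rmax <- 1
  kLo <- max(rmin, 1e-3 * rmax)
  tmax <- max(targetTrace, 1e-6)
  betaHi <- 10
  list(lower = c(alpha = 0, beta = 1e-2, gamma = 0, k = kLo, n = 1),
       upper = c(alpha = betaHi * tmax, beta = betaHi,
                 gamma = betaHi * tmax, k = rmax, n = 10))
}

#' Fit a single-edge Hill model by basin-hopping global search
#'
#' Repeated bounded quasi-Newton (L-BFGS-B) local refinements started
#' from random jumps of maximal displacement \code{stepSize} (in
#' normalised box coordinates), with Metropolis accept/reject at
#' temperature \code{temperature} and step-size adaptation every
#' \code{interval} iterations, minimising the mean squared error between
#' the model prediction and the measured target trace.
#'
#' @param targetTrace,regulatorTrace observed traces on \code{times}.
#' @param times sampling times.
#' @param sign \code{"activation"} or \code{"repression"}.
#' @param iterations number of basin-hopping jumps (default 10).
#' @param temperature Metropolis temperature (default 1).
#' @param stepSize maximal jump displacement in [0,1] box units (default 0.5).
#' @param interval iterations between step-size adaptations (default 10).
#' @param bounds parameter box, see \code{\link{edgeFitBounds}}.
#' @param nSub integration substeps, see \code{\link{predictTarget}}.
#' @param localMaxit iteration cap for each local L-BFGS-B refinement.
#' @return list with \code{optimum} (named parameter vector),
#'   \code{lossAtOpt} (MSE) and \code{nEval}.
#' @export
fitEdgeModel <- function(targetTrace, regulatorTrace, times, sign,
                         iterations = 10, temperature = 1, stepSize = 0.5,
                         interval = 10, bounds = NULL, nSub = 4L,
                         localMaxit = 60L) {
  if (is.null(bounds)) bounds <- edgeFitBounds(targetTrace, regulatorTrace)
  lo <- bounds$lower; hi <- bounds$upper
  span <- hi - lo
  toRaw <- function(z) lo + pmin(pmax(z, 0), 1) * span
  act <- match.arg(sign, c("activation", "repression")) == "activation"
  loss <- function(z) {
    p <- toRaw(z)
    pred <- .predictFast(regulatorTrace, times, act, p[[1]], p[[2]],
                         p[[3]], p[[4]], p[[5]], targetTrace[1], nSub)
    if (is.null(pred)) return(1e10)
    mean((pred - targetTrace)^2)
  }
  nEval <- 0L
  lossCounted <- function(z) { nEval <<- nEval + 1L; loss(z) }
  localOpt <- function(z0) {
    o <- try(optim(z0, lossCounted, method = "L-BFGS-B", lower = 0, upper = 1,
                   control = list(maxit = localMaxit)), silent = TRUE)
    if (inherits(o, "try-error")) list(par = z0, value = lossCounted(z0))
    else o
  }
  z <- runif(5)
  cur <- localOpt(z)
  best <- cur
  s <- stepSize
  nAccept <- 0L
  for (it in seq_len(iterations)) {
    zNew <- cur$par + runif(5, -s, s)
    zNew <- pmin(pmax(zNew, 0), 1)
    cand <- localOpt(zNew)
    if (cand$value < best$value) best <- cand
    if (cand$value <= cur$value ||
        runif(1) < exp(-(cand$value - cur$value) / temperature)) {
      cur <- cand
      nAccept <- nAccept + 1L
    }
    if (it %% interval == 0L) {
      # steer the acceptance rate toward one half, scipy-style
      s <- if (nAccept / it > 0.5) s * 1.1 else s * 0.9
    }
  }
  if (!is.finite(best$value) || best$value >= 1e10)
    stop("all basin-hopping starts were infeasible")
  list(optimum = setNames(toRaw(best$par), names(lo)),
       lossAtOpt = best$value, nEval = nEval,
       .bounds = bounds, .z = best$par)
}

#' Laplace approximation of the log model evidence
#'
#' \code{log[(2*pi)^(dim/2) * det(H)^(-1/2) * exp(-E)]} for an energy
#' with value \code{energyAtOpt} and positive-definite Hessian
#' \code{hessian} at its minimum.  A non-positive-definite Hessian is
#' ridge-regularised (and noted); if it remains singular the evidence
#' falls back to \code{-energyAtOpt} with a warning.
#'
#' @param energyAtOpt energy (scaled loss) at the optimum.
#' @param hessian Hessian matrix of the energy at the optimum.
#' @param dim parameter dimension (defaults to \code{nrow(hessian)}).
#' @return log evidence (scalar).
#' @export
laplaceLogEvidence <- function(energyAtOpt, hessian, dim = nrow(hessian)) {
  H <- (hessian + t(hessian)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    ridge <- abs(min(ev)) + 1e-8 * max(abs(ev), 1)
    .msg("regularising non-positive-definite Hessian (ridge ", ridge, ")")
    H <- H + diag(ridge, nrow(H))
    ev <- ev + ridge
  }
  ld <- determinant(H, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) {
    warning("singular Hessian after regularisation; ",
            "falling back to loss-only evidence")
    return(-energyAtOpt)
  }
  dim / 2 * log(2 * pi) - as.numeric(ld$modulus) / 2 - energyAtOpt
}

# goodness-of-fit energy: E(params) = T * MSE(params) / (2 * sigma2),
# with sigma2 the model's own MSE at its optimum (the profiled noise
# variance).  The model's log evidence is then the profiled Gaussian
# log likelihood at the optimum plus the Laplace volume term, so fit
# quality enters through -(T/2) log(MSE*) and fragility through the
# energy Hessian.  Isolated here deliberately: this is the one place
# where the evidence scaling convention lives.
.edgeEnergyFactory <- function(targetTrace, regulatorTrace, times, sign,
                               sigma2, nSub = 4L) {
  nT <- length(targetTrace)
  act <- sign == "activation"
  function(par) {
    pred <- .predictFast(regulatorTrace, times, act, par[[1]], par[[2]],
                         par[[3]], par[[4]], par[[5]], targetTrace[1],
                         nSub)
    if (is.null(pred)) return(1e10)
    nT * mean((pred - targetTrace)^2) / (2 * sigma2)
  }
}

#' Enumerate allowed single-edge hypotheses
#'
#' Without annotations: all N targets x N sources x 2 signs (self-edges
#' included).  Annotations remove models: a gene with
#' \code{may_be_target = FALSE} is never a target; a source with role
#' \code{none} contributes no out-edges, \code{activator_only} no
#' repression models, \code{repressor_only} no activation models.
#'
#' @param nodes character vector of gene names.
#' @param annotations optional annotation data.frame, see
#'   \code{\link{readAnnotations}}.
#' @return data.frame with columns target, source, sign.
#' @export
enumerateHypotheses <- function(nodes, annotations = NULL) {
  stopifnot(length(nodes) >= 1)
  hy <- expand.grid(target = nodes, source = nodes,
                    sign = c("activation", "repression"),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(annotations)) {
    unknown <- setdiff(annotations$gene, nodes)
    if (length(unknown))
      stop("annotation references unknown gene: ",
           paste(unknown, collapse = ", "))
    for (r in seq_len(nrow(annotations))) {
      g <- annotations$gene[r]
      if (!annotations$may_be_target[r]) hy <- hy[hy$target != g, ]
      role <- annotations$regulator_role[r]
      if (role == "none") hy <- hy[hy$source != g, ]
      if (role == "activator_only")
        hy <- hy[!(hy$source == g & hy$sign == "repression"), ]
      if (role == "repressor_only")
        hy <- hy[!(hy$source == g & hy$sign == "activation"), ]
    }
  }
  rownames(hy) <- NULL
  hy
}

.edgeKey <- function(target, source, sign) {
  paste0(source, ifelse(sign == "activation", " -> ", " -| "), target)
}

#' Fit all edge hypotheses and compute posterior pld scores
#'
#' For each target, every allowed single-edge model is fit on each
#' replicate; evidence from successive replicates is chained (the
#' posterior after one replicate is the prior for the next).  The pld of
#' a model is its posterior probability within its target's model set.
#'
#' @param datasets list of \linkS4class{TimeSeriesSet} replicates sharing
#'   a gene set (genes missing from any replicate are dropped with a
#'   warning).
#' @param annotations optional annotation data.frame.
#' @param hypotheses optional precomputed hypothesis table (defaults to
#'   \code{enumerateHypotheses} on the shared gene set).
#' @param prior optional named prior over edge keys (uniform per target
#'   by default).
#' @param ... fitting controls forwarded to \code{\link{fitEdgeModel}}.
#' @return data.frame with columns target, source, sign, loss, logEvidence
#'   (summed over replicates), pld.
#' @export
fitAllEdges <- function(datasets, annotations = NULL, hypotheses = NULL,
                        prior = NULL, ...) {
  if (is(datasets, "TimeSeriesSet")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  genes <- Reduce(intersect, lapply(datasets, geneNames))
  dropped <- setdiff(unique(unlist(lapply(datasets, geneNames))), genes)
  if (length(dropped))
    warning("genes missing from some replicate dropped: ",
            paste(dropped, collapse = ", "))
  if (is.null(hypotheses))
    hypotheses <- enumerateHypotheses(genes, annotations)
  res <- hypotheses
  res$loss <- NA_real_
  res$logEvidence <- 0
  for (rep in seq_along(datasets)) {
    tss <- datasets[[rep]]
    v <- exprValues(tss)[genes, , drop = FALSE]
    tt <- sampleTimes(tss)
    nT <- length(tt)
    for (r in seq_len(nrow(res))) {
      tg <- res$target[r]
      fit <- fitEdgeModel(v[tg, ], v[res$source[r], ], tt, res$sign[r],
                          ...)
      # profiled noise variance: the model's own optimal MSE, floored
      # relative to the target's variance to keep exact fits finite
      sigma2 <- max(fit$lossAtOpt, 1e-9 * stats::var(v[tg, ]), 1e-300)
      eFun <- .edgeEnergyFactory(v[tg, ], v[res$source[r], ], tt,
                                 res$sign[r], sigma2)
      H <- pracma::hessian(eFun, fit$optimum)
      le <- laplaceLogEvidence(eFun(fit$optimum), H) -
        (nT / 2) * log(2 * pi * sigma2)
      res$logEvidence[r] <- res$logEvidence[r] + le
      res$loss[r] <- fit$lossAtOpt
    }
  }
  res$pld <- NA_real_
  res$lpld <- NA_real_
  for (tg in unique(res$target)) {
    idx <- which(res$target == tg)
    pr <- if (is.null(prior)) rep(1 / length(idx), length(idx)) else {
      k <- .edgeKey(res$target[idx], res$source[idx], res$sign[idx])
      p <- prior[k]
      p / sum(p)
    }
    res$pld[idx] <- pldPosterior(res$logEvidence[idx], pr)
    # log posterior kept alongside: the ranking is computed in the log
    # domain, so models whose pld underflows remain fully ordered
    lp <- log(pr) + res$logEvidence[idx]
    res$lpld[idx] <- lp - .logSumExp(lp)
  }
  res
}

.logSumExp <- function(x) {
  m <- max(x[is.finite(x)], -Inf)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Posterior model probabilities from log evidences
#'
#' \code{pld = prior * exp(logEvidence)}, normalised in the log domain
#' (softmax) to avoid underflow.  Chaining replicate data is equivalent
#' to summing their log evidences before the softmax.
#'
#' @param logEvidence numeric vector of log evidences for one target's
#'   allowed models.
#' @param prior prior probabilities (uniform default; must sum to 1).
#' @return posterior probabilities summing to 1.
#' @export
pldPosterior <- function(logEvidence, prior = NULL) {
  m <- length(logEvidence)
  stopifnot(m >= 1)
  if (is.null(prior)) prior <- rep(1 / m, m)
  stopifnot(length(prior) == m, abs(sum(prior) - 1) < 1e-6)
  lp <- log(prior) + logEvidence
  if (all(!is.finite(lp))) {
    warning("all model evidences are -Inf; returning the uniform posterior")
    return(rep(1 / m, m))
  }
  lp <- lp - max(lp[is.finite(lp)])
  w <- exp(lp)
  w / sum(w)
}

#' Local edge ranking from fitted pld scores
#'
#' All hypotheses across all targets merged and ranked by pld
#' (descending); ties broken by the lexicographic edge key.
#'
#' @param results data.frame from \code{\link{fitAllEdges}} (needs columns
#'   target, source, sign, pld).
#' @return a \linkS4class{RankingTable}.
#' @export
localEdgeRanking <- function(results) {
  stopifnot(all(c("target", "source", "sign", "pld") %in% names(results)))
  it <- data.frame(
    item = .edgeKey(results$target, results$source, results$sign),
    score = results$pld, target = results$target, source = results$source,
    sign = results$sign, stringsAsFactors = FALSE)
  if (!is.null(results$lpld)) {
    # order by the log posterior (no underflow ties), then item key
    ord <- order(-results$lpld, it$item, method = "radix")
    it <- it[ord, , drop = FALSE]
    it$rank <- seq_len(nrow(it))
    rownames(it) <- NULL
    return(new("RankingTable", items = it, direction = "higher_is_better",
               tiebreakNote = paste("ordered by log posterior;",
                                    "ties broken by lexicographic item key")))
  }
  rankingTable(it, "higher_is_better")
}

#' Node participation score within an edge ranking
#'
#' For each node, the median (mid-average for even counts) of the ranks
#' of its incident edges (either endpoint) within \code{restrictTo};
#' nodes are then ranked ascending by this median.  A node incident to no
#' restricted edge is assigned the worst score (the restriction size) and
#' flagged.
#'
#' @param ranking an edge \linkS4class{RankingTable} with target/source
#'   columns.
#' @param nodeSet nodes to score.
#' @param restrictTo optional character vector of edge item keys defining
#'   the restriction (e.g. the top-ranked edges); defaults to all edges.
#' @return a \linkS4class{RankingTable} with an extra \code{noIncident}
#'   flag column.
#' @export
nodeParticipation <- function(ranking, nodeSet = NULL, restrictTo = NULL) {
  it <- rankedItems(ranking)
  if (is.null(restrictTo)) restrictTo <- it$item
  stopifnot(all(restrictTo %in% it$item))
  sub <- it[it$item %in% restrictTo, , drop = FALSE]
  if (is.null(nodeSet)) nodeSet <- sort(unique(c(it$target, it$source)))
  worst <- nrow(sub)
  sc <- vapply(nodeSet, function(g) {
    r <- sub$rank[sub$target == g | sub$source == g]
    if (!length(r)) worst else median(r)
  }, 0)
  flag <- vapply(nodeSet, function(g)
    !any(sub$target == g | sub$source == g), TRUE)
  rankingTable(data.frame(item = nodeSet, score = sc, noIncident = flag,
                          stringsAsFactors = FALSE),
               "lower_is_better")
}
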