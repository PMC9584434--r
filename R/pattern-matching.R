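# Extremum-order pattern matching: datasets are reduced to partial orders
# of labelled extremum events (data graphs) and a network's stable cycles
# are searched for closed paths realizing those orders cyclically.

#' Extract noise-robust extremum events from a trace
#'
#' Identifies the alternating sequence of local maxima/minima whose
#' successive amplitude difference exceeds \code{epsilon} times the
#' trace's global range (smaller wiggles are merged away).  Each
#' surviving extremum carries the maximal time window over which the
#' trace stays within \code{epsilon * range} of the extremal value.
#'
#' @param trace numeric vector (>= 3 samples).
#' @param times sampling times.
#' @param epsilon noise level in [0, 1), as a fraction of the trace's
#'   global range.
#' @param gene gene label attached to the events.
#' @return data.frame with columns gene, kind, time, tLo, tHi.
#' @export
extractEvents <- function(trace, times, epsilon = 0, gene = "gene") {
  if (length(trace) < 3) stop("need at least 3 samples to find extrema")
  stopifnot(epsilon >= 0, epsilon < 1, length(trace) == length(times))
  rng <- diff(range(trace))
  empty <- data.frame(gene = character(0), kind = character(0),
                      time = numeric(0), tLo = numeric(0), tHi = numeric(0),
                      stringsAsFactors = FALSE)
  if (rng == 0) return(empty)
  band <- epsilon * rng
  # candidate alternating extrema on the sample grid (plateau-safe)
  d <- diff(trace)
  sgn <- sign(d)[sign(d) != 0]
  if (!length(sgn)) return(empty)
  idx <- integer(0); kind <- character(0)
  nz <- which(sign(d) != 0)
  for (q in seq_along(nz)[-1]) {
    if (sign(d)[nz[q]] != sign(d)[nz[q - 1]]) {
      i <- nz[q]  # turning point at sample i (end of previous run)
      idx <- c(idx, i)
      kind <- c(kind, if (sign(d)[nz[q - 1]] > 0) "max" else "min")
    }
  }
  if (!length(idx)) return(empty)
  # merge wiggles: drop adjacent extremum pairs whose amplitude
  # difference is within the noise band, keeping alternation
  repeat {
    if (length(idx) < 2) break
    amp <- abs(diff(trace[idx]))
    k <- which.min(amp)
    if (amp[k] > band) break
    idx <- idx[-c(k, k + 1)]
    kind <- kind[-c(k, k + 1)]
  }
  if (!length(idx)) return(empty)
  # uncertainty interval: maximal window staying within the band
  lo <- hi <- numeric(length(idx))
  for (q in seq_along(idx)) {
    v <- trace[idx[q]]
    ok <- abs(trace - v) <= band
    a <- idx[q]; b <- idx[q]
    while (a > 1 && ok[a - 1]) a <- a - 1
    while (b < length(trace) && ok[b + 1]) b <- b + 1
    lo[q] <- times[a]; hi[q] <- times[b]
  }
  data.frame(gene = gene, kind = kind, time = times[idx],
             tLo = lo, tHi = hi, stringsAsFactors = FALSE)
}

#' Build a data graph from extremum events
#'
#' Precedence edge (e1, e2) exactly when e1's uncertainty interval wholly
#' precedes e2's; consecutive events of the same gene are always ordered.
#' The result is a DAG (events whose intervals overlap are incomparable).
#'
#' @param events data.frame of events across genes, as returned by
#'   \code{\link{extractEvents}} (row-bound).
#' @return a \linkS4class{DataGraph}.
#' @export
buildDataGraph <- function(events) {
  n <- nrow(events)
  el <- NULL
  if (n > 1) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (events$tHi[i] < events$tLo[j] ||
          (events$gene[i] == events$gene[j] && events$time[i] < events$time[j]))
        el <- rbind(el, c(i, j))
    }
  }
  if (is.null(el)) el <- matrix(0L, 0, 2)
  new("DataGraph", events = events, edges = el)
}

#' One-period data graph of a dataset on its attractor
#'
#' Discards the transient, estimates the oscillation period from the
#' first gene's peaks, and collects, for every gene, the first max and
#' first min event strictly after the reference peak, so that the graph
#' describes one full period of the attracting oscillation.
#'
#' @param tss a \linkS4class{TimeSeriesSet}.
#' @param epsilon noise level, see \code{\link{extractEvents}}.
#' @param transientFraction initial fraction of the time span discarded.
#' @return a \linkS4class{DataGraph}.
#' @export
periodDataGraph <- function(tss, epsilon = 0, transientFraction = 0.5) {
  tt <- sampleTimes(tss)
  keep <- tt >= tt[1] + transientFraction * diff(range(tt))
  tt <- tt[keep]
  v <- exprValues(tss)[, keep, drop = FALSE]
  ref <- extractEvents(v[1, ], tt, epsilon, rownames(v)[1])
  refMax <- ref[ref$kind == "max", ]
  if (nrow(refMax) < 2)
    stop("fewer than two reference peaks on the post-transient window; ",
         "extend the time grid or lower the transient fraction")
  period <- mean(diff(refMax$time))
  t0 <- refMax$time[1]
  evs <- NULL
  for (g in rownames(v)) {
    e <- extractEvents(v[g, ], tt, epsilon, g)
    for (k in c("max", "min")) {
      cand <- e[e$kind == k & e$time > t0 + 1e-9, , drop = FALSE]
      if (nrow(cand)) {
        hit <- cand[which.min(cand$time), , drop = FALSE]
        if (hit$time <= t0 + period * 1.05) evs <- rbind(evs, hit)
      }
    }
  }
  if (is.null(evs)) stop("no extremum events found on the attractor window")
  evs <- evs[order(evs$time), , drop = FALSE]
  rownames(evs) <- NULL
  buildDataGraph(evs)
}

# ---- internal: expanded cycle graph with extremum event labels --------
#
# A gene's qualitative trajectory changes level only through its own
# transitions, so its extrema are anchored to its own moves: a gene
# emits a local max on the transition where it steps down after having
# last stepped up, and a min in the opposite case.  (Anchoring events
# to the input-flip wall instead is rejected by the self-consistency
# requirement that a Hill simulation's extremum order be realizable by
# the generating parameter region: the finite Hill exponent delays the
# turn past the wall, up to the gene's own next level change.)  The
# component is therefore expanded by a last-move-direction code over the
# network's genes; each expanded edge emits at most one event.
#
# Event codes: gene i max -> i, gene i min -> i + N.
.expandComponent <- function(states, D, E, strides) {
  N <- ncol(D)
  if (N > 12L)
    stop("pattern matching supports at most 12 genes per network")
  inComp <- logical(max(c(states, E)))
  inComp[states] <- TRUE
  loc <- integer(max(states)); loc[states] <- seq_along(states)
  keep <- E[inComp[E[, 1]] & inComp[E[, 2]], , drop = FALSE]
  nC <- as.integer(2^N)
  codes <- 0:(nC - 1L)
  dif <- keep[, 2] - keep[, 1]
  mover <- match(abs(dif), strides)
  up <- dif > 0
  nK <- nrow(keep)
  # vectorize over edges x codes
  eCodes <- rep(codes, nK)
  eIdx <- rep(seq_len(nK), each = nC)
  w <- 2L^(mover[eIdx] - 1L)
  lastUp <- bitwAnd(eCodes, w) > 0L
  upv <- up[eIdx]
  emits <- xor(lastUp, upv)
  ev <- ifelse(emits, ifelse(upv, mover[eIdx] + N, mover[eIdx]), 0L)
  codeV <- eCodes - as.integer(lastUp) * w + as.integer(upv) * w
  list(nNodes = length(states) * nC,
       from = (loc[keep[eIdx, 1]] - 1L) * nC + eCodes + 1L,
       to = (loc[keep[eIdx, 2]] - 1L) * nC + codeV + 1L,
       event = as.integer(ev),
       stateOf = rep(states, each = nC))
}

# restrict an expanded component to edges inside nontrivial strongly
# connected components: cyclic matches cannot leave an SCC, and only a
# small fraction of last-move codes is cyclically consistent
.pruneExpanded <- function(exp) {
  if (!length(exp$from)) return(exp)
  g <- igraph::graph_from_edgelist(cbind(exp$from, exp$to),
                                   directed = TRUE)
  memb <- igraph::components(g, "strong")$membership
  keep <- memb[exp$from] == memb[exp$to]
  list(nNodes = exp$nNodes, from = exp$from[keep], to = exp$to[keep],
       event = exp$event[keep], stateOf = exp$stateOf)
}

# direct cyclic matcher for totally ordered event words: in a valid
# cyclic match a gene's last-move direction equals the phase implied by
# the cyclic word (its most recent event, cyclically), so the product is
# simply (component state, word position) with no memory expansion.
# word: integer event codes in chain order (gene i max -> i, min -> i+N).
.chainMatchDirect <- function(states, D, E, strides, word, N) {
  L <- length(word)
  inComp <- logical(max(c(states, E)))
  inComp[states] <- TRUE
  loc <- integer(max(states)); loc[states] <- seq_along(states)
  keep <- E[inComp[E[, 1]] & inComp[E[, 2]], , drop = FALSE]
  if (!nrow(keep)) return(FALSE)
  dif <- keep[, 2] - keep[, 1]
  mover <- match(abs(dif), strides)
  up <- dif > 0
  # phase of each gene after consuming k letters (k = 0..L-1):
  # TRUE = rising (most recent event, cyclically, was its min)
  phase <- matrix(NA, N, L)
  wGene <- ifelse(word > N, word - N, word)
  wIsMin <- word > N
  for (j in seq_len(N)) {
    pos <- which(wGene == j)
    if (!length(pos)) next  # gene without events: moves must be silent
    for (k in 0:(L - 1L)) {
      prev <- pos[pos <= k]
      lastEv <- if (length(prev)) max(prev) else max(pos)
      phase[j, k + 1L] <- wIsMin[lastEv]
    }
  }
  nS <- length(states)
  pid <- function(i, k) (k - 1L) * nS + i
  pf <- integer(0); pt <- integer(0); isEv <- logical(0)
  for (k in 0:(L - 1L)) {
    ph <- phase[mover, k + 1L]
    silent <- !is.na(ph) & (ph == up)
    pf <- c(pf, pid(loc[keep[silent, 1]], k + 1L))
    pt <- c(pt, pid(loc[keep[silent, 2]], k + 1L))
    isEv <- c(isEv, rep(FALSE, sum(silent)))
    # reversal moves must consume the next letter
    nxt <- word[k + 1L]
    gene <- if (nxt > N) nxt - N else nxt
    needUp <- nxt > N  # a min is emitted by an upward reversing move
    evSel <- !is.na(ph) & (ph != up) & mover == gene & up == needUp
    if (any(evSel)) {
      pf <- c(pf, pid(loc[keep[evSel, 1]], k + 1L))
      pt <- c(pt, pid(loc[keep[evSel, 2]], (k + 1L) %% L + 1L))
      isEv <- c(isEv, rep(TRUE, sum(evSel)))
    }
  }
  if (!any(isEv)) return(FALSE)
  g <- igraph::graph_from_edgelist(cbind(pf, pt), directed = TRUE)
  memb <- igraph::components(g, "strong")$membership
  any(memb[pf[isEv]] == memb[pt[isEv]])
}

# is the (projected) data graph a total order? if so return the word of
# event codes in chain order, else NULL
.chainWord <- function(dg, eventCode) {
  n <- nrow(dg@events)
  if (n < 2) return(eventCode)
  # a DAG on n events is a total order iff it has n(n-1)/2 edges
  if (nrow(dg@edges) != n * (n - 1) / 2) return(NULL)
  ord <- order(dg@events$time)
  eventCode[ord]
}

# contract strongly connected groups of silent (event-free) edges to
# single nodes; reachability and matches are preserved exactly while the
# layered product shrinks by an order of magnitude
.quotientExpanded <- function(exp) {
  if (!length(exp$from)) return(exp)
  sil <- exp$event == 0L
  nv <- max(exp$from, exp$to)
  if (any(sil)) {
    g <- igraph::make_empty_graph(nv, directed = TRUE)
    g <- igraph::add_edges(g, rbind(exp$from[sil], exp$to[sil]))
    q <- as.integer(igraph::components(g, "strong")$membership)
  } else q <- seq_len(nv)
  qf <- q[exp$from]; qt <- q[exp$to]
  keep <- exp$event > 0L | qf != qt
  key <- paste(qf[keep], qt[keep], exp$event[keep])
  uq <- !duplicated(key)
  list(nNodes = max(q), from = qf[keep][uq], to = qt[keep][uq],
       event = exp$event[keep][uq], stateOf = NULL)
}

# down-set lattice of a data graph; returns list(sets=list of integer
# vectors, index lookup env, nEvents)
.downSets <- function(dg, maxSets = 20000L) {
  n <- nrow(dg@events)
  preds <- vector("list", n)
  if (nrow(dg@edges))
    for (r in seq_len(nrow(dg@edges)))
      preds[[dg@edges[r, 2]]] <- c(preds[[dg@edges[r, 2]]], dg@edges[r, 1])
  keyOf <- function(s) paste0("k", paste(sort(s), collapse = ","))
  sets <- list(integer(0))
  lookup <- new.env(parent = emptyenv())
  assign("k", 1L, envir = lookup)
  q <- 1L
  while (q <= length(sets)) {
    cur <- sets[[q]]
    addable <- setdiff(which(vapply(seq_len(n), function(e)
      all(preds[[e]] %in% cur), TRUE)), cur)
    for (e in addable) {
      s2 <- sort(c(cur, e))
      k <- keyOf(s2)
      if (is.null(lookup[[k]])) {
        sets[[length(sets) + 1L]] <- s2
        lookup[[k]] <- length(sets)
        if (length(sets) > maxSets)
          stop("data-graph down-set lattice exceeds ", maxSets,
               " elements; the event poset is too wide")
      }
    }
    q <- q + 1L
  }
  list(sets = sets, lookup = lookup, n = n, preds = preds)
}

# cyclic match of an expanded component against a data graph:
# product nodes (expanded node, down-set), event edges consume an addable
# event, the full set glues back to the empty set; a match is a product
# SCC containing an event edge.
.cyclicMatch <- function(exp, dgLat, eventCode) {
  # eventCode: integer vector over data-graph events giving their
  # component event code (gene index or gene+N); distinct per event here
  L <- length(dgLat$sets)
  n <- dgLat$n
  if (n == 0) return(TRUE)  # vacuous match by convention
  if (!length(exp$from)) return(FALSE)
  # necessary condition: every data event code must be emitted somewhere
  if (!all(eventCode %in% exp$event)) return(FALSE)
  if (L == n + 1L) return(.cyclicMatchChain(exp, dgLat, eventCode))
  fullKey <- paste0("k", paste(seq_len(n), collapse = ","))
  fullIdx <- dgLat$lookup[[fullKey]]
  # successor table: for set index s and event e addable: target index
  succ <- matrix(NA_integer_, L, n)
  for (s in seq_len(L)) {
    cur <- dgLat$sets[[s]]
    for (e in seq_len(n)) {
      if (e %in% cur) next
      if (!all(dgLat$preds[[e]] %in% cur)) next
      k <- paste0("k", paste(sort(c(cur, e)), collapse = ","))
      tgt <- dgLat$lookup[[k]]
      succ[s, e] <- if (tgt == fullIdx) 1L else tgt  # glue full -> empty
    }
  }
  # build product edge list (vectorized across lattice layers)
  nE <- length(exp$from)
  if (!nE) return(FALSE)
  nn <- exp$nNodes
  silent <- which(exp$event == 0L)
  layers <- setdiff(seq_len(L), fullIdx)
  sf <- exp$from[silent]; stv <- exp$to[silent]
  pf <- rep(sf, length(layers)) +
    nn * rep(layers - 1L, each = length(sf))
  pt <- rep(stv, length(layers)) +
    nn * rep(layers - 1L, each = length(stv))
  ef <- integer(0); et <- integer(0)
  for (de in seq_len(n)) {
    eIdx <- which(exp$event == eventCode[de])
    if (!length(eIdx)) next
    ss <- setdiff(which(!is.na(succ[, de])), fullIdx)
    if (!length(ss)) next
    ef <- c(ef, rep(exp$from[eIdx], length(ss)) +
              nn * rep(ss - 1L, each = length(eIdx)))
    et <- c(et, rep(exp$to[eIdx], length(ss)) +
              nn * rep(succ[ss, de] - 1L, each = length(eIdx)))
  }
  if (!length(ef)) return(FALSE)
  g <- igraph::graph_from_edgelist(cbind(c(pf, ef), c(pt, et)),
                                   directed = TRUE)
  memb <- igraph::components(g, "strong")$membership
  any(memb[ef] == memb[et])
}

# fast path for totally ordered data graphs: the down-set lattice is a
# chain, so the product is a cyclic layered graph over word positions
.cyclicMatchChain <- function(exp, dgLat, eventCode) {
  n <- dgLat$n
  sizes <- lengths(dgLat$sets)
  ordSets <- order(sizes)
  word <- integer(n)
  for (k in seq_len(n)) {
    added <- setdiff(dgLat$sets[[ordSets[k + 1L]]],
                     dgLat$sets[[ordSets[k]]])
    word[k] <- eventCode[added]
  }
  nn <- exp$nNodes
  silent <- exp$event == 0L
  layers <- seq_len(n) - 1L
  sf <- exp$from[silent]; st <- exp$to[silent]
  pf <- rep(sf, n) + nn * rep(layers, each = length(sf))
  pt <- rep(st, n) + nn * rep(layers, each = length(st))
  evIdx <- which(!silent)
  pos <- lapply(exp$event[evIdx], function(cd) which(word == cd))
  reps <- lengths(pos)
  ef <- rep(exp$from[evIdx], reps) + nn * (unlist(pos) - 1L)
  et <- rep(exp$to[evIdx], reps) + nn * (unlist(pos) %% n)
  if (!length(ef)) return(FALSE)
  g <- igraph::graph_from_edgelist(cbind(c(pf, ef), c(pt, et)),
                                   directed = TRUE)
  memb <- igraph::components(g, "strong")$membership
  any(memb[ef] == memb[et])
}

#' Cyclic extremum-event structure of a recurrent component
#'
#' Exposes the component's paths as a searchable labelled graph: nodes
#' are component states expanded by the pending direction of their steady
#' coordinates, and each edge carries at most one extremum event (a gene
#' switching increase-to-decrease emits its max; decrease-to-increase its
#' min).  Also reports one representative cyclic event word obtained by
#' following a cycle through the structure.
#'
#' @param stg a \linkS4class{StateTransitionGraph}.
#' @param morse the corresponding \linkS4class{MorseGraph}.
#' @param component index of a cycle-annotated component.
#' @return list with the expanded graph (\code{nNodes}, \code{from},
#'   \code{to}, \code{event}, \code{stateOf}) and \code{word}, a
#'   character vector like \code{c("max_A", "min_B", ...)} for one cycle.
#' @export
cycleEventSequence <- function(stg, morse, component) {
  ann <- morse@annotation[component]
  if (ann == "fixed_point")
    stop("component ", component, " is a fixed point, not a cycle")
  st <- which(morse@membership == component)
  exp <- .expandComponent(st, stg@directions, stg@edges, .stgStrides(stg))
  N <- ncol(stg@directions)
  lab <- function(code) {
    g <- ((code - 1L) %% N) + 1L
    paste0(if (code > N) "min_" else "max_", stg@nodeNames[g])
  }
  # representative cycle word: walk a cycle in the expanded graph
  g <- igraph::graph_from_edgelist(cbind(exp$from, exp$to), directed = TRUE)
  memb <- igraph::components(g, "strong")$membership
  big <- which.max(tabulate(memb))
  inBig <- which(memb[exp$from] == big & memb[exp$to] == big)
  word <- character(0)
  if (length(inBig)) {
    # follow successors greedily until a node repeats
    adj <- split(inBig, exp$from[inBig])
    start <- exp$from[inBig[1]]
    seen <- integer(0)
    node <- start
    for (step in seq_len(10L * exp$nNodes)) {
      es <- adj[[as.character(node)]]
      if (is.null(es)) break
      e <- es[1]
      if (exp$event[e] > 0L) word <- c(word, lab(exp$event[e]))
      node <- exp$to[e]
      if (node == start && length(word)) break
    }
  }
  c(exp, list(word = word))
}

#' Does a stable cycle realize a data graph's event order?
#'
#' TRUE exactly when some closed path through the component emits the
#' data graph's events (restricted to the network's genes) in an order
#' consistent with its partial order, cyclically: implemented as a cycle
#' search in the product of the expanded component graph and the data
#' graph's down-set (order-ideal) lattice, with the full ideal glued back
#' to the empty one.  An empty data graph matches vacuously.
#'
#' @param stg a \linkS4class{StateTransitionGraph}.
#' @param morse its \linkS4class{MorseGraph}.
#' @param component index of a stable cycle component.
#' @param dataGraph a \linkS4class{DataGraph}; events for genes absent
#'   from the network are projected out before matching.
#' @return logical.
#' @export
patternMatch <- function(stg, morse, component, dataGraph) {
  if (morse@annotation[component] == "fixed_point")
    stop("pattern matching requires a cycle component")
  st <- which(morse@membership == component)
  .patternMatchStates(st, stg@directions, stg@edges, stg@nodeNames,
                      .stgStrides(stg), dataGraph)
}

.projectDataGraph <- function(dataGraph, genes) {
  keep <- which(dataGraph@events$gene %in% genes)
  if (length(keep) == nrow(dataGraph@events)) return(dataGraph)
  ev <- dataGraph@events[keep, , drop = FALSE]
  rownames(ev) <- NULL
  buildDataGraph(ev)
}

.patternMatchStates <- function(states, D, E, nodeNames, strides,
                                dataGraph, lattice = NULL) {
  dg <- .projectDataGraph(dataGraph, nodeNames)
  if (nrow(dg@events) == 0) return(TRUE)  # vacuous match, documented
  N <- length(nodeNames)
  gi <- match(dg@events$gene, nodeNames)
  eventCode <- ifelse(dg@events$kind == "max", gi, gi + N)
  word <- .chainWord(dg, eventCode)
  if (!is.null(word))
    return(.chainMatchDirect(states, D, E, strides, word, N))
  exp <- .quotientExpanded(
    .pruneExpanded(.expandComponent(states, D, E, strides)))
  if (is.null(lattice)) lattice <- .downSets(dg)
  .cyclicMatch(exp, lattice, eventCode)
}

#' Pattern match score of a network against datasets
#'
#' Numerator: stably-oscillating essential parameter regions whose stable
#' full cycle matches at least one dataset's extremum order (per-dataset
#' flags are retained for replicate rules); denominator: stably
#' oscillating essential regions.  Defined as 0 when the denominator is
#' 0.
#'
#' @param net a \linkS4class{RegulatoryNetwork} without self-repression.
#' @param dataGraphs one \linkS4class{DataGraph} or a list of them (one
#'   per dataset/replicate).
#' @param essentialOnly restrict to essential regions (default TRUE).
#' @param regionCap capacity cap, see \code{\link{oscillationScore}}.
#' @return list with \code{score} (match to >= 1 dataset), \code{perDataset}
#'   scores, \code{nOscillating}, \code{nRegions}, and the logical match
#'   matrix \code{matches} (region x dataset).
#' @export
patternMatchScore <- function(net, dataGraphs, essentialOnly = TRUE,
                              regionCap = 3000) {
  if (is(dataGraphs, "DataGraph")) dataGraphs <- list(dataGraphs)
  if (hasSelfRepression(net))
    stop("pattern matching is not supported for self-repressing edges")
  regs <- enumerateParameterRegions(net, essentialOnly, cap = regionCap)
  m <- outDegrees(net)
  X <- .stateMatrix(m)
  outT <- .outTargets(net)
  strides <- cumprod(c(1, (m + 1L)[-length(m)]))
  dgs <- lapply(dataGraphs, .projectDataGraph, genes = net@nodes)
  N <- length(net@nodes)
  codes <- lapply(dgs, function(d) {
    gi <- match(d@events$gene, net@nodes)
    ifelse(d@events$kind == "max", gi, gi + N)
  })
  words <- lapply(seq_along(dgs), function(ds)
    .chainWord(dgs[[ds]], codes[[ds]]))
  lats <- lapply(seq_along(dgs), function(ds) {
    if (nrow(dgs[[ds]]@events) && is.null(words[[ds]]))
      .downSets(dgs[[ds]]) else NULL
  })
  nR <- length(regs)
  osc <- logical(nR)
  matches <- matrix(FALSE, nR, length(dgs))
  for (r in seq_len(nR)) {
    dyn <- .regionDynamics(net, X, outT, strides, regs[[r]])
    if (!length(dyn$stableFullCycles)) next
    osc[r] <- TRUE
    exps <- NULL  # built lazily, only for non-chain data graphs
    for (ds in seq_along(dgs)) {
      dg <- dgs[[ds]]
      if (nrow(dg@events) == 0) { matches[r, ds] <- TRUE; next }
      if (!is.null(words[[ds]])) {
        for (st in dyn$stableFullCycles) {
          if (.chainMatchDirect(st, dyn$D, dyn$E, strides,
                                words[[ds]], N)) {
            matches[r, ds] <- TRUE
            break
          }
        }
        next
      }
      if (is.null(exps))
        exps <- lapply(dyn$stableFullCycles, function(st)
          .quotientExpanded(
            .pruneExpanded(.expandComponent(st, dyn$D, dyn$E, strides))))
      for (exp in exps) {
        if (.cyclicMatch(exp, lats[[ds]], codes[[ds]])) {
          matches[r, ds] <- TRUE
          break
        }
      }
    }
  }
  nOsc <- sum(osc)
  per <- if (nOsc == 0) rep(0, length(dgs)) else colSums(matches) / nOsc
  overall <- if (nOsc == 0) 0 else sum(rowSums(matches) > 0) / nOsc
  list(score = overall, perDataset = per, nOscillating = nOsc,
       nRegions = nR, matches = matches, oscillating = osc)
}

# strides of the state index per node, recovered from an STG's states
.stgStrides <- function(stg) {
  m <- apply(stg@states, 2, max)
  cumprod(c(1, (m + 1L)[-length(m)]))
}

#' Write/read a data graph as TSV
#'
#' Events with their identifiers, gene, kind and uncertainty interval,
#' followed by the precedence pairs, in one tab-delimited file.
#'
#' @param dg a \linkS4class{DataGraph}.
#' @param path file path.
#' @return \code{path} (write) or a \linkS4class{DataGraph} (read).
#' @export
writeDataGraph <- function(dg, path) {
  stopifnot(is(dg, "DataGraph"))
  ev <- dg@events
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("event_id\tgene\tkind\ttime\tt_lo\tt_hi", con)
  for (i in seq_len(nrow(ev)))
    writeLines(paste(i, ev$gene[i], ev$kind[i], ev$time[i], ev$tLo[i],
                     ev$tHi[i], sep = "\t"), con)
  writeLines("# precedence", con)
  e <- dg@edges
  for (r in seq_len(nrow(e)))
    writeLines(paste(e[r, 1], e[r, 2], sep = "\t"), con)
  invisible(path)
}

#' @rdname writeDataGraph
#' @export
readDataGraph <- function(path) {
  lines <- readLines(path)
  cut <- which(lines == "# precedence")
  ev <- read.table(text = lines[2:(cut - 1)], sep = "\t",
                   col.names = c("event_id", "gene", "kind", "time",
                                 "t_lo", "t_hi"),
                   stringsAsFactors = FALSE)
  events <- data.frame(gene = ev$gene, kind = ev$kind, time = ev$time,
                       tLo = ev$t_lo, tHi = ev$t_hi,
                       stringsAsFactors = FALSE)
  buildDataGraph(events)
}
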