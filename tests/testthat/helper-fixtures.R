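# Shared fixtures and independent oracles used across the test files.

toyTss <- function(nGenes = 3, nTimes = 5, seed = 42) {
  set.seed(seed)
  v <- matrix(runif(nGenes * nTimes, 1, 10), nGenes, nTimes,
              dimnames = list(paste0("g", seq_len(nGenes)), NULL))
  TimeSeriesSet(v, seq_len(nTimes))
}

negLoop <- function() parseNetwork(c("A : ~B", "B : A"))
posLoop <- function() parseNetwork(c("A : B", "B : A"))
repressilator <- function() parseNetwork(c("A : ~C", "B : ~A", "C : ~B"))

mkEvents <- function(genes, kinds, times, lo = times, hi = times) {
  data.frame(gene = genes, kind = kinds, time = times, tLo = lo, tHi = hi,
             stringsAsFactors = FALSE)
}

# all permutations of 1..n as rows (n small)
combinat_perms <- function(n) {
  permsOf <- function(v) {
    if (length(v) <= 1) return(matrix(v, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], permsOf(v[-i]))))
  }
  permsOf(seq_len(n))
}

# --- independent strong-connectivity / SCC oracle (Warshall closure) ---
reachOracle <- function(n, edges) {
  R <- diag(n) > 0
  if (nrow(edges)) for (r in seq_len(nrow(edges)))
    R[edges[r, 1], edges[r, 2]] <- TRUE
  for (k in seq_len(n)) R <- R | (outer(R[, k], R[k, ], "&"))
  R
}

sccOracle <- function(n, edges) {
  R <- reachOracle(n, edges)
  memb <- integer(n)
  cc <- 0L
  for (i in seq_len(n)) {
    if (memb[i] > 0) next
    cc <- cc + 1L
    memb[R[i, ] & R[, i]] <- cc
  }
  memb
}

stronglyConnectedOracle <- function(net) {
  el <- edgeList(net)
  nodes <- nodeNames(net)
  if (!nrow(el)) return(length(nodes) == 1 && FALSE)
  E <- cbind(match(el$source, nodes), match(el$target, nodes))
  all(reachOracle(length(nodes), E))
}

# --- randomized-witness brute force for per-node region counts ---------
# draws many positive parameter sets and collects the distinct
# (logic, order) patterns they realize
witnessRegionCount <- function(groups, m, essentialOnly = FALSE,
                               nDraws = 40000, seed = 7) {
  set.seed(seed)
  nIn <- length(unlist(groups))
  S <- coreosc:::.inputStates(nIn)
  pats <- new.env(parent = emptyenv())
  for (d in seq_len(nDraws)) {
    l <- exp(runif(nIn, -3, 3))
    u <- l + exp(runif(nIn, -3, 3))
    th <- exp(runif(m, -3, 3))
    p <- coreosc:::.prodValues(S, groups, l, u)
    ord <- order(th)
    lam <- vapply(p, function(x) sum(x > th), 0L)
    if (essentialOnly) {
      if (!coreosc:::.lambdaEssential(S, lam, m)) next
    }
    rankOfEdge <- match(seq_len(m), ord)  # threshold rank per out-edge
    key <- paste(c(lam, rankOfEdge), collapse = ",")
    assign(key, TRUE, envir = pats)
  }
  length(ls(pats))
}

# --- exhaustive cyclic pattern-match oracle ----------------------------
# enumerates elementary cycles of the expanded component graph, extracts
# their cyclic event words, and tests whether any rotation of any word is
# a linear extension of the data poset consumed exactly once
linearExtensions <- function(n, preds) {
  res <- list()
  rec <- function(done, rest) {
    if (!length(rest)) { res[[length(res) + 1]] <<- done; return(invisible()) }
    for (e in rest) if (all(preds[[e]] %in% done))
      rec(c(done, e), setdiff(rest, e))
  }
  rec(integer(0), seq_len(n))
  res
}

patternMatchOracle <- function(stg, morse, component, dataGraph) {
  dg <- coreosc:::.projectDataGraph(dataGraph, nodeNames(stg))
  n <- nrow(eventTable(dg))
  if (n == 0) return(TRUE)
  st <- which(morse@membership == component)
  exp <- coreosc:::.expandComponent(st, stg@directions, stg@edges,
                                    coreosc:::.stgStrides(stg))
  N <- length(nodeNames(stg))
  gi <- match(eventTable(dg)$gene, nodeNames(stg))
  code <- ifelse(eventTable(dg)$kind == "max", gi, gi + N)
  preds <- vector("list", n)
  el <- edgeList(dg)
  if (nrow(el)) for (r in seq_len(nrow(el)))
    preds[[el[r, 2]]] <- c(preds[[el[r, 2]]], el[r, 1])
  lex <- linearExtensions(n, preds)
  # enumerate cyclic event words of closed walks (bounded depth DFS over
  # edges, tracking event words up to length n, allowing silent edges)
  target <- new.env(parent = emptyenv())
  for (L in lex) for (r in seq_len(n)) {
    w <- code[c(L[r:n], L[seq_len(r - 1)])]
    assign(paste(w, collapse = ","), TRUE, envir = target)
  }
  adj <- split(seq_along(exp$from), exp$from)
  found <- FALSE
  walk <- function(node, start, word, steps) {
    if (found || steps > 4L * exp$nNodes) return(invisible())
    if (node == start && length(word) == n) {
      if (!is.null(target[[paste(word, collapse = ",")]])) found <<- TRUE
      return(invisible())
    }
    if (length(word) > n) return(invisible())
    for (e in adj[[as.character(node)]]) {
      ev <- exp$event[e]
      walk(exp$to[e], start, if (ev > 0) c(word, ev) else word, steps + 1L)
    }
  }
  for (s in unique(exp$from)) { if (found) break; walk(s, s, integer(0), 0L) }
  found
}
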