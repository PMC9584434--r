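# Stochastic neighbourhood search in network space around a seed network
# built from the top of the local edge ranking.

#' Seed network from a pld threshold
#'
#' The network induced by all edges whose pld exceeds the threshold;
#' possibly empty (an empty seed is legal and used as a control).
#'
#' @param localRanking edge \linkS4class{RankingTable} from
#'   \code{\link{localEdgeRanking}}.
#' @param pldThreshold threshold in [0, 1]; edges with \code{pld >
#'   threshold} enter the seed.
#' @return a \linkS4class{RegulatoryNetwork} (product input algebra).
#' @export
seedNetwork <- function(localRanking, pldThreshold = 0.98) {
  stopifnot(pldThreshold >= 0, pldThreshold <= 1)
  it <- rankedItems(localRanking)
  sel <- it[it$score > pldThreshold, , drop = FALSE]
  nodes <- sort(unique(c(sel$target, sel$source)))
  regulatoryNetwork(nodes, sel[, c("target", "source", "sign")])
}

#' Candidate edge list for network sampling
#'
#' The seed's edges plus the next \code{k} edges of the local ranking,
#' with self-repressing edges removed (they are not supported by the
#' pattern matcher).  The size of this list is also the worst-rank
#' constant of the global edge ranking.
#'
#' @param localRanking edge \linkS4class{RankingTable}.
#' @param seed the seed \linkS4class{RegulatoryNetwork}.
#' @param k number of additional ranked edges (user choice).
#' @return data.frame of candidate edges with their local rank; seed
#'   edges first, then the next \code{k} by rank.
#' @export
topLemEdges <- function(localRanking, seed, k = 40) {
  it <- rankedItems(localRanking)
  seedEdges <- edgeList(seed)
  seedKey <- .edgeKey(seedEdges$target, seedEdges$source, seedEdges$sign)
  inSeed <- it$item %in% seedKey
  rest <- it[!inSeed, , drop = FALSE]
  rest <- rest[order(rest$rank), , drop = FALSE]
  extra <- head(rest, k)
  cand <- rbind(it[inSeed, , drop = FALSE], extra)
  selfRep <- cand$target == cand$source & cand$sign == "repression"
  if (any(selfRep))
    .msg("removed ", sum(selfRep), " self-repressing candidate edge(s)")
  cand <- cand[!selfRep, , drop = FALSE]
  cand <- cand[order(cand$rank), , drop = FALSE]
  rownames(cand) <- NULL
  cand[, c("item", "target", "source", "sign", "score", "rank")]
}

.netFromEdges <- function(edges) {
  nodes <- sort(unique(c(edges$target, edges$source)))
  regulatoryNetwork(nodes, edges)
}

.canonicalKey <- function(edges) {
  k <- .edgeKey(edges$target, edges$source, edges$sign)
  paste(sort(k), collapse = ";")
}

#' Sample strongly connected candidate networks around a seed
#'
#' Repeatedly perturbs the seed by a random number of moves (each move
#' type drawn by \code{moveProbs}: add a node with an incident candidate
#' edge, add an unused candidate edge, drop a node, drop an edge) and
#' accepts the result when it is strongly connected, within the
#' parameter-region cap and free of self-repression.  Accepted networks
#' are deduplicated by canonical serialization; sampling continues until
#' \code{m} unique networks or the attempt budget is exhausted.
#'
#' @param seed seed \linkS4class{RegulatoryNetwork}.
#' @param candidates candidate edge table from \code{\link{topLemEdges}}.
#' @param m number of unique networks requested.
#' @param moveProbs probabilities (addNode, addEdge, dropNode, dropEdge)
#'   summing to 1.
#' @param opRange integer range of operations per attempt.
#' @param regionCap maximal number of essential parameter regions.
#' @param maxAttempts attempt budget; an acceptance rate below
#'   \code{m / maxAttempts} raises an error suggesting revised
#'   hyperparameters.
#' @return list with \code{networks} (list of RegulatoryNetwork),
#'   \code{manifest} data.frame (network_id, serialized network,
#'   n_regions) and \code{rejections} (counts by reason).
#' @export
sampleNetworks <- function(seed, candidates, m = 2000,
                           moveProbs = c(addNode = 0.1, addEdge = 0.9,
                                         dropNode = 0, dropEdge = 0),
                           opRange = 2:10, regionCap = 3000,
                           maxAttempts = 50 * m) {
  stopifnot(abs(sum(moveProbs) - 1) < 1e-9, all(moveProbs >= 0),
            length(opRange) >= 1, m >= 1)
  if (any(candidates$target == candidates$source &
          candidates$sign == "repression"))
    stop("candidate list contains a self-repressing edge")
  seedEdges <- edgeList(seed)
  found <- new.env(parent = emptyenv())
  nets <- list()
  manifest <- NULL
  rej <- c(not_strongly_connected = 0L, region_cap = 0L, duplicate = 0L,
           degenerate = 0L)
  moveNames <- c("addNode", "addEdge", "dropNode", "dropEdge")
  attempts <- 0L
  candKey <- .edgeKey(candidates$target, candidates$source, candidates$sign)
  while (length(nets) < m && attempts < maxAttempts) {
    attempts <- attempts + 1L
    cur <- seedEdges
    nOps <- if (length(opRange) == 1) opRange else sample(opRange, 1)
    nApplied <- 0L
    for (op in seq_len(nOps)) {
      done <- FALSE
      for (try in seq_len(10L)) {
        mv <- sample(moveNames, 1, prob = moveProbs)
        curPair <- if (nrow(cur)) paste(cur$target, cur$source)
                   else character(0)
        curNodes <- unique(c(cur$target, cur$source))
        # an unused candidate must not duplicate a present (target,
        # source) pair with either sign: one signed edge per ordered pair
        unused <- which(!paste(candidates$target, candidates$source) %in%
                          curPair)
        if (mv == "addEdge") {
          avail <- if (nrow(cur) == 0) unused else
            unused[candidates$target[unused] %in% curNodes &
                   candidates$source[unused] %in% curNodes]
          if (length(avail)) {
            e <- if (length(avail) == 1) avail else sample(avail, 1)
            cur <- rbind(cur, candidates[e, c("target", "source", "sign")])
            done <- TRUE
          }
        } else if (mv == "addNode") {
          outside <- setdiff(unique(c(candidates$target, candidates$source)),
                             curNodes)
          if (nrow(cur) == 0 && length(unused)) {
            e <- if (length(unused) == 1) unused else sample(unused, 1)
            cur <- rbind(cur, candidates[e, c("target", "source", "sign")])
            done <- TRUE
          } else if (length(outside)) {
            nd <- if (length(outside) == 1) outside else sample(outside, 1)
            inc <- unused[(candidates$target[unused] == nd &
                             candidates$source[unused] %in% c(curNodes, nd)) |
                          (candidates$source[unused] == nd &
                             candidates$target[unused] %in% c(curNodes, nd))]
            if (length(inc)) {
              # prefer connecting the node in both directions at once
              into <- inc[candidates$target[inc] == nd]
              outof <- inc[candidates$source[inc] == nd]
              pick <- integer(0)
              if (length(into)) pick <- c(pick, if (length(into) == 1) into
                                          else sample(into, 1))
              if (length(outof)) pick <- c(pick, if (length(outof) == 1) outof
                                           else sample(outof, 1))
              pick <- unique(pick)
              cur <- rbind(cur, candidates[pick,
                                           c("target", "source", "sign")])
              done <- TRUE
            }
          }
        } else if (mv == "dropEdge") {
          if (nrow(cur) > 0) {
            e <- sample(nrow(cur), 1)
            cur <- cur[-e, , drop = FALSE]
            done <- TRUE
          }
        } else if (mv == "dropNode") {
          if (length(curNodes) > 1) {
            nd <- sample(curNodes, 1)
            cur <- cur[cur$target != nd & cur$source != nd, , drop = FALSE]
            done <- TRUE
          }
        }
        if (done) break
      }
      if (!done) break  # no applicable move left: stop early, then try
                        # to accept what was applied so far
      nApplied <- nApplied + 1L
    }
    if (nApplied == 0L || nrow(cur) == 0) {
      rej["degenerate"] <- rej["degenerate"] + 1L
      next
    }
    net <- .netFromEdges(cur)
    if (!isStronglyConnected(net)) {
      rej["not_strongly_connected"] <- rej["not_strongly_connected"] + 1L
      next
    }
    key <- .canonicalKey(cur)
    if (!is.null(found[[key]])) { rej["duplicate"] <- rej["duplicate"] + 1L; next }
    nReg <- tryCatch(countParameterRegions(net, essentialOnly = TRUE),
                     error = function(e) Inf)  # e.g. in-degree capacity
    if (nReg > regionCap) { rej["region_cap"] <- rej["region_cap"] + 1L; next }
    found[[key]] <- TRUE
    nets[[length(nets) + 1L]] <- net
    manifest <- rbind(manifest, data.frame(
      network_id = length(nets),
      network = paste(serializeNetwork(net), collapse = " / "),
      n_regions = nReg, stringsAsFactors = FALSE))
  }
  if (length(nets) < m)
    stop("sampler accepted only ", length(nets), " of the requested ", m,
         " networks within ", maxAttempts, " attempts; revise the ",
         "hyperparameters (candidate count, move probabilities, caps)")
  list(networks = nets, manifest = manifest, rejections = rej,
       attempts = attempts)
}
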