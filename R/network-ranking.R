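# Top-network selection, edge prevalence, global rankings and the
# local-versus-global comparison report.

#' Score a list of candidate networks
#'
#' Computes the oscillation and pattern match scores of each sampled
#' network against the datasets' extremum orders.
#'
#' @param networks list of \linkS4class{RegulatoryNetwork}.
#' @param dataGraphs list of \linkS4class{DataGraph} (one per replicate
#'   or dataset).
#' @param regionCap per-network parameter-region cap.
#' @return data.frame with network_id, oscillation_score,
#'   pattern_match_score and one match column per dataset (proportion of
#'   stably oscillating regions matching that dataset).
#' @export
scoreNetworks <- function(networks, dataGraphs, regionCap = 3000) {
  if (is(dataGraphs, "DataGraph")) dataGraphs <- list(dataGraphs)
  rows <- lapply(seq_along(networks), function(i) {
    pm <- patternMatchScore(networks[[i]], dataGraphs,
                            regionCap = regionCap)
    osc <- pm$nOscillating / max(pm$nRegions, 1L)
    row <- data.frame(network_id = i, oscillation_score = osc,
                      pattern_match_score = pm$score)
    for (ds in seq_along(dataGraphs))
      row[[paste0("match_ds", ds)]] <- pm$perDataset[ds]
    row
  })
  do.call(rbind, rows)
}

#' Select top-ranked networks by score criteria
#'
#' @param scores data.frame from \code{\link{scoreNetworks}}.
#' @param oscillationWindow numeric c(lo, hi) window for the oscillation
#'   score (inclusive).
#' @param patternMatchMin minimal pattern match score (inclusive).
#' @param replicateRule \code{"any"} (default) or \code{"all"}: with
#'   \code{"all"}, every dataset must be matched by at least one stably
#'   oscillating region.
#' @return the selected subset of \code{scores}; an empty selection is
#'   allowed but reported loudly.
#' @export
selectTopNetworks <- function(scores, oscillationWindow = c(1, 1),
                              patternMatchMin = 0.5,
                              replicateRule = c("any", "all")) {
  replicateRule <- match.arg(replicateRule)
  if (oscillationWindow[1] > oscillationWindow[2])
    stop("malformed oscillation window (lo > hi)")
  keep <- scores$oscillation_score >= oscillationWindow[1] &
    scores$oscillation_score <= oscillationWindow[2] &
    scores$pattern_match_score >= patternMatchMin
  if (replicateRule == "all") {
    dsCols <- grep("^match_ds", names(scores), value = TRUE)
    for (cl in dsCols) keep <- keep & scores[[cl]] > 0
  }
  out <- scores[keep, , drop = FALSE]
  if (nrow(out) == 0)
    warning("no network meets the top-network criteria; downstream ",
            "prevalence tables will be empty")
  rownames(out) <- NULL
  out
}

#' Edge prevalence over the top-ranked networks
#'
#' For every candidate edge, the proportion of top networks containing
#' it (edges appearing in no top network get prevalence 0).
#'
#' @param topNetworks list of \linkS4class{RegulatoryNetwork} selected by
#'   \code{\link{selectTopNetworks}}.
#' @param candidates candidate edge table from \code{\link{topLemEdges}}.
#' @return data.frame with item, target, source, sign, n_top, prevalence.
#' @export
edgePrevalence <- function(topNetworks, candidates) {
  tCount <- length(topNetworks)
  if (tCount == 0)
    warning("no top networks; all prevalence scores are zero")
  n <- integer(nrow(candidates))
  for (net in topNetworks) {
    e <- edgeList(net)
    k <- .edgeKey(e$target, e$source, e$sign)
    n <- n + as.integer(candidates$item %in% k)
  }
  data.frame(item = candidates$item, target = candidates$target,
             source = candidates$source, sign = candidates$sign,
             local_rank = candidates$rank, n_top = n,
             prevalence = if (tCount > 0) n / tCount else 0,
             stringsAsFactors = FALSE)
}

#' Global edge ranking from prevalence scores
#'
#' Descending by prevalence; ties broken by ascending local rank.  Every
#' zero-prevalence edge is assigned the single worst possible rank: the
#' number of top-ranked candidate edges.
#'
#' @param prevalences data.frame from \code{\link{edgePrevalence}}.
#' @param worstRank the worst-rank constant (defaults to
#'   \code{nrow(prevalences)}, the candidate count).
#' @return a \linkS4class{RankingTable} whose extra columns carry the
#'   prevalence bookkeeping.
#' @export
globalEdgeRanking <- function(prevalences, worstRank = nrow(prevalences)) {
  p <- prevalences
  ord <- order(-p$prevalence, p$local_rank, p$item, method = "radix")
  p <- p[ord, , drop = FALSE]
  p$rank <- seq_len(nrow(p))
  p$rank[p$prevalence == 0] <- worstRank
  p <- p[, c("item", "prevalence", "rank", "target", "source", "sign",
             "local_rank", "n_top")]
  names(p)[2] <- "score"
  rownames(p) <- NULL
  new("RankingTable", items = p, direction = "higher_is_better",
      tiebreakNote = paste("prevalence ties broken by local edge rank;",
                           "zero-prevalence edges share the worst rank",
                           worstRank))
}

#' Compare local and global node participation
#'
#' Both participation scores are computed on a shared edge restriction
#' (typically the intersection of the top-ranked candidate edges across
#' runs); nodes with a negative delta (global better than local) are the
#' upranked experiment-prioritisation candidates.
#'
#' @param localParticipation \linkS4class{RankingTable} from
#'   \code{\link{nodeParticipation}} on the local edge ranking.
#' @param globalParticipation likewise on the global edge ranking.
#' @return data.frame with node, local_score, global_score, delta
#'   (global - local; negative = upranked) and an \code{upranked} flag.
#' @export
compareRankings <- function(localParticipation, globalParticipation) {
  lo <- rankedItems(localParticipation)
  gl <- rankedItems(globalParticipation)
  nodes <- intersect(lo$item, gl$item)
  if (!length(nodes)) stop("empty node restriction in ranking comparison")
  ls <- lo$score[match(nodes, lo$item)]
  gs <- gl$score[match(nodes, gl$item)]
  data.frame(node = nodes, local_score = ls, global_score = gs,
             delta = gs - ls, upranked = gs < ls,
             stringsAsFactors = FALSE)
}
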