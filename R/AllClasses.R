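#' TimeSeriesSet: named gene expression traces on a shared time grid
#'
#' The universal input container of the package: a genes-by-times numeric
#' matrix together with the (strictly increasing) sampling times and a
#' replicate label.  Row names are the gene identifiers and must be unique.
#'
#' @slot values numeric matrix, genes in rows, time points in columns.
#' @slot times numeric vector of sampling times, strictly increasing,
#'   length equal to \code{ncol(values)}.
#' @slot replicateId single character label for the replicate.
#' @export
setClass("TimeSeriesSet",
  representation(values = "matrix", times = "numeric", replicateId = "character"),
  prototype(values = matrix(0, 0, 0), times = numeric(0), replicateId = "rep1"))

setValidity("TimeSeriesSet", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (length(object@times) != ncol(v))
    return("length(times) must equal ncol(values)")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("'times' must be strictly increasing")
  if (is.null(rownames(v)) && nrow(v) > 0)
    return("'values' must have gene names as row names")
  if (anyDuplicated(rownames(v)))
    return("gene names must be unique within a replicate")
  if (length(object@replicateId) != 1L)
    return("'replicateId' must be a single label")
  TRUE
})

#' RankingTable: ordered list of scored items
#'
#' Holds one of the pipeline's rankings (nodes, edges or networks).  Ranks
#' are 1-based and consistent with \code{direction}; score ties are broken
#' by the stable lexicographic order of the item keys and the applied rule
#' is recorded in \code{tiebreakNote}.
#'
#' @slot items data.frame with at least columns \code{item}, \code{score},
#'   \code{rank} (additional per-item columns are preserved).
#' @slot direction either \code{"lower_is_better"} or
#'   \code{"higher_is_better"}.
#' @slot tiebreakNote character note recording the tie-break rule.
#' @export
setClass("RankingTable",
  representation(items = "data.frame", direction = "character",
                 tiebreakNote = "character"))

setValidity("RankingTable", function(object) {
  it <- object@items
  if (!all(c("item", "score", "rank") %in% names(it)))
    return("items must have columns item, score, rank")
  if (!object@direction %in% c("lower_is_better", "higher_is_better"))
    return("direction must be lower_is_better or higher_is_better")
  if (nrow(it) > 0) {
    if (anyDuplicated(it$item)) return("item keys must be unique")
    r <- it$rank
    # ranks are 1..n except for the documented worst-rank collapse, in
    # which several zero-prevalence edges share a single worst value
    if (any(r < 1)) return("ranks must be >= 1")
    s <- it$score
    ord <- if (object@direction == "lower_is_better") diff(s[order(r)]) else
      -diff(s[order(r)])
    if (any(ord < -1e-12)) return("ordering inconsistent with direction")
  }
  TRUE
})

#' RegulatoryNetwork: signed digraph with sum-of-products input algebra
#'
#' Each node carries an input algebra: its in-edges are partitioned into
#' groups; contributions are summed within a group and the group sums are
#' multiplied.  Each in-edge is signed (activation or repression).  A
#' node's out-edges are ordered; the switching-system model assigns one
#' threshold per out-edge, so a node with \code{d} out-edges has
#' \code{d + 1} qualitative expression levels.
#'
#' @slot nodes character vector of node names (unique, nonempty).
#' @slot inputs list (per node) of data.frames with columns \code{source}
#'   (index into \code{nodes}) and \code{sign} (+1 activation, -1
#'   repression).
#' @slot groups list (per node) of lists of integer vectors partitioning
#'   that node's in-edge indices into product groups.
#' @export
setClass("RegulatoryNetwork",
  representation(nodes = "character", inputs = "list", groups = "list"))

setValidity("RegulatoryNetwork", function(object) {
  n <- length(object@nodes)
  if (n == 0) return(TRUE)  # empty network is legal (empty seed)
  if (anyDuplicated(object@nodes)) return("node names must be unique")
  if (length(object@inputs) != n || length(object@groups) != n)
    return("inputs and groups must have one entry per node")
  for (i in seq_len(n)) {
    inp <- object@inputs[[i]]
    if (nrow(inp) == 0) next
    if (any(inp$source < 1 | inp$source > n)) return("unknown source index")
    if (any(!inp$sign %in% c(-1, 1))) return("sign must be +1 or -1")
    if (anyDuplicated(inp$source))
      return("at most one edge per (source, target) pair")
    gr <- unlist(object@groups[[i]])
    if (!setequal(gr, seq_len(nrow(inp))) || anyDuplicated(gr))
      return("groups must partition the in-edge indices")
  }
  TRUE
})

#' DataGraph: partial order of labelled extremum events
#'
#' Events are local maxima/minima of the gene traces with an uncertainty
#' interval at a given noise level; an edge (e1, e2) is present exactly
#' when the interval of e1 wholly precedes the interval of e2, so the
#' graph is a DAG.
#'
#' @slot events data.frame with columns \code{gene}, \code{kind}
#'   ("max"/"min"), \code{time}, \code{tLo}, \code{tHi}.
#' @slot edges two-column integer matrix of precedence pairs
#'   (row indices into \code{events}).
#' @export
setClass("DataGraph",
  representation(events = "data.frame", edges = "matrix"))

setValidity("DataGraph", function(object) {
  ev <- object@events
  need <- c("gene", "kind", "time", "tLo", "tHi")
  if (!all(need %in% names(ev))) return("events missing required columns")
  if (nrow(ev) > 0) {
    if (any(!ev$kind %in% c("max", "min"))) return("kind must be max/min")
    if (any(ev$tLo > ev$time | ev$time > ev$tHi))
      return("need tLo <= time <= tHi")
  }
  e <- object@edges
  if (nrow(e) > 0) {
    if (ncol(e) != 2) return("edges must have two columns")
    if (any(e < 1 | e > nrow(ev))) return("edge endpoint out of range")
    g <- igraph::graph_from_edgelist(e)
    if (!igraph::is_dag(g)) return("precedence relation must be acyclic")
  }
  TRUE
})

#' StateTransitionGraph: qualitative dynamics of one parameter region
#'
#' States are the product of per-node qualitative levels; directed edges
#' are admissible single-node level steps; \code{directions} records, per
#' state and node, whether the node's production pushes it up (+1), down
#' (-1) or keeps it steady (0).
#'
#' @slot states integer matrix, one row per state, one column per node.
#' @slot edges two-column integer matrix of state transitions.
#' @slot directions integer matrix parallel to \code{states}.
#' @slot nodeNames character vector of node names.
#' @export
setClass("StateTransitionGraph",
  representation(states = "matrix", edges = "matrix",
                 directions = "matrix", nodeNames = "character"))

setValidity("StateTransitionGraph", function(object) {
  if (!identical(dim(object@states), dim(object@directions)))
    return("states and directions must have the same shape")
  if (nrow(object@edges) > 0 &&
      (max(object@edges) > nrow(object@states) || min(object@edges) < 1))
    return("edge endpoint out of range")
  TRUE
})

#' MorseGraph: condensation of a state transition graph
#'
#' The DAG of strongly connected components of an STG.  Leaves (components
#' with no exits) are the stable behaviours.  Each component is annotated
#' as a fixed point, a cycle, or a full cycle (a recurrent component in
#' which every network node attains both a local-max and a local-min
#' event).
#'
#' @slot membership integer vector mapping each STG state to a component.
#' @slot condensation two-column integer matrix of component-level edges.
#' @slot stable logical per component (leaf of the condensation).
#' @slot annotation character per component: \code{"fixed_point"},
#'   \code{"cycle"} or \code{"full_cycle"}.
#' @export
setClass("MorseGraph",
  representation(membership = "integer", condensation = "matrix",
                 stable = "logical", annotation = "character"))

setValidity("MorseGraph", function(object) {
  k <- length(object@stable)
  if (length(object@annotation) != k)
    return("one annotation per component required")
  if (any(!object@annotation %in% c("fixed_point", "cycle", "full_cycle")))
    return("bad annotation value")
  if (nrow(object@condensation) > 0) {
    g <- igraph::graph_from_edgelist(object@condensation)
    if (!igraph::is_dag(g)) return("condensation must be a DAG")
  }
  TRUE
})
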