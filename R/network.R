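#' Construct a RegulatoryNetwork from an edge table
#'
#' @param nodes character vector of node names.
#' @param edges data.frame with columns \code{target}, \code{source},
#'   \code{sign} ("activation"/"repression" or +1/-1).
#' @param groups optional list (named by target) of lists of source-name
#'   vectors giving the input algebra; by default every in-edge forms its
#'   own product group (pure product algebra).
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
regulatoryNetwork <- function(nodes, edges, groups = NULL) {
  n <- length(nodes)
  inputs <- vector("list", n)
  grp <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- edges$target == nodes[i]
    e <- edges[sel, , drop = FALSE]
    sg <- if (is.character(e$sign))
      ifelse(e$sign == "repression", -1L, 1L) else as.integer(e$sign)
    src <- match(e$source, nodes)
    if (anyNA(src)) stop("unknown source name: ",
                         paste(e$source[is.na(src)], collapse = ", "))
    inputs[[i]] <- data.frame(source = src, sign = sg)
    grp[[i]] <- if (!is.null(groups) && !is.null(groups[[nodes[i]]])) {
      lapply(groups[[nodes[i]]], function(g) match(g, nodes[src]))
    } else {
      as.list(seq_len(nrow(e)))
    }
  }
  new("RegulatoryNetwork", nodes = nodes, inputs = inputs, groups = grp)
}

#' Parse a regulatory network from its text format
#'
#' One line per target: \code{Target : (S1 + S2)(~S3)}.  Sources inside a
#' parenthesised group are summed; adjacent groups are multiplied;
#' \code{~} marks repression.  A single group may omit the parentheses.
#'
#' @param text character vector of lines (or a single newline-separated
#'   string).
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
parseNetwork <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(new("RegulatoryNetwork", nodes = character(0),
                                 inputs = list(), groups = list()))
  parts <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(parts) > 2 | !grepl(":", lines, fixed = TRUE)
  if (any(bad)) stop("malformed network line (expected 'Target : expr'): ",
                     lines[bad][1])
  nodes <- trimws(vapply(parts, `[[`, "", 1L))
  if (anyDuplicated(nodes)) stop("duplicate target line for node ",
                                 nodes[duplicated(nodes)][1])
  exprs <- trimws(vapply(parts, function(p)
    if (length(p) >= 2) p[[2]] else "", ""))
  if (any(!nzchar(exprs)))
    stop("empty expression for node ", nodes[!nzchar(exprs)][1])
  parseGroup <- function(s, line) {
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    if (!length(terms) || any(!nzchar(terms)))
      stop("empty expression in network line: ", line)
    sign <- ifelse(startsWith(terms, "~"), -1L, 1L)
    src <- trimws(sub("^~\\s*", "", terms))
    list(src = src, sign = sign)
  }
  edges <- NULL
  groups <- list()
  for (i in seq_along(nodes)) {
    s <- exprs[i]
    if (!nzchar(s)) stop("empty expression for node ", nodes[i])
    if (grepl("(", s, fixed = TRUE)) {
      if (lengths(regmatches(s, gregexpr("(", s, fixed = TRUE))) !=
          lengths(regmatches(s, gregexpr(")", s, fixed = TRUE))))
        stop("malformed parentheses in network line: ", lines[i])
      gs <- regmatches(s, gregexpr("\\(([^()]*)\\)", s))[[1]]
      rest <- trimws(gsub("\\(([^()]*)\\)", "", s))
      if (nzchar(rest))
        stop("malformed expression (tokens outside groups) in: ", lines[i])
      gs <- sub("^\\(", "", sub("\\)$", "", gs))
    } else {
      gs <- s
    }
    glist <- lapply(gs, parseGroup, line = lines[i])
    gnames <- list()
    for (g in glist) {
      edges <- rbind(edges, data.frame(
        target = nodes[i], source = g$src,
        sign = ifelse(g$sign > 0, "activation", "repression"),
        stringsAsFactors = FALSE))
      gnames[[length(gnames) + 1L]] <- g$src
    }
    groups[[nodes[i]]] <- gnames
  }
  unknown <- setdiff(edges$source, nodes)
  if (length(unknown)) stop("unknown source name: ",
                            paste(unknown, collapse = ", "))
  regulatoryNetwork(nodes, edges, groups)
}

#' Serialize a network to its text format
#'
#' @param net a \linkS4class{RegulatoryNetwork}.
#' @return character vector, one line per node; parseable by
#'   \code{\link{parseNetwork}}.
#' @export
serializeNetwork <- function(net) {
  vapply(seq_along(net@nodes), function(i) {
    inp <- net@inputs[[i]]
    if (nrow(inp) == 0) return(paste0(net@nodes[i], " :"))
    gs <- vapply(net@groups[[i]], function(g) {
      terms <- paste0(ifelse(inp$sign[g] < 0, "~", ""),
                      net@nodes[inp$source[g]])
      paste(terms, collapse = " + ")
    }, "")
    expr <- if (length(gs) == 1 && length(net@groups[[i]][[1]]) == 1)
      gs else paste0("(", gs, ")", collapse = "")
    paste0(net@nodes[i], " : ", expr)
  }, "")
}

#' Number of qualitative levels per node
#'
#' \code{out_degree + 1} for every node (one threshold per out-edge).
#'
#' @param net a \linkS4class{RegulatoryNetwork}.
#' @return named integer vector.
#' @export
nodeLevels <- function(net) {
  setNames(outDegrees(net) + 1L, net@nodes)
}

#' Out-degrees (threshold counts) per node
#' @param net a \linkS4class{RegulatoryNetwork}.
#' @return named integer vector.
#' @export
outDegrees <- function(net) {
  d <- integer(length(net@nodes))
  for (i in seq_along(net@nodes)) {
    inp <- net@inputs[[i]]
    if (nrow(inp)) for (s in inp$source) d[s] <- d[s] + 1L
  }
  setNames(d, net@nodes)
}

# ordered out-edge targets per node (by target index; the order is the
# canonical labelling of the node's thresholds)
.outTargets <- function(net) {
  lapply(seq_along(net@nodes), function(j) {
    tg <- integer(0)
    for (i in seq_along(net@nodes)) {
      inp <- net@inputs[[i]]
      if (nrow(inp) && any(inp$source == j)) tg <- c(tg, i)
    }
    sort(tg)
  })
}

#' Is the network strongly connected?
#'
#' @param net a \linkS4class{RegulatoryNetwork}.
#' @return logical; vacuously FALSE for empty networks, TRUE for a single
#'   node with a self-edge.
#' @export
isStronglyConnected <- function(net) {
  n <- length(net@nodes)
  if (n == 0) return(FALSE)
  el <- NULL
  for (i in seq_len(n)) {
    inp <- net@inputs[[i]]
    if (nrow(inp)) el <- rbind(el, cbind(inp$source, i))
  }
  if (is.null(el)) return(n == 1)
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::is_connected(g, mode = "strong")
}

#' Does the network contain a self-repressing edge?
#' @param net a \linkS4class{RegulatoryNetwork}.
#' @return logical.
#' @export
hasSelfRepression <- function(net) {
  for (i in seq_along(net@nodes)) {
    inp <- net@inputs[[i]]
    if (nrow(inp) && any(inp$source == i & inp$sign < 0)) return(TRUE)
  }
  FALSE
}

#' The six-gene ground-truth oscillator network
#'
#' A is activated by F; B by C; C carries the composite input
#' (A + E)(~D); D the input (~A)(~E); E the input (~B)(F); F is repressed
#' by B.  Ten signed edges in total.
#'
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
groundTruthNetwork <- function() {
  parseNetwork(c(
    "A : F",
    "B : C",
    "C : (A + E)(~D)",
    "D : (~A)(~E)",
    "E : (~B)(F)",
    "F : ~B"))
}
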