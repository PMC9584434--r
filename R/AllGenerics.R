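#' @name coreosc-generics
#' @title Accessor generics
#' @description Accessors for the package's S4 containers.
#' @param x,object an object.
#' @param ... further arguments.
NULL

#' @rdname coreosc-generics
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname coreosc-generics
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname coreosc-generics
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname coreosc-generics
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))

#' @rdname coreosc-generics
#' @export
setGeneric("rankedItems", function(x) standardGeneric("rankedItems"))

#' @rdname coreosc-generics
#' @export
setGeneric("scoreDirection", function(x) standardGeneric("scoreDirection"))

#' @rdname coreosc-generics
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname coreosc-generics
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @rdname coreosc-generics
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

setMethod("geneNames", "TimeSeriesSet", function(x) rownames(x@values))
setMethod("sampleTimes", "TimeSeriesSet", function(x) x@times)
setMethod("exprValues", "TimeSeriesSet", function(x) x@values)
setMethod("replicateId", "TimeSeriesSet", function(x) x@replicateId)
setMethod("rankedItems", "RankingTable", function(x) x@items)
setMethod("scoreDirection", "RankingTable", function(x) x@direction)
setMethod("nodeNames", "RegulatoryNetwork", function(x) x@nodes)
setMethod("nodeNames", "StateTransitionGraph", function(x) x@nodeNames)
setMethod("eventTable", "DataGraph", function(x) x@events)

#' @rdname coreosc-generics
#' @export
setMethod("edgeList", "RegulatoryNetwork", function(x) {
  out <- NULL
  for (i in seq_along(x@nodes)) {
    inp <- x@inputs[[i]]
    if (nrow(inp) == 0) next
    out <- rbind(out, data.frame(
      target = x@nodes[i], source = x@nodes[inp$source],
      sign = ifelse(inp$sign > 0, "activation", "repression"),
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(target = character(0), source = character(0),
                      sign = character(0))
  out
})

setMethod("edgeList", "DataGraph", function(x) x@edges)

setMethod("show", "TimeSeriesSet", function(object) {
  cat("TimeSeriesSet with", nrow(object@values), "genes x",
      length(object@times), "time points (replicate",
      object@replicateId, ")\n")
  if (length(object@times))
    cat("  times:", head(object@times, 3), "...", max(object@times), "\n")
  if (nrow(object@values))
    cat("  genes:", paste(head(rownames(object@values), 8), collapse = " "),
        if (nrow(object@values) > 8) "..." else "", "\n")
})

setMethod("show", "RankingTable", function(object) {
  cat("RankingTable (", object@direction, "), ",
      nrow(object@items), " items\n", sep = "")
  print(head(object@items, 5))
  if (nrow(object@items) > 5) cat("  ...\n")
})

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork with", length(object@nodes), "nodes\n")
  if (length(object@nodes)) cat(serializeNetwork(object), sep = "\n")
})

setMethod("show", "DataGraph", function(object) {
  cat("DataGraph:", nrow(object@events), "extremum events,",
      nrow(object@edges), "precedence pairs\n")
})

setMethod("show", "MorseGraph", function(object) {
  cat("MorseGraph:", length(object@stable), "components (",
      sum(object@stable), "stable );",
      sum(object@annotation == "full_cycle"), "full cycle(s)\n")
})

setMethod("show", "StateTransitionGraph", function(object) {
  cat("StateTransitionGraph:", nrow(object@states), "states,",
      nrow(object@edges), "transitions over nodes",
      paste(object@nodeNames, collapse = ", "), "\n")
})
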