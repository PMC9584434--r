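#' Build a RankingTable from scored items
#'
#' Items are ordered by score in the stated direction; ties are broken by
#' the stable lexicographic order of the item keys and ranks are 1-based.
#'
#' @param items data.frame with at least columns \code{item} and
#'   \code{score}; other columns are preserved.
#' @param direction \code{"lower_is_better"} or \code{"higher_is_better"}.
#' @param tiebreakNote note recorded in the table.
#' @return a \linkS4class{RankingTable}.
#' @export
rankingTable <- function(items, direction = c("lower_is_better",
                                              "higher_is_better"),
                         tiebreakNote = "ties broken by lexicographic item key") {
  direction <- match.arg(direction)
  stopifnot(all(c("item", "score") %in% names(items)))
  ord <- .tieOrder(items$score, items$item,
                   decreasing = direction == "higher_is_better")
  items <- items[ord, , drop = FALSE]
  items$rank <- seq_len(nrow(items))
  rownames(items) <- NULL
  new("RankingTable", items = items, direction = direction,
      tiebreakNote = tiebreakNote)
}

#' Write a RankingTable as TSV
#'
#' @param rt a \linkS4class{RankingTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRankingTable <- function(rt, path) {
  stopifnot(is(rt, "RankingTable"))
  write.table(rt@items, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a RankingTable from TSV
#'
#' @param path file path.
#' @param direction score direction of the stored ranking.
#' @return a \linkS4class{RankingTable}.
#' @export
readRankingTable <- function(path, direction = "lower_is_better") {
  items <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  new("RankingTable", items = items, direction = direction,
      tiebreakNote = "as stored")
}
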