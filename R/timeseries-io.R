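#' Construct a TimeSeriesSet
#'
#' @param values numeric matrix (genes x times) with gene row names.
#' @param times strictly increasing numeric sampling times.
#' @param replicateId label for the replicate.
#' @return a validated \linkS4class{TimeSeriesSet}.
#' @export
TimeSeriesSet <- function(values, times, replicateId = "rep1") {
  new("TimeSeriesSet", values = as.matrix(values), times = as.numeric(times),
      replicateId = as.character(replicateId))
}

#' Read a gene expression time-series matrix from TSV
#'
#' Expected layout: tab-delimited UTF-8 text, first row the numeric
#' sampling times, first column the gene names, one row per gene.
#'
#' @param path file path.
#' @param replicateId replicate label; defaults to the file base name.
#' @return a \linkS4class{TimeSeriesSet}.
#' @export
readTimeSeries <- function(path, replicateId = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("time-series file needs a header and a gene row")
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  # header may or may not carry a leading label cell for the gene column
  htimes <- suppressWarnings(as.numeric(hdr))
  if (is.na(htimes[1]) && length(htimes) > 1) htimes <- htimes[-1]
  if (anyNA(htimes))
    stop("non-numeric sampling time in header row of ", path)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  genes <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene names in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- matrix(NA_real_, length(genes), length(htimes),
                 dimnames = list(genes, NULL))
  for (r in seq_along(body)) {
    row <- body[[r]][-1]
    if (length(row) != length(htimes))
      stop("row ", r + 1L, " (gene ", genes[r], ") has ", length(row),
           " values but the header has ", length(htimes), " times")
    v <- suppressWarnings(as.numeric(row))
    if (anyNA(v))
      stop("non-numeric value at row ", r + 1L, " (gene ", genes[r],
           "), column ", which(is.na(v))[1] + 1L)
    vals[r, ] <- v
  }
  if (length(htimes) > 1 && any(diff(htimes) <= 0))
    stop("sampling times must be strictly increasing in ", path)
  if (is.null(replicateId))
    replicateId <- sub("\\.[^.]*$", "", basename(path))
  TimeSeriesSet(vals, htimes, replicateId)
}

#' Write a TimeSeriesSet as TSV
#'
#' @param tss a \linkS4class{TimeSeriesSet}.
#' @param path output file path.
#' @param digits significant digits used for the values.
#' @return \code{path}, invisibly.
#' @export
writeTimeSeries <- function(tss, path, digits = 10) {
  stopifnot(is(tss, "TimeSeriesSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", format(tss@times, digits = digits,
                                    trim = TRUE, scientific = FALSE)),
                   collapse = "\t"), con)
  v <- tss@values
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i],
                       format(v[i, ], digits = digits, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read per-gene annotations
#'
#' TSV with columns \code{gene}, \code{may_be_target} (TRUE/FALSE) and
#' \code{regulator_role} (one of activator_only, repressor_only, either,
#' none).
#'
#' @param path file path.
#' @return data.frame of annotations.
#' @export
readAnnotations <- function(path) {
  a <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "may_be_target", "regulator_role")
  if (!all(need %in% names(a)))
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(a$regulator_role,
                 c("activator_only", "repressor_only", "either", "none"))
  if (length(bad)) stop("unknown regulator_role: ", paste(bad, collapse = ", "))
  a$may_be_target <- as.logical(a$may_be_target)
  a
}
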