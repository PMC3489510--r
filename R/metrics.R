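#' @include AllClasses.R
NULL

contigLengths <- function(assembly) as.numeric(Biostrings::width(contigs(assembly)))

#' Length-weighted quantile of contig lengths (N50, N90, ...)
#'
#' Sorts contig lengths in decreasing order and returns the length of the
#' contig at which the cumulative length first reaches \code{fraction} times
#' the total assembled length. \code{fraction = 0.5} gives N50 and
#' \code{fraction = 0.9} gives N90. All contigs present in the assembly
#' enter the statistic; reporting thresholds such as ">= 100 bp" are applied
#' only when counting contigs, never as a filter here.
#'
#' @param assembly a non-empty [Assembly-class].
#' @param fraction fraction of the total length in (0, 1).
#' @return contig length in bp.
#' @examples
#' a <- Assembly("k19", setNames(
#'   vapply(c(10, 5, 3, 2), function(n) paste(rep("A", n), collapse = ""), ""),
#'   paste0("c", 1:4)))
#' nStatistic(a, 0.5) # 10
#' nStatistic(a, 0.9) # 3
#' @export
nStatistic <- function(assembly, fraction) {
  stopifnot(is(assembly, "Assembly"), fraction > 0, fraction < 1)
  len <- contigLengths(assembly)
  if (!length(len)) stop("cannot compute length-weighted quantile of an empty assembly")
  len <- sort(len, decreasing = TRUE)
  cum <- cumsum(len)
  len[which(cum >= fraction * cum[length(cum)] - 1e-9)[1L]]
}

#' Count contigs at or above a length threshold
#'
#' @param assembly an [Assembly-class].
#' @param minLength threshold in bp (inclusive), >= 1.
#' @return integer count.
#' @export
countGe <- function(assembly, minLength) {
  stopifnot(is(assembly, "Assembly"), minLength >= 1)
  sum(contigLengths(assembly) >= minLength)
}

#' Summarize an assembly
#'
#' Computes the standard assembly report: contig counts above each length
#' threshold, average (full precision) and longest contig length, N50, N90,
#' and total assembled length.
#'
#' @param assembly a non-empty [Assembly-class].
#' @param thresholds length thresholds in bp (default \code{c(100, 5000, 8000)}).
#' @return An [AssemblyMetrics-class].
#' @examples
#' a <- Assembly("k19", setNames(
#'   vapply(c(10, 5, 3, 2), function(n) paste(rep("A", n), collapse = ""), ""),
#'   paste0("c", 1:4)))
#' assemblyMetrics(a, thresholds = 5)
#' @export
assemblyMetrics <- function(assembly, thresholds = c(100, 5000, 8000)) {
  stopifnot(is(assembly, "Assembly"))
  len <- contigLengths(assembly)
  if (!length(len)) stop("cannot summarize an empty assembly")
  cg <- vapply(thresholds, function(th) countGe(assembly, th), numeric(1))
  names(cg) <- as.character(thresholds)
  new("AssemblyMetrics",
    label = assemblyLabel(assembly),
    nContigs = length(len),
    nContigsGe = cg,
    averageLength = sum(len) / length(len),
    longestLength = max(len),
    n50 = nStatistic(assembly, 0.5),
    n90 = nStatistic(assembly, 0.9),
    totalLength = sum(len)
  )
}

#' Contig length-frequency distribution
#'
#' Bins contig lengths into half-open bins \code{[start, start + width)}
#' whose starts are the floor multiples of the bin width, and returns counts
#' together with the cumulative count series. Empty bins are omitted; the
#' counts always sum to the number of contigs.
#'
#' @param assembly an [Assembly-class].
#' @param binWidth bin width in bp, >= 1.
#' @return data.frame with columns \code{bin_start}, \code{count},
#'   \code{cumulative}, ordered by \code{bin_start}.
#' @export
lengthHistogram <- function(assembly, binWidth) {
  stopifnot(is(assembly, "Assembly"), binWidth >= 1)
  len <- contigLengths(assembly)
  if (!length(len)) {
    return(data.frame(bin_start = numeric(), count = integer(), cumulative = integer()))
  }
  start <- floor(len / binWidth) * binWidth
  tab <- table(start)
  out <- data.frame(
    bin_start = as.numeric(names(tab)),
    count = as.integer(tab)
  )
  out <- out[order(out$bin_start), , drop = FALSE]
  out$cumulative <- cumsum(out$count)
  rownames(out) <- NULL
  out
}
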