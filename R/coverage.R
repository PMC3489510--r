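#' @include AllClasses.R
NULL

#' Remove reads shorter than the assembly's k-mer length
#'
#' Before mapping reads back to a single-k assembly, any read shorter than
#' that assembly's k value is removed from the trimmed read set, so that
#' reads which could not have contributed to the assembly are not mapped to
#' it. Order is preserved; the boundary is inclusive (length >= k is kept).
#'
#' @param reads a [ReadSet-class].
#' @param k the assembly's k-mer length, >= 1.
#' @return A [ReadSet-class] with only the reads of length >= k.
#' @export
filterReadsByK <- function(reads, k) {
  stopifnot(is(reads, "ReadSet"), k >= 1)
  keep <- Biostrings::width(reads@sequences) >= k
  quals <- if (length(reads@qualities)) reads@qualities[keep] else character()
  new("ReadSet", sequences = reads@sequences[keep], qualities = quals)
}

readLegacyAlignments <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  trimws(readLines(con))
}

readSamReferenceNames <- function(path) {
  # Standards-route SAM handling: convert to BAM and scan only the reference
  # name of mapped records. Requires a proper header (@SQ lines).
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("rname"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  as.character(res$rname)
}

#' Count alignment records per contig
#'
#' Counts how many alignment records hit each contig of the target assembly.
#' Input is either a SAM file (mapped records only; the unmapped flag is
#' skipped) or a legacy text stream with one reference contig name per line —
#' the single column left by a Bowtie run invoked with
#' \code{-a --suppress 1,2,4,5,6,7,8}, which reports every alignment of every
#' read. A multi-mapping read therefore contributes one count per alignment
#' record; deduplicate upstream for per-read counts. Contigs with no
#' alignments appear with count 0.
#'
#' @param path path to a SAM file or legacy one-name-per-line text file.
#' @param assembly the target [Assembly-class].
#' @param mismatchesAllowed 0, 1 or 2; metadata recording how the alignments
#'   were produced (no mismatch counting is done here).
#' @param format "auto" (by extension), "sam" or "legacy".
#' @param strict if TRUE (default) a reference name absent from the assembly
#'   is an error; if FALSE it is kept under its own name with a warning.
#' @return An [AlignmentCounts-class].
#' @export
countAlignments <- function(path, assembly, mismatchesAllowed = 0L,
                            format = c("auto", "sam", "legacy"), strict = TRUE) {
  stopifnot(is(assembly, "Assembly"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam(\\.gz)?$", path)) "sam" else "legacy"
  }
  refs <- switch(format,
    sam = readSamReferenceNames(path),
    legacy = readLegacyAlignments(path)
  )
  refs <- refs[nzchar(refs)]
  ids <- contigIds(assembly)
  unknown <- setdiff(unique(refs), ids)
  if (length(unknown)) {
    if (strict) {
      stop("alignment reference(s) absent from assembly '", assemblyLabel(assembly),
           "': ", paste(head(unknown, 3L), collapse = ", "))
    }
    warning(length(unknown), " unknown reference name(s) counted separately: ",
            paste(head(unknown, 3L), collapse = ", "))
  }
  counts <- setNames(numeric(length(ids)), ids)
  tab <- table(refs)
  known <- intersect(names(tab), ids)
  counts[known] <- as.numeric(tab[known])
  if (!strict && length(unknown)) {
    counts <- c(counts, setNames(as.numeric(tab[unknown]), unknown))
  }
  new("AlignmentCounts",
      assemblyLabel = assemblyLabel(assembly),
      perContigReads = counts,
      mismatchesAllowed = as.integer(mismatchesAllowed),
      nRecords = as.numeric(length(refs)))
}

#' Fold coverage of an assembly
#'
#' Computes fold coverage as the average number of reads mapped per contig:
#' total alignment records divided by the number of contigs in the assembly.
#' When the read length is supplied, a base-level fold coverage
#' (records x read length / total assembled length) is reported as a
#' secondary statistic.
#'
#' @param counts an [AlignmentCounts-class].
#' @param assembly the non-empty target [Assembly-class].
#' @param readLength optional read length in bp.
#' @return A [CoverageReport-class].
#' @export
foldCoverage <- function(counts, assembly, readLength = NULL) {
  stopifnot(is(counts, "AlignmentCounts"), is(assembly, "Assembly"))
  n <- length(assembly)
  if (n == 0L) stop("cannot compute coverage of an empty assembly")
  base <- if (is.null(readLength)) NA_real_ else {
    counts@nRecords * readLength / sum(contigLengths(assembly))
  }
  new("CoverageReport",
      assemblyLabel = assemblyLabel(assembly),
      mismatchesAllowed = counts@mismatchesAllowed,
      foldCoverageReadsPerContig = counts@nRecords / n,
      baseFoldCoverage = base,
      nContigs = n,
      nRecords = counts@nRecords)
}
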