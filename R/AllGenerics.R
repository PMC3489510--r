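#' @include AllClasses.R
NULL

#' @rdname Assembly-class
#' @param x,object an object.
#' @export
setGeneric("assemblyLabel", function(x) standardGeneric("assemblyLabel"))

#' @rdname Assembly-class
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname Assembly-class
#' @export
setGeneric("contigIds", function(x) standardGeneric("contigIds"))

#' @rdname Assembly-class
#' @export
setGeneric("sourceLabels", function(x) standardGeneric("sourceLabels"))

#' Per-assembly KOI set
#'
#' The set of distinct KEGG Ortholog Identifiers induced by an annotation
#' table: the union of KOIs over all annotated contigs, duplicates collapsed.
#' Returned sorted for reproducibility.
#'
#' @param x an [AnnotationTable-class].
#' @return character vector of distinct KOIs (sorted).
#' @examples
#' tab <- AnnotationTable("k19", list(c1 = c("K00001", "K00002"), c2 = "K00002"))
#' koiSet(tab)
#' @export
setGeneric("koiSet", function(x) standardGeneric("koiSet"))

#' @rdname AnnotationTable-class
#' @param x an object.
#' @export
setGeneric("annotationEntries", function(x) standardGeneric("annotationEntries"))

#' @rdname ClusterResult-class
#' @param x an object.
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname RecoveryResult-class
#' @param x an object.
#' @export
setGeneric("finalAssembly", function(x) standardGeneric("finalAssembly"))

#' @rdname RecoveryResult-class
#' @export
setGeneric("recoveredKois", function(x) standardGeneric("recoveredKois"))

#' @rdname CaComparisonReport-class
#' @param x an object.
#' @export
setGeneric("totalMissingFromCa", function(x) standardGeneric("totalMissingFromCa"))

# ---- Assembly methods -------------------------------------------------------

#' @rdname Assembly-class
#' @export
setMethod("assemblyLabel", "Assembly", function(x) x@label)

#' @rdname Assembly-class
#' @export
setMethod("contigs", "Assembly", function(x) x@contigs)

#' @rdname Assembly-class
#' @export
setMethod("contigIds", "Assembly", function(x) names(x@contigs))

#' @rdname Assembly-class
#' @export
setMethod("sourceLabels", "Assembly", function(x) x@sourceLabels)

#' @rdname Assembly-class
#' @export
setMethod("length", "Assembly", function(x) length(x@contigs))

#' @rdname Assembly-class
#' @param i index (numeric, logical or contig ids).
#' @param j,drop,... unused.
#' @export
setMethod("[", "Assembly", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@contigs))
  idx <- seq_along(x@contigs)[i]
  new("Assembly", label = x@label, contigs = x@contigs[idx],
      sourceLabels = x@sourceLabels[idx])
})

setMethod("show", "Assembly", function(object) {
  w <- Biostrings::width(object@contigs)
  cat(sprintf("Assembly '%s': %d contig(s)", object@label, length(object@contigs)))
  if (length(w)) {
    cat(sprintf(", lengths %d..%d bp, total %.0f bp", min(w), max(w), sum(as.numeric(w))))
  }
  cat("\n")
  src <- unique(object@sourceLabels)
  if (length(src) > 1L) {
    cat("  sources:", paste(head(src, 8L), collapse = ", "),
        if (length(src) > 8L) "..." else "", "\n")
  }
})

# ---- AnnotationTable methods ------------------------------------------------

#' @rdname AnnotationTable-class
#' @export
setMethod("assemblyLabel", "AnnotationTable", function(x) x@assemblyLabel)

#' @rdname AnnotationTable-class
#' @export
setMethod("annotationEntries", "AnnotationTable", function(x) x@entries)

#' @rdname koiSet
#' @export
setMethod("koiSet", "AnnotationTable", function(x) sort(unique(x@entries$ko)))

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf(
    "AnnotationTable '%s': %d (contig, KOI) pair(s), %d contig(s), %d distinct KOI(s)\n",
    object@assemblyLabel, nrow(object@entries),
    length(unique(object@entries$contig_id)), length(unique(object@entries$ko))
  ))
})

# ---- ReadSet methods --------------------------------------------------------

#' @rdname ReadSet-class
#' @param x a ReadSet.
#' @export
setMethod("length", "ReadSet", function(x) length(x@sequences))

#' @rdname ReadSet-class
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))

#' @rdname ReadSet-class
#' @export
setMethod("readSequences", "ReadSet", function(x) x@sequences)

setMethod("show", "ReadSet", function(object) {
  cat(sprintf("ReadSet: %d read(s)%s\n", length(object@sequences),
              if (length(object@qualities)) " with qualities" else ""))
})

# ---- ClusterResult methods --------------------------------------------------

#' @rdname ClusterResult-class
#' @export
setMethod("representatives", "ClusterResult", function(x) x@representatives)

#' @rdname ClusterResult-class
#' @export
setMethod("clusterMembers", "ClusterResult", function(x) x@members)

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf(
    "ClusterResult: %d representative(s), %d collapsed member(s) (c = %g, word size %d, %s)\n",
    length(object@representatives), nrow(object@members),
    object@params@identityThreshold, object@params@wordSize,
    if (object@params@bothStrands) "both strands" else "forward strand only"
  ))
})

# ---- AssemblyMetrics methods ------------------------------------------------

setMethod("show", "AssemblyMetrics", function(object) {
  cat(sprintf("AssemblyMetrics '%s'\n", object@label))
  for (th in names(object@nContigsGe)) {
    cat(sprintf("  Number of contigs (>= %s bp): %s\n", th,
                format(object@nContigsGe[[th]], big.mark = ",")))
  }
  cat(sprintf("  Average length of contigs:     %s\n",
              format(round(object@averageLength), big.mark = ",")))
  cat(sprintf("  Longest contig length:         %s\n",
              format(object@longestLength, big.mark = ",")))
  cat(sprintf("  N50:                           %s\n", format(object@n50, big.mark = ",")))
  cat(sprintf("  N90:                           %s\n", format(object@n90, big.mark = ",")))
  cat(sprintf("  Total length:                  %s\n",
              format(object@totalLength, big.mark = ",")))
})

#' Convert AssemblyMetrics to a one-row data.frame
#' @param x an [AssemblyMetrics-class].
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return data.frame with one row.
#' @export
as.data.frame.AssemblyMetrics <- function(x, row.names = NULL, optional = FALSE, ...) {
  cg <- as.list(x@nContigsGe)
  names(cg) <- paste0("n_contigs_ge_", names(cg))
  data.frame(
    label = x@label, n_contigs = x@nContigs, cg,
    average_length = x@averageLength, longest_length = x@longestLength,
    n50 = x@n50, n90 = x@n90, total_length = x@totalLength,
    stringsAsFactors = FALSE
  )
}

# ---- CoverageReport / AlignmentCounts ---------------------------------------

setMethod("show", "AlignmentCounts", function(object) {
  cat(sprintf(
    "AlignmentCounts '%s': %.0f record(s) over %d contig(s) (mismatches allowed: %d)\n",
    object@assemblyLabel, object@nRecords, length(object@perContigReads),
    object@mismatchesAllowed
  ))
})

setMethod("show", "CoverageReport", function(object) {
  cat(sprintf("CoverageReport '%s' (mismatches allowed: %d)\n",
              object@assemblyLabel, object@mismatchesAllowed))
  cat(sprintf("  reads mapped per contig: %.2f (%.0f records / %d contigs)\n",
              object@foldCoverageReadsPerContig, object@nRecords, object@nContigs))
  if (!is.na(object@baseFoldCoverage)) {
    cat(sprintf("  base-level fold coverage: %.2fx\n", object@baseFoldCoverage))
  }
})

# ---- CaComparisonReport -----------------------------------------------------

#' @rdname CaComparisonReport-class
#' @export
setMethod("totalMissingFromCa", "CaComparisonReport", function(x) x@totalMissingFromCa)

setMethod("show", "CaComparisonReport", function(object) {
  cat(sprintf("CaComparisonReport vs '%s' (%d single-k assemblies)\n",
              object@caLabel, nrow(object@perK)))
  cat(sprintf("  total KOIs missing from the CA (per-k sum): %.0f\n",
              object@totalMissingFromCa))
  if (!is.na(object@totalMissingFromCaDistinct)) {
    cat(sprintf("  distinct KOIs missing from the CA:          %.0f\n",
                object@totalMissingFromCaDistinct))
  }
})

# ---- RecoveryResult ---------------------------------------------------------

#' @rdname RecoveryResult-class
#' @export
setMethod("finalAssembly", "RecoveryResult", function(x) x@finalAssembly)

#' @rdname RecoveryResult-class
#' @export
setMethod("recoveredKois", "RecoveryResult", function(x) x@recoveredKois)

setMethod("show", "RecoveryResult", function(object) {
  cat(sprintf(
    "RecoveryResult: final assembly of %d contig(s); %d contig(s) recovered carrying %d KOI(s)\n",
    length(object@finalAssembly), nrow(object@recovered), length(object@recoveredKois)
  ))
  if (length(object@notCoverable)) {
    cat(sprintf("  not coverable: %s\n", paste(object@notCoverable, collapse = ", ")))
  }
})

# ---- TruthCatalog -----------------------------------------------------------

setMethod("show", "TruthCatalog", function(object) {
  tr <- object@transcripts
  cat(sprintf(
    "TruthCatalog: %d transcript(s), %d KO-labeled, lengths %d..%d bp (seed %d)\n",
    nrow(tr), sum(!is.na(tr$ko)), min(nchar(tr$sequence)), max(nchar(tr$sequence)),
    as.integer(object@seed)
  ))
})

#' @rdname TruthCatalog-class
#' @param x a TruthCatalog.
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @rdname TruthCatalog-class
#' @export
setMethod("transcripts", "TruthCatalog", function(x) x@transcripts)
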