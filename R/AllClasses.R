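#' @include multika-package.R
NULL

KO_PATTERN <- "^K[0-9]{5}$"

isKo <- function(x) grepl(KO_PATTERN, x)

# "k19" -> 19; anything else -> NA (clustering labels such as "CA" are opaque)
parseKLabel <- function(label) {
  k <- suppressWarnings(as.integer(sub("^k([0-9]+)$", "\\1", label)))
  ifelse(grepl("^k[0-9]+$", label), k, NA_integer_)
}

#' Assembly: a labeled set of contigs
#'
#' A set of contigs that originated from one single-k de novo assembly (label
#' \code{"k19"} ... \code{"k63"}, odd k) or from a downstream step such as
#' clustering (label \code{"CA"}) or recovery. Contig sequences are stored as
#' a named \link[Biostrings]{DNAStringSet}; names are the contig identifiers
#' and must be unique, non-empty and whitespace-free. Each contig carries a
#' source label recording which assembly it came from, which stays meaningful
#' after pooling contigs from several assemblies.
#'
#' @slot label character(1), assembly label.
#' @slot contigs named \link[Biostrings]{DNAStringSet} over the ACGTN alphabet.
#' @slot sourceLabels character vector, one source label per contig.
#'
#' @seealso [Assembly()], [readFasta()], [poolAssemblies()]
#' @export
setClass("Assembly",
  representation(
    label = "character",
    contigs = "DNAStringSet",
    sourceLabels = "character"
  )
)

setValidity("Assembly", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !nzchar(object@label)) {
    msg <- c(msg, "label must be a single non-empty string")
  }
  ids <- names(object@contigs)
  n <- length(object@contigs)
  if (n > 0L) {
    if (is.null(ids) || any(!nzchar(ids))) {
      msg <- c(msg, "all contigs must have non-empty ids")
    } else {
      if (anyDuplicated(ids)) {
        msg <- c(msg, sprintf(
          "duplicate contig id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", ")
        ))
      }
      if (any(grepl("[[:space:]]", ids))) {
        msg <- c(msg, "contig ids must not contain whitespace")
      }
    }
    if (any(Biostrings::width(object@contigs) < 1L)) {
      msg <- c(msg, "contig sequences must have length >= 1")
    }
    freq <- Biostrings::alphabetFrequency(object@contigs, baseOnly = FALSE)
    allowed <- c("A", "C", "G", "T", "N")
    bad <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE]) > 0
    if (any(bad)) {
      msg <- c(msg, sprintf(
        "contig(s) with characters outside ACGTN: %s",
        paste(head(ids[bad], 3L), collapse = ", ")
      ))
    }
  }
  if (length(object@sourceLabels) != n) {
    msg <- c(msg, "sourceLabels must have one entry per contig")
  }
  k <- parseKLabel(object@label)
  if (!is.na(k) && (k %% 2L == 0L || k < 19L || k > 63L)) {
    msg <- c(msg, sprintf("k-mer label '%s' must encode an odd k in 19..63", object@label))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an Assembly
#'
#' @param label assembly label, e.g. \code{"k19"} or \code{"CA"}.
#' @param contigs a named [Biostrings::DNAStringSet], or a named character
#'   vector of DNA sequences (uppercased on conversion).
#' @param sourceLabels optional per-contig source labels; defaults to `label`.
#' @return An [Assembly-class] object.
#' @examples
#' a <- Assembly("k19", c(c1 = "ACGT", c2 = "TTTTT"))
#' contigIds(a)
#' @export
Assembly <- function(label, contigs = Biostrings::DNAStringSet(), sourceLabels = NULL) {
  if (is.character(contigs)) {
    contigs <- Biostrings::DNAStringSet(toupper(contigs))
  }
  if (is.null(sourceLabels)) {
    sourceLabels <- rep(label, length(contigs))
  }
  new("Assembly", label = label, contigs = contigs, sourceLabels = sourceLabels)
}

#' AnnotationTable: contig-to-KOI assignments for one assembly
#'
#' Maps contig identifiers to zero or more KEGG Ortholog Identifiers
#' (KOIs, tokens of the form \code{K} followed by exactly five digits), as
#' produced by an annotation service such as KAAS. Contigs without any
#' annotation are simply absent. The induced per-assembly KOI set is the
#' union over all contigs, available via [koiSet()].
#'
#' @slot assemblyLabel character(1), label of the annotated assembly.
#' @slot entries data.frame with columns \code{contig_id} and \code{ko};
#'   one row per (contig, KOI) pair.
#'
#' @seealso [AnnotationTable()], [readAnnotationTable()], [koiSet()]
#' @export
setClass("AnnotationTable",
  representation(assemblyLabel = "character", entries = "data.frame")
)

setValidity("AnnotationTable", function(object) {
  msg <- character()
  e <- object@entries
  if (!all(c("contig_id", "ko") %in% names(e))) {
    msg <- c(msg, "entries must have columns contig_id and ko")
  } else if (nrow(e)) {
    bad <- !isKo(e$ko)
    if (any(bad)) {
      msg <- c(msg, sprintf(
        "malformed KO identifier(s): %s",
        paste(head(unique(e$ko[bad]), 3L), collapse = ", ")
      ))
    }
  }
  if (length(object@assemblyLabel) != 1L) {
    msg <- c(msg, "assemblyLabel must be a single string")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationTable
#'
#' @param assemblyLabel label of the annotated assembly.
#' @param entries data.frame with columns \code{contig_id}, \code{ko}, or a
#'   named list mapping contig ids to character vectors of KOIs.
#' @return An [AnnotationTable-class] object.
#' @examples
#' AnnotationTable("k19", list(c1 = c("K00001", "K00002"), c2 = "K00002"))
#' @export
AnnotationTable <- function(assemblyLabel, entries = data.frame(contig_id = character(), ko = character())) {
  if (is.list(entries) && !is.data.frame(entries)) {
    entries <- data.frame(
      contig_id = if (length(entries)) rep(names(entries), lengths(entries)) else character(),
      ko = as.character(unlist(entries, use.names = FALSE)),
      stringsAsFactors = FALSE
    )
  }
  rownames(entries) <- NULL
  new("AnnotationTable", assemblyLabel = assemblyLabel,
      entries = unique(entries[c("contig_id", "ko")]))
}

#' ReadSet: a collection of sequencing reads
#'
#' Trimmed reads as used for mapping back to an assembly. Qualities are
#' optional (FASTA input has none); when present there is one quality string
#' per read, of the same length as the read.
#'
#' @slot sequences named \link[Biostrings]{DNAStringSet}.
#' @slot qualities character vector of per-read quality strings, or empty.
#' @seealso [ReadSet()], [filterReadsByK()]
#' @export
setClass("ReadSet",
  representation(sequences = "DNAStringSet", qualities = "character")
)

setValidity("ReadSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (n && any(Biostrings::width(object@sequences) < 1L)) {
    msg <- c(msg, "read sequences must have length >= 1")
  }
  nq <- length(object@qualities)
  if (nq != 0L && nq != n) {
    msg <- c(msg, "qualities must be empty or have one entry per read")
  }
  if (nq == n && n > 0L &&
      any(nchar(object@qualities) != Biostrings::width(object@sequences))) {
    msg <- c(msg, "quality strings must match read lengths")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReadSet
#' @param sequences named [Biostrings::DNAStringSet] or named character vector.
#' @param qualities optional character vector of quality strings.
#' @return A [ReadSet-class] object.
#' @export
ReadSet <- function(sequences = Biostrings::DNAStringSet(), qualities = character()) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(toupper(sequences))
  new("ReadSet", sequences = sequences, qualities = qualities)
}

#' AssemblyMetrics: summary statistics for one assembly
#'
#' Holds the standard de novo assembly report: contig counts above length
#' thresholds, average and longest contig length, total assembled length, and
#' the length-weighted medians N50 and N90 (the contig length at which the
#' cumulative length of contigs sorted in decreasing order first reaches 50%
#' or 90% of the total).
#'
#' @slot label assembly label.
#' @slot nContigs total number of contigs.
#' @slot nContigsGe named numeric vector: count of contigs with length >=
#'   each threshold (names are the thresholds in bp).
#' @slot averageLength mean contig length in bp (full precision).
#' @slot longestLength length of the longest contig in bp.
#' @slot n50,n90 length-weighted medians in bp.
#' @slot totalLength total assembled length in bp.
#' @seealso [assemblyMetrics()], [nStatistic()]
#' @export
setClass("AssemblyMetrics",
  representation(
    label = "character", nContigs = "numeric", nContigsGe = "numeric",
    averageLength = "numeric", longestLength = "numeric",
    n50 = "numeric", n90 = "numeric", totalLength = "numeric"
  )
)

setValidity("AssemblyMetrics", function(object) {
  msg <- character()
  if (object@nContigs > 0) {
    if (object@n50 < object@n90) msg <- c(msg, "N50 must be >= N90")
    if (object@longestLength < object@n50) msg <- c(msg, "longest contig must be >= N50")
    cg <- object@nContigsGe
    if (length(cg) > 1L && is.unsorted(rev(cg[order(as.numeric(names(cg)))]))) {
      msg <- c(msg, "threshold counts must be non-increasing in the threshold")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClusterParams: greedy clustering parameters
#'
#' Parameters for identity-threshold clustering of pooled multi-k contigs.
#' The identity threshold \code{c} is the minimum fraction of matching bases,
#' relative to the shorter sequence, for a contig to join a representative's
#' cluster (as in CD-HIT-EST's \code{-c}); typical values are 0.9, 0.95 and
#' 1.0. \code{wordSize} is the length of the exact words used to prefilter
#' candidate representatives (as in \code{-n 8}); it is an optimization only
#' and never changes the clustering result. With \code{bothStrands} the
#' reverse complement of the shorter sequence is also considered, since
#' different k runs may assemble opposite strands of the same transcript.
#'
#' @slot identityThreshold numeric in (0.8, 1].
#' @slot wordSize integer >= 4.
#' @slot bothStrands logical.
#' @seealso [ClusterParams()], [clusterContigs()]
#' @export
setClass("ClusterParams",
  representation(identityThreshold = "numeric", wordSize = "integer", bothStrands = "logical")
)

setValidity("ClusterParams", function(object) {
  msg <- character()
  c0 <- object@identityThreshold
  if (length(c0) != 1L || is.na(c0) || c0 <= 0.8 || c0 > 1) {
    msg <- c(msg, "identityThreshold must lie in (0.8, 1]")
  }
  if (length(object@wordSize) != 1L || object@wordSize < 4L) {
    msg <- c(msg, "wordSize must be an integer >= 4")
  }
  if (length(msg)) msg else TRUE
})

#' Construct ClusterParams
#' @param identityThreshold sequence identity threshold c in (0.8, 1].
#' @param wordSize prefilter word length (default 8).
#' @param bothStrands consider the reverse complement too (default TRUE).
#' @return A [ClusterParams-class] object.
#' @export
ClusterParams <- function(identityThreshold = 1.0, wordSize = 8L, bothStrands = TRUE) {
  new("ClusterParams",
      identityThreshold = as.numeric(identityThreshold),
      wordSize = as.integer(wordSize), bothStrands = isTRUE(bothStrands))
}

#' ClusterResult: a non-redundant clustered assembly (CA)
#'
#' The result of greedy identity clustering: the representative contigs (the
#' CA itself, an [Assembly-class] labeled \code{"CA"}) plus the membership of
#' every collapsed contig. Every input contig appears exactly once, either as
#' a representative or as a member, and a representative is always at least
#' as long as every member of its cluster.
#'
#' @slot representatives the CA [Assembly-class].
#' @slot members data.frame with columns \code{representative_id},
#'   \code{member_id}, \code{source_label}, \code{identity}.
#' @slot params the [ClusterParams-class] used.
#' @seealso [clusterContigs()], [buildCA()]
#' @export
setClass("ClusterResult",
  representation(representatives = "Assembly", members = "data.frame", params = "ClusterParams")
)

#' AlignmentCounts: per-contig alignment record counts
#'
#' Counts of alignment records per target contig, from SAM input or from a
#' legacy one-reference-name-per-line stream (the single surviving column of
#' a Bowtie run with all other columns suppressed). A multi-mapping read
#' contributes one count per alignment record, matching Bowtie \code{-a}
#' semantics. Contigs with no alignments are present with count 0.
#'
#' @slot assemblyLabel label of the target assembly.
#' @slot perContigReads named numeric vector, contig id -> record count.
#' @slot mismatchesAllowed report metadata: mismatches allowed (0, 1 or 2)
#'   when the alignments were produced.
#' @slot nRecords total number of alignment records counted.
#' @seealso [countAlignments()], [foldCoverage()]
#' @export
setClass("AlignmentCounts",
  representation(
    assemblyLabel = "character", perContigReads = "numeric",
    mismatchesAllowed = "integer", nRecords = "numeric"
  )
)

setValidity("AlignmentCounts", function(object) {
  msg <- character()
  if (length(object@perContigReads) &&
      !isTRUE(all.equal(sum(object@perContigReads), object@nRecords))) {
    msg <- c(msg, "per-contig counts must sum to nRecords")
  }
  if (!object@mismatchesAllowed %in% c(0L, 1L, 2L)) {
    msg <- c(msg, "mismatchesAllowed must be 0, 1 or 2")
  }
  if (length(msg)) msg else TRUE
})

#' CoverageReport: fold coverage of an assembly
#'
#' Fold coverage computed as the average number of mapped reads per contig
#' (\code{nRecords / nContigs}). When the read length is known, a base-level
#' fold coverage \code{nRecords * readLength / totalLength} is also reported
#' as a clearly separate secondary statistic.
#'
#' @slot assemblyLabel label of the target assembly.
#' @slot mismatchesAllowed mismatches allowed when mapping (metadata).
#' @slot foldCoverageReadsPerContig average reads mapped per contig.
#' @slot baseFoldCoverage base-level fold coverage, or NA when no read length
#'   was supplied.
#' @slot nContigs number of contigs in the assembly.
#' @slot nRecords number of alignment records.
#' @seealso [foldCoverage()]
#' @export
setClass("CoverageReport",
  representation(
    assemblyLabel = "character", mismatchesAllowed = "integer",
    foldCoverageReadsPerContig = "numeric", baseFoldCoverage = "numeric",
    nContigs = "numeric", nRecords = "numeric"
  )
)

#' CaComparisonReport: CA versus single-k KOI comparison
#'
#' For each single-k assembly, the number of KOIs present in that assembly
#' but missing from the clustered assembly (forward direction; the per-k rows
#' of a missing-KOI table) and the number present in the CA but missing from
#' the single-k assembly (reverse direction). The total sums the per-k
#' forward counts as conventionally printed, even though the same KOI may be
#' missing from several rows; the deduplicated union size is reported
#' alongside as \code{totalMissingFromCaDistinct}.
#'
#' @slot caLabel label of the clustered assembly.
#' @slot perK data.frame with columns \code{label}, \code{missing_from_ca},
#'   \code{missing_from_single}.
#' @slot missingByK named list of character vectors: the actual KOIs missing
#'   from the CA per single-k label (empty when the report was built from
#'   published counts only).
#' @slot totalMissingFromCa sum of the per-k forward counts.
#' @slot totalMissingFromCaDistinct size of the union of per-k missing KOI
#'   sets; NA when only counts are available.
#' @seealso [caComparison()], [caReportFromCounts()]
#' @export
setClass("CaComparisonReport",
  representation(
    caLabel = "character", perK = "data.frame", missingByK = "list",
    totalMissingFromCa = "numeric", totalMissingFromCaDistinct = "numeric"
  )
)

#' RecoveryResult: final assembly after annotation recovery
#'
#' The final assembly product: the CA representatives plus the contigs
#' recovered from single-k assemblies because they carry KOIs missing from
#' the CA. The KOI set of the final assembly equals the union of the CA's
#' KOIs and every single-k assembly's KOIs.
#'
#' @slot finalAssembly the final [Assembly-class] (label \code{"final"}).
#' @slot finalTable [AnnotationTable-class] for the final assembly.
#' @slot recovered data.frame with columns \code{contig_id},
#'   \code{source_label}, \code{kois} (comma-separated new KOIs contributed).
#' @slot recoveredKois character vector of KOIs restored by recovery.
#' @slot notCoverable KOIs targeted for recovery with no annotated contig
#'   (empty in consistent inputs).
#' @seealso [recoverAnnotations()]
#' @export
setClass("RecoveryResult",
  representation(
    finalAssembly = "Assembly", finalTable = "AnnotationTable",
    recovered = "data.frame", recoveredKois = "character",
    notCoverable = "character"
  )
)

#' TruthCatalog: a synthetic transcript catalog with ground truth
#'
#' A reproducible catalog of synthetic mRNA transcripts, a fraction of which
#' carry distinct KO labels, each assigned a low or high abundance class.
#' Downstream synthetic per-k assemblies are sampled from the catalog with
#' class-dependent capture probabilities (low-k assemblies favor
#' low-abundance transcripts, high-k favor high-abundance ones), so every
#' emitted contig and annotation traces back to a catalog transcript.
#'
#' @slot transcripts data.frame with columns \code{id}, \code{sequence},
#'   \code{ko} (NA when unlabeled), \code{abundance} ("low"/"high").
#' @slot seed integer seed the catalog was generated with.
#' @slot params list of generation parameters.
#' @seealso [simulateCatalog()], [simulateAssembly()], [simulateMultikScenario()]
#' @export
setClass("TruthCatalog",
  representation(transcripts = "data.frame", seed = "numeric", params = "list")
)
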