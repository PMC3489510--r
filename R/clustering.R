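#' @include AllClasses.R
NULL

#' Pool several single-k assemblies into one contig set
#'
#' Concatenates contigs from all assemblies, rewriting each id as
#' \code{<source_label>|<original id>} so ids are globally unique; the
#' per-contig source label is preserved.
#'
#' @param assemblies list of [Assembly-class] (at least one).
#' @param label label for the pooled assembly (default \code{"pooled"}).
#' @return An [Assembly-class].
#' @export
poolAssemblies <- function(assemblies, label = "pooled") {
  stopifnot(length(assemblies) >= 1L, all(vapply(assemblies, is, TRUE, "Assembly")))
  seqs <- lapply(assemblies, function(a) {
    s <- contigs(a)
    if (length(s)) names(s) <- paste0(assemblyLabel(a), "|", names(s))
    s
  })
  pooled <- do.call(c, unname(seqs))
  src <- unlist(lapply(assemblies, function(a) rep(assemblyLabel(a), length(a))),
                use.names = FALSE)
  new("Assembly", label = label, contigs = pooled,
      sourceLabels = if (is.null(src)) character() else src)
}

#' Gap-free containment identity between two contigs
#'
#' The identity used by the clustering step: the shorter sequence is slid
#' end-to-end along the longer at every ungapped offset, and the identity is
#' the maximum number of matching bases over all offsets divided by the
#' length of the shorter sequence (CD-HIT's denominator convention, so an
#' exact substring scores 1.0). Positions where either base is N never count
#' as matches. With \code{bothStrands} the reverse complement of the shorter
#' sequence is also tried and the maximum taken. This exhaustive version
#' scores every offset; the clustering loop reaches identical decisions
#' through word-seeded evaluation.
#'
#' @param a,b DNA sequences: single-contig character strings, or
#'   [Biostrings::DNAString]s.
#' @param params a [ClusterParams-class]; only \code{bothStrands} affects the
#'   value.
#' @return identity in [0, 1].
#' @examples
#' pairIdentity("CGTA", "ACGTACGT")  # exact substring: 1
#' @export
pairIdentity <- function(a, b, params = ClusterParams()) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  stopifnot(nchar(a) >= 1L, nchar(b) >= 1L)
  .cppPairIdentity(a, b, params@bothStrands)
}

#' Greedy identity-threshold clustering with redundancy removal
#'
#' Clusters a pooled contig set the way CD-HIT-EST does: contigs are sorted
#' by decreasing length (ties by id, ascending, for determinism) and scanned
#' in order; each contig joins the cluster of the first earlier
#' representative it matches at identity >= c (see [pairIdentity()] for the
#' identity definition), otherwise it becomes a new representative.
#' Representatives are therefore always at least as long as their members,
#' and no two representatives reach identity >= c with one another under the
#' greedy scan. Candidate scoring is word-seeded (an optimization only;
#' \code{usePrefilter = FALSE} scores every offset and gives identical
#' results). A contig shorter than the word size always becomes its own
#' representative and is reported in a message.
#'
#' @param pooled a non-empty [Assembly-class] (typically from
#'   [poolAssemblies()]).
#' @param params a [ClusterParams-class].
#' @param usePrefilter use word-seeded offset evaluation (default TRUE).
#' @return A [ClusterResult-class]; the representatives form the clustered
#'   assembly, labeled \code{"CA"}.
#' @export
clusterContigs <- function(pooled, params = ClusterParams(), usePrefilter = TRUE) {
  stopifnot(is(pooled, "Assembly"), is(params, "ClusterParams"))
  validObject(params)
  n <- length(pooled)
  if (n == 0L) stop("cannot cluster an empty assembly")
  ids <- contigIds(pooled)
  lens <- Biostrings::width(contigs(pooled))
  ord <- order(-lens, ids)
  seqs <- as.character(contigs(pooled))[ord]
  res <- .cppGreedyCluster(seqs, params@identityThreshold, params@wordSize,
                           params@bothStrands, isTRUE(usePrefilter))
  idsOrd <- ids[ord]
  srcOrd <- sourceLabels(pooled)[ord]
  if (any(res$too_short)) {
    message(sum(res$too_short), " contig(s) shorter than the word size kept as own representatives")
  }
  isRep <- res$rep_of == seq_len(length(seqs))
  repIds <- idsOrd[isRep]
  reps <- new("Assembly", label = "CA",
              contigs = contigs(pooled)[ord][isRep],
              sourceLabels = srcOrd[isRep])
  mem <- data.frame(
    representative_id = idsOrd[res$rep_of[!isRep]],
    member_id = idsOrd[!isRep],
    source_label = srcOrd[!isRep],
    identity = res$identity[!isRep],
    stringsAsFactors = FALSE
  )
  new("ClusterResult", representatives = reps, members = mem, params = params)
}

#' Build the clustered assembly (CA) from single-k assemblies
#'
#' Pools the given single-k assemblies ([poolAssemblies()]) and clusters the
#' pool ([clusterContigs()]); the representatives are the non-redundant CA
#' used downstream for annotation comparison and recovery.
#'
#' @inheritParams clusterContigs
#' @param assemblies list of [Assembly-class].
#' @return A [ClusterResult-class].
#' @export
buildCA <- function(assemblies, params = ClusterParams(), usePrefilter = TRUE) {
  clusterContigs(poolAssemblies(assemblies), params, usePrefilter)
}

#' Write cluster membership as TSV
#'
#' @param result a [ClusterResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClusterMembers <- function(result, path) {
  stopifnot(is(result, "ClusterResult"))
  write.table(clusterMembers(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
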