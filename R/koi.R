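#' @include AllClasses.R
NULL

asKoiSets <- function(sets) {
  # accept a named list of character vectors or of AnnotationTables
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    if (all(vapply(sets, is, TRUE, "AnnotationTable"))) {
      names(sets) <- vapply(sets, assemblyLabel, "")
    } else {
      stop("KOI sets must be named by assembly label")
    }
  }
  lapply(sets, function(s) {
    if (is(s, "AnnotationTable")) koiSet(s) else sort(unique(as.character(s)))
  })
}

#' Pairwise missing-KOI matrix
#'
#' For every ordered pair of assemblies, the number of KOIs present in the
#' row assembly but not identified in the column assembly:
#' \code{cell(r, c) = |KOI(r) \\ KOI(c)|}. The diagonal is zero. The
#' alternative reading, each row compared against the union of all other
#' assemblies, is available as \code{mode = "vs-rest"}, where
#' \code{cell(r, c) = |KOI(r) \\ union of KOI(j), j != r|} is constant along
#' each row.
#'
#' @param sets named list of KOI sets (character vectors) or of
#'   [AnnotationTable-class] objects; labels must be distinct.
#' @param mode \code{"pairwise"} (default) or \code{"vs-rest"}.
#' @return numeric matrix with assembly labels as dimnames.
#' @examples
#' pairwiseMissingMatrix(list(k19 = c("K00001", "K00002"), k21 = "K00002"))
#' @export
pairwiseMissingMatrix <- function(sets, mode = c("pairwise", "vs-rest")) {
  mode <- match.arg(mode)
  sets <- asKoiSets(sets)
  if (length(sets) < 2L) stop("need at least two KOI sets")
  labels <- names(sets)
  if (anyDuplicated(labels)) {
    stop("duplicate assembly label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  n <- length(sets)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (r in seq_len(n)) {
    for (cc in seq_len(n)) {
      if (r == cc) next
      other <- if (mode == "pairwise") sets[[cc]] else {
        unique(unlist(sets[-r], use.names = FALSE))
      }
      m[r, cc] <- length(setdiff(sets[[r]], other))
    }
  }
  m
}

#' Compare a clustered assembly's KOIs with each single-k assembly
#'
#' For each single-k assembly: the number of KOIs annotated in that assembly
#' but missing from the CA (forward direction), and the number annotated in
#' the CA but missing from the single-k assembly (reverse direction). The
#' total sums the forward per-k counts row by row, the convention used when
#' such tables are printed, even though one KOI may be missing from the CA
#' in several rows; the size of the deduplicated union is reported alongside.
#'
#' @param caSet the CA's KOI set (character vector) or its
#'   [AnnotationTable-class].
#' @param singleSets named list of single-k KOI sets or annotation tables.
#' @param caLabel label for the CA (default \code{"CA"}).
#' @return A [CaComparisonReport-class].
#' @export
caComparison <- function(caSet, singleSets, caLabel = "CA") {
  if (is(caSet, "AnnotationTable")) {
    caLabel <- assemblyLabel(caSet)
    caSet <- koiSet(caSet)
  }
  singles <- asKoiSets(singleSets)
  if (!length(singles)) stop("need at least one single-k KOI set")
  if (caLabel %in% names(singles)) {
    stop("the CA label must be distinct from the single-k labels")
  }
  missingByK <- lapply(singles, function(s) sort(setdiff(s, caSet)))
  perK <- data.frame(
    label = names(singles),
    missing_from_ca = vapply(missingByK, length, 0L),
    missing_from_single = vapply(singles, function(s) length(setdiff(caSet, s)), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  new("CaComparisonReport",
      caLabel = caLabel, perK = perK, missingByK = missingByK,
      totalMissingFromCa = as.numeric(sum(perK$missing_from_ca)),
      totalMissingFromCaDistinct = as.numeric(length(unique(unlist(missingByK, use.names = FALSE)))))
}

#' Build a CA comparison report from published per-k counts
#'
#' Totals a table of per-k missing-KOI counts the way [caComparison()] does,
#' for use when only the printed counts (not the underlying KOI sets) are
#' available. The distinct-union size cannot be computed from counts alone
#' and is reported as NA.
#'
#' @param missingFromCa named numeric vector: per-k-label count of KOIs
#'   present in that single-k assembly but missing from the CA.
#' @param missingFromSingle optional named numeric vector for the reverse
#'   direction (defaults to NA).
#' @param caLabel label for the CA.
#' @return A [CaComparisonReport-class].
#' @examples
#' caReportFromCounts(c(k19 = 3, k21 = 1))
#' @export
caReportFromCounts <- function(missingFromCa, missingFromSingle = NULL, caLabel = "CA") {
  stopifnot(!is.null(names(missingFromCa)))
  if (is.null(missingFromSingle)) {
    missingFromSingle <- setNames(rep(NA_real_, length(missingFromCa)), names(missingFromCa))
  }
  perK <- data.frame(
    label = names(missingFromCa),
    missing_from_ca = as.numeric(missingFromCa),
    missing_from_single = as.numeric(missingFromSingle[names(missingFromCa)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  new("CaComparisonReport",
      caLabel = caLabel, perK = perK, missingByK = list(),
      totalMissingFromCa = sum(perK$missing_from_ca),
      totalMissingFromCaDistinct = NA_real_)
}

#' Select contigs covering a set of target KOIs
#'
#' Minimal covering selection: target KOIs are visited in sorted order; for
#' each KOI not yet covered by an already selected contig, the longest
#' contig annotated with it is chosen (ties broken by id, ascending). Longer
#' contigs are preferred because annotation accuracy improves with contig
#' length. KOIs with no annotated contig are returned in
#' \code{notCoverable} rather than raising an error.
#'
#' @param assembly the [Assembly-class] to draw contigs from.
#' @param table its [AnnotationTable-class].
#' @param targetKois non-empty character vector of KOIs to cover.
#' @return list with \code{contigIds} (character), \code{contigs}
#'   (the selected sub-[Assembly-class]) and \code{notCoverable} (character).
#' @export
uniqueContigsForKois <- function(assembly, table, targetKois) {
  stopifnot(is(assembly, "Assembly"), is(table, "AnnotationTable"),
            length(targetKois) >= 1L)
  e <- annotationEntries(table)
  e <- e[e$contig_id %in% contigIds(assembly), , drop = FALSE]
  lens <- setNames(Biostrings::width(contigs(assembly)), contigIds(assembly))
  kosByContig <- split(e$ko, e$contig_id)
  targets <- sort(unique(targetKois))
  covered <- character()
  chosen <- character()
  notCoverable <- character()
  for (ko in targets) {
    if (ko %in% covered) next
    cand <- unique(e$contig_id[e$ko == ko])
    if (!length(cand)) {
      notCoverable <- c(notCoverable, ko)
      next
    }
    pick <- cand[order(-lens[cand], cand)][1L]
    chosen <- c(chosen, pick)
    covered <- union(covered, intersect(kosByContig[[pick]], targets))
  }
  list(contigIds = chosen, contigs = assembly[chosen], notCoverable = notCoverable)
}

#' Recover annotations lost from the clustered assembly
#'
#' The final step of the multi-k optimization workflow: for each single-k
#' assembly (processed in ascending k order, so a KOI recovered once is not
#' re-added from a later k), the KOIs present in that assembly but missing
#' from the CA are identified, covering contigs are selected with
#' [uniqueContigsForKois()], and those whole contigs are incorporated into
#' the final assembly product prior to downstream annotation. The final
#' assembly's KOI set equals the union of the CA's KOIs and every single-k
#' assembly's KOIs.
#'
#' @param ca the CA as a [ClusterResult-class] or [Assembly-class].
#' @param caTable the CA's [AnnotationTable-class] (e.g. from
#'   [projectAnnotations()]).
#' @param singles list of \code{list(assembly =, table =)} pairs, one per
#'   single-k assembly.
#' @return A [RecoveryResult-class].
#' @export
recoverAnnotations <- function(ca, caTable, singles) {
  if (is(ca, "ClusterResult")) ca <- representatives(ca)
  stopifnot(is(ca, "Assembly"), is(caTable, "AnnotationTable"), length(singles) >= 1L)
  labs <- vapply(singles, function(s) assemblyLabel(s$assembly), "")
  kvals <- parseKLabel(labs)
  ord <- order(ifelse(is.na(kvals), Inf, kvals), labs)
  caKois <- koiSet(caTable)

  recoveredSeqs <- Biostrings::DNAStringSet()
  recoveredSrc <- character()
  recRows <- list()
  recEntries <- list()
  recovered <- character()
  notCoverable <- character()

  for (s in singles[ord]) {
    asm <- s$assembly
    tab <- s$table
    missing <- setdiff(koiSet(tab), c(caKois, recovered))
    if (!length(missing)) next
    sel <- uniqueContigsForKois(asm, tab, missing)
    notCoverable <- union(notCoverable, sel$notCoverable)
    if (!length(sel$contigIds)) next
    e <- annotationEntries(tab)
    for (cid in sel$contigIds) {
      newKois <- sort(intersect(e$ko[e$contig_id == cid], missing))
      newKois <- setdiff(newKois, recovered)
      nid <- paste0(assemblyLabel(asm), "|", cid)
      seqs <- contigs(asm)[cid]
      names(seqs) <- nid
      recoveredSeqs <- c(recoveredSeqs, seqs)
      recoveredSrc <- c(recoveredSrc, assemblyLabel(asm))
      recRows[[nid]] <- data.frame(
        contig_id = nid, source_label = assemblyLabel(asm),
        kois = paste(newKois, collapse = ","), stringsAsFactors = FALSE
      )
      allKois <- unique(e$ko[e$contig_id == cid])
      recEntries[[nid]] <- data.frame(contig_id = nid, ko = allKois,
                                      stringsAsFactors = FALSE)
      recovered <- union(recovered, newKois)
    }
  }

  finalSeqs <- c(contigs(ca), recoveredSeqs)
  finalAsm <- new("Assembly", label = "final", contigs = finalSeqs,
                  sourceLabels = c(sourceLabels(ca), recoveredSrc))
  finalEntries <- rbind(
    annotationEntries(caTable),
    do.call(rbind, c(recEntries, list(data.frame(contig_id = character(), ko = character()))))
  )
  new("RecoveryResult",
      finalAssembly = finalAsm,
      finalTable = AnnotationTable("final", finalEntries),
      recovered = do.call(rbind, c(recRows, list(data.frame(
        contig_id = character(), source_label = character(), kois = character())))),
      recoveredKois = sort(recovered),
      notCoverable = sort(notCoverable))
}

#' Per-assembly contig and KOI counts
#'
#' @param assemblies list of [Assembly-class].
#' @param tables list of matching [AnnotationTable-class] (same order).
#' @return data.frame with columns \code{label}, \code{n_contigs},
#'   \code{n_kois}, one row per assembly in input order.
#' @export
contigKoiCounts <- function(assemblies, tables) {
  stopifnot(length(assemblies) == length(tables))
  data.frame(
    label = vapply(assemblies, assemblyLabel, ""),
    n_contigs = vapply(assemblies, length, 0L),
    n_kois = vapply(tables, function(t) length(koiSet(t)), 0L),
    stringsAsFactors = FALSE
  )
}
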