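#' @include AllClasses.R
NULL

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substituteBases <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  nmut <- round(rate * n)
  if (nmut < 1L) return(seq)
  pos <- sample.int(n, nmut)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic transcript catalog with ground truth
#'
#' Creates \code{n} random DNA transcripts with lengths uniform in
#' \code{lengthRange}. The first \code{floor(koFraction * n)} transcripts (in
#' a random order) receive distinct synthetic KO labels; abundance classes
#' ("low"/"high") are assigned uniformly at random. The catalog is fully
#' reproducible from \code{(seed, params)}.
#'
#' @param n number of transcripts, >= 1.
#' @param lengthRange length bounds in bp, e.g. \code{c(150, 1200)}.
#' @param koFraction fraction of transcripts receiving a KO label, in [0, 1].
#' @param seed integer seed.
#' @return A [TruthCatalog-class].
#' @examples
#' simulateCatalog(10, c(100, 200), koFraction = 0.5, seed = 7)
#' @export
simulateCatalog <- function(n = 60, lengthRange = c(150, 900), koFraction = 0.6,
                            seed = 1) {
  stopifnot(n >= 1, length(lengthRange) == 2L, lengthRange[1L] >= 1,
            lengthRange[1L] <= lengthRange[2L], koFraction >= 0, koFraction <= 1)
  withSeed(seed, {
    lens <- sample(seq(lengthRange[1L], lengthRange[2L]), n, replace = TRUE)
    seqs <- vapply(lens, randomDna, "")
    nko <- floor(koFraction * n)
    kos <- rep(NA_character_, n)
    if (nko > 0L) {
      labeled <- sample.int(n, nko)
      kos[labeled] <- sprintf("K%05d", sample.int(99999L, nko))
    }
    tr <- data.frame(
      id = sprintf("t%04d", seq_len(n)),
      sequence = seqs,
      ko = kos,
      abundance = sample(c("low", "high"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    new("TruthCatalog", transcripts = tr, seed = as.numeric(seed),
        params = list(n = n, lengthRange = lengthRange, koFraction = koFraction))
  })
}

#' Simulate one single-k assembly from a catalog
#'
#' Each transcript is captured independently with the probability of its
#' abundance class (low-k assemblies capture low-abundance transcripts more
#' readily; high-k, high-abundance ones). A captured transcript is emitted
#' whole, or split into two fragments (probability \code{fragProb}, both
#' fragments inheriting the KO label), or duplicated alongside a copy with a
#' small substitution load (probability \code{dupProb}), creating the
#' intra-assembly redundancy that clustering later removes. Every emitted
#' contig derived from a KO-labeled transcript is listed in the annotation
#' table.
#'
#' @param catalog a [TruthCatalog-class].
#' @param k the assembly's k-mer length (odd, 19..63); labels the output.
#' @param captureLow,captureHigh capture probabilities for the two abundance
#'   classes, in [0, 1].
#' @param fragProb probability a captured transcript is fragmented.
#' @param dupProb probability a captured transcript is duplicated with edits.
#' @param editRate substitution rate for duplicated copies (default 0.02).
#' @param seed integer seed.
#' @return list with elements \code{assembly} ([Assembly-class]) and
#'   \code{table} ([AnnotationTable-class]).
#' @export
simulateAssembly <- function(catalog, k, captureLow = 0.8, captureHigh = 0.8,
                             fragProb = 0.15, dupProb = 0.1, editRate = 0.02,
                             seed = 1) {
  stopifnot(is(catalog, "TruthCatalog"),
            all(c(captureLow, captureHigh, fragProb, dupProb) >= 0),
            all(c(captureLow, captureHigh, fragProb, dupProb) <= 1))
  tr <- transcripts(catalog)
  label <- paste0("k", k)
  withSeed(seed, {
    seqs <- character()
    kos <- list()
    for (i in seq_len(nrow(tr))) {
      p <- if (tr$abundance[i] == "low") captureLow else captureHigh
      if (runif(1) > p) next
      id <- tr$id[i]
      sq <- tr$sequence[i]
      ko <- tr$ko[i]
      u <- runif(1)
      if (u < fragProb && nchar(sq) >= 4L) {
        cut <- max(2L, min(nchar(sq) - 2L,
                           round(nchar(sq) * runif(1, 0.3, 0.7))))
        ids <- paste0(id, c(".f1", ".f2"))
        seqs[ids] <- c(substr(sq, 1L, cut), substr(sq, cut + 1L, nchar(sq)))
        if (!is.na(ko)) kos[ids] <- list(ko, ko)
      } else if (u < fragProb + dupProb) {
        ids <- paste0(id, c("", ".d1"))
        seqs[ids] <- c(sq, substituteBases(sq, editRate))
        if (!is.na(ko)) kos[ids] <- list(ko, ko)
      } else {
        seqs[id] <- sq
        if (!is.na(ko)) kos[[id]] <- ko
      }
    }
    list(
      assembly = Assembly(label, seqs),
      table = AnnotationTable(label, kos)
    )
  })
}

defaultCaptureProfile <- function(kValues) {
  # Monotone schedule: low k favors low-abundance transcripts and produces
  # the most contigs; capture falls with k overall, matching the qualitative
  # contig-count trend across k 19..63. Fragmentation is highest at low k.
  t <- (kValues - 19) / (63 - 19)
  data.frame(
    k = kValues,
    captureLow = 0.95 - 0.60 * t,
    captureHigh = 0.55 + 0.20 * t,
    fragProb = 0.25 - 0.15 * t,
    dupProb = 0.10
  )
}

#' Simulate a full multi-k study with recorded truth
#'
#' Generates one synthetic assembly plus annotation table per k value using
#' a capture-probability schedule over k (by default monotone: low k favors
#' low-abundance transcripts, high k high-abundance ones, with overall
#' capture and fragmentation falling as k grows). The returned truth records
#' the per-k KOI sets, which KOIs each assembly uniquely carries, the union
#' over all assemblies, and any planted clustering losses.
#'
#' Clustering losses are planted explicitly: for \code{plantLosses} randomly
#' chosen KO-labeled transcripts, one "host" k emits an unannotated
#' elongated copy of the transcript (a random tail appended, so it wins
#' representative selection at any identity threshold) while a guaranteed
#' annotated copy is emitted whole in another k. The host representative
#' absorbs the annotated copies, so the planted KOIs are present in single-k
#' annotation but absent from the projected CA annotation — the situation
#' the recovery step exists to repair.
#'
#' @param catalog a [TruthCatalog-class].
#' @param kValues odd k values in 19..63 (default every odd k, 23 values).
#' @param profile data.frame with columns \code{k}, \code{captureLow},
#'   \code{captureHigh}, \code{fragProb}, \code{dupProb}; defaults to the
#'   monotone schedule above.
#' @param plantLosses number of KOIs to plant as clustering losses
#'   (default 3; 0 disables planting).
#' @param tailLength length in bp of the random tail on planted host copies.
#' @param seed integer seed.
#' @return list with \code{assemblies} (named list of [Assembly-class]),
#'   \code{tables} (named list of [AnnotationTable-class]) and \code{truth}
#'   (list: \code{perKKois}, \code{perKUnique}, \code{koiUnion},
#'   \code{plantedLostKois}, \code{catalog}).
#' @export
simulateMultikScenario <- function(catalog, kValues = seq(19L, 63L, 2L),
                                   profile = NULL, plantLosses = 3L,
                                   tailLength = 30L, seed = 1) {
  stopifnot(is(catalog, "TruthCatalog"), length(kValues) >= 2L)
  if (is.null(profile)) profile <- defaultCaptureProfile(kValues)
  tr <- transcripts(catalog)

  withSeed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, length(kValues) + 1L)
    labeled <- which(!is.na(tr$ko))
    plantLosses <- min(plantLosses, length(labeled))
    planted <- if (plantLosses > 0L) sort(sample(labeled, plantLosses)) else integer()
    hostK <- if (plantLosses > 0L) sample(seq_along(kValues), plantLosses, replace = TRUE) else integer()
    donorK <- vapply(hostK, function(h) {
      sample(setdiff(seq_along(kValues), h), 1L)
    }, 0L)
    tails <- vapply(rep(tailLength, plantLosses), randomDna, "")

    out <- vector("list", length(kValues))
    for (j in seq_along(kValues)) {
      row <- profile[profile$k == kValues[j], , drop = FALSE]
      stopifnot(nrow(row) == 1L)
      sim <- simulateAssembly(catalog, kValues[j],
                              captureLow = row$captureLow,
                              captureHigh = row$captureHigh,
                              fragProb = row$fragProb, dupProb = row$dupProb,
                              seed = seeds[j])
      out[[j]] <- sim
    }

    # apply the planted losses after the independent per-k draws
    for (p in seq_along(planted)) {
      i <- planted[p]
      id <- tr$id[i]
      sq <- tr$sequence[i]
      ko <- tr$ko[i]
      h <- hostK[p]
      d <- donorK[p]
      # Host k: drop every emission of this transcript before emitting the
      # elongated unannotated copy. In every other k, drop edited duplicate
      # copies of it: unlike whole copies and fragments they are not exact
      # substrings of the host copy, so at c = 1.0 they would survive as
      # annotated representatives and undo the planted loss.
      for (j in seq_along(kValues)) {
        asm <- out[[j]]$assembly
        tab <- out[[j]]$table
        pat <- if (j == h) paste0("^", id, "(\\.|$)") else paste0("^", id, "\\.d[0-9]+$")
        own <- grepl(pat, contigIds(asm))
        if (any(own)) asm <- asm[!own]
        e <- annotationEntries(tab)
        e <- e[!grepl(pat, e$contig_id), , drop = FALSE]
        out[[j]]$assembly <- asm
        out[[j]]$table <- AnnotationTable(assemblyLabel(tab), e)
      }
      hostSeqs <- c(as.character(contigs(out[[h]]$assembly)),
                    setNames(paste0(sq, tails[p]), paste0(id, ".x")))
      out[[h]]$assembly <- Assembly(assemblyLabel(out[[h]]$assembly), hostSeqs)
      # donor k: guarantee one annotated whole copy
      dAsm <- out[[d]]$assembly
      if (!id %in% contigIds(dAsm)) {
        dSeqs <- c(as.character(contigs(dAsm)), setNames(sq, id))
        out[[d]]$assembly <- Assembly(assemblyLabel(dAsm), dSeqs)
      }
      dTab <- out[[d]]$table
      e <- annotationEntries(dTab)
      if (!any(e$contig_id == id & e$ko == ko)) {
        e <- rbind(e, data.frame(contig_id = id, ko = ko, stringsAsFactors = FALSE))
      }
      out[[d]]$table <- AnnotationTable(assemblyLabel(dTab), e)
    }

    labels <- paste0("k", kValues)
    assemblies <- setNames(lapply(out, `[[`, "assembly"), labels)
    tables <- setNames(lapply(out, `[[`, "table"), labels)
    perK <- lapply(tables, koiSet)
    perKUnique <- lapply(seq_along(perK), function(j) {
      setdiff(perK[[j]], unique(unlist(perK[-j], use.names = FALSE)))
    })
    names(perKUnique) <- labels
    list(
      assemblies = assemblies,
      tables = tables,
      truth = list(
        perKKois = perK,
        perKUnique = perKUnique,
        koiUnion = sort(unique(unlist(perK, use.names = FALSE))),
        plantedLostKois = sort(tr$ko[planted]),
        catalog = catalog
      )
    )
  })
}

#' Simulate reads and an alignment stream for an assembly
#'
#' Emits exactly \code{readsPerContig} reads per contig (substrings at
#' random offsets; a contig shorter than the read length yields full-length
#' copies of itself) together with the matching legacy alignment stream: one
#' reference contig name per read, in read order. Closes the loop with
#' [countAlignments()] and [foldCoverage()], which returns exactly
#' \code{readsPerContig}.
#'
#' @param assembly an [Assembly-class].
#' @param readsPerContig number of reads per contig, >= 0.
#' @param readLength read length in bp.
#' @param seed integer seed.
#' @return list with \code{reads} ([ReadSet-class]) and \code{refNames}
#'   (character vector of reference names, one per read).
#' @export
simulateAlignments <- function(assembly, readsPerContig, readLength = 99L, seed = 1) {
  stopifnot(is(assembly, "Assembly"), readsPerContig >= 0)
  withSeed(seed, {
    seqs <- as.character(contigs(assembly))
    reads <- character()
    refs <- character()
    for (cid in names(seqs)) {
      sq <- seqs[[cid]]
      L <- nchar(sq)
      for (r in seq_len(readsPerContig)) {
        if (L <= readLength) {
          rd <- sq
        } else {
          off <- sample.int(L - readLength + 1L, 1L)
          rd <- substr(sq, off, off + readLength - 1L)
        }
        reads[paste0(cid, "_r", r)] <- rd
        refs <- c(refs, cid)
      }
    }
    list(reads = ReadSet(reads), refNames = refs)
  })
}

#' Write a legacy alignment stream (one reference name per line)
#' @param refNames character vector of reference contig names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLegacyAlignments <- function(refNames, path) {
  writeLines(refNames, path)
  invisible(path)
}

#' Write simulated alignments as a minimal SAM file
#'
#' Emits a valid SAM file (with \code{@SQ} header lines for every contig of
#' the target assembly) describing one perfect-match alignment record per
#' read. Intended for exercising the SAM input path of [countAlignments()].
#'
#' @param alignments result of [simulateAlignments()].
#' @param assembly the target [Assembly-class].
#' @param path output path (should end in .sam).
#' @return `path`, invisibly.
#' @export
writeSam <- function(alignments, assembly, path) {
  stopifnot(is(assembly, "Assembly"))
  seqs <- readSequences(alignments$reads)
  ids <- names(seqs)
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", contigIds(assembly),
            Biostrings::width(contigs(assembly)))
  )
  body <- sprintf("%s\t0\t%s\t1\t255\t%dM\t*\t0\t0\t%s\t*",
                  ids, alignments$refNames, Biostrings::width(seqs),
                  as.character(seqs))
  writeLines(c(header, body), path)
  invisible(path)
}
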