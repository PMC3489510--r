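#' @include AllClasses.R
NULL

#' Read a contig FASTA file into an Assembly
#'
#' Reads a (optionally gzip-compressed) FASTA file of assembled contigs. The
#' header token before the first whitespace becomes the contig id; sequences
#' are uppercased. Duplicate ids and characters outside ACGTN are hard
#' errors; an empty file yields an empty Assembly with a warning.
#'
#' @param path path to a FASTA file (plain or .gz).
#' @param sourceLabel assembly label to attach, e.g. \code{"k19"}.
#' @return An [Assembly-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1 some description", "acgt", ">c2", "TTTT"), fa)
#' readFasta(fa, "k19")
#' @export
readFasta <- function(path, sourceLabel) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
    return(Assembly(sourceLabel))
  }
  ids <- sub("[[:space:]].*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate contig id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  # readDNAStringSet accepts the full IUPAC alphabet; restrict to ACGTN here
  # and uppercase. Going through character keeps the error message simple.
  chr <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ",
         paste(head(ids[bad], 3L), collapse = ", "))
  }
  names(chr) <- ids
  Assembly(sourceLabel, chr)
}

#' Write an Assembly to FASTA
#'
#' Writes contigs in input order, wrapping sequence lines at a fixed width.
#' Re-reading the file with [readFasta()] reproduces ids and sequences
#' exactly.
#'
#' @param assembly an [Assembly-class].
#' @param path output path.
#' @param width line wrap width in bases (default 60).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(assembly, path, width = 60L) {
  stopifnot(is(assembly, "Assembly"), width >= 1L)
  Biostrings::writeXStringSet(contigs(assembly), filepath = path, width = as.integer(width))
  invisible(path)
}

#' Read a contig-to-KOI annotation table
#'
#' Reads a two-column TSV mapping contig ids to KO identifiers, one (contig,
#' KOI) pair per line; the KO field may be empty (unannotated contig) and the
#' same contig id may appear on several lines (its KOIs accumulate). This is
#' the package's own minimal interchange format for annotation output such
#' as KAAS's; in permissive mode columns beyond the second are ignored.
#'
#' @param path path to the TSV file (plain or .gz).
#' @param assemblyLabel label of the annotated assembly.
#' @param permissive ignore extra columns (default TRUE).
#' @return An [AnnotationTable-class].
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("c1\tK00001", "c1\tK00002", "c2\t"), tsv)
#' readAnnotationTable(tsv, "k19")
#' @export
readAnnotationTable <- function(path, assemblyLabel, permissive = TRUE) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(AnnotationTable(assemblyLabel))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (!permissive && any(lengths(parts) > 2L)) {
    stop("more than 2 columns at line ", which(lengths(parts) > 2L)[1L])
  }
  cid <- trimws(vapply(parts, `[`, "", 1L))
  ko <- trimws(vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", ""))
  has <- nzchar(ko)
  bad <- has & !isKo(ko)
  if (any(bad)) {
    stop(sprintf("malformed KO identifier '%s' at line %d", ko[which(bad)[1L]], which(bad)[1L]))
  }
  AnnotationTable(assemblyLabel, data.frame(
    contig_id = cid[has], ko = ko[has], stringsAsFactors = FALSE
  ))
}

#' Write an annotation table as TSV
#'
#' Inverse of [readAnnotationTable()]: one \code{contig_id<TAB>ko} line per
#' (contig, KOI) pair.
#'
#' @param table an [AnnotationTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTable <- function(table, path) {
  stopifnot(is(table, "AnnotationTable"))
  e <- annotationEntries(table)
  writeLines(paste(e$contig_id, e$ko, sep = "\t"), path)
  invisible(path)
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' @param path path to a FASTA or FASTQ file (plain or .gz); the format is
#'   taken from the extension unless given.
#' @param format "auto", "fasta" or "fastq".
#' @return A [ReadSet-class].
#' @export
readReads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  if (format == "fastq") {
    seqs <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    quals <- as.character(S4Vectors::mcols(seqs)$qualities)
  } else {
    seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
    quals <- character()
  }
  names(seqs) <- sub("[[:space:]].*$", "", names(seqs))
  ReadSet(Biostrings::DNAStringSet(toupper(as.character(seqs)), use.names = TRUE), quals)
}

#' Project source annotations onto a pooled or clustered assembly
#'
#' Contigs in pooled assemblies (and hence in CA representatives) carry ids
#' of the form \code{<source_label>|<original id>}. This looks each contig's
#' original id up in its source assembly's annotation table and returns the
#' annotation table of the given assembly. Contigs whose original id has no
#' annotation contribute nothing.
#'
#' @param assembly an [Assembly-class] with namespaced ids (see
#'   [poolAssemblies()]).
#' @param tables named list of [AnnotationTable-class], keyed by source label.
#' @return An [AnnotationTable-class] for `assembly`.
#' @export
projectAnnotations <- function(assembly, tables) {
  stopifnot(is(assembly, "Assembly"), is.list(tables))
  ids <- contigIds(assembly)
  src <- sourceLabels(assembly)
  orig <- sub("^[^|]*\\|", "", ids)
  out <- vector("list", length(tables))
  for (lab in names(tables)) {
    sel <- src == lab
    if (!any(sel)) next
    e <- annotationEntries(tables[[lab]])
    m <- e[e$contig_id %in% orig[sel], , drop = FALSE]
    if (!nrow(m)) next
    # map original ids back to the namespaced ids of this source
    lookup <- setNames(ids[sel], orig[sel])
    m$contig_id <- unname(lookup[m$contig_id])
    out[[lab]] <- m
  }
  entries <- do.call(rbind, c(out, list(data.frame(contig_id = character(), ko = character()))))
  AnnotationTable(assemblyLabel(assembly), entries)
}
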