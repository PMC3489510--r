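#' @include AllClasses.R
NULL

#' Run the multi-k optimization workflow end to end
#'
#' Executes, in order: per-assembly metrics and KOI summaries; CA
#' construction by pooling and greedy clustering; the pairwise missing-KOI
#' matrix; the CA-versus-single-k comparison; and annotation recovery.
#' Writes \code{metrics.tsv}, \code{koi_counts.tsv}, \code{ca.fasta},
#' \code{ca_members.tsv}, \code{matrix.tsv}, \code{ca_comparison.tsv},
#' \code{final.fasta}, \code{final_annotations.tsv}, \code{recovery.json}
#' and \code{run_report.json} under the output directory. Inputs are never
#' mutated; identical inputs and config give byte-identical outputs (aside
#' from timings in the run report).
#'
#' @param config a named list, or the path of a YAML file holding one, with
#'   entries:
#'   \describe{
#'     \item{assemblies}{named list, label -> contig FASTA path.}
#'     \item{annotations}{named list, label -> annotation TSV path (labels
#'       must match \code{assemblies}).}
#'     \item{cluster}{optional list with \code{identity} (default 1.0),
#'       \code{word_size} (8), \code{both_strands} (TRUE).}
#'     \item{comparison_mode}{"pairwise" (default) or "vs-rest".}
#'     \item{outdir}{output directory (created if needed).}
#'   }
#' @param overrides optional named list merged over the config (CLI flags).
#' @return invisibly, a list with the in-memory stage results
#'   (\code{metrics}, \code{counts}, \code{ca}, \code{matrix},
#'   \code{comparison}, \code{recovery}) and the run report.
#' @export
runWorkflow <- function(config, overrides = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config[names(overrides)] <- overrides
  for (field in c("assemblies", "annotations", "outdir")) {
    if (is.null(config[[field]])) stop("config error: missing '", field, "'")
  }
  labels <- names(config$assemblies)
  if (!setequal(labels, names(config$annotations))) {
    stop("config error: assembly and annotation labels differ")
  }
  cl <- config$cluster
  params <- ClusterParams(
    identityThreshold = if (is.null(cl$identity)) 1.0 else cl$identity,
    wordSize = if (is.null(cl$word_size)) 8L else cl$word_size,
    bothStrands = if (is.null(cl$both_strands)) TRUE else cl$both_strands
  )
  mode <- if (is.null(config$comparison_mode)) "pairwise" else config$comparison_mode
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message("[", name, "] running")
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  inputs <- stage("load", {
    list(
      assemblies = lapply(labels, function(l) readFasta(config$assemblies[[l]], l)),
      tables = lapply(labels, function(l) readAnnotationTable(config$annotations[[l]], l))
    )
  })
  names(inputs$assemblies) <- names(inputs$tables) <- labels

  metrics <- stage("metrics", {
    m <- do.call(rbind, lapply(inputs$assemblies, function(a) {
      as.data.frame(assemblyMetrics(a))
    }))
    write.table(m, file.path(outdir, "metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    m
  })

  counts <- stage("koi_counts", {
    cnt <- contigKoiCounts(inputs$assemblies, inputs$tables)
    write.table(cnt, file.path(outdir, "koi_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cnt
  })

  ca <- stage("cluster", {
    res <- buildCA(inputs$assemblies, params)
    writeFasta(representatives(res), file.path(outdir, "ca.fasta"))
    writeClusterMembers(res, file.path(outdir, "ca_members.tsv"))
    res
  })
  caTable <- projectAnnotations(representatives(ca), inputs$tables)

  mat <- stage("matrix", {
    m <- pairwiseMissingMatrix(inputs$tables, mode = mode)
    write.table(m, file.path(outdir, "matrix.tsv"), sep = "\t", quote = FALSE,
                col.names = NA)
    m
  })

  comparison <- stage("compare", {
    rep <- caComparison(caTable, inputs$tables)
    out <- rep@perK
    out <- rbind(out, data.frame(label = "TOTAL",
                                 missing_from_ca = rep@totalMissingFromCa,
                                 missing_from_single = NA))
    write.table(out, file.path(outdir, "ca_comparison.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rep
  })

  recovery <- stage("recover", {
    singles <- lapply(labels, function(l) {
      list(assembly = inputs$assemblies[[l]], table = inputs$tables[[l]])
    })
    rec <- recoverAnnotations(ca, caTable, singles)
    writeFasta(finalAssembly(rec), file.path(outdir, "final.fasta"))
    writeAnnotationTable(rec@finalTable, file.path(outdir, "final_annotations.tsv"))
    jsonlite::write_json(list(
      recovered_contigs = rec@recovered,
      recovered_kois = rec@recoveredKois,
      not_coverable = rec@notCoverable
    ), file.path(outdir, "recovery.json"), auto_unbox = TRUE, pretty = TRUE)
    rec
  })

  report <- list(
    package = "multika",
    version = as.character(utils::packageVersion("multika")),
    params = list(
      identity_threshold = params@identityThreshold,
      word_size = params@wordSize,
      both_strands = params@bothStrands,
      comparison_mode = mode
    ),
    config = config[setdiff(names(config), "outdir")],
    n_assemblies = length(labels),
    n_representatives = length(representatives(ca)),
    total_missing_from_ca = comparison@totalMissingFromCa,
    n_recovered_kois = length(recoveredKois(recovery)),
    timings_s = timings
  )
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    metrics = metrics, counts = counts, ca = ca, matrix = mat,
    comparison = comparison, recovery = recovery, report = report
  ))
}
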