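#' @include AllClasses.R
NULL

#' Published per-k missing-KOI counts for reference clustered assemblies
#'
#' Loads the package's copy of a published reference table from a multi-k
#' (odd k, 19 to 63) de novo transcriptome study of a green microalga: for
#' each single-k assembly, the number of KOIs annotated in that assembly but
#' missing from the clustered assembly, for CAs built with the Oases multi-k
#' merge, CD-HIT-EST at identity thresholds 0.90, 0.95 and 1.00, and VMATCH.
#' These counts are input data for the totaling conventions of
#' [caReportFromCounts()]; the package does not attempt to reproduce them
#' from sequence (that would require the original read set and the original
#' external tools).
#'
#' @return data.frame with columns \code{k}, \code{oases_multik},
#'   \code{cdhit_c0.90}, \code{cdhit_c0.95}, \code{cdhit_c1.00},
#'   \code{vmatch}; one row per odd k in 19..63.
#' @examples
#' counts <- publishedCaMissingCounts()
#' rpt <- caReportFromCounts(setNames(counts$cdhit_c1.00, paste0("k", counts$k)))
#' totalMissingFromCa(rpt)  # 456
#' @export
publishedCaMissingCounts <- function() {
  path <- system.file("extdata", "published_ca_missing_kois.tsv",
                      package = "multika", mustWork = TRUE)
  read.delim(path, check.names = FALSE)
}
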