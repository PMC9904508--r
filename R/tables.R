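## Readers for the packaged worked-example tables: summary statistics,
## QTL/detection tables and gene lists distilled from a published rice
## salt-tolerance mapping study, used as desk-scale inputs for the
## table-arithmetic, stability and colocalization stages.

.exampleFile <- function(name) {
  path <- system.file("extdata", name, package = "saltQTL")
  if (path == "") stop("worked-example file not found: ", name)
  path
}

#' Worked-example tables
#'
#' Small packaged tables that exercise the arithmetic/rule stages of the
#' pipeline on real published summary numbers: a per-chromosome bin-map
#' summary, a 12-QTL mapping table, a 5-region x 6-cell cross-condition
#' detection matrix, six-class DEG counts for the parent and bulk
#' comparisons (plus the direction-split common counts), and the candidate
#' gene list with coordinates.
#'
#' @return \code{workedExampleMapSummary}: per-chromosome data.frame in the
#'   \code{\link{mapSummary}} layout.
#' @name workedExample
NULL

#' @rdname workedExample
#' @export
workedExampleMapSummary <- function() {
  read.csv(.exampleFile("worked_example_map_summary.csv"),
           stringsAsFactors = FALSE)
}

#' @rdname workedExample
#' @return \code{workedExampleQtlTable}: data.frame of 12 QTLs with LOD,
#'   genetic and physical (Mb) intervals, PVE\% and additive effects.
#' @export
workedExampleQtlTable <- function() {
  read.csv(.exampleFile("worked_example_qtl_table.csv"),
           stringsAsFactors = FALSE)
}

#' @rdname workedExample
#' @return \code{workedExampleDetectionMatrix}: list with \code{regions}
#'   (chrom, qtl, cM and Mb bounds) and \code{detection} (logical matrix,
#'   columns \code{<condition>.<trait>}).
#' @export
workedExampleDetectionMatrix <- function() {
  df <- read.csv(.exampleFile("worked_example_detection_matrix.csv"),
                 stringsAsFactors = FALSE, check.names = FALSE)
  cells <- as.vector(outer(c("greenhouse", "field", "BLUP"),
                           c("W2SES", "W4SES"), paste, sep = "."))
  det <- as.matrix(df[, cells]) == 1
  list(regions = df[, c("chrom", "qtl", "cm_start", "cm_end",
                        "mb_start", "mb_end")],
       detection = det)
}

#' @rdname workedExample
#' @return \code{workedExampleDegClassCounts}: list with named six-class
#'   count vectors \code{parent} and \code{bulk}, and scalars
#'   \code{common_up} / \code{common_down}.
#' @export
workedExampleDegClassCounts <- function() {
  df <- read.csv(.exampleFile("worked_example_deg_class_counts.csv"),
                 stringsAsFactors = FALSE)
  common <- read.csv(.exampleFile("worked_example_deg_common_counts.csv"),
                     stringsAsFactors = FALSE)
  list(parent = setNames(df$parent, df$class),
       bulk = setNames(df$bulk, df$class),
       common_up = common$n[common$direction == "up"],
       common_down = common$n[common$direction == "down"])
}

#' @rdname workedExample
#' @return \code{workedExampleCandidateGenes}: list with \code{table}
#'   (data.frame gene_id, chrom, start, end, qtl) and \code{granges}.
#' @export
workedExampleCandidateGenes <- function() {
  df <- read.csv(.exampleFile("worked_example_candidate_genes.csv"),
                 stringsAsFactors = FALSE)
  list(table = df,
       granges = GRanges(df$chrom, IRanges(df$start, df$end),
                         gene_id = df$gene_id))
}

#' @rdname workedExample
#' @return \code{workedExampleStableRegions}: data.frame of the five regions
#'   with Mb bounds and QTL labels, ready for
#'   \code{\link{overlayCandidates}}.
#' @export
workedExampleStableRegions <- function() {
  workedExampleDetectionMatrix()$regions
}
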