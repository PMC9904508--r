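## DEG x QTL colocalization: gene-model parsing and overlay of shared
## salt-specific DEGs on stable QTL physical intervals.

#' Read gene models from GFF3
#'
#' Parses gene-type features (1-based inclusive coordinates preserved) and
#' returns them sorted by chromosome, then start.
#'
#' @param path GFF3 file.
#' @return GRanges with a \code{gene_id} metadata column.
#' @export
readAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[mcols(gr)$type == "gene"]
  if (!length(gr)) stop("no gene features in ", path)
  id <- mcols(gr)$ID
  if (is.null(id)) id <- mcols(gr)$gene_id
  mcols(gr) <- DataFrame(gene_id = as.character(id))
  gr[order(as.character(seqnames(gr)), start(gr))]
}

## stable regions in any of the accepted forms -> GRanges with qtl label
.regionsAsGRanges <- function(regions) {
  if (is(regions, "GRanges")) {
    gr <- regions
    if (is.null(mcols(gr)$qtl)) mcols(gr)$qtl <- sprintf("region%02d", seq_along(gr))
    return(gr)
  }
  stopifnot(is.data.frame(regions))
  start <- if ("bp_start" %in% names(regions)) regions$bp_start
           else round(regions$mb_start * 1e6)
  end <- if ("bp_end" %in% names(regions)) regions$bp_end
         else round(regions$mb_end * 1e6)
  qtl <- if ("qtl" %in% names(regions)) regions$qtl
         else sprintf("region%02d", seq_len(nrow(regions)))
  GRanges(regions$chrom, IRanges(start, end), qtl = qtl)
}

#' Overlay shared DEGs on stable QTL intervals
#'
#' A shared salt-specific DEG becomes a candidate when its gene model
#' overlaps a stable region by at least 1 bp (\code{rule = "overlap"}) or
#' lies entirely within it (\code{rule = "within"}). Mb-precision region
#' bounds are converted to bp as round(Mb x 1e6).
#'
#' @param shared_degs character vector of shared DEG gene ids, or a
#'   data.frame with a \code{gene} column (extra columns such as class and
#'   direction are carried through).
#' @param gene_models GRanges with \code{gene_id} (from
#'   \code{\link{readAnnotation}} or the generator).
#' @param stable_regions data.frame with \code{chrom} and either
#'   \code{bp_start}/\code{bp_end} or \code{mb_start}/\code{mb_end} (plus an
#'   optional \code{qtl} label), or an equivalent GRanges.
#' @param rule overlap rule, \code{"overlap"} (default) or \code{"within"}.
#' @return data.frame of candidates sorted by chromosome then position:
#'   gene, chrom, start, end, qtl (comma-joined when a gene touches several
#'   regions), n_regions, plus any carried columns.
#' @export
overlayCandidates <- function(shared_degs, gene_models, stable_regions,
                              rule = c("overlap", "within")) {
  rule <- match.arg(rule)
  deg_df <- if (is.data.frame(shared_degs)) shared_degs
            else data.frame(gene = as.character(shared_degs))
  stopifnot("gene" %in% names(deg_df))
  gm <- gene_models[mcols(gene_models)$gene_id %in% deg_df$gene]
  reg <- .regionsAsGRanges(stable_regions)
  hits <- findOverlaps(gm, reg,
                       type = if (rule == "within") "within" else "any")
  if (!length(hits))
    return(data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      qtl = character(0), n_regions = integer(0)))
  qh <- queryHits(hits); sh <- subjectHits(hits)
  by_gene <- split(sh, qh)
  gi <- as.integer(names(by_gene))
  out <- data.frame(
    gene = mcols(gm)$gene_id[gi],
    chrom = as.character(seqnames(gm))[gi],
    start = start(gm)[gi], end = end(gm)[gi],
    qtl = vapply(by_gene, function(s)
      paste(unique(mcols(reg)$qtl[s]), collapse = ","), ""),
    n_regions = vapply(by_gene, function(s) length(unique(s)), 0L),
    row.names = NULL)
  extra <- setdiff(names(deg_df), "gene")
  if (length(extra))
    out <- cbind(out, deg_df[match(out$gene, deg_df$gene), extra, drop = FALSE])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate tallies per stable region
#'
#' Counts candidates overlapping each region, including zero-count regions;
#' genes touching several regions count once per region.
#'
#' @param candidates data.frame from \code{\link{overlayCandidates}}.
#' @param stable_regions regions in any form accepted by
#'   \code{\link{overlayCandidates}}.
#' @return data.frame: chrom, bp_start, bp_end, qtl, n_candidates.
#' @export
perRegionCounts <- function(candidates, stable_regions) {
  reg <- .regionsAsGRanges(stable_regions)
  n <- if (nrow(candidates)) {
    countOverlaps(reg, GRanges(candidates$chrom,
                               IRanges(candidates$start, candidates$end)))
  } else rep(0L, length(reg))
  data.frame(chrom = as.character(seqnames(reg)), bp_start = start(reg),
             bp_end = end(reg), qtl = mcols(reg)$qtl,
             n_candidates = as.integer(n), row.names = NULL)
}
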