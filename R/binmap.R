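## Bin-map construction: depth/quality filtering, sliding-window genotype
## calling, collapse to recombination bins, RIL-corrected recombination
## fractions, Kosambi genetic distances, and map summary statistics.

#' Map function utilities
#'
#' \code{kosambiDistance} converts a meiotic recombination fraction r into a
#' genetic distance d = 25 ln((1+2r)/(1-2r)) cM. \code{rilCorrectRf} converts
#' an observed recombinant fraction R between homozygous RIL genotypes into
#' the meiotic r = R / (2(1-R)), the inverse of the selfed-RIL expansion
#' R = 2r/(1+2r). \code{haldaneRf} is the inverse Haldane map function,
#' r = (1 - exp(-2d/100))/2, used when placing simulated loci.
#'
#' @param r meiotic recombination fraction(s) in [0, 0.5).
#' @param R observed RIL recombinant fraction(s) in [0, 0.5).
#' @param d_cm genetic distance(s) in cM.
#' @return numeric vector.
#' @name mapFunctions
NULL

#' @rdname mapFunctions
#' @export
kosambiDistance <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname mapFunctions
#' @export
rilCorrectRf <- function(R) {
  if (any(R < 0 | R >= 0.5)) stop("R must lie in [0, 0.5)")
  R / (2 * (1 - R))
}

#' @rdname mapFunctions
#' @export
haldaneRf <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

#' Filter SNP calls on depth and sites on quality
#'
#' Calls below \code{min_depth} are set to missing (per line); sites below
#' \code{min_quality} are dropped entirely. Counts of affected calls/sites are
#' reported via \code{message} and attached as the \code{"filter_log"}
#' attribute of the result.
#'
#' @param snps a \code{\linkS4class{SnpGenotypes}}.
#' @param min_depth minimum per-call sequencing depth (default 3).
#' @param min_quality minimum per-site quality score (default 30).
#' @return a filtered \code{SnpGenotypes}.
#' @export
filterSnps <- function(snps, min_depth = 3, min_quality = 30) {
  stopifnot(is(snps, "SnpGenotypes"))
  if (length(snpSites(snps)) == 0) stop("empty SNP matrix")
  calls <- snpCalls(snps); depth <- snpDepth(snps)
  low <- depth < min_depth & calls != "U"
  calls[low] <- "U"
  keep <- mcols(snpSites(snps))$quality >= min_quality
  if (!any(keep)) stop("all sites removed by the quality filter")
  message(sprintf("filterSnps: %d call(s) set missing by depth < %g; %d site(s) dropped by quality < %g",
                  sum(low), min_depth, sum(!keep), min_quality))
  out <- new("SnpGenotypes", calls = calls[, keep, drop = FALSE],
             sites = snpSites(snps)[keep],
             depth = depth[, keep, drop = FALSE])
  attr(out, "filter_log") <- c(calls_masked = sum(low), sites_dropped = sum(!keep))
  out
}

## running window sums of an indicator matrix, window ws, step 1
.runSum <- function(M, ws) {
  if (ws == 1L) return(M)
  cs <- t(apply(M, 1, cumsum))
  W <- ncol(M) - ws + 1L
  if (W == 1L) return(cs[, ncol(M), drop = FALSE])
  cbind(cs[, ws, drop = FALSE],
        cs[, (ws + 1L):ncol(M), drop = FALSE] - cs[, 1:(W - 1L), drop = FALSE])
}

#' Sliding-window genotype calls
#'
#' Joins consecutive SNPs into windows of \code{window_size} SNPs stepping one
#' SNP at a time. Within a window the call is decided by the ratio of
#' parental SNP calls among non-missing ones: A if fraction(A) >=
#' \code{homo_fraction}, B if fraction(B) >= \code{homo_fraction}, otherwise
#' H; U if every call in the window is missing. A chromosome with fewer SNPs
#' than \code{window_size} collapses to a single whole-chromosome window,
#' with a warning.
#'
#' @param snps a \code{SnpGenotypes} (ideally after \code{\link{filterSnps}}).
#' @param window_size window width in SNPs (default 15).
#' @param homo_fraction homozygous-call fraction threshold (default 0.7).
#' @return named list per chromosome: \code{calls} (lines x windows matrix),
#'   \code{center_bp} (window center positions), \code{chrom_length}.
#' @export
callWindows <- function(snps, window_size = 15, homo_fraction = 0.7) {
  stopifnot(is(snps, "SnpGenotypes"), window_size >= 1)
  chr <- as.character(seqnames(snpSites(snps)))
  pos <- start(snpSites(snps))
  sl <- seqlengths(snpSites(snps))
  out <- list()
  for (cc in unique(chr)) {
    j <- which(chr == cc)
    calls <- snpCalls(snps)[, j, drop = FALSE]
    p <- pos[j]
    ws <- window_size
    if (length(j) < window_size) {
      warning(sprintf("chromosome %s has %d SNPs < window size %d; using one window",
                      cc, length(j), window_size))
      ws <- length(j)
    }
    nA <- .runSum(matrix(as.numeric(calls == "A"), nrow(calls)), ws)
    nB <- .runSum(matrix(as.numeric(calls == "B"), nrow(calls)), ws)
    nH <- .runSum(matrix(as.numeric(calls == "H"), nrow(calls)), ws)
    inf <- nA + nB + nH
    w <- matrix("H", nrow(calls), ncol(nA), dimnames = list(rownames(calls), NULL))
    w[inf > 0 & nA / pmax(inf, 1) >= homo_fraction] <- "A"
    w[inf > 0 & nB / pmax(inf, 1) >= homo_fraction] <- "B"
    w[inf == 0] <- "U"
    centers <- p[seq_len(ncol(nA)) + (ws - 1L) %/% 2L]
    len <- if (!is.na(sl[cc])) as.numeric(sl[cc]) else max(p)
    out[[cc]] <- list(calls = w, center_bp = centers, chrom_length = len)
  }
  out
}

## Refine one line's window-call sequence. Windows straddling a crossover
## mix calls from both parents and come out H, so a true A->B junction reads
## A..A H..H B..B; the H transition run is split at its midpoint between the
## two homozygous flanks, recovering a point breakpoint. Missing (U) runs are
## bridged when both flanks agree and split like transition runs when they
## differ. Internal H runs with identical homozygous flanks are genuine
## residual heterozygous tracts and are kept. Edge U runs are absorbed into
## their single neighbour.
.refineLineCalls <- function(w) {
  for (pass in 1:2) {
    r <- rle(w)
    k <- length(r$values)
    if (k <= 1) return(w)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    vals <- r$values
    if (vals[1] == "U") w[starts[1]:ends[1]] <- vals[2]
    if (vals[k] == "U") w[starts[k]:ends[k]] <- vals[k - 1]
    if (k > 2) for (t in 2:(k - 1)) {
      v <- vals[t]
      left <- vals[t - 1]; right <- vals[t + 1]
      if (v == "U") {
        if (left == right) w[starts[t]:ends[t]] <- left
        else {
          half <- r$lengths[t] %/% 2L
          if (half > 0) w[starts[t]:(starts[t] + half - 1L)] <- left
          w[(starts[t] + half):ends[t]] <- right
        }
      } else if (v == "H" && left %in% c("A", "B") && right %in% c("A", "B") &&
                 left != right) {
        half <- r$lengths[t] %/% 2L
        if (half > 0) w[starts[t]:(starts[t] + half - 1L)] <- left
        w[(starts[t] + half):ends[t]] <- right
      }
    }
  }
  w
}

#' Collapse window calls into population-level recombination bins
#'
#' Per line, runs of identical window calls form tracts; a breakpoint between
#' two tracts is placed at the midpoint between the centers of the flanking
#' windows. Short heterozygous/missing transition runs created by windows
#' that straddle a crossover are first refined to a point breakpoint (see
#' \code{refine}). The population bin boundaries are the union of all lines'
#' breakpoints, so bins tile each chromosome exactly and every line is
#' constant within a bin. Adjacent bins identical in every line are merged.
#'
#' @param window_calls result of \code{\link{callWindows}}.
#' @param refine refine per-line transition tracts before collapsing
#'   (default TRUE; FALSE keeps the raw window-call tracts).
#' @param min_line_frac minimum fraction of lines with a non-missing bin
#'   genotype for the bin to enter the linkage map (default 0.8); all bins are
#'   kept in the physical tiling either way.
#' @return a \code{\linkS4class{BinMap}} with genetic positions from
#'   RIL-corrected Kosambi distances between adjacent mapped bins.
#' @export
collapseToBins <- function(window_calls, min_line_frac = 0.8, refine = TRUE) {
  all_bins <- NULL; all_geno <- NULL
  for (cc in names(window_calls)) {
    wc <- window_calls[[cc]]
    w <- wc$calls; centers <- wc$center_bp; W <- ncol(w)
    if (refine && W > 1) w <- t(apply(w, 1, .refineLineCalls))
    bp <- integer(0)
    if (W > 1) {
      for (l in seq_len(nrow(w))) {
        tr <- which(w[l, -1L] != w[l, -W])
        if (length(tr))
          bp <- c(bp, as.integer((centers[tr] + centers[tr + 1L]) %/% 2))
      }
    }
    bp <- sort(unique(bp))
    starts <- c(1, bp + 1)
    ends <- c(bp, wc$chrom_length)
    ## genotype of each bin per line = the line's window call at the first
    ## window center inside the bin (constant within the bin by construction)
    first_center <- findInterval(starts - 1L, centers) + 1L
    first_center <- pmin(first_center, W)
    geno <- w[, first_center, drop = FALSE]
    ## merge adjacent bins with identical genotype columns
    if (ncol(geno) > 1) {
      same <- c(FALSE, vapply(2:ncol(geno), function(j)
        all(geno[, j] == geno[, j - 1L]), TRUE))
      grp <- cumsum(!same)
      starts <- tapply(starts, grp, min)
      ends <- tapply(ends, grp, max)
      geno <- geno[, !same, drop = FALSE]
    }
    all_bins <- rbind(all_bins, data.frame(chrom = cc, start = as.numeric(starts),
                                           end = as.numeric(ends)))
    all_geno <- cbind(all_geno, geno)
  }
  informative <- colMeans(all_geno != "U")
  mapped <- informative >= min_line_frac
  cm <- rep(NA_real_, nrow(all_bins))
  for (cc in unique(all_bins$chrom)) {
    i <- which(all_bins$chrom == cc & mapped)
    if (!length(i)) next
    if (length(i) == 1) { cm[i] <- 0; next }
    d <- numeric(length(i) - 1)
    for (k in seq_len(length(i) - 1)) {
      R <- .pairRf(all_geno[, i[k]], all_geno[, i[k + 1]])
      if (is.na(R)) {
        warning(sprintf("no informative lines between bins %d and %d on %s; distance set to 0",
                        i[k], i[k + 1], cc))
        d[k] <- 0
      } else d[k] <- kosambiDistance(rilCorrectRf(R))
    }
    cm[i] <- cumsum(c(0, d))
  }
  bins <- GRanges(all_bins$chrom, IRanges(all_bins$start, all_bins$end),
                  cm = cm, mapped = mapped)
  sl <- vapply(window_calls, function(z) z$chrom_length, 0)
  seqlengths(bins) <- sl[seqlevels(bins)]
  colnames(all_geno) <- NULL
  new("BinMap", bins = bins, geno = all_geno)
}

## observed recombinant fraction between two bin genotype columns; NA when no
## informative (homozygous, non-missing in both) lines exist
.pairRf <- function(g1, g2) {
  inf <- g1 %in% c("A", "B") & g2 %in% c("A", "B")
  if (!any(inf)) return(NA_real_)
  min(mean(g1[inf] != g2[inf]), 0.49999)
}

#' Observed recombinant fractions between adjacent mapped bins
#'
#' R = (number of lines whose homozygous genotypes differ between the two
#' bins) / (number of lines homozygous and non-missing at both); clamped to
#' [0, 0.49999]. Heterozygous and missing lines are excluded.
#'
#' @param binmap a \code{BinMap}.
#' @return data.frame: chrom, bin1, bin2, n_informative, R.
#' @export
estimateAdjacentRf <- function(binmap) {
  stopifnot(is(binmap, "BinMap"))
  chr <- as.character(seqnames(binRanges(binmap)))
  mapped <- mcols(binRanges(binmap))$mapped
  geno <- binGenotypes(binmap)
  out <- NULL
  for (cc in unique(chr)) {
    i <- which(chr == cc & mapped)
    if (length(i) < 2) next
    for (k in seq_len(length(i) - 1)) {
      g1 <- geno[, i[k]]; g2 <- geno[, i[k + 1]]
      inf <- sum(g1 %in% c("A", "B") & g2 %in% c("A", "B"))
      out <- rbind(out, data.frame(chrom = cc, bin1 = i[k], bin2 = i[k + 1],
                                   n_informative = inf,
                                   R = .pairRf(g1, g2)))
    }
  }
  out
}

#' Build a bin map from observed SNP genotypes
#'
#' Convenience wrapper: \code{\link{filterSnps}} then \code{\link{callWindows}}
#' then \code{\link{collapseToBins}}.
#'
#' @param snps a \code{SnpGenotypes}.
#' @param window_size,homo_fraction see \code{\link{callWindows}}.
#' @param min_depth,min_quality see \code{\link{filterSnps}}.
#' @param min_line_frac see \code{\link{collapseToBins}}.
#' @return a \code{BinMap}.
#' @export
buildBinMap <- function(snps, window_size = 15, homo_fraction = 0.7,
                        min_depth = 3, min_quality = 30, min_line_frac = 0.8) {
  filtered <- filterSnps(snps, min_depth = min_depth, min_quality = min_quality)
  wc <- callWindows(filtered, window_size = window_size,
                    homo_fraction = homo_fraction)
  collapseToBins(wc, min_line_frac = min_line_frac)
}

#' Per-chromosome and genome summary of a bin map
#'
#' One row per chromosome plus a genome row: bin counts (all bins created and
#' bins entering the linkage map), average physical bin length in kb
#' (chromosome length / created bins), linkage-group length in cM, average
#' adjacent gap (LG length / mapped bin count) and the maximum adjacent gap.
#'
#' @param binmap a \code{BinMap}.
#' @return data.frame with columns chrom, bins_mapped, bins_created,
#'   mean_bin_length_kb, lg_length_cm, mean_gap_cm, max_gap_cm.
#' @export
mapSummary <- function(binmap) {
  stopifnot(is(binmap, "BinMap"))
  gr <- binRanges(binmap)
  chr <- as.character(seqnames(gr))
  mapped <- mcols(gr)$mapped
  cm <- mcols(gr)$cm
  rows <- lapply(unique(chr), function(cc) {
    i <- which(chr == cc)
    im <- i[mapped[i]]
    lg <- if (length(im) > 1) max(cm[im]) else 0
    data.frame(chrom = cc,
               bins_mapped = length(im),
               bins_created = length(i),
               mean_bin_length_kb = sum(width(gr)[i]) / length(i) / 1000,
               lg_length_cm = lg,
               mean_gap_cm = if (length(im)) lg / length(im) else 0,
               max_gap_cm = if (length(im) > 1) max(diff(cm[im])) else 0)
  })
  per_chrom <- do.call(rbind, rows)
  rbind(per_chrom, combineMapSummaries(per_chrom))
}

#' Aggregate per-chromosome map summaries into a genome row
#'
#' Average bin length is weighted by created-bin counts (equivalently, total
#' physical span over total bins); the average gap is total map length over
#' total mapped bins; the maximum gap is the genome-wide maximum.
#'
#' @param per_chrom data.frame in the layout produced by \code{\link{mapSummary}}
#'   (per-chromosome rows only).
#' @return one-row data.frame with \code{chrom = "genome"}.
#' @export
combineMapSummaries <- function(per_chrom) {
  data.frame(chrom = "genome",
             bins_mapped = sum(per_chrom$bins_mapped),
             bins_created = sum(per_chrom$bins_created),
             mean_bin_length_kb = sum(per_chrom$bins_created *
                                      per_chrom$mean_bin_length_kb) /
                                  sum(per_chrom$bins_created),
             lg_length_cm = sum(per_chrom$lg_length_cm),
             mean_gap_cm = sum(per_chrom$lg_length_cm) /
                           sum(per_chrom$bins_mapped),
             max_gap_cm = max(per_chrom$max_gap_cm))
}

#' Write bin-map artifacts (genotype matrix TSV, BED-like map, summary CSV)
#' @param binmap a BinMap
#' @param dir output directory
#' @export
writeBinMapFiles <- function(binmap, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gr <- binRanges(binmap)
  map <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
                    end = end(gr), cm = mcols(gr)$cm,
                    mapped = mcols(gr)$mapped)
  write.table(map, file.path(dir, "binmap.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  geno <- binGenotypes(binmap)
  colnames(geno) <- sprintf("bin%04d", seq_len(ncol(geno)))
  write.table(data.frame(line = rownames(geno), geno),
              file.path(dir, "bin_genotypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(mapSummary(binmap), file.path(dir, "map_summary.csv"),
            row.names = FALSE)
  invisible(dir)
}
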