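## QTL scanning on bin markers: marker regression LOD profiles, forward
## cofactor selection (multiple-QTL background control), permutation
## thresholds, 2-LOD support intervals, interval merging and the
## cross-condition stability rule.

## numeric coding of bin genotypes: A (P1) = +1, B (P2) = -1, H/U = NA.
## With this coding the regression slope equals the additive effect
## a = (mean_A - mean_B)/2, positive when the P1 allele raises the trait.
.genoNumeric <- function(geno) {
  x <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  x[geno == "A"] <- 1
  x[geno == "B"] <- -1
  x
}

## Vectorized marker-regression scan. X: lines x bins in {+1,-1,NA};
## Y: lines x P trait columns (no NAs). Returns m x P LOD matrix plus
## per-bin additive/PVE for the first trait column.
.lodScanCore <- function(X, Y) {
  M <- is.finite(X) * 1
  Xz <- ifelse(is.na(X), 0, X)
  n_b <- colSums(M)
  Sx <- colSums(Xz)
  Sxx <- colSums(Xz^2)
  Sy <- crossprod(M, Y)                      # m x P
  Syy <- crossprod(M, Y^2)
  Sxy <- crossprod(Xz, Y)
  rss0 <- Syy - Sy^2 / n_b
  sxx_c <- Sxx - Sx^2 / n_b
  sxy_c <- Sxy - (Sx / n_b) * Sy
  mono <- sxx_c < 1e-12
  sxx_safe <- ifelse(mono, 1, sxx_c)
  beta <- sxy_c / sxx_safe
  rss1 <- pmax(rss0 - sxy_c^2 / sxx_safe, 1e-12 * pmax(rss0, 1e-300))
  lod <- (n_b / 2) * log10(pmax(rss0, 1e-300) / rss1)
  lod[mono | rss0 <= 1e-300] <- 0
  beta[mono] <- 0
  pve <- 1 - rss1 / pmax(rss0, 1e-300)
  pve[mono | rss0 <= 1e-300] <- 0
  list(lod = lod, additive = beta, pve = pve, n = n_b, monomorphic = mono)
}

## align a named trait vector with the rows of a bin genotype matrix
.alignTrait <- function(binmap, trait) {
  lines <- rownames(binGenotypes(binmap))
  if (!is.null(names(trait))) {
    shared <- intersect(lines, names(trait))
    if (!length(shared)) stop("no shared lines between bin map and trait")
    trait <- trait[shared]
  } else {
    stopifnot(length(trait) == length(lines))
    names(trait) <- lines
    shared <- lines
  }
  keep <- is.finite(trait)
  list(lines = shared[keep], y = unname(trait[keep]))
}

.mappedProfileSkeleton <- function(binmap) {
  gr <- binRanges(binmap)
  i <- which(mcols(gr)$mapped)
  data.frame(bin = i, chrom = as.character(seqnames(gr))[i],
             cm = mcols(gr)$cm[i], start = start(gr)[i], end = end(gr)[i])
}

#' Single-marker regression scan
#'
#' At every mapped bin, regresses the trait on the bin genotype (A vs B;
#' heterozygous and missing lines dropped at that bin) and reports
#' \eqn{LOD = (n/2) \log_{10}(RSS_0 / RSS_1)}, the additive effect
#' a = (mean_A - mean_B)/2 (positive when the P1 allele raises the trait) and
#' the per-bin PVE = 1 - RSS1/RSS0. Monomorphic bins are recorded with LOD 0
#' and flagged.
#'
#' @param binmap a \code{\linkS4class{BinMap}}.
#' @param trait named numeric vector of per-line trait values (typically line
#'   BLUPs or per-environment line means).
#' @param trait_name,condition labels stored in the result.
#' @return a \code{\linkS4class{QtlScan}}.
#' @export
singleMarkerScan <- function(binmap, trait, trait_name = "trait",
                             condition = "BLUP") {
  stopifnot(is(binmap, "BinMap"))
  al <- .alignTrait(binmap, trait)
  prof <- .mappedProfileSkeleton(binmap)
  X <- .genoNumeric(binGenotypes(binmap)[al$lines, prof$bin, drop = FALSE])
  core <- .lodScanCore(X, matrix(al$y, ncol = 1))
  prof$lod <- as.numeric(core$lod)
  prof$additive <- as.numeric(core$additive)
  prof$pve <- as.numeric(core$pve)
  prof$n_informative <- as.integer(core$n)
  prof$monomorphic <- as.logical(core$monomorphic)
  new("QtlScan", profile = prof, trait = trait_name, condition = condition,
      threshold = NA_real_, cofactors = integer(0))
}

#' Genome-wide LOD threshold by trait permutation
#'
#' Permutes trait values across lines \code{n_perm} times, rescans the whole
#' genome for each permutation, and returns the empirical (1 - alpha)
#' quantile of the genome-wide maximum LOD (the k-th largest with
#' k = ceiling((1-alpha) n_perm) of the sorted maxima). Deterministic for a
#' given seed.
#'
#' @param binmap a \code{BinMap}.
#' @param trait named per-line trait vector.
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param seed integer seed.
#' @return LOD threshold (numeric scalar) with attribute \code{"max_lods"}.
#' @export
permutationThreshold <- function(binmap, trait, n_perm = 1000, alpha = 0.05,
                                 seed = 1L) {
  if (n_perm < 100) warning("fewer than 100 permutations: threshold is noisy")
  al <- .alignTrait(binmap, trait)
  prof <- .mappedProfileSkeleton(binmap)
  X <- .genoNumeric(binGenotypes(binmap)[al$lines, prof$bin, drop = FALSE])
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) sample(al$y), numeric(length(al$y)))
  core <- .lodScanCore(X, Y)
  max_lods <- apply(core$lod, 2, max)
  k <- ceiling((1 - alpha) * n_perm)
  thr <- sort(max_lods)[k]
  attr(thr, "max_lods") <- max_lods
  thr
}

## conditional scan: LOD of each bin given cofactor bins, excluding cofactors
## within window_cm of the tested bin (same chromosome)
.cofactorScan <- function(binmap, al, prof, cofactors, window_cm) {
  geno <- binGenotypes(binmap)[al$lines, , drop = FALSE]
  X <- .genoNumeric(geno[, prof$bin, drop = FALSE])
  Z <- .genoNumeric(geno[, cofactors, drop = FALSE])
  Z[is.na(Z)] <- 0                      # mean-impute cofactor genotypes
  gr <- binRanges(binmap)
  cof_chr <- as.character(seqnames(gr))[cofactors]
  cof_cm <- mcols(gr)$cm[cofactors]
  y <- al$y
  m <- nrow(prof)
  lod <- additive <- pve <- numeric(m)
  n_inf <- integer(m); mono <- logical(m)
  for (j in seq_len(m)) {
    x <- X[, j]
    ok <- is.finite(x)
    n <- sum(ok)
    n_inf[j] <- n
    allowed <- !(cof_chr == prof$chrom[j] & abs(cof_cm - prof$cm[j]) < window_cm)
    Zj <- Z[ok, allowed, drop = FALSE]
    yj <- y[ok]
    if (n < ncol(Zj) + 3 || var(x[ok]) < 1e-12) { mono[j] <- TRUE; next }
    f0 <- lm.fit(cbind(1, Zj), yj)
    f1 <- lm.fit(cbind(1, Zj, x[ok]), yj)
    rss0 <- sum(f0$residuals^2)
    rss1 <- max(sum(f1$residuals^2), 1e-12 * max(rss0, 1e-300))
    lod[j] <- (n / 2) * log10(max(rss0, 1e-300) / rss1)
    b <- f1$coefficients[length(f1$coefficients)]
    additive[j] <- if (is.na(b)) 0 else b
    pve[j] <- 1 - rss1 / max(rss0, 1e-300)
  }
  prof$lod <- lod; prof$additive <- additive; prof$pve <- pve
  prof$n_informative <- n_inf; prof$monomorphic <- mono
  prof
}

#' Forward cofactor selection and conditional rescan
#'
#' Approximates multiple-QTL mapping by marker regression with forward
#' selection: the strongest genome-wide-significant bin is added as a
#' regression cofactor, the genome is rescanned conditional on the cofactor
#' set (cofactors within \code{window_cm} of the tested bin are excluded from
#' its model), and the cycle repeats until no new bin clears the threshold.
#'
#' @param binmap a \code{BinMap}.
#' @param trait named per-line trait vector.
#' @param threshold genome-wide LOD threshold (from
#'   \code{\link{permutationThreshold}}).
#' @param trait_name,condition labels stored in the result.
#' @param window_cm exclusion window around the tested bin (default 10 cM).
#' @param max_iter cap on the number of cofactors.
#' @return a \code{QtlScan} whose profile is conditioned on the selected
#'   cofactors (slot \code{cofactors}).
#' @export
selectCofactors <- function(binmap, trait, threshold, trait_name = "trait",
                            condition = "BLUP", window_cm = 10, max_iter = 8) {
  al <- .alignTrait(binmap, trait)
  skel <- .mappedProfileSkeleton(binmap)
  scan <- singleMarkerScan(binmap, trait, trait_name, condition)
  cof <- integer(0)
  prof <- scanProfile(scan)
  gr <- binRanges(binmap)
  repeat {
    ## a new cofactor must clear the threshold and sit at least window_cm
    ## away from every existing cofactor (one cofactor per QTL region)
    near_cof <- rep(FALSE, nrow(prof))
    for (cf in cof) {
      cf_chr <- as.character(seqnames(gr))[cf]
      cf_cm <- mcols(gr)$cm[cf]
      near_cof <- near_cof |
        (prof$chrom == cf_chr & abs(prof$cm - cf_cm) < window_cm)
    }
    cand <- which(prof$lod >= threshold & !near_cof)
    if (!length(cand) || length(cof) >= max_iter) break
    new_cof <- prof$bin[cand[which.max(prof$lod[cand])]]
    cof <- c(cof, new_cof)
    prof <- .cofactorScan(binmap, al, skel, cof, window_cm)
  }
  new("QtlScan", profile = prof, trait = trait_name, condition = condition,
      threshold = as.numeric(threshold), cofactors = as.integer(cof))
}

#' 2-LOD support interval around a peak
#'
#' Walks left and right from the peak bin while the LOD stays within 2 of the
#' peak value; the interval spans from the start of the leftmost qualifying
#' bin to the end of the rightmost. If the 2-LOD drop is never reached before
#' a chromosome end the interval is truncated there and flagged.
#'
#' @param scan a \code{QtlScan} (or its profile data.frame).
#' @param peak_row row index of the peak in the profile.
#' @param drop LOD drop defining the support interval (default 2).
#' @return list: \code{cm_start}, \code{cm_end}, \code{bp_start},
#'   \code{bp_end}, \code{rows} (profile row range), \code{truncated}.
#' @export
supportInterval2Lod <- function(scan, peak_row, drop = 2) {
  prof <- if (is(scan, "QtlScan")) scanProfile(scan) else scan
  chrom <- prof$chrom[peak_row]
  rows <- which(prof$chrom == chrom)
  peak_lod <- prof$lod[peak_row]
  cutoff <- peak_lod - drop
  left <- peak_row
  while (left > min(rows) && prof$lod[left - 1] >= cutoff) left <- left - 1
  right <- peak_row
  while (right < max(rows) && prof$lod[right + 1] >= cutoff) right <- right + 1
  truncated <- (left == min(rows) && prof$lod[left] >= cutoff) ||
               (right == max(rows) && prof$lod[right] >= cutoff)
  list(cm_start = prof$cm[left], cm_end = prof$cm[right],
       bp_start = prof$start[left], bp_end = prof$end[right],
       rows = c(left, right), truncated = truncated)
}

#' Extract significant QTL peaks with 2-LOD intervals from a scan
#'
#' Iteratively takes the highest remaining LOD above the threshold (ties
#' broken toward the lower chromosome, then lower position), records its
#' 2-LOD interval, masks the interval, and repeats.
#'
#' @param scan a \code{QtlScan} with its threshold set (or supply
#'   \code{threshold}).
#' @param threshold optional LOD threshold override.
#' @param drop LOD drop for the support interval.
#' @param flank_mask_cm after extracting a QTL, bins within this genetic
#'   distance of its interval are masked as well (default 10 cM, matching the
#'   cofactor exclusion window: shoulder bins there were tested without the
#'   cofactor representing the extracted QTL and are not independent
#'   evidence).
#' @return data.frame, one row per QTL: trait, condition, chrom, peak_bin,
#'   peak_cm, lod, pve_pct, additive, cm_start, cm_end, bp_start, bp_end,
#'   truncated. Zero rows when nothing is significant.
#' @export
extractQtls <- function(scan, threshold = NULL, drop = 2, flank_mask_cm = 10) {
  stopifnot(is(scan, "QtlScan"))
  thr <- if (!is.null(threshold)) threshold else scanThreshold(scan)
  if (is.na(thr)) stop("no threshold set on this scan")
  prof <- scanProfile(scan)
  avail <- prof$lod >= thr
  out <- NULL
  while (any(avail)) {
    idx <- which(avail)
    peak <- idx[which.max(prof$lod[idx])]   # profile is chrom/bp ordered
    si <- supportInterval2Lod(prof, peak, drop)
    out <- rbind(out, data.frame(
      trait = scan@trait, condition = scan@condition,
      chrom = prof$chrom[peak], peak_bin = prof$bin[peak],
      peak_cm = prof$cm[peak], lod = prof$lod[peak],
      pve_pct = 100 * prof$pve[peak], additive = prof$additive[peak],
      cm_start = si$cm_start, cm_end = si$cm_end,
      bp_start = si$bp_start, bp_end = si$bp_end,
      truncated = si$truncated))
    avail[si$rows[1]:si$rows[2]] <- FALSE
    avail[prof$chrom == prof$chrom[peak] &
          prof$cm >= si$cm_start - flank_mask_cm &
          prof$cm <= si$cm_end + flank_mask_cm] <- FALSE
  }
  if (is.null(out))
    out <- data.frame(trait = character(0), condition = character(0),
                      chrom = character(0), peak_bin = integer(0),
                      peak_cm = numeric(0), lod = numeric(0),
                      pve_pct = numeric(0), additive = numeric(0),
                      cm_start = numeric(0), cm_end = numeric(0),
                      bp_start = numeric(0), bp_end = numeric(0),
                      truncated = logical(0))
  out[order(out$chrom, out$bp_start), , drop = FALSE]
}

#' Merge QTLs with overlapping physical intervals
#'
#' Same-chromosome intervals overlapping by at least 1 bp are merged to their
#' union (transitively); the merged record keeps the statistics of the
#' member with the highest LOD.
#'
#' @param qtls data.frame as returned by \code{\link{extractQtls}} (possibly
#'   concatenated across traits/conditions).
#' @return data.frame in the same layout, one row per merged interval, with a
#'   \code{n_merged} column.
#' @export
mergeOverlapping <- function(qtls) {
  if (!nrow(qtls)) { qtls$n_merged <- integer(0); return(qtls) }
  gr <- GRanges(qtls$chrom, IRanges(qtls$bp_start, qtls$bp_end))
  red <- reduce(gr, with.revmap = TRUE, min.gapwidth = 0L)
  rows <- lapply(seq_along(red), function(i) {
    members <- mcols(red)$revmap[[i]]
    best <- members[which.max(qtls$lod[members])]
    rec <- qtls[best, , drop = FALSE]
    rec$bp_start <- start(red)[i]; rec$bp_end <- end(red)[i]
    rec$cm_start <- min(qtls$cm_start[members])
    rec$cm_end <- max(qtls$cm_end[members])
    rec$n_merged <- length(members)
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chrom, out$bp_start), , drop = FALSE]
}

#' Stability flags from a detection matrix
#'
#' A region is \emph{stable} when, for at least one trait, it was detected
#' under every condition; it satisfies the \emph{all-cells} rule when every
#' condition x trait cell is detected.
#'
#' @param det logical matrix, regions in rows; columns named
#'   \code{"<condition>.<trait>"}.
#' @param conditions,traits the condition and trait levels spanning the
#'   columns.
#' @return data.frame with logical columns \code{stable} and \code{all_cells}.
#' @export
detectionFlags <- function(det, conditions, traits) {
  stopifnot(all(outer(conditions, traits, paste, sep = ".") %in% colnames(det)))
  stable <- apply(det, 1, function(row) {
    any(vapply(traits, function(tr)
      all(row[paste(conditions, tr, sep = ".")]), TRUE))
  })
  data.frame(stable = stable, all_cells = apply(det, 1, all))
}

#' Cross-condition stable QTL regions
#'
#' Clusters QTL intervals from all conditions and traits by physical overlap
#' (transitive union per chromosome), builds the detection matrix over
#' condition x trait cells, and applies the stability rule: a region is
#' stable when supported under every condition for at least one trait. The
#' reported interval of a region is the union over its supporting QTLs.
#'
#' @param qtls data.frame of QTLs (rows from \code{\link{extractQtls}} /
#'   \code{\link{mergeOverlapping}} concatenated over conditions and traits;
#'   must carry \code{condition}, \code{trait}, \code{chrom},
#'   \code{bp_start}, \code{bp_end}).
#' @param conditions condition levels required for stability (default
#'   greenhouse, field, BLUP).
#' @param traits trait levels; defaults to those present.
#' @return list: \code{regions} (data.frame chrom, bp_start, bp_end, stable,
#'   all_cells, n_qtls) and \code{detection} (logical matrix).
#' @export
stableRegions <- function(qtls,
                          conditions = c("greenhouse", "field", "BLUP"),
                          traits = NULL) {
  if (is.null(traits)) traits <- unique(qtls$trait)
  if (!nrow(qtls))
    return(list(regions = data.frame(chrom = character(0),
                                     bp_start = numeric(0), bp_end = numeric(0),
                                     stable = logical(0), all_cells = logical(0),
                                     n_qtls = integer(0)),
                detection = matrix(FALSE, 0, length(conditions) * length(traits))))
  gr <- GRanges(qtls$chrom, IRanges(qtls$bp_start, qtls$bp_end))
  red <- reduce(gr, with.revmap = TRUE, min.gapwidth = 0L)
  cells <- as.vector(outer(conditions, traits, paste, sep = "."))
  det <- matrix(FALSE, length(red), length(cells),
                dimnames = list(NULL, cells))
  n_qtls <- integer(length(red))
  for (i in seq_along(red)) {
    members <- mcols(red)$revmap[[i]]
    n_qtls[i] <- length(members)
    key <- paste(qtls$condition[members], qtls$trait[members], sep = ".")
    det[i, intersect(unique(key), cells)] <- TRUE
  }
  flags <- detectionFlags(det, conditions, traits)
  regions <- data.frame(chrom = as.character(seqnames(red)),
                        bp_start = start(red), bp_end = end(red),
                        stable = flags$stable, all_cells = flags$all_cells,
                        n_qtls = n_qtls)
  ord <- order(regions$chrom, regions$bp_start)
  list(regions = regions[ord, , drop = FALSE],
       detection = det[ord, , drop = FALSE])
}

#' One-call QTL analysis for a trait under one condition
#'
#' Runs the permutation threshold, forward cofactor selection, peak
#' extraction with 2-LOD intervals, and overlap merging.
#'
#' @param binmap a \code{BinMap}.
#' @param trait named per-line trait vector.
#' @param trait_name,condition labels.
#' @param n_perm,alpha,seed permutation-threshold settings.
#' @param window_cm cofactor exclusion window (cM).
#' @param use_cofactors set FALSE for a plain single-marker analysis.
#' @return list: \code{scan} (QtlScan), \code{threshold}, \code{qtls}
#'   (merged QTL table).
#' @export
scanQtl <- function(binmap, trait, trait_name = "trait", condition = "BLUP",
                    n_perm = 1000, alpha = 0.05, seed = 1L, window_cm = 10,
                    use_cofactors = TRUE) {
  thr <- permutationThreshold(binmap, trait, n_perm = n_perm, alpha = alpha,
                              seed = seed)
  scan <- if (use_cofactors) {
    selectCofactors(binmap, trait, thr, trait_name, condition,
                    window_cm = window_cm)
  } else {
    s <- singleMarkerScan(binmap, trait, trait_name, condition)
    s@threshold <- as.numeric(thr)
    s
  }
  scan@threshold <- as.numeric(thr)
  qtls <- mergeOverlapping(extractQtls(scan))
  list(scan = scan, threshold = as.numeric(thr), qtls = qtls)
}
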