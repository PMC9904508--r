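## Salt-specific differential expression: TMM normalization, no-replicate
## negative-binomial exact contrasts, the six-class condition-specific
## classification with delta-LFC, and the parent x bulk intersection.

DEG_CLASSES <- c("SalOnly_up", "SalOnly_down", "NorOnly_up", "NorOnly_down",
                 "DeltaLFC_gt1", "DeltaLFC_ltm1")
DEG_UP_CLASSES <- c("SalOnly_up", "NorOnly_down", "DeltaLFC_gt1")
DEG_DOWN_CLASSES <- c("SalOnly_down", "NorOnly_up", "DeltaLFC_ltm1")

#' TMM (trimmed mean of M-values) scaling factors
#'
#' The reference library is the one whose upper quartile of library-size-scaled
#' counts is closest to the mean upper quartile. For every library, M-values
#' (log2 ratios to the reference) and A-values (average log2 abundance) are
#' computed over genes expressed in both; the most extreme 30\% of M and 5\%
#' of A are trimmed on each side, and the factor is the precision-weighted
#' mean of the remaining M-values. Factors are rescaled to geometric mean 1.
#'
#' @param counts non-negative matrix, genes x libraries (>= 2 libraries).
#' @param logratio_trim,abundance_trim per-side trim fractions for M and A.
#' @return named numeric vector of scaling factors, one per library; the
#'   effective library size is \code{colSums(counts) * factors}.
#' @export
tmmNormalize <- function(counts, logratio_trim = 0.3, abundance_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 libraries")
  N <- colSums(counts)
  if (any(N <= 0)) stop("zero-count library")
  uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  xr <- counts[, ref]; Nr <- N[ref]
  f <- vapply(seq_len(ncol(counts)), function(k) {
    xk <- counts[, k]; Nk <- N[k]
    ok <- xk > 0 & xr > 0
    if (!any(ok)) return(1)
    M <- log2((xk[ok] / Nk) / (xr[ok] / Nr))
    if (max(abs(M)) < 1e-6) return(1)
    A <- 0.5 * log2((xk[ok] / Nk) * (xr[ok] / Nr))
    ## delta-method variance of M; weights are its inverse (precision)
    v <- (Nk - xk[ok]) / (Nk * xk[ok]) + (Nr - xr[ok]) / (Nr * xr[ok])
    w <- 1 / v
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, 0)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

## exact conditional two-sided p-value for a pair of NB counts with equal
## underlying (normalized) expression; enumeration over the conditional
## distribution of the first count given the pair sum
.nbExactP <- function(a, b, ne_a, ne_b, dispersion) {
  s <- a + b
  if (s == 0) return(1)
  lambda <- s / (ne_a + ne_b)
  k <- 0:s
  logp <- if (dispersion == 0) {
    dpois(k, lambda * ne_a, log = TRUE) + dpois(s - k, lambda * ne_b, log = TRUE)
  } else {
    dnbinom(k, size = 1 / dispersion, mu = lambda * ne_a, log = TRUE) +
      dnbinom(s - k, size = 1 / dispersion, mu = lambda * ne_b, log = TRUE)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[a + 1] * (1 + 1e-10)])
}

#' No-replicate differential-expression contrast
#'
#' One library per side, as in the 8-sample design. The log2 fold change uses
#' a symmetric 0.5 pseudocount on TMM-adjusted effective library sizes:
#' \eqn{LFC = \log_2((a + 0.5)/N^{eff}_A) - \log_2((b + 0.5)/N^{eff}_B)}.
#' P-values come from an exact negative-binomial test at a fixed dispersion,
#' conditioned on the pair sum (dispersion 0 reduces to the exact binomial /
#' Poisson test); FDR is Benjamini-Hochberg across genes. A gene is flagged
#' DE when |LFC| >= \code{lfc_cut} and FDR <= \code{fdr_cut}.
#'
#' @param counts genes x samples count matrix (with gene rownames).
#' @param num,den column names of the numerator and denominator libraries.
#' @param dispersion fixed NB dispersion (default 0.1; must be >= 0).
#' @param norm_factors optional TMM factors (named as columns of
#'   \code{counts}); computed from the full matrix when NULL.
#' @param lfc_cut,fdr_cut DE-flag cutoffs (defaults 1 and 0.05).
#' @return data.frame: gene, lfc, pvalue, fdr, de.
#' @export
contrastTest <- function(counts, num, den, dispersion = 0.1,
                         norm_factors = NULL, lfc_cut = 1, fdr_cut = 0.05) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  counts <- as.matrix(counts)
  stopifnot(all(c(num, den) %in% colnames(counts)))
  if (is.null(norm_factors)) norm_factors <- tmmNormalize(counts)
  ne <- colSums(counts) * norm_factors
  a <- counts[, num]; b <- counts[, den]
  lfc <- log2((a + 0.5) / ne[num]) - log2((b + 0.5) / ne[den])
  pv <- vapply(seq_along(a),
               function(g) .nbExactP(a[g], b[g], ne[num], ne[den], dispersion),
               0)
  fdr <- p.adjust(pv, "BH")
  data.frame(gene = rownames(counts), lfc = lfc, pvalue = pv, fdr = fdr,
             de = abs(lfc) >= lfc_cut & fdr <= fdr_cut,
             row.names = NULL)
}

#' Six-way salt-specific DEG classification
#'
#' Compares a salt-condition contrast with its normal-condition counterpart
#' and assigns every gene one label: DE only under salt gives
#' \code{SalOnly_up} / \code{SalOnly_down} by LFC sign; DE only under normal
#' conditions gives \code{NorOnly_up} / \code{NorOnly_down}; DE under both
#' gives \code{DeltaLFC_gt1} when \eqn{\Delta LFC = LFC_{salt} - LFC_{normal}}
#' exceeds \code{delta_thresh}, \code{DeltaLFC_ltm1} below
#' \code{-delta_thresh}, and \code{none} in between; genes DE in neither are
#' \code{none}. The salt-specific direction is up for \{SalOnly_up,
#' NorOnly_down, DeltaLFC_gt1\} and down for \{SalOnly_down, NorOnly_up,
#' DeltaLFC_ltm1\}.
#'
#' @param salt,normal contrast data.frames from \code{\link{contrastTest}}
#'   covering the same genes.
#' @param delta_thresh delta-LFC threshold (default 1).
#' @return data.frame: gene, salt_lfc, normal_lfc, delta_lfc, class, direction.
#' @export
classifySixWay <- function(salt, normal, delta_thresh = 1) {
  shared <- intersect(salt$gene, normal$gene)
  if (length(shared) < max(nrow(salt), nrow(normal)))
    warning(sprintf("%d gene(s) present in only one contrast were excluded",
                    max(nrow(salt), nrow(normal)) - length(shared)))
  s <- salt[match(shared, salt$gene), ]
  n <- normal[match(shared, normal$gene), ]
  delta <- s$lfc - n$lfc
  class <- rep("none", length(shared))
  class[s$de & !n$de & s$lfc > 0] <- "SalOnly_up"
  class[s$de & !n$de & s$lfc < 0] <- "SalOnly_down"
  class[!s$de & n$de & n$lfc > 0] <- "NorOnly_up"
  class[!s$de & n$de & n$lfc < 0] <- "NorOnly_down"
  class[s$de & n$de & delta > delta_thresh] <- "DeltaLFC_gt1"
  class[s$de & n$de & delta < -delta_thresh] <- "DeltaLFC_ltm1"
  direction <- rep("none", length(shared))
  direction[class %in% DEG_UP_CLASSES] <- "up"
  direction[class %in% DEG_DOWN_CLASSES] <- "down"
  data.frame(gene = shared, salt_lfc = s$lfc, normal_lfc = n$lfc,
             delta_lfc = delta, class = class, direction = direction,
             row.names = NULL)
}

#' Salt-specific gene sets and per-class counts
#'
#' @param classified data.frame from \code{\link{classifySixWay}}.
#' @return list: \code{up} and \code{down} gene-id vectors, \code{counts}
#'   (named count per class, in the up-then-down class order), \code{n_up},
#'   \code{n_down}, \code{total}.
#' @export
saltSpecificSets <- function(classified) {
  counts <- vapply(c(DEG_UP_CLASSES, DEG_DOWN_CLASSES),
                   function(cl) sum(classified$class == cl), 0L)
  list(up = classified$gene[classified$direction == "up"],
       down = classified$gene[classified$direction == "down"],
       counts = counts,
       n_up = sum(counts[DEG_UP_CLASSES]),
       n_down = sum(counts[DEG_DOWN_CLASSES]),
       total = sum(counts))
}

#' Totals from a named vector of six class counts
#'
#' Arithmetic used for class-count tables: upregulated salt-specific DEGs are
#' the SalOnly_up + NorOnly_down + DeltaLFC_gt1 classes, downregulated the
#' other three.
#'
#' @param counts named numeric vector over the six classes.
#' @return list: n_up, n_down, total.
#' @export
degClassTotals <- function(counts) {
  stopifnot(all(DEG_CLASSES %in% names(counts)))
  list(n_up = sum(counts[DEG_UP_CLASSES]),
       n_down = sum(counts[DEG_DOWN_CLASSES]),
       total = sum(counts[DEG_CLASSES]))
}

#' Direction-consistent intersection of parent and bulk DEG sets
#'
#' Shared upregulated genes are parent-up intersected with bulk-up, and
#' likewise for downregulated; the combined set is their union.
#'
#' @param parent_sets,bulk_sets lists from \code{\link{saltSpecificSets}}.
#' @return list: \code{up}, \code{down}, \code{genes} (all shared ids),
#'   \code{n_up}, \code{n_down}, \code{total}.
#' @export
intersectParentBulk <- function(parent_sets, bulk_sets) {
  up <- intersect(parent_sets$up, bulk_sets$up)
  down <- intersect(parent_sets$down, bulk_sets$down)
  list(up = up, down = down, genes = c(up, down),
       n_up = length(up), n_down = length(down),
       total = length(up) + length(down))
}

#' Full salt-specific DEG analysis of the eight-library design
#'
#' Runs the four contrasts (parents and bulks, salt and normal), classifies
#' both comparisons six ways, and intersects the parent and bulk salt-specific
#' sets.
#'
#' @param counts genes x 8 matrix with columns SalP1, SalP2, NorP1, NorP2,
#'   SalT, SalS, NorT, NorS.
#' @param dispersion,lfc_cut,fdr_cut,delta_thresh see
#'   \code{\link{contrastTest}} and \code{\link{classifySixWay}}.
#' @return list: \code{parent} and \code{bulk} (each with \code{salt},
#'   \code{normal}, \code{classified}, \code{sets}) and \code{shared}.
#' @export
degAnalysis <- function(counts, dispersion = 0.1, lfc_cut = 1, fdr_cut = 0.05,
                        delta_thresh = 1) {
  nf <- tmmNormalize(counts)
  run <- function(num, den)
    contrastTest(counts, num, den, dispersion, nf, lfc_cut, fdr_cut)
  parent_salt <- run("SalP2", "SalP1")
  parent_norm <- run("NorP2", "NorP1")
  bulk_salt <- run("SalT", "SalS")
  bulk_norm <- run("NorT", "NorS")
  parent_cls <- classifySixWay(parent_salt, parent_norm, delta_thresh)
  bulk_cls <- classifySixWay(bulk_salt, bulk_norm, delta_thresh)
  parent_sets <- saltSpecificSets(parent_cls)
  bulk_sets <- saltSpecificSets(bulk_cls)
  list(parent = list(salt = parent_salt, normal = parent_norm,
                     classified = parent_cls, sets = parent_sets),
       bulk = list(salt = bulk_salt, normal = bulk_norm,
                   classified = bulk_cls, sets = bulk_sets),
       shared = intersectParentBulk(parent_sets, bulk_sets))
}
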