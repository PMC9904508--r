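## Central S4 containers.
##
## Genotype codes used throughout:
##   "A" = homozygous for the P1 (donor) allele
##   "B" = homozygous for the P2 (recurrent) allele
##   "H" = heterozygous
##   "U" = missing / unknown
GENO_CODES <- c("A", "B", "H", "U")

#' RilPopulation: true parental-origin mosaics of a simulated RIL population
#'
#' Holds, for every line and chromosome, the two homologous chromosomes as
#' piecewise-constant tracts of parental origin (1 = P1, 2 = P2) in genetic
#' (cM) coordinates, together with the simulation configuration and the true
#' crossover record of every meiosis.
#'
#' @slot homologs nested list: \code{homologs[[line]][[chrom]]} is a list with
#'   elements \code{h1} and \code{h2}, each a list \code{(ends, origin)} where
#'   \code{ends} are increasing tract end positions in cM (last = chromosome
#'   map length) and \code{origin} is 1/2 per tract.
#' @slot config the \code{\link{simConfig}} list used to generate the population.
#' @slot crossovers list of per-generation crossover-count summaries.
#' @export
setClass("RilPopulation",
  representation(homologs = "list", config = "list", crossovers = "list")
)

#' SnpGenotypes: observed SNP calls for a RIL population
#'
#' @slot calls character matrix (lines x sites) of codes A/B/H/U.
#' @slot sites \code{GRanges} of SNP positions (width 1) carrying a per-site
#'   \code{quality} metadata column; seqlengths give chromosome sizes.
#' @slot depth integer matrix (lines x sites) of per-call sequencing depth.
#' @export
setClass("SnpGenotypes",
  representation(calls = "matrix", sites = "GRanges", depth = "matrix")
)

setValidity("SnpGenotypes", function(object) {
  msg <- NULL
  if (ncol(object@calls) != length(object@sites))
    msg <- c(msg, "ncol(calls) must equal length(sites)")
  if (!all(object@calls %in% GENO_CODES))
    msg <- c(msg, "calls must be one of A, B, H, U")
  pos <- GenomicRanges::start(object@sites)
  chr <- as.character(GenomicRanges::seqnames(object@sites))
  for (cc in unique(chr)) {
    p <- pos[chr == cc]
    if (is.unsorted(p, strictly = TRUE))
      msg <- c(msg, sprintf("positions not strictly increasing on %s", cc))
  }
  if (is.null(msg)) TRUE else msg
})

#' BinMap: ordered recombination bins with genetic positions
#'
#' Bins tile each chromosome without overlap. Bins with enough informative
#' lines (\code{mapped} metadata flag) carry a genetic position in cM,
#' cumulative from 0 at the first mapped bin of each chromosome.
#'
#' @slot bins \code{GRanges} of bin spans (1-based inclusive) with metadata
#'   columns \code{cm} (genetic position, NA for unmapped bins) and
#'   \code{mapped} (logical).
#' @slot geno character matrix (lines x bins) of codes A/B/H/U.
#' @export
setClass("BinMap", representation(bins = "GRanges", geno = "matrix"))

setValidity("BinMap", function(object) {
  msg <- NULL
  if (ncol(object@geno) != length(object@bins))
    msg <- c(msg, "ncol(geno) must equal number of bins")
  if (!all(object@geno %in% GENO_CODES))
    msg <- c(msg, "bin genotypes must be one of A, B, H, U")
  chr <- as.character(GenomicRanges::seqnames(object@bins))
  cm <- mcols(object@bins)$cm
  mapped <- mcols(object@bins)$mapped
  for (cc in unique(chr)) {
    i <- which(chr == cc)
    st <- GenomicRanges::start(object@bins)[i]
    en <- GenomicRanges::end(object@bins)[i]
    if (length(i) > 1 && any(st[-1] != en[-length(i)] + 1))
      msg <- c(msg, sprintf("bins do not tile chromosome %s", cc))
    cmi <- cm[i][mapped[i]]
    if (length(cmi)) {
      if (abs(cmi[1]) > 1e-9)
        msg <- c(msg, sprintf("first mapped bin on %s must sit at 0 cM", cc))
      if (is.unsorted(cmi))
        msg <- c(msg, sprintf("cM positions decrease on %s", cc))
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' QtlScan: genome scan profile for one trait under one condition
#'
#' @slot profile data.frame with one row per tested bin: \code{bin}, \code{chrom},
#'   \code{cm}, \code{start}, \code{end}, \code{lod}, \code{additive},
#'   \code{pve}, \code{n_informative}, \code{monomorphic}.
#' @slot trait,condition character scalars.
#' @slot threshold numeric genome-wide LOD threshold (NA until set).
#' @slot cofactors integer vector of bin indices used as regression cofactors.
#' @export
setClass("QtlScan",
  representation(profile = "data.frame", trait = "character",
                 condition = "character", threshold = "numeric",
                 cofactors = "integer")
)

setValidity("QtlScan", function(object) {
  msg <- NULL
  need <- c("bin", "chrom", "cm", "start", "end", "lod", "additive", "pve")
  if (!all(need %in% names(object@profile)))
    msg <- c(msg, "profile lacks required columns")
  else {
    if (any(object@profile$lod < -1e-9, na.rm = TRUE))
      msg <- c(msg, "LOD must be non-negative")
    if (any(object@profile$pve < -1e-9 | object@profile$pve > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "PVE must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' VarianceComponents: random-effect variances from the phenotype model
#'
#' @slot sigma_g2 genotypic (line) variance.
#' @slot sigma_ge2 line-by-environment interaction variance.
#' @slot sigma_e2 residual variance.
#' @slot sigma_r2 replicate-within-environment variance.
#' @slot n_env number of environments entering the heritability denominator.
#' @slot n_reps replicates per environment.
#' @slot truncated names of components whose negative estimates were set to 0.
#' @export
setClass("VarianceComponents",
  representation(sigma_g2 = "numeric", sigma_ge2 = "numeric",
                 sigma_e2 = "numeric", sigma_r2 = "numeric",
                 n_env = "numeric", n_reps = "numeric",
                 truncated = "character")
)

setValidity("VarianceComponents", function(object) {
  vals <- c(object@sigma_g2, object@sigma_ge2, object@sigma_e2, object@sigma_r2)
  if (any(vals < 0)) "variance components must be non-negative" else TRUE
})

## ---- accessors ----

#' @describeIn SnpGenotypes-class line identifiers
#' @param x a \code{SnpGenotypes}, \code{BinMap} or other container
#' @export
lineNames <- function(x) {
  if (is(x, "SnpGenotypes")) rownames(x@calls)
  else if (is(x, "BinMap")) rownames(x@geno)
  else stop("no line names for this object")
}

#' SNP call matrix
#' @param x a SnpGenotypes
#' @export
snpCalls <- function(x) { stopifnot(is(x, "SnpGenotypes")); x@calls }

#' SNP site ranges
#' @param x a SnpGenotypes
#' @export
snpSites <- function(x) { stopifnot(is(x, "SnpGenotypes")); x@sites }

#' Per-call sequencing depth
#' @param x a SnpGenotypes
#' @export
snpDepth <- function(x) { stopifnot(is(x, "SnpGenotypes")); x@depth }

#' Bin spans of a BinMap
#' @param x a BinMap
#' @export
binRanges <- function(x) { stopifnot(is(x, "BinMap")); x@bins }

#' Bin genotype matrix (lines x bins)
#' @param x a BinMap
#' @export
binGenotypes <- function(x) { stopifnot(is(x, "BinMap")); x@geno }

#' Genetic positions (cM) of bins, NA for unmapped bins
#' @param x a BinMap
#' @export
binPositionsCm <- function(x) { stopifnot(is(x, "BinMap")); mcols(x@bins)$cm }

#' Scan profile table
#' @param x a QtlScan
#' @export
scanProfile <- function(x) { stopifnot(is(x, "QtlScan")); x@profile }

#' Genome-wide LOD threshold of a scan (NA if unset)
#' @param x a QtlScan
#' @export
scanThreshold <- function(x) { stopifnot(is(x, "QtlScan")); x@threshold }

#' Broad-sense heritability inputs as a named list
#' @param x a VarianceComponents
#' @export
varianceComponents <- function(x) {
  stopifnot(is(x, "VarianceComponents"))
  list(sigma_g2 = x@sigma_g2, sigma_ge2 = x@sigma_ge2, sigma_e2 = x@sigma_e2,
       sigma_r2 = x@sigma_r2, n_env = x@n_env, n_reps = x@n_reps,
       truncated = x@truncated)
}

## ---- show methods ----

setMethod("show", "RilPopulation", function(object) {
  cfg <- object@config
  cat(sprintf("RilPopulation: %d lines, %d chromosomes, F%d (SSD)\n",
              length(object@homologs), cfg$n_chromosomes,
              cfg$n_selfing_generations + 1L))
  cat(sprintf("  map length: %.1f cM total\n", sum(cfg$chrom_length_cm)))
})

setMethod("show", "SnpGenotypes", function(object) {
  tab <- table(factor(object@calls, levels = GENO_CODES))
  cat(sprintf("SnpGenotypes: %d lines x %d sites on %d chromosomes\n",
              nrow(object@calls), ncol(object@calls),
              length(unique(as.character(seqnames(object@sites))))))
  cat(sprintf("  call mix: A %.1f%%  B %.1f%%  H %.1f%%  U %.1f%%\n",
              100 * tab[["A"]] / length(object@calls),
              100 * tab[["B"]] / length(object@calls),
              100 * tab[["H"]] / length(object@calls),
              100 * tab[["U"]] / length(object@calls)))
})

setMethod("show", "BinMap", function(object) {
  mapped <- mcols(object@bins)$mapped
  cat(sprintf("BinMap: %d bins (%d mapped) on %d chromosomes, %d lines\n",
              length(object@bins), sum(mapped),
              length(unique(as.character(seqnames(object@bins)))),
              nrow(object@geno)))
  cm <- mcols(object@bins)$cm
  chr <- as.character(seqnames(object@bins))
  lg <- vapply(split(cm[mapped], chr[mapped]), function(z) max(z) - min(z), 0)
  cat(sprintf("  total map length: %.2f cM\n", sum(lg)))
})

setMethod("show", "QtlScan", function(object) {
  cat(sprintf("QtlScan: trait '%s', condition '%s', %d bins\n",
              object@trait, object@condition, nrow(object@profile)))
  cat(sprintf("  max LOD %.2f at %s:%.1f cM; threshold %s; %d cofactor(s)\n",
              max(object@profile$lod),
              object@profile$chrom[which.max(object@profile$lod)],
              object@profile$cm[which.max(object@profile$lod)],
              ifelse(is.na(object@threshold), "unset",
                     sprintf("%.2f", object@threshold)),
              length(object@cofactors)))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(paste0("VarianceComponents: sigma_g2 = %.4f, sigma_ge2 = %.4f, ",
                     "sigma_e2 = %.4f, sigma_r2 = %.4f (n = %g env, r = %g reps)\n"),
              object@sigma_g2, object@sigma_ge2, object@sigma_e2,
              object@sigma_r2, object@n_env, object@n_reps))
  if (length(object@truncated))
    cat("  truncated at 0:", paste(object@truncated, collapse = ", "), "\n")
})
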