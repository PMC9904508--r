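## Synthetic study generator: RIL genotypes by single-seed descent, balanced
## multi-environment phenotypes, and an 8-library bulked-segregant expression
## design, all with recorded ground truth.

#' Simulation configuration
#'
#' Assembles and validates the configuration driving every synthetic-data
#' generator. Defaults emulate the study design this pipeline targets: a
#' 253-line F10 RIL population over 12 rice-sized chromosomes, scored in
#' 2 environments x 3 years x 3 replicates, with an 8-library expression
#' design (2 parents and 2 phenotypic bulks under salt and control).
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_cm genetic map length per chromosome (cM); recycled.
#' @param chrom_length_bp physical length per chromosome (bp); recycled.
#' @param n_lines number of RILs.
#' @param n_selfing_generations selfing rounds after the F1 (9 gives F10).
#' @param snp_density SNP sites per Mb.
#' @param genotyping_error_rate probability an observed call is miscalled.
#' @param missing_rate probability an observed call is missing.
#' @param depth_mean mean per-call sequencing depth (Poisson).
#' @param quality_mean,quality_sd per-site quality score distribution.
#' @param qtl_spec data.frame with columns \code{chrom} (index), \code{pos_bp},
#'   \code{additive} (effect of the P1 allele, trait units) and \code{trait}.
#' @param varcomps named list of variance components in trait units squared:
#'   \code{sigma_g2}, \code{sigma_ge2}, \code{sigma_e2}, \code{sigma_env2},
#'   \code{sigma_rep2}, plus \code{grand_mean}.
#' @param design named list: \code{n_env}, \code{n_years}, \code{n_reps}.
#' @param deg_spec named list controlling the expression design; see
#'   \code{\link{simulateExpression}}.
#' @param seed integer; fixes every generated artifact bit-for-bit.
#' @return a validated list of class \code{sim_config}.
#' @export
simConfig <- function(n_chromosomes = 12,
                      chrom_length_cm = 117.3,
                      chrom_length_bp = 31.1e6,
                      n_lines = 253,
                      n_selfing_generations = 9,
                      snp_density = 60,
                      genotyping_error_rate = 0.005,
                      missing_rate = 0.05,
                      depth_mean = 8,
                      quality_mean = 45,
                      quality_sd = 10,
                      qtl_spec = NULL,
                      varcomps = list(sigma_g2 = 1, sigma_ge2 = 0.5,
                                      sigma_e2 = 1, sigma_env2 = 0.25,
                                      sigma_rep2 = 0.1, grand_mean = 4.5),
                      design = list(n_env = 2, n_years = 3, n_reps = 3),
                      deg_spec = list(n_genes = 2000, lfc = 4,
                                      delta_pair = c(4.5, 3), dispersion = 0.1,
                                      lib_sizes = rep(2e6, 8),
                                      base_mean_log = log(150),
                                      base_mean_sdlog = 1,
                                      planted_mean_log = log(400),
                                      planted_mean_sdlog = 0.5,
                                      n_per_class_parent = 40,
                                      n_per_class_bulk = 40,
                                      n_shared_per_class = 10,
                                      n_shared_in_qtl = 10,
                                      qtl_window_bp = 250000),
                      seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_cm = rep_len(chrom_length_cm, n_chromosomes),
    chrom_length_bp = rep_len(chrom_length_bp, n_chromosomes),
    n_lines = as.integer(n_lines),
    n_selfing_generations = as.integer(n_selfing_generations),
    snp_density = snp_density,
    genotyping_error_rate = genotyping_error_rate,
    missing_rate = missing_rate,
    depth_mean = depth_mean,
    quality_mean = quality_mean,
    quality_sd = quality_sd,
    qtl_spec = qtl_spec,
    varcomps = varcomps,
    design = design,
    deg_spec = deg_spec,
    seed = as.integer(seed)
  )
  if (cfg$n_chromosomes < 1 || cfg$n_lines < 1)
    stop("configuration error: need at least one chromosome and one line")
  if (any(cfg$chrom_length_cm <= 0) || any(cfg$chrom_length_bp <= 0))
    stop("configuration error: non-positive chromosome length")
  probs <- c(cfg$genotyping_error_rate, cfg$missing_rate)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  vc <- unlist(cfg$varcomps[c("sigma_g2", "sigma_ge2", "sigma_e2",
                              "sigma_env2", "sigma_rep2")])
  if (any(vc < 0)) stop("configuration error: variances must be >= 0")
  if (!is.null(cfg$qtl_spec)) {
    qs <- cfg$qtl_spec
    if (any(qs$chrom < 1 | qs$chrom > cfg$n_chromosomes))
      stop("configuration error: QTL on a chromosome outside the genome")
    if (any(qs$pos_bp < 1 | qs$pos_bp > cfg$chrom_length_bp[qs$chrom]))
      stop("configuration error: QTL position outside its chromosome")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Additive effect sized to a target per-environment PVE
#'
#' The proportion of variance explained is defined against the phenotypic
#' variance of a per-environment line mean, \eqn{\sigma_g^2 + \sigma_{ge}^2 +
#' \sigma_e^2 / r}, so a QTL planted at a given PVE is detectable in the
#' single-environment scans that the cross-condition stability rule requires,
#' not only in the (less noisy) BLUP scan.
#'
#' @param pve target proportion of variance explained, in [0, 1).
#' @param varcomps variance-component list as in \code{\link{simConfig}}.
#' @param n_reps replicates per environment.
#' @return additive effect a such that a RIL QTL genotype (coded +1/-1)
#'   contributes \code{pve} of the per-environment line-mean variance.
#' @export
qtlEffectForPve <- function(pve, varcomps, n_reps) {
  stopifnot(pve >= 0, pve < 1)
  v <- varcomps$sigma_g2 + varcomps$sigma_ge2 + varcomps$sigma_e2 / n_reps
  sqrt(pve * v)
}

## Deterministic per-stage seed so each generator is independently
## reproducible from one global seed.
.stageSeed <- function(seed, stage) {
  (as.integer(seed) %% 20000L) * 100000L + stage * 101L
}

## ---- meiosis engine (tract representation, cM coordinates) ----

.mergeTracts <- function(ends, origin) {
  if (length(origin) <= 1) return(list(ends = ends, origin = origin))
  keep <- c(origin[-1] != origin[-length(origin)], TRUE)
  list(ends = ends[keep], origin = origin[keep])
}

## tract structure of homolog restricted to (a, b]
.sliceTracts <- function(h, a, b) {
  starts <- c(0, h$ends[-length(h$ends)])
  keep <- which(h$ends > a & starts < b)
  list(ends = pmin(h$ends[keep], b), origin = h$origin[keep])
}

## one gamete from a pair of homologs; crossover count ~ Poisson(map length
## in Morgans), positions uniform in cM (no interference)
.meiosis <- function(h1, h2, len_cm) {
  k <- rpois(1L, len_cm / 100)
  phase <- sample.int(2L, 1L)
  if (k == 0L) {
    h <- if (phase == 1L) h1 else h2
    return(list(ends = h$ends, origin = h$origin, xo = numeric(0)))
  }
  xo <- sort(runif(k, 0, len_cm))
  bounds <- c(0, xo, len_cm)
  src <- rep_len(if (phase == 1L) c(1L, 2L) else c(2L, 1L), k + 1L)
  ends <- numeric(0); origin <- integer(0)
  for (i in seq_len(k + 1L)) {
    piece <- .sliceTracts(if (src[i] == 1L) h1 else h2, bounds[i], bounds[i + 1L])
    ends <- c(ends, piece$ends); origin <- c(origin, piece$origin)
  }
  c(.mergeTracts(ends, origin), list(xo = xo))
}

#' Simulate a RIL population by single-seed descent
#'
#' Starts every line from the F1 (one homolog per parent), then iterates
#' \code{n_selfing_generations} rounds of selfing, drawing two independent
#' gametes per plant per generation. Crossovers per chromosome per meiosis
#' follow a no-interference count process with mean equal to the map length in
#' Morgans. Residual heterozygous tracts are retained, not forced out.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \code{\linkS4class{RilPopulation}}.
#' @export
simulateRilPopulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stageSeed(config$seed, 1L))
  nchr <- config$n_chromosomes
  lens <- config$chrom_length_cm
  xo_counts <- matrix(0L, config$n_selfing_generations, nchr)
  homologs <- vector("list", config$n_lines)
  for (l in seq_len(config$n_lines)) {
    plant <- lapply(seq_len(nchr), function(cc) list(
      h1 = list(ends = lens[cc], origin = 1L),
      h2 = list(ends = lens[cc], origin = 2L)))
    for (g in seq_len(config$n_selfing_generations)) {
      plant <- lapply(seq_len(nchr), function(cc) {
        g1 <- .meiosis(plant[[cc]]$h1, plant[[cc]]$h2, lens[cc])
        g2 <- .meiosis(plant[[cc]]$h1, plant[[cc]]$h2, lens[cc])
        xo_counts[g, cc] <<- xo_counts[g, cc] + length(g1$xo) + length(g2$xo)
        list(h1 = g1[c("ends", "origin")], h2 = g2[c("ends", "origin")])
      })
    }
    homologs[[l]] <- plant
  }
  names(homologs) <- sprintf("RIL%03d", seq_len(config$n_lines))
  new("RilPopulation", homologs = homologs, config = unclass(config),
      crossovers = list(per_generation_counts = xo_counts))
}

.originAt <- function(h, pos_cm) {
  idx <- findInterval(pos_cm, c(0, h$ends), left.open = TRUE)
  h$origin[pmax(idx, 1L)]
}

#' True genotype codes of a simulated population at given positions
#'
#' @param pop a \code{RilPopulation}.
#' @param chrom chromosome index (scalar).
#' @param pos_bp physical positions on that chromosome.
#' @return character matrix (lines x positions) of codes A/B/H.
#' @export
trueGenotypesAt <- function(pop, chrom, pos_bp) {
  cfg <- pop@config
  pos_cm <- pos_bp / cfg$chrom_length_bp[chrom] * cfg$chrom_length_cm[chrom]
  out <- matrix("H", length(pop@homologs), length(pos_bp),
                dimnames = list(names(pop@homologs), NULL))
  for (l in seq_along(pop@homologs)) {
    o1 <- .originAt(pop@homologs[[l]][[chrom]]$h1, pos_cm)
    o2 <- .originAt(pop@homologs[[l]][[chrom]]$h2, pos_cm)
    out[l, ] <- ifelse(o1 == o2, ifelse(o1 == 1L, "A", "B"), "H")
  }
  out
}

#' Per-locus heterozygosity of a simulated population
#'
#' Mean fraction of heterozygous calls over a grid of loci, used to check the
#' expected 2^-g decay under g rounds of selfing.
#'
#' @param pop a \code{RilPopulation}.
#' @param n_loci grid size per chromosome.
#' @return mean heterozygosity across all lines and loci.
#' @export
heterozygosity <- function(pop, n_loci = 50) {
  cfg <- pop@config
  hets <- vapply(seq_len(cfg$n_chromosomes), function(cc) {
    pos <- seq(1, cfg$chrom_length_bp[cc], length.out = n_loci)
    mean(trueGenotypesAt(pop, cc, pos) == "H")
  }, 0)
  mean(hets)
}

## ---- SNP observation layer ----

#' Emit an observed SNP genotype matrix from true parental origins
#'
#' Places SNP sites uniformly at the configured density, reads the true
#' parental origin at each site, then corrupts calls: with probability
#' \code{genotyping_error_rate} a call is replaced by a random homozygous
#' miscall, and with probability \code{missing_rate} it is masked. Per-call
#' depth (Poisson) and per-site quality scores are attached so downstream
#' depth/quality filters can be exercised; calls with depth 0 are missing.
#'
#' @param pop a \code{RilPopulation}.
#' @param config the \code{\link{simConfig}} used to build it.
#' @return a \code{\linkS4class{SnpGenotypes}}.
#' @export
emitSnpObservations <- function(pop, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stageSeed(config$seed, 2L))
  nchr <- config$n_chromosomes
  n_sites <- round(config$snp_density * config$chrom_length_bp / 1e6)
  if (any(n_sites < 1))
    stop("configuration error: snp_density yields zero sites on a chromosome")
  calls <- NULL; chroms <- character(0); positions <- integer(0)
  for (cc in seq_len(nchr)) {
    pos <- sort(sample.int(config$chrom_length_bp[cc], n_sites[cc]))
    true <- trueGenotypesAt(pop, cc, pos)
    calls <- cbind(calls, true)
    chroms <- c(chroms, rep(sprintf("chr%02d", cc), n_sites[cc]))
    positions <- c(positions, pos)
  }
  n <- length(calls)
  err <- matrix(runif(n) < config$genotyping_error_rate, nrow(calls))
  if (any(err)) {
    flip <- matrix(sample(c("A", "B"), n, replace = TRUE), nrow(calls))
    ## a miscall never reproduces the true call
    flip[calls == "A"] <- "B"; flip[calls == "B"] <- "A"
    calls[err] <- flip[err]
  }
  depth <- matrix(rpois(n, config$depth_mean), nrow(calls))
  calls[matrix(runif(n) < config$missing_rate, nrow(calls))] <- "U"
  calls[depth == 0L] <- "U"
  quality <- pmax(0, pmin(60, round(rnorm(ncol(calls), config$quality_mean,
                                          config$quality_sd), 1)))
  sl <- setNames(as.integer(config$chrom_length_bp),
                 sprintf("chr%02d", seq_len(nchr)))
  sites <- GRanges(chroms, IRanges(positions, positions), quality = quality,
                   seqlengths = sl)
  dimnames(depth) <- dimnames(calls) <- list(names(pop@homologs), NULL)
  new("SnpGenotypes", calls = calls, sites = sites, depth = depth)
}

## ---- phenotypes ----

#' Simulate balanced multi-environment SES phenotypes
#'
#' Draws phenotypes under the random-effects model
#' \eqn{Y_{ijk} = \mu + L_k + E_i + R(E)_{ij} + (L \times E)_{ik} + e_{ijk}}
#' with an environment index i running over environment-by-year combinations.
#' The line genetic value is the sum of planted QTL effects (+a for the A/P1
#' genotype, -a for B, 0 for residual heterozygotes) plus a normal polygenic
#' draw scaled so the total line variance equals \code{sigma_g2}.
#'
#' @param pop a \code{RilPopulation}.
#' @param config the \code{\link{simConfig}} (its \code{qtl_spec}, \code{varcomps}
#'   and \code{design} blocks are used).
#' @return list with \code{phenotypes} (data.frame: line, env, year, rep,
#'   env_year, value) and \code{truth} (line genetic values and inputs).
#' @export
simulatePhenotypes <- function(pop, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stageSeed(config$seed, 3L))
  vc <- config$varcomps; dz <- config$design
  lines <- names(pop@homologs); nl <- length(lines)
  qtl_var <- 0
  g_qtl <- numeric(nl)
  if (!is.null(config$qtl_spec) && nrow(config$qtl_spec)) {
    qs <- config$qtl_spec
    for (q in seq_len(nrow(qs))) {
      gt <- trueGenotypesAt(pop, qs$chrom[q], qs$pos_bp[q])[, 1]
      z <- ifelse(gt == "A", 1, ifelse(gt == "B", -1, 0))
      g_qtl <- g_qtl + qs$additive[q] * z
      qtl_var <- qtl_var + qs$additive[q]^2
    }
  }
  if (qtl_var > vc$sigma_g2)
    warning("planted QTL variance exceeds sigma_g2; polygenic background set to 0")
  g_poly <- rnorm(nl, 0, sqrt(max(vc$sigma_g2 - qtl_var, 0)))
  G <- g_qtl + g_poly
  envs <- sprintf("env%d", seq_len(dz$n_env))
  years <- 2017L + seq_len(dz$n_years) - 1L
  grid <- expand.grid(rep = seq_len(dz$n_reps), year = years, env = envs,
                      line = lines, stringsAsFactors = FALSE)
  grid$env_year <- paste(grid$env, grid$year, sep = "_")
  ey <- unique(grid$env_year)
  E <- setNames(rnorm(length(ey), 0, sqrt(vc$sigma_env2)), ey)
  rep_key <- unique(paste(grid$env_year, grid$rep))
  R <- setNames(rnorm(length(rep_key), 0, sqrt(vc$sigma_rep2)), rep_key)
  ge_key <- unique(paste(grid$line, grid$env_year))
  GE <- setNames(rnorm(length(ge_key), 0, sqrt(vc$sigma_ge2)), ge_key)
  Gline <- setNames(G, lines)
  grid$value <- vc$grand_mean + Gline[grid$line] + E[grid$env_year] +
    R[paste(grid$env_year, grid$rep)] + GE[paste(grid$line, grid$env_year)] +
    rnorm(nrow(grid), 0, sqrt(vc$sigma_e2))
  phen <- grid[, c("line", "env", "year", "rep", "env_year", "value")]
  rownames(phen) <- NULL
  list(phenotypes = phen,
       truth = list(genetic_value = Gline, qtl_spec = config$qtl_spec,
                    varcomps = vc, design = dz))
}

## ---- expression ----

.CONTRAST_SAMPLES <- c("SalP1", "SalP2", "NorP1", "NorP2",
                       "SalT", "SalS", "NorT", "NorS")

.DEG_CLASSES <- c("SalOnly_up", "SalOnly_down", "NorOnly_up", "NorOnly_down",
                  "DeltaLFC_gt1", "DeltaLFC_ltm1")

## salt/normal LFC pair planted for each class (LFC = log2 tolerant/sensitive)
.classLfc <- function(class, lfc, delta_pair) {
  switch(class,
    SalOnly_up    = c(lfc, 0),
    SalOnly_down  = c(-lfc, 0),
    NorOnly_up    = c(0, lfc),
    NorOnly_down  = c(0, -lfc),
    DeltaLFC_gt1  = c(delta_pair[1], delta_pair[2]),
    DeltaLFC_ltm1 = c(delta_pair[2], delta_pair[1]),
    none          = c(0, 0))
}

#' Simulate the eight-library expression design with planted DEG classes
#'
#' Genes are tiled over the chromosomes and written as GFF3-ready ranges.
#' Counts are negative binomial with gene-level baseline means, a configured
#' dispersion and library sizes; one library per sample, as in the target
#' 8-library design (SalP1, SalP2, NorP1, NorP2, SalT, SalS, NorT, NorS).
#' Planted classes cover all six salt-specific types for both the parent and
#' the bulk contrast; a configurable number of shared (parent-and-bulk) DEGs
#' is placed inside the planted QTL windows, the rest outside all of them.
#'
#' @param config a \code{\link{simConfig}}.
#' @param truth_qtls optional data.frame like \code{config$qtl_spec}; defaults
#'   to it. Planted in-QTL DEGs land within \code{qtl_window_bp} of these.
#' @return list with \code{counts} (integer matrix genes x 8), \code{genes}
#'   (GRanges with \code{gene_id}), and \code{truth} (per-gene planted classes
#'   and placement flags).
#' @export
simulateExpression <- function(config, truth_qtls = config$qtl_spec) {
  stopifnot(inherits(config, "sim_config"))
  ds <- config$deg_spec
  if (is.null(ds$n_genes) || ds$n_genes <= 0)
    stop("configuration error: need n_genes > 0")
  if (any(ds$lib_sizes <= 0))
    stop("configuration error: library sizes must be positive")
  set.seed(.stageSeed(config$seed, 4L))
  nchr <- config$n_chromosomes
  per_chr <- round(ds$n_genes * config$chrom_length_bp / sum(config$chrom_length_bp))
  per_chr[1] <- ds$n_genes - sum(per_chr[-1])
  chroms <- rep(sprintf("chr%02d", seq_len(nchr)), per_chr)
  starts <- unlist(lapply(seq_len(nchr), function(cc) {
    sort(sample.int(config$chrom_length_bp[cc] - 5000L, per_chr[cc]))
  }))
  widths <- sample(800:3000, ds$n_genes, replace = TRUE)
  ## planted class assignment
  truth <- data.frame(
    gene_id = sprintf("G%05d", seq_len(ds$n_genes)),
    parent_class = "none", bulk_class = "none",
    shared = FALSE, in_qtl = FALSE, stringsAsFactors = FALSE)
  idx <- seq_len(ds$n_genes)
  take <- function(n) { out <- idx[seq_len(n)]; idx <<- idx[-seq_len(n)]; out }
  for (cl in .DEG_CLASSES) {
    sh <- take(ds$n_shared_per_class)
    truth$parent_class[sh] <- cl; truth$bulk_class[sh] <- cl
    truth$shared[sh] <- TRUE
    po <- take(ds$n_per_class_parent)
    truth$parent_class[po] <- cl
    bo <- take(ds$n_per_class_bulk)
    truth$bulk_class[bo] <- cl
  }
  ## place a subset of shared salt-specific (up/down) genes inside QTL windows
  if (!is.null(truth_qtls) && nrow(truth_qtls) && ds$n_shared_in_qtl > 0) {
    salt_up_down <- truth$shared &
      truth$parent_class %in% c("SalOnly_up", "SalOnly_down")
    cand <- which(salt_up_down)
    pick <- cand[seq_len(min(ds$n_shared_in_qtl, length(cand)))]
    truth$in_qtl[pick] <- TRUE
    w <- ds$qtl_window_bp
    for (j in seq_along(pick)) {
      q <- 1L + (j - 1L) %% nrow(truth_qtls)
      chroms[pick[j]] <- sprintf("chr%02d", truth_qtls$chrom[q])
      lo <- max(1L, truth_qtls$pos_bp[q] - w)
      hi <- min(config$chrom_length_bp[truth_qtls$chrom[q]] - 5000L,
                truth_qtls$pos_bp[q] + w)
      starts[pick[j]] <- sample(seq(lo, hi), 1L)
    }
    ## keep every other gene clear of the QTL windows so "outside" is exact
    qtl_gr <- GRanges(sprintf("chr%02d", truth_qtls$chrom),
                      IRanges(pmax(1, truth_qtls$pos_bp - 4 * w),
                              truth_qtls$pos_bp + 4 * w))
    gr_all <- GRanges(chroms, IRanges(starts, width = widths))
    clash <- unique(queryHits(findOverlaps(gr_all, qtl_gr)))
    clash <- setdiff(clash, pick)
    for (g in clash) starts[g] <- max(1L, starts[g] - as.integer(8 * w))
  }
  ord <- order(chroms, starts)
  genes <- GRanges(chroms[ord], IRanges(starts[ord], width = widths[ord]),
                   gene_id = truth$gene_id)
  ## note gene_id follows the original indexing; reorder truth rows to match
  truth <- truth[ord, ]; rownames(truth) <- NULL
  mcols(genes)$gene_id <- truth$gene_id
  sl <- setNames(as.integer(config$chrom_length_bp),
                 sprintf("chr%02d", seq_len(nchr)))
  seqlengths(genes) <- sl[seqlevels(genes)]
  base <- rlnorm(nrow(truth), ds$base_mean_log, ds$base_mean_sdlog)
  ## planted DEGs are drawn moderately-to-highly expressed: the no-replicate
  ## 8-library design only has power for such genes, and planting effects the
  ## design cannot see would make every recovery rate a statement about the
  ## generator rather than the analysis
  pml <- if (is.null(ds$planted_mean_log)) log(400) else ds$planted_mean_log
  pms <- if (is.null(ds$planted_mean_sdlog)) 0.5 else ds$planted_mean_sdlog
  planted <- truth$parent_class != "none" | truth$bulk_class != "none"
  base[planted] <- rlnorm(sum(planted), pml, pms)
  mu <- matrix(base, nrow(truth), 8,
               dimnames = list(truth$gene_id, .CONTRAST_SAMPLES))
  half <- function(l) 2^(l / 2)
  for (g in seq_len(nrow(truth))) {
    pl <- .classLfc(truth$parent_class[g], ds$lfc, ds$delta_pair)
    bl <- .classLfc(truth$bulk_class[g], ds$lfc, ds$delta_pair)
    mu[g, "SalP2"] <- mu[g, "SalP2"] * half(pl[1])
    mu[g, "SalP1"] <- mu[g, "SalP1"] / half(pl[1])
    mu[g, "NorP2"] <- mu[g, "NorP2"] * half(pl[2])
    mu[g, "NorP1"] <- mu[g, "NorP1"] / half(pl[2])
    mu[g, "SalT"] <- mu[g, "SalT"] * half(bl[1])
    mu[g, "SalS"] <- mu[g, "SalS"] / half(bl[1])
    mu[g, "NorT"] <- mu[g, "NorT"] * half(bl[2])
    mu[g, "NorS"] <- mu[g, "NorS"] / half(bl[2])
  }
  sf <- ds$lib_sizes / mean(ds$lib_sizes)
  mu <- sweep(mu, 2, sf, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / ds$dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  truth$chrom <- as.character(seqnames(genes))
  truth$start <- start(genes); truth$end <- end(genes)
  list(counts = counts, genes = genes, truth = truth)
}

## ---- writers / readers ----

#' Write observed genotypes as a long TSV (line_id, chrom, pos, code)
#' @param snps a SnpGenotypes
#' @param path output path
#' @export
writeGenotypesTsv <- function(snps, path) {
  chr <- as.character(seqnames(snpSites(snps)))
  pos <- start(snpSites(snps))
  df <- data.frame(
    line_id = rep(lineNames(snps), times = ncol(snpCalls(snps))),
    chrom = rep(chr, each = nrow(snpCalls(snps))),
    pos = rep(pos, each = nrow(snpCalls(snps))),
    code = as.vector(snpCalls(snps)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long genotype TSV back into a SnpGenotypes
#'
#' Depth and quality are not carried by the TSV; they are filled with
#' sentinels that pass the default filters.
#' @param path TSV written by \code{\link{writeGenotypesTsv}}
#' @param seqlengths optional named chromosome lengths (bp)
#' @export
readGenotypesTsv <- function(path, seqlengths = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lines <- unique(df$line_id)
  key <- paste(df$chrom, df$pos)
  sites <- unique(df[, c("chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), ]
  calls <- matrix("U", length(lines), nrow(sites),
                  dimnames = list(lines, NULL))
  calls[cbind(match(df$line_id, lines),
              match(key, paste(sites$chrom, sites$pos)))] <- df$code
  gr <- GRanges(sites$chrom, IRanges(sites$pos, sites$pos),
                quality = rep(99, nrow(sites)))
  if (!is.null(seqlengths)) seqlengths(gr) <- seqlengths[seqlevels(gr)]
  new("SnpGenotypes", calls = calls, sites = gr,
      depth = matrix(99L, length(lines), nrow(sites),
                     dimnames = list(lines, NULL)))
}

#' Write a minimal VCF 4.2 of the observed genotypes
#'
#' Parental origins are encoded as pseudo-alleles (REF = P1 allele, ALT = P2
#' allele): A -> 0/0, B -> 1/1, H -> 0/1, U -> ./. ; per-call depth goes in
#' the DP field and per-site quality in QUAL.
#' @param snps a SnpGenotypes
#' @param path output path
#' @export
writeMinimalVcf <- function(snps, path) {
  chr <- as.character(seqnames(snpSites(snps)))
  pos <- start(snpSites(snps))
  qual <- mcols(snpSites(snps))$quality
  gt_map <- c(A = "0/0", B = "1/1", H = "0/1", U = "./.")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", lineNames(snps)), collapse = "\t")),
             con)
  calls <- snpCalls(snps); depth <- snpDepth(snps)
  for (j in seq_along(pos)) {
    cells <- paste(gt_map[calls[, j]], depth[, j], sep = ":")
    writeLines(paste(c(chr[j], pos[j], sprintf("s%06d", j), "A", "G", qual[j],
                       "PASS", ".", "GT:DP", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write phenotypes as CSV (line, env, year, rep, env_year, value)
#' @param phen phenotype data.frame
#' @param path output path
#' @export
writePhenotypeCsv <- function(phen, path) {
  write.csv(phen, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype CSV
#' @param path CSV path
#' @export
readPhenotypeCsv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write the counts matrix with gene coordinates as TSV
#' @param counts integer matrix genes x 8 samples
#' @param genes GRanges with gene_id matching the rows
#' @param path output path
#' @export
writeCountsTsv <- function(counts, genes, path) {
  df <- data.frame(gene_id = mcols(genes)$gene_id,
                   chrom = as.character(seqnames(genes)),
                   start = start(genes), end = end(genes),
                   counts[mcols(genes)$gene_id, , drop = FALSE])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV into (counts, genes)
#' @param path TSV written by \code{\link{writeCountsTsv}}
#' @export
readCountsTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, .CONTRAST_SAMPLES])
  rownames(counts) <- df$gene_id
  genes <- GRanges(df$chrom, IRanges(df$start, df$end), gene_id = df$gene_id)
  list(counts = counts, genes = genes)
}

#' Write gene models as GFF3
#' @param genes GRanges with gene_id
#' @param path output path
#' @export
writeGeneGff3 <- function(genes, path) {
  gr <- genes
  mcols(gr)$type <- "gene"
  mcols(gr)$ID <- mcols(gr)$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Generate the full synthetic study
#'
#' Runs every generator off one configuration and optionally persists all
#' artifacts (genotype TSV + minimal VCF, phenotype CSV, counts TSV, GFF3,
#' truth JSON) under \code{out_dir}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param out_dir optional output directory.
#' @return list: \code{population}, \code{snps}, \code{phenotypes},
#'   \code{expression}, \code{truth}.
#' @export
simulateStudy <- function(config, out_dir = NULL) {
  pop <- simulateRilPopulation(config)
  snps <- emitSnpObservations(pop, config)
  ph <- simulatePhenotypes(pop, config)
  expr <- simulateExpression(config)
  truth <- list(qtl_spec = config$qtl_spec,
                varcomps = config$varcomps,
                genetic_value = as.list(ph$truth$genetic_value),
                deg_truth = expr$truth[expr$truth$parent_class != "none" |
                                       expr$truth$bulk_class != "none", ])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeGenotypesTsv(snps, file.path(out_dir, "genotypes.tsv"))
    writeMinimalVcf(snps, file.path(out_dir, "genotypes.vcf"))
    writePhenotypeCsv(ph$phenotypes, file.path(out_dir, "phenotypes.csv"))
    writeCountsTsv(expr$counts, expr$genes, file.path(out_dir, "counts.tsv"))
    writeGeneGff3(expr$genes, file.path(out_dir, "genes.gff3"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(population = pop, snps = snps, phenotypes = ph$phenotypes,
       expression = expr, truth = truth)
}
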