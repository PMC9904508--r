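## Independent oracles and small constructors shared across the suite.

## Exhaustive two-locus selfing Markov chain. Haplotypes 1=AB, 2=Ab, 3=aB,
## 4=ab; genotype = unordered pair. Starting from the F1 (AB/ab), iterates g
## generations of selfing at meiotic recombination fraction r and returns the
## expected RIL recombinant fraction among lines homozygous at both loci,
## i.e. P(Ab/Ab or aB/aB) / P(fully homozygous).
twoLocusRilRf <- function(r, g) {
  hap <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))  # allele at locus1, locus2
  gametes <- function(h1, h2) {
    ## returns probability over the 4 haplotypes of one gamete
    p <- numeric(4)
    add <- function(a1, a2, pr) {
      idx <- which(hap[, 1] == a1 & hap[, 2] == a2)
      p[idx] <<- p[idx] + pr
    }
    add(hap[h1, 1], hap[h1, 2], (1 - r) / 2)
    add(hap[h2, 1], hap[h2, 2], (1 - r) / 2)
    add(hap[h1, 1], hap[h2, 2], r / 2)
    add(hap[h2, 1], hap[h1, 2], r / 2)
    p
  }
  ## genotype states: 10 unordered pairs
  states <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  state_id <- function(a, b) which(states[, 1] == min(a, b) &
                                   states[, 2] == max(a, b))
  P <- matrix(0, nrow(states), nrow(states))
  for (s in seq_len(nrow(states))) {
    gp <- gametes(states[s, 1], states[s, 2])
    for (i in 1:4) for (j in 1:4)  # unordered pair collects both orders
      P[s, state_id(i, j)] <- P[s, state_id(i, j)] + gp[i] * gp[j]
  }
  v <- numeric(nrow(states)); v[state_id(1, 4)] <- 1
  for (k in seq_len(g)) v <- as.numeric(v %*% P)
  hom <- vapply(seq_len(nrow(states)), function(s)
    states[s, 1] == states[s, 2], TRUE)
  p_par <- v[state_id(1, 1)] + v[state_id(4, 4)]
  p_rec <- v[state_id(2, 2)] + v[state_id(3, 3)]
  p_rec / (p_rec + p_par)
}

## Balanced-design ANOVA expected-mean-squares moment estimators for the
## model y = mu + line + env + rep(env) + line:env + error.
anovaMoments <- function(phen) {
  y <- phen$value
  line <- factor(phen$line); env <- factor(phen$env_year)
  rp <- factor(paste(phen$env_year, phen$rep))
  L <- nlevels(line); E <- nlevels(env)
  R <- nrow(phen) / (L * E)
  gm <- mean(y)
  m_l <- tapply(y, line, mean)
  m_e <- tapply(y, env, mean)
  m_le <- tapply(y, list(line, env), mean)
  m_er <- tapply(y, rp, mean)
  ms_line <- E * R * sum((m_l - gm)^2) / (L - 1)
  dev_le <- sweep(sweep(m_le, 1, m_l, "-"), 2, m_e, "-") + gm
  ms_lxe <- R * sum(dev_le^2) / ((L - 1) * (E - 1))
  env_of_rep <- tapply(phen$env_year, rp, function(z) z[1])
  ms_rep <- L * sum((m_er - m_e[env_of_rep])^2) / (E * (R - 1))
  fit_resid <- y - m_le[cbind(line, env)] - m_er[rp] + m_e[env]
  ms_err <- sum(fit_resid^2) / ((L - 1) * E * (R - 1))
  list(sigma_g2 = (ms_line - ms_lxe) / (E * R),
       sigma_ge2 = (ms_lxe - ms_err) / R,
       sigma_r2 = (ms_rep - ms_err) / L,
       sigma_e2 = ms_err)
}

## Brute-force conditional NB exact test, written independently of the
## package implementation (straight loop over the conditional support).
bruteForceNbExact <- function(a, b, ne_a, ne_b, phi) {
  s <- a + b
  lam <- s / (ne_a + ne_b)
  probs <- numeric(s + 1)
  for (k in 0:s) {
    pk <- if (phi == 0) {
      dpois(k, lam * ne_a) * dpois(s - k, lam * ne_b)
    } else {
      dnbinom(k, size = 1 / phi, mu = lam * ne_a) *
        dnbinom(s - k, size = 1 / phi, mu = lam * ne_b)
    }
    probs[k + 1] <- pk
  }
  probs <- probs / sum(probs)
  sum(probs[probs <= probs[a + 1] * (1 + 1e-10)])
}

## Construct a BinMap directly from a genotype matrix and bin layout.
makeBinMap <- function(geno, chrom = "chr01", start = NULL, end = NULL,
                       cm = NULL, chrom_len = NULL) {
  m <- ncol(geno)
  if (is.null(start)) {
    width <- 1e5
    start <- seq(1, by = width, length.out = m)
    end <- start + width - 1
  }
  if (is.null(cm)) cm <- (seq_len(m) - 1) * 1.0
  chrom <- rep_len(chrom, m)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               cm = cm, mapped = rep(TRUE, m))
  if (!is.null(chrom_len))
    GenomeInfoDb::seqlengths(gr) <- chrom_len
  new("BinMap", bins = gr, geno = geno)
}

## Bin genotypes as a first-order Markov chain along each chromosome with
## the RIL recombinant fraction implied by the bin spacing; a cheap stand-in
## population for scan-calibration tests where meiotic realism is not the
## property under test.
makeMarkovBinMap <- function(n_lines, n_chr = 12, bins_per_chr = 42,
                             spacing_cm = 3, seed = 1) {
  set.seed(seed)
  R <- 2 * haldaneRf(spacing_cm) / (1 + 2 * haldaneRf(spacing_cm))
  geno <- NULL; chroms <- character(0); cms <- numeric(0)
  for (cc in seq_len(n_chr)) {
    g <- matrix("", n_lines, bins_per_chr)
    g[, 1] <- sample(c("A", "B"), n_lines, replace = TRUE)
    for (j in 2:bins_per_chr) {
      flip <- runif(n_lines) < R
      g[, j] <- ifelse(flip, ifelse(g[, j - 1] == "A", "B", "A"), g[, j - 1])
    }
    geno <- cbind(geno, g)
    chroms <- c(chroms, rep(sprintf("chr%02d", cc), bins_per_chr))
    cms <- c(cms, (seq_len(bins_per_chr) - 1) * spacing_cm)
  }
  rownames(geno) <- sprintf("L%04d", seq_len(n_lines))
  width <- 1e5
  start <- unlist(lapply(seq_len(n_chr), function(cc)
    seq(1, by = width, length.out = bins_per_chr)))
  makeBinMap(geno, chrom = chroms, start = start, end = start + width - 1,
             cm = cms)
}

## Small, fast simulation config used in several tests.
tinySimConfig <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2, chrom_length_cm = 100, chrom_length_bp = 20e6,
         n_lines = 60, snp_density = 30,
         deg_spec = list(n_genes = 400, lfc = 4, delta_pair = c(4.5, 3),
                         dispersion = 0.1, lib_sizes = rep(2e6, 8),
                         base_mean_log = log(150), base_mean_sdlog = 1,
                         n_per_class_parent = 8, n_per_class_bulk = 8,
                         n_shared_per_class = 4, n_shared_in_qtl = 4,
                         qtl_window_bp = 250000),
         seed = 101L),
    list(...))
  do.call(simConfig, args)
}
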