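## small hand-built SnpGenotypes
makeSnps <- function(calls, pos = NULL, quality = NULL, depth = NULL,
                     chrom = "chr01", chrom_len = NULL) {
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(quality)) quality <- rep(50, m)
  if (is.null(depth)) depth <- matrix(10L, n, m)
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("L%03d", seq_len(n))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                               quality = quality)
  if (!is.null(chrom_len)) GenomeInfoDb::seqlengths(gr) <- chrom_len
  dimnames(depth) <- dimnames(calls)
  new("SnpGenotypes", calls = calls, sites = gr, depth = depth)
}

test_that("depth and quality filters mask calls and drop sites", {
  calls <- matrix("A", 3, 100)
  qual <- rep(50, 100); qual[1:10] <- 10
  depth <- matrix(10L, 3, 100); depth[1, 50] <- 2L
  snps <- makeSnps(calls, quality = qual, depth = depth)
  out <- suppressMessages(filterSnps(snps))
  expect_equal(ncol(snpCalls(out)), 90)
  ## site 50 survives but line 1's call there is masked
  expect_equal(unname(snpCalls(out)[1, 40]), "U")   # site 50 is column 40 after drop
  expect_equal(unname(snpCalls(out)[2, 40]), "A")
  ## identity when everything passes
  clean <- makeSnps(matrix("B", 2, 20))
  expect_identical(snpCalls(suppressMessages(filterSnps(clean))),
                   snpCalls(clean))
  ## everything dropped is an explicit error
  bad <- makeSnps(matrix("A", 2, 5), quality = rep(1, 5))
  expect_error(filterSnps(bad), "all sites removed")
})

test_that("sliding-window calls follow the homozygous-fraction rule", {
  win <- function(codes) {
    snps <- makeSnps(matrix(codes, 1, 15), chrom_len = 16000L)
    wc <- callWindows(snps, window_size = 15)
    unname(wc[[1]]$calls[1, 1])
  }
  expect_equal(win(rep("A", 15)), "A")
  expect_equal(win(c(rep("A", 12), rep("B", 3))), "A")   # 0.8 >= 0.7
  expect_equal(win(c(rep("A", 8), rep("B", 7))), "H")    # 0.53 < 0.7
  expect_equal(win(rep("U", 15)), "U")
  ## missing calls are excluded from the denominator
  expect_equal(win(c(rep("A", 8), rep("U", 7))), "A")
  ## short chromosome collapses to one window with a warning
  short <- makeSnps(matrix("A", 1, 5), chrom_len = 6000L)
  expect_warning(wc <- callWindows(short, window_size = 15), "one window")
  expect_equal(ncol(wc[[1]]$calls), 1)
})

test_that("bins are the union of per-line breakpoints", {
  ## 2 lines on a 3 Mb chromosome, window centers at 0.5/1.5/2.5 Mb;
  ## line 1 switches A->B across the first gap (midpoint 1 Mb), line 2
  ## across the second (midpoint 2 Mb)
  wc <- list(chr01 = list(
    calls = rbind(L1 = c("A", "B", "B"), L2 = c("A", "A", "B")),
    center_bp = c(5e5, 1.5e6, 2.5e6), chrom_length = 3e6))
  bm <- collapseToBins(wc)
  gr <- binRanges(bm)
  expect_equal(GenomicRanges::start(gr), c(1, 1e6 + 1, 2e6 + 1))
  expect_equal(GenomicRanges::end(gr), c(1e6, 2e6, 3e6))
  expect_equal(unname(binGenotypes(bm)["L1", ]), c("A", "B", "B"))
  expect_equal(unname(binGenotypes(bm)["L2", ]), c("A", "A", "B"))
  ## one line, no crossover: a single whole-chromosome bin
  wc1 <- list(chr01 = list(calls = rbind(L1 = c("A", "A", "A")),
                           center_bp = c(5e5, 1.5e6, 2.5e6),
                           chrom_length = 3e6))
  expect_equal(length(binRanges(collapseToBins(wc1))), 1)
})

test_that("bins tile the chromosome and match truth at zero noise", {
  cfg <- simConfig(n_chromosomes = 1, chrom_length_cm = 100,
                   chrom_length_bp = 20e6, n_lines = 80, snp_density = 40,
                   genotyping_error_rate = 0, missing_rate = 0,
                   depth_mean = 30, quality_mean = 55, quality_sd = 1,
                   seed = 9L)
  pop <- simulateRilPopulation(cfg)
  snps <- emitSnpObservations(pop, cfg)
  bm <- suppressMessages(buildBinMap(snps))
  gr <- binRanges(bm)
  ## exact tiling
  expect_equal(sum(GenomicRanges::width(gr)), 20e6)
  expect_equal(GenomicRanges::start(gr)[-1],
               GenomicRanges::end(gr)[-length(gr)] + 1)
  ## bin genotypes equal true parental origins at bin midpoints
  mids <- floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
  truth <- trueGenotypesAt(pop, 1, mids)
  agree <- mean(binGenotypes(bm) == truth)
  expect_gt(agree, 0.995)
})

test_that("map functions satisfy their closed forms and inverses", {
  expect_equal(kosambiDistance(0), 0)
  expect_equal(kosambiDistance(0.25), 25 * log(3), tolerance = 1e-12)
  expect_lt(abs(kosambiDistance(0.01) - 1) / 1, 0.01)  # d ~ 100 r near 0
  expect_equal(rilCorrectRf(0), 0)
  expect_equal(rilCorrectRf(1 / 6), 0.1, tolerance = 1e-12)
  ## exact inverse of the selfed-RIL expansion across the domain
  r <- seq(0, 0.4999, by = 1e-3)
  expect_lt(max(abs(rilCorrectRf(2 * r / (1 + 2 * r)) - r)), 1e-12)
  ## strictly increasing
  d <- kosambiDistance(seq(0, 0.49, by = 1e-3))
  expect_true(all(diff(d) > 0))
  expect_error(kosambiDistance(0.5), "0.5")
  expect_error(rilCorrectRf(0.6), "0.5")
})

test_that("adjacent recombinant fractions are the informative-line ratio", {
  geno <- cbind(rep("A", 100),
                c(rep("B", 10), rep("A", 90)))
  rownames(geno) <- sprintf("L%03d", 1:100)
  bm <- makeBinMap(geno)
  rf <- estimateAdjacentRf(bm)
  expect_equal(rf$R, 0.10)
  expect_equal(rf$n_informative, 100)
  ## identical columns give R = 0; H lines drop from the denominator
  geno2 <- cbind(c(rep("A", 50), rep("H", 10)), rep("A", 60))
  geno2[1:5, 2] <- "B"
  rownames(geno2) <- sprintf("L%03d", 1:60)
  rf2 <- estimateAdjacentRf(makeBinMap(geno2))
  expect_equal(rf2$n_informative, 50)
  expect_equal(rf2$R, 5 / 50)
})

test_that("map summaries aggregate with the documented conventions", {
  ## single-bin chromosome: zero-length linkage group, zero gaps
  bm <- makeBinMap(matrix("A", 5, 1, dimnames = list(paste0("L", 1:5), NULL)))
  ms <- mapSummary(bm)
  expect_equal(ms$lg_length_cm[1], 0)
  expect_equal(ms$max_gap_cm[1], 0)
  ## genome aggregation of the worked-example per-chromosome rows
  g <- combineMapSummaries(workedExampleMapSummary())
  expect_equal(g$bins_mapped, 2921)
  expect_equal(g$bins_created, 3061)
  expect_equal(g$mean_bin_length_kb, 121.94, tolerance = 5e-5)
  expect_equal(g$mean_gap_cm, 0.48, tolerance = 0.005)
})

test_that("estimated map length tracks the simulated truth", {
  err <- vapply(1:10, function(s) {
    cfg <- simConfig(n_chromosomes = 1, chrom_length_cm = 120,
                     chrom_length_bp = 30e6, n_lines = 253, snp_density = 60,
                     seed = 400L + s)
    pop <- simulateRilPopulation(cfg)
    bm <- suppressMessages(buildBinMap(emitSnpObservations(pop, cfg)))
    lg <- mapSummary(bm)$lg_length_cm[1]
    abs(lg - 120) / 120
  }, 0)
  expect_true(all(err < 0.15))
})
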