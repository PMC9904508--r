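test_that("marker regression matches the hand least-squares oracle", {
  geno <- matrix(c("A", "A", "B", "B"), 4, 1,
                 dimnames = list(paste0("L", 1:4), NULL))
  bm <- makeBinMap(geno)
  sc <- singleMarkerScan(bm, setNames(c(0, 2, 4, 6), paste0("L", 1:4)))
  prof <- scanProfile(sc)
  ## group means 1 and 5; RSS0 = 20, RSS1 = 4
  expect_equal(prof$lod, 2 * log10(5), tolerance = 1e-12)
  expect_equal(prof$pve, 0.8, tolerance = 1e-12)
  expect_equal(prof$additive, -2, tolerance = 1e-12)  # P1 allele lowers trait
  ## heterozygous and missing lines are dropped per bin
  geno2 <- matrix(c("A", "A", "B", "B", "H", "U"), 6, 1,
                  dimnames = list(paste0("L", 1:6), NULL))
  sc2 <- singleMarkerScan(makeBinMap(geno2),
                          setNames(c(0, 2, 4, 6, 100, -100), paste0("L", 1:6)))
  expect_equal(scanProfile(sc2)$lod, 2 * log10(5), tolerance = 1e-12)
  expect_equal(scanProfile(sc2)$n_informative, 4L)
  ## monomorphic bin: LOD 0 with flag
  mono <- singleMarkerScan(makeBinMap(matrix("A", 4, 1,
                           dimnames = list(paste0("L", 1:4), NULL))),
                           setNames(c(0, 2, 4, 6), paste0("L", 1:4)))
  expect_equal(scanProfile(mono)$lod, 0)
  expect_true(scanProfile(mono)$monomorphic)
})

test_that("LOD is invariant to affine trait transformations", {
  bm <- makeMarkovBinMap(n_lines = 80, n_chr = 2, bins_per_chr = 25, seed = 4)
  set.seed(8)
  y <- setNames(rnorm(80), rownames(binGenotypes(bm)))
  l1 <- scanProfile(singleMarkerScan(bm, y))$lod
  l2 <- scanProfile(singleMarkerScan(bm, 3 * y - 7))$lod
  expect_lt(max(abs(l1 - l2)), 1e-9)
})

test_that("peak PVE and LOD satisfy the regression identity", {
  bm <- makeMarkovBinMap(n_lines = 100, n_chr = 1, bins_per_chr = 30, seed = 6)
  x <- binGenotypes(bm)[, 15]
  set.seed(2)
  y <- setNames(ifelse(x == "A", 1, -1) * 0.5 + rnorm(100),
                rownames(binGenotypes(bm)))
  prof <- scanProfile(singleMarkerScan(bm, y))
  expect_lt(max(abs(prof$pve -
                    (1 - 10^(-2 * prof$lod / prof$n_informative)))), 1e-9)
})

test_that("permutation thresholds are deterministic and quantile-monotone", {
  bm <- makeMarkovBinMap(n_lines = 60, n_chr = 2, bins_per_chr = 20, seed = 3)
  set.seed(10)
  y <- setNames(rnorm(60), rownames(binGenotypes(bm)))
  t1 <- permutationThreshold(bm, y, n_perm = 150, seed = 42)
  t2 <- permutationThreshold(bm, y, n_perm = 150, seed = 42)
  expect_identical(as.numeric(t1), as.numeric(t2))
  t10 <- permutationThreshold(bm, y, n_perm = 150, alpha = 0.10, seed = 42)
  expect_gte(as.numeric(t1), as.numeric(t10))
  expect_warning(permutationThreshold(bm, y, n_perm = 50, seed = 1), "noisy")
  ## a null trait stays below its genome-wide threshold (fixed seed)
  null_scan <- singleMarkerScan(bm, y)
  expect_lt(max(scanProfile(null_scan)$lod), as.numeric(t1))
})

test_that("2-LOD support intervals walk the constructed profile", {
  ## symmetric triangle, slope 1 per bin, peak LOD 6 at bin 6 of 11
  prof <- data.frame(bin = 1:11, chrom = "chr01", cm = 0:10,
                     start = seq(1, by = 1e5, length.out = 11),
                     end = seq(1e5, by = 1e5, length.out = 11),
                     lod = 6 - abs(6 - (1:11)))
  si <- supportInterval2Lod(prof, peak_row = 6)
  expect_equal(si$rows, c(4, 8))            # peak +/- 2 bins at LOD >= 4
  expect_equal(si$cm_start, 3); expect_equal(si$cm_end, 7)
  expect_false(si$truncated)
  ## peak at the chromosome edge: one-sided, flagged
  prof2 <- prof; prof2$lod <- 6 - (0:10)
  si2 <- supportInterval2Lod(prof2, peak_row = 1)
  expect_equal(si2$rows, c(1, 3))
  expect_true(si2$truncated)
  ## flat profile: the whole chromosome, flagged
  prof3 <- prof; prof3$lod <- rep(5, 11)
  si3 <- supportInterval2Lod(prof3, peak_row = 6)
  expect_equal(si3$rows, c(1, 11))
  expect_true(si3$truncated)
})

test_that("overlapping QTL intervals merge transitively", {
  q <- function(chrom, s, e, lod) data.frame(
    trait = "SES", condition = "BLUP", chrom = chrom, peak_bin = 1,
    peak_cm = 0, lod = lod, pve_pct = 10, additive = 0.2,
    cm_start = 0, cm_end = 1, bp_start = s, bp_end = e, truncated = FALSE)
  m1 <- mergeOverlapping(rbind(q("chr01", 1e6, 3e6, 5), q("chr01", 2e6, 5e6, 7)))
  expect_equal(nrow(m1), 1)
  expect_equal(m1$bp_start, 1e6); expect_equal(m1$bp_end, 5e6)
  expect_equal(m1$lod, 7)  # keeps the max-LOD member's statistics
  m2 <- mergeOverlapping(rbind(q("chr01", 1e6, 2e6, 5), q("chr01", 3e6, 4e6, 7)))
  expect_equal(nrow(m2), 2)
  chain <- rbind(q("chr01", 1e6, 2e6, 3), q("chr01", 1.5e6, 3e6, 4),
                 q("chr01", 2.5e6, 4e6, 5))
  m3 <- mergeOverlapping(chain)
  expect_equal(nrow(m3), 1)
  expect_equal(c(m3$bp_start, m3$bp_end), c(1e6, 4e6))
  ## property: merged intervals disjoint, every input inside exactly one
  set.seed(20)
  rq <- do.call(rbind, lapply(1:40, function(i) {
    s <- sample(1e7, 1); q(sample(c("chr01", "chr02"), 1), s, s + sample(2e6, 1), runif(1, 3, 9))
  }))
  mm <- mergeOverlapping(rq)
  for (cc in unique(mm$chrom)) {
    mi <- mm[mm$chrom == cc, ]
    if (nrow(mi) > 1)
      expect_true(all(mi$bp_start[-1] > mi$bp_end[-nrow(mi)]))
  }
  hits <- vapply(seq_len(nrow(rq)), function(i) {
    sum(mm$chrom == rq$chrom[i] & mm$bp_start <= rq$bp_start[i] &
        mm$bp_end >= rq$bp_end[i])
  }, 0L)
  expect_true(all(hits == 1))
})

test_that("the stability rule requires all conditions for some trait", {
  dm <- workedExampleDetectionMatrix()
  fl <- detectionFlags(dm$detection, c("greenhouse", "field", "BLUP"),
                       c("W2SES", "W4SES"))
  expect_equal(sum(fl$stable), 5)
  expect_equal(sum(fl$all_cells), 3)
  ## a QTL seen only under BLUP is not stable
  q <- data.frame(trait = "SES", condition = "BLUP", chrom = "chr01",
                  peak_bin = 1, peak_cm = 0, lod = 5, pve_pct = 10,
                  additive = 0.2, cm_start = 0, cm_end = 1,
                  bp_start = 1e6, bp_end = 2e6, truncated = FALSE)
  sr <- stableRegions(q, conditions = c("greenhouse", "field", "BLUP"))
  expect_false(any(sr$regions$stable))
  ## the same interval in all three conditions is stable
  q3 <- rbind(q, transform(q, condition = "greenhouse"),
              transform(q, condition = "field"))
  sr3 <- stableRegions(q3, conditions = c("greenhouse", "field", "BLUP"))
  expect_true(all(sr3$regions$stable))
})

test_that("cofactor selection finds two unlinked QTLs and nothing under the null", {
  bm <- makeMarkovBinMap(n_lines = 150, n_chr = 3, bins_per_chr = 35,
                         spacing_cm = 3, seed = 12)
  g <- binGenotypes(bm)
  x1 <- ifelse(g[, 15] == "A", 1, -1)          # chr01, 42 cM
  x2 <- ifelse(g[, 35 + 20] == "A", 1, -1)     # chr02, 57 cM
  set.seed(30)
  y <- setNames(0.6 * x1 + 0.6 * x2 + rnorm(150), rownames(g))
  thr <- permutationThreshold(bm, y, n_perm = 200, seed = 5)
  scan <- selectCofactors(bm, y, thr, condition = "BLUP")
  qtls <- extractQtls(scan)
  expect_setequal(unique(qtls$chrom), c("chr01", "chr02"))
  expect_lte(nrow(qtls), 3)
  for (cc in c("chr01", "chr02")) {
    truth_cm <- if (cc == "chr01") 14 * 3 else 19 * 3
    expect_lt(min(abs(qtls$peak_cm[qtls$chrom == cc] - truth_cm)), 5)
  }
  expect_gte(length(scan@cofactors), 2)
  ## null trait: no cofactors, no QTLs (fixed seed)
  y0 <- setNames(rnorm(150), rownames(g))
  thr0 <- permutationThreshold(bm, y0, n_perm = 200, seed = 6)
  scan0 <- selectCofactors(bm, y0, thr0)
  expect_length(scan0@cofactors, 0)
  expect_equal(nrow(extractQtls(scan0)), 0)
})
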