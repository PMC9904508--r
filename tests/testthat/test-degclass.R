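## deterministic counts matrix with known structure
fakeCounts <- function(n_genes = 500, seed = 17) {
  set.seed(seed)
  base <- rlnorm(n_genes, log(200), 1)
  counts <- vapply(1:8, function(s) rnbinom(n_genes, mu = base, size = 10),
                   numeric(n_genes))
  colnames(counts) <- c("SalP1", "SalP2", "NorP1", "NorP2",
                        "SalT", "SalS", "NorT", "NorS")
  rownames(counts) <- sprintf("G%04d", seq_len(n_genes))
  counts
}

test_that("TMM factors behave on constructed libraries", {
  cts <- fakeCounts()
  ## identical libraries: all factors 1
  same <- cts[, rep(1, 4)]
  colnames(same) <- paste0("S", 1:4)
  expect_equal(unname(tmmNormalize(same)), rep(1, 4), tolerance = 1e-9)
  ## doubling a library with no DE: normalized expression identical
  two <- cbind(A = cts[, 1], B = 2 * cts[, 1])
  f <- tmmNormalize(two)
  ne <- colSums(two) * f
  expect_lt(max(abs(two[, "A"] / ne["A"] - two[, "B"] / ne["B"])), 1e-6)
  ## factors always multiply to 1
  f8 <- tmmNormalize(cts)
  expect_equal(prod(f8), 1, tolerance = 1e-9)
  expect_error(tmmNormalize(cbind(a = rep(0, 10), b = 1:10)), "zero-count")
})

test_that("TMM agrees with the edgeR reference implementation", {
  cts <- fakeCounts(800, seed = 23)
  ## impose library-size and composition differences
  cts[, 2] <- rnbinom(800, mu = 3 * rlnorm(800, log(150), 1), size = 10)
  f_pkg <- tmmNormalize(cts)
  f_ref <- edgeR::calcNormFactors(edgeR::DGEList(counts = cts))$samples$norm.factors
  expect_lt(max(abs(f_pkg - f_ref)), 0.03)
})

test_that("the exact NB test matches brute-force enumeration", {
  cases <- list(c(200, 50), c(30, 12), c(5, 0), c(120, 115), c(0, 0))
  for (cs in cases) {
    p_pkg <- saltQTL:::.nbExactP(cs[1], cs[2], 1e6, 1e6, 0.1)
    p_ora <- bruteForceNbExact(cs[1], cs[2], 1e6, 1e6, 0.1)
    expect_equal(p_pkg, p_ora, tolerance = 1e-10,
                 label = paste(cs, collapse = " vs "))
  }
  ## unequal effective sizes
  expect_equal(saltQTL:::.nbExactP(90, 40, 2e6, 1e6, 0.1),
               bruteForceNbExact(90, 40, 2e6, 1e6, 0.1), tolerance = 1e-10)
  ## symmetry under swapping the pair at equal sizes
  expect_equal(saltQTL:::.nbExactP(70, 20, 1e6, 1e6, 0.1),
               saltQTL:::.nbExactP(20, 70, 1e6, 1e6, 0.1), tolerance = 1e-12)
  ## Poisson limit: dispersion 0 equals the exact binomial test
  expect_equal(saltQTL:::.nbExactP(30, 12, 1e6, 1e6, 0),
               binom.test(30, 42, 0.5)$p.value, tolerance = 1e-9)
  expect_equal(saltQTL:::.nbExactP(80, 25, 3e6, 1e6, 0),
               binom.test(80, 105, 0.75)$p.value, tolerance = 1e-9)
  expect_error(contrastTest(fakeCounts(50), "SalP2", "SalP1",
                            dispersion = -1), ">= 0")
})

test_that("contrasts flag DE by the joint LFC and FDR rule", {
  cts <- fakeCounts(300, seed = 31)
  ## symmetric input: equal counts give LFC 0 and no DE call
  cts[, "SalP2"] <- cts[, "SalP1"]
  res <- contrastTest(cts, "SalP2", "SalP1",
                      norm_factors = setNames(rep(1, 8), colnames(cts)))
  expect_equal(res$lfc, rep(0, 300))
  expect_false(any(res$de))
  ## BH monotonicity: a looser FDR cutoff never shrinks the DE set
  cts2 <- fakeCounts(300, seed = 32)
  r05 <- contrastTest(cts2, "SalT", "SalS", fdr_cut = 0.05)
  r10 <- contrastTest(cts2, "SalT", "SalS", fdr_cut = 0.10)
  expect_true(all(r05$gene[r05$de] %in% r10$gene[r10$de]))
})

test_that("six-way classification implements the class rules exactly", {
  mk <- function(gene, lfc, de) data.frame(gene = gene, lfc = lfc,
                                           pvalue = 0.01, fdr = 0.01, de = de)
  salt <- mk(paste0("g", 1:8), c(2, -2, 0.2, 0.3, 2.5, 1.2, 1.8, 0.1),
             c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  norm <- mk(paste0("g", 1:8), c(0.2, 0.1, 1.5, -1.5, 1.2, 2.5, 1.4, 0.2),
             c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  cls <- classifySixWay(salt, norm)
  expect_equal(cls$class,
               c("SalOnly_up", "SalOnly_down", "NorOnly_up", "NorOnly_down",
                 "DeltaLFC_gt1", "DeltaLFC_ltm1", "none", "none"))
  expect_equal(cls$direction,
               c("up", "down", "down", "up", "up", "down", "none", "none"))
  expect_equal(cls$delta_lfc[5], 1.3, tolerance = 1e-12)
  ## every gene gets exactly one label from the seven-value partition
  expect_true(all(cls$class %in% c(saltQTL:::DEG_CLASSES, "none")))
  ## genes present in only one contrast are excluded with a warning
  expect_warning(classifySixWay(salt[1:5, ], norm), "excluded")
})

test_that("swapping salt and normal relabels classes symmetrically", {
  set.seed(41)
  n <- 200
  mkr <- function() data.frame(gene = paste0("g", 1:n),
                               lfc = rnorm(n, 0, 2), pvalue = 0.01,
                               fdr = runif(n), de = NA)
  salt <- mkr(); norm <- mkr()
  salt$de <- abs(salt$lfc) >= 1 & salt$fdr <= 0.3
  norm$de <- abs(norm$lfc) >= 1 & norm$fdr <= 0.3
  fwd <- classifySixWay(salt, norm)
  rev <- classifySixWay(norm, salt)
  map <- c(SalOnly_up = "NorOnly_up", SalOnly_down = "NorOnly_down",
           NorOnly_up = "SalOnly_up", NorOnly_down = "SalOnly_down",
           DeltaLFC_gt1 = "DeltaLFC_ltm1", DeltaLFC_ltm1 = "DeltaLFC_gt1",
           none = "none")
  expect_equal(unname(map[fwd$class]), rev$class)
})

test_that("set construction and intersection follow the direction rule", {
  cls <- data.frame(gene = paste0("g", 1:6),
                    salt_lfc = 0, normal_lfc = 0, delta_lfc = 0,
                    class = c("SalOnly_up", "NorOnly_down", "DeltaLFC_gt1",
                              "SalOnly_down", "NorOnly_up", "none"),
                    direction = c("up", "up", "up", "down", "down", "none"))
  sets <- saltSpecificSets(cls)
  expect_setequal(sets$up, c("g1", "g2", "g3"))
  expect_setequal(sets$down, c("g4", "g5"))
  expect_equal(sets$total, 5)
  other <- list(up = c("g2", "g9"), down = c("g4", "g5", "g8"))
  sh <- intersectParentBulk(sets, other)
  expect_setequal(sh$up, "g2")
  expect_setequal(sh$down, c("g4", "g5"))
  expect_equal(sh$total, 3)
  ## shared sets are subsets of both inputs
  expect_true(all(sh$genes %in% c(sets$up, sets$down)))
  expect_true(all(sh$genes %in% c(other$up, other$down)))
  ## disjoint inputs give the empty set
  none <- intersectParentBulk(sets, list(up = "z1", down = "z2"))
  expect_equal(none$total, 0)
})

test_that("published class counts reproduce the study totals", {
  wx <- workedExampleDegClassCounts()
  tp <- degClassTotals(wx$parent)
  expect_equal(tp$n_up, 3521)
  expect_equal(tp$n_down, 3344)
  expect_equal(tp$total, 6865)
  expect_equal(degClassTotals(wx$bulk)$total, 3618)
  expect_equal(wx$common_up + wx$common_down, 551)
})

test_that("null expression data yields an almost-empty shared set", {
  totals <- vapply(1:3, function(s) {
    cfg <- tinySimConfig(seed = 600L + s, deg_spec = list(
      n_genes = 1000, lfc = 4, delta_pair = c(4.5, 3), dispersion = 0.1,
      lib_sizes = rep(2e6, 8), base_mean_log = log(150), base_mean_sdlog = 1,
      n_per_class_parent = 0, n_per_class_bulk = 0, n_shared_per_class = 0,
      n_shared_in_qtl = 0, qtl_window_bp = 250000))
    expr <- simulateExpression(cfg)
    degAnalysis(expr$counts)$shared$total
  }, 0)
  ## two independent comparisons must both miscall the same gene in the
  ## same direction; expectation is well under 1 per 1000 genes
  expect_lt(mean(totals), 5)
})
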