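## End-to-end orchestration: synthetic inputs (or user files) -> bin map ->
## BLUP/heritability -> per-condition QTL scans -> stability rule -> DEG
## classification -> colocalization, with persisted intermediates and a
## machine-readable run report.

#' Assemble a pipeline configuration
#'
#' @param out_dir output directory for intermediates and the report.
#' @param seed global seed; per-stage seeds are derived deterministically as
#'   \code{(seed mod 20000) * 100000 + stage * 101}, so any stage can be
#'   re-run in isolation.
#' @param synth a \code{\link{simConfig}} to generate inputs, or NULL to read
#'   them from \code{inputs}.
#' @param inputs named list of file paths (\code{genotypes}, \code{phenotypes},
#'   \code{counts}, \code{gff}) used when \code{synth} is NULL; any of
#'   \code{counts}/\code{gff} may be absent, which skips the expression stages.
#' @param condition_map named map from phenotype \code{env} values to scan
#'   condition labels (default env1 = greenhouse, env2 = field).
#' @param binmap,qtl,deg,coloc stage parameter lists; see
#'   \code{\link{buildBinMap}}, \code{\link{scanQtl}}, \code{\link{degAnalysis}}
#'   and \code{\link{overlayCandidates}} for meanings and defaults.
#' @return a \code{pipeline_config} list.
#' @export
pipelineConfig <- function(out_dir, seed = 1L, synth = NULL, inputs = list(),
                           condition_map = c(env1 = "greenhouse", env2 = "field"),
                           binmap = list(), qtl = list(), deg = list(),
                           coloc = list()) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), synth = synth, inputs = inputs,
    condition_map = condition_map,
    binmap = utils::modifyList(list(window_size = 15, homo_fraction = 0.7,
                                    min_depth = 3, min_quality = 30,
                                    min_line_frac = 0.8), binmap),
    qtl = utils::modifyList(list(n_perm = 1000, alpha = 0.05, window_cm = 10,
                                 use_cofactors = TRUE), qtl),
    deg = utils::modifyList(list(dispersion = 0.1, lfc_cut = 1, fdr_cut = 0.05,
                                 delta_thresh = 1), deg),
    coloc = utils::modifyList(list(rule = "overlap"), coloc))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' The configuration round-trips losslessly: \code{readPipelineConfig}
#' rebuilds the \code{sim_config} and \code{pipeline_config} classes.
#'
#' @param config a \code{pipeline_config}.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$synth)) {
    cfg$synth <- unclass(cfg$synth)
    if (!is.null(cfg$synth$qtl_spec))
      cfg$synth$qtl_spec <- as.list(cfg$synth$qtl_spec)
  }
  cfg$condition_map <- as.list(cfg$condition_map)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  synth <- cfg$synth
  if (!is.null(synth)) {
    if (!is.null(synth$qtl_spec))
      synth$qtl_spec <- as.data.frame(synth$qtl_spec)
    keep <- intersect(names(synth), names(formals(simConfig)))
    synth <- do.call(simConfig, synth[keep])
  }
  pipelineConfig(out_dir = cfg$out_dir, seed = cfg$seed, synth = synth,
                 inputs = cfg$inputs,
                 condition_map = unlist(cfg$condition_map),
                 binmap = cfg$binmap, qtl = cfg$qtl, deg = cfg$deg,
                 coloc = cfg$coloc)
}

.stageLog <- function(report, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  report$log <- c(report$log, sprintf("[%s] %s", stage, msg))
  report
}

#' Run the full pipeline
#'
#' Executes the stages in order, persisting every intermediate under
#' \code{out_dir} and returning (and writing) a run report that contains the
#' stage parameters, the map summary, variance components and heritability,
#' the QTL and stable-region tables, DEG class counts, the candidate list,
#' and — when synthetic truth is available — truth-recovery metrics (QTL
#' localization distance and planted-DEG recall). Two runs from the same
#' configuration produce byte-identical reports.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return the run report (list), invisibly written to
#'   \code{out_dir/report.json}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = list(
    seed = config$seed, binmap = config$binmap, qtl = config$qtl,
    deg = config$deg, coloc = config$coloc,
    condition_map = as.list(config$condition_map),
    synth = if (!is.null(config$synth)) {
      s <- unclass(config$synth)
      if (!is.null(s$qtl_spec)) s$qtl_spec <- as.list(s$qtl_spec)
      s
    }), log = character(0))

  ## -- stage 1: inputs --------------------------------------------------
  truth <- NULL
  if (!is.null(config$synth)) {
    study <- simulateStudy(config$synth, file.path(out, "inputs"))
    snps <- study$snps
    phen <- study$phenotypes
    counts <- study$expression$counts
    genes <- study$expression$genes
    truth <- study$truth
    report <- .stageLog(report, "inputs",
                        "synthetic study: %d lines, %d SNPs, %d genes",
                        nrow(snpCalls(snps)), ncol(snpCalls(snps)),
                        nrow(counts))
  } else {
    if (is.null(config$inputs$genotypes) || is.null(config$inputs$phenotypes))
      stop("inputs stage failed: need genotype and phenotype files (or a synth block)")
    snps <- readGenotypesTsv(config$inputs$genotypes)
    phen <- readPhenotypeCsv(config$inputs$phenotypes)
    counts <- genes <- NULL
    if (!is.null(config$inputs$counts)) {
      ct <- readCountsTsv(config$inputs$counts)
      counts <- ct$counts
      genes <- if (!is.null(config$inputs$gff))
        readAnnotation(config$inputs$gff) else ct$genes
    }
    report <- .stageLog(report, "inputs", "read %d lines x %d SNP sites",
                        nrow(snpCalls(snps)), ncol(snpCalls(snps)))
  }

  ## -- stage 2: bin map -------------------------------------------------
  bm <- tryCatch(
    do.call(buildBinMap, c(list(snps = snps), config$binmap)),
    error = function(e) stop("binmap stage failed: ", conditionMessage(e)))
  writeBinMapFiles(bm, file.path(out, "binmap"))
  report$map_summary <- mapSummary(bm)
  report <- .stageLog(report, "binmap", "%d bins (%d mapped), %.1f cM",
                      length(binRanges(bm)),
                      sum(mcols(binRanges(bm))$mapped),
                      report$map_summary$lg_length_cm[nrow(report$map_summary)])

  ## -- stage 3: phenotype model -----------------------------------------
  fit <- tryCatch(fitBlup(phen),
                  error = function(e) stop("phenostats stage failed: ",
                                           conditionMessage(e)))
  h2 <- heritability(fit$varcomp)
  write.csv(data.frame(line = names(fit$blup), blup = fit$blup),
            file.path(out, "blup.csv"), row.names = FALSE)
  jsonlite::write_json(c(varianceComponents(fit$varcomp),
                         list(heritability_pct = h2)),
                       file.path(out, "varcomp.json"), auto_unbox = TRUE,
                       digits = NA)
  report$varcomp <- varianceComponents(fit$varcomp)
  report$heritability_pct <- h2
  report <- .stageLog(report, "phenostats", "H2 = %.1f%%", h2)

  ## -- stage 4: QTL scans per condition ---------------------------------
  traits <- list(BLUP = fit$blup)
  for (e in names(config$condition_map))
    traits[[config$condition_map[[e]]]] <- lineMeans(phen, env = e)
  all_qtls <- NULL
  for (i in seq_along(traits)) {
    cond <- names(traits)[i]
    res <- scanQtl(bm, traits[[cond]], trait_name = "SES", condition = cond,
                   n_perm = config$qtl$n_perm, alpha = config$qtl$alpha,
                   seed = .stageSeed(config$seed, 10L + i),
                   window_cm = config$qtl$window_cm,
                   use_cofactors = config$qtl$use_cofactors)
    write.csv(scanProfile(res$scan),
              file.path(out, sprintf("scan_%s.csv", cond)), row.names = FALSE)
    all_qtls <- rbind(all_qtls, res$qtls)
    report <- .stageLog(report, "qtlscan", "%s: threshold %.2f, %d QTL(s)",
                        cond, res$threshold, nrow(res$qtls))
  }
  report$qtls <- all_qtls
  if (!is.null(all_qtls) && nrow(all_qtls)) {
    write.csv(all_qtls, file.path(out, "qtls.csv"), row.names = FALSE)
  }
  sr <- stableRegions(if (is.null(all_qtls)) data.frame() else all_qtls,
                      conditions = c(unname(config$condition_map), "BLUP"),
                      traits = "SES")
  report$stable_regions <- sr$regions
  write.csv(cbind(sr$regions,
                  as.data.frame(sr$detection * 1)),
            file.path(out, "stable_regions.csv"), row.names = FALSE)
  report <- .stageLog(report, "qtlscan", "%d region(s), %d stable",
                      nrow(sr$regions), sum(sr$regions$stable))

  ## -- stage 5/6: expression + colocalization ---------------------------
  if (is.null(counts)) {
    report <- .stageLog(report, "degclass",
                        "no counts supplied: expression stages skipped")
    report$candidates <- NULL
  } else {
    deg <- do.call(degAnalysis, c(list(counts = counts), config$deg))
    report$deg_class_counts <- list(
      parent = as.list(deg$parent$sets$counts),
      bulk = as.list(deg$bulk$sets$counts),
      shared_up = deg$shared$n_up, shared_down = deg$shared$n_down)
    write.csv(deg$parent$classified, file.path(out, "deg_parent.csv"),
              row.names = FALSE)
    write.csv(deg$bulk$classified, file.path(out, "deg_bulk.csv"),
              row.names = FALSE)
    writeLines(deg$shared$genes, file.path(out, "shared_degs.txt"))
    report <- .stageLog(report, "degclass",
                        "parent %d, bulk %d, shared %d salt-specific DEGs",
                        deg$parent$sets$total, deg$bulk$sets$total,
                        deg$shared$total)
    stable_only <- sr$regions[sr$regions$stable, , drop = FALSE]
    shared_df <- data.frame(gene = deg$shared$genes,
                            direction = c(rep("up", deg$shared$n_up),
                                          rep("down", deg$shared$n_down)))
    cands <- overlayCandidates(shared_df, genes, stable_only,
                               rule = config$coloc$rule)
    report$candidates <- cands
    report$per_region_counts <- perRegionCounts(cands, stable_only)
    write.csv(cands, file.path(out, "candidates.csv"), row.names = FALSE)
    report <- .stageLog(report, "colocalize", "%d candidate gene(s)",
                        nrow(cands))
  }

  ## -- truth recovery ----------------------------------------------------
  if (!is.null(truth) && !is.null(truth$qtl_spec) && nrow(truth$qtl_spec)) {
    report$recovery <- .truthRecovery(truth, bm, all_qtls, sr$regions,
                                      report$candidates, config)
    report <- .stageLog(report, "recovery",
                        "QTL localized (<= 5 cM): %d/%d; planted-DEG recall %.2f",
                        sum(report$recovery$qtl$localized_5cm),
                        nrow(report$recovery$qtl),
                        ifelse(is.null(report$recovery$deg_recall), NA,
                               report$recovery$deg_recall))
  }
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

## truth-recovery metrics: genetic distance from each planted QTL to the
## nearest significant peak (BLUP condition), stable-region coverage of the
## true position, and recall of planted shared in-QTL DEGs
.truthRecovery <- function(truth, bm, qtls, regions, candidates, config) {
  qs <- truth$qtl_spec
  gr <- binRanges(bm)
  chr <- as.character(seqnames(gr))
  rows <- lapply(seq_len(nrow(qs)), function(q) {
    qchr <- sprintf("chr%02d", qs$chrom[q])
    i <- which(chr == qchr & start(gr) <= qs$pos_bp[q] & end(gr) >= qs$pos_bp[q])
    true_cm <- if (length(i)) mcols(gr)$cm[i[1]] else NA_real_
    peaks <- qtls[qtls$condition == "BLUP" & qtls$chrom == qchr, , drop = FALSE]
    dist_cm <- if (nrow(peaks) && is.finite(true_cm))
      min(abs(peaks$peak_cm - true_cm)) else NA_real_
    stable <- regions[regions$stable & regions$chrom == qchr, , drop = FALSE]
    covered <- any(stable$bp_start <= qs$pos_bp[q] & stable$bp_end >= qs$pos_bp[q])
    data.frame(chrom = qchr, pos_bp = qs$pos_bp[q], true_cm = true_cm,
               nearest_peak_cm = dist_cm,
               localized_5cm = is.finite(dist_cm) && dist_cm <= 5,
               in_stable_region = covered)
  })
  qtl_rec <- do.call(rbind, rows)
  deg_recall <- NULL
  if (!is.null(truth$deg_truth) && !is.null(candidates)) {
    planted <- truth$deg_truth
    target <- planted$gene_id[planted$shared & planted$in_qtl]
    if (length(target))
      deg_recall <- mean(target %in% candidates$gene)
  }
  list(qtl = qtl_rec, deg_recall = deg_recall)
}
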