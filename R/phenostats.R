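## Phenotype statistics: plot-level SES scores, the multi-environment
## random-effects model (variance components + line BLUPs), broad-sense
## heritability, descriptive statistics and trait correlations.

#' Plot-level standard evaluation score from per-level injury counts
#'
#' SES = sum(number of salt-injured plants at each level x level score) /
#' total number of plants scored. Levels default to the 1/3/5/7/9 injury
#' grades (1 = tolerant ... 9 = sensitive).
#'
#' @param counts non-negative counts of plants per level.
#' @param levels score attached to each level (same length as counts).
#' @return plot SES, a weighted mean in [min(levels), max(levels)].
#' @export
plotSes <- function(counts, levels = c(1, 3, 5, 7, 9)) {
  stopifnot(length(counts) == length(levels))
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("no plants scored")
  sum(counts * levels) / total
}

#' Fit the multi-environment random-effects model for line BLUPs
#'
#' Fits \eqn{Y_{ijk} = \mu + L_k + E_i + R(E)_{ij} + (L\times E)_{ik} + e_{ijk}}
#' with every factor random, by REML (\pkg{lme4}). The environment index is
#' whichever grouping column is supplied, so environment-by-year combinations
#' or plain environments can play the role of E.
#'
#' @param phen data.frame of phenotype records.
#' @param value,line,env,rep column names (defaults \code{"value"},
#'   \code{"line"}, \code{"env_year"}, \code{"rep"}).
#' @return list with \code{varcomp} (a \code{\linkS4class{VarianceComponents}}),
#'   \code{blup} (named per-line BLUP of the line effect, on the trait scale,
#'   centered at 0), \code{grand_mean}, and the fitted \code{model}.
#' @export
## tight optimizer settings so balanced-design REML matches the analytic
## ANOVA moment estimators to ~1e-6 absolute
.blupControl <- function() {
  lme4::lmerControl(optimizer = "bobyqa",
                    optCtrl = list(rhobeg = 0.2, rhoend = 1e-13),
                    check.conv.singular = "ignore")
}

fitBlup <- function(phen, value = "value", line = "line", env = "env_year",
                    rep = "rep") {
  stopifnot(all(c(value, line, env, rep) %in% names(phen)))
  d <- data.frame(y = phen[[value]], line = factor(phen[[line]]),
                  env = factor(phen[[env]]),
                  rep = factor(phen[[rep]]))
  if (nlevels(d$line) < 10) stop("need at least 10 lines")
  ## degenerate noise-free case: y depends on the line alone. REML is
  ## ill-posed there (flat deviance in the zero-variance components); the
  ## exact answer is unshrunken line deviations.
  within_var <- tapply(d$y, d$line, var)
  if (all(is.na(within_var) | within_var < 1e-12) &&
      var(tapply(d$y, d$line, mean)) > 0) {
    m <- tapply(d$y, d$line, mean)
    gm <- mean(d$y)
    vcomp <- new("VarianceComponents", sigma_g2 = var(as.numeric(m)),
                 sigma_ge2 = 0, sigma_e2 = 0, sigma_r2 = 0,
                 n_env = nlevels(d$env),
                 n_reps = nrow(d) / (nlevels(d$line) * nlevels(d$env)),
                 truncated = character(0))
    return(list(varcomp = vcomp, blup = setNames(as.numeric(m) - gm, names(m)),
                grand_mean = gm, model = NULL))
  }
  if (nlevels(d$env) < 2) {
    warning("fewer than 2 environments: sigma_ge2 fixed at 0")
    fit <- lme4::lmer(y ~ (1 | line), data = d,
                      control = .blupControl())
  } else {
    fit <- lme4::lmer(y ~ (1 | line) + (1 | env) + (1 | env:rep) + (1 | line:env),
                      data = d,
                      control = .blupControl())
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  n_env <- nlevels(d$env)
  n_reps <- nrow(d) / (nlevels(d$line) * n_env)
  vcomp <- new("VarianceComponents",
               sigma_g2 = comp("line"),
               sigma_ge2 = comp("line:env"),
               sigma_e2 = comp("Residual"),
               sigma_r2 = comp("env:rep"),
               n_env = n_env, n_reps = n_reps, truncated = character(0))
  re <- lme4::ranef(fit)$line
  blup <- setNames(re[, 1], rownames(re))
  list(varcomp = vcomp, blup = blup,
       grand_mean = as.numeric(lme4::fixef(fit)[1]), model = fit)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{H^2(\%) = \sigma_g^2 / (\sigma_g^2 + \sigma_{ge}^2/n + \sigma_e^2/(nr))
#'   \times 100}
#' where n is the number of environments and r the replicates per environment.
#'
#' @param vc a \code{\linkS4class{VarianceComponents}}, or a named list with
#'   \code{sigma_g2}, \code{sigma_ge2}, \code{sigma_e2}, \code{n_env},
#'   \code{n_reps}.
#' @param n_env,n_reps optional overrides of the design constants.
#' @return heritability in percent.
#' @export
heritability <- function(vc, n_env = NULL, n_reps = NULL) {
  if (is(vc, "VarianceComponents")) vc <- varianceComponents(vc)
  n <- if (is.null(n_env)) vc$n_env else n_env
  r <- if (is.null(n_reps)) vc$n_reps else n_reps
  stopifnot(n >= 1, r >= 1)
  denom <- vc$sigma_g2 + vc$sigma_ge2 / n + vc$sigma_e2 / (n * r)
  if (denom <= 0) stop("heritability undefined: all variance components zero")
  100 * vc$sigma_g2 / denom
}

#' Descriptive statistics of a trait vector
#'
#' @param values numeric vector (>= 3 finite values).
#' @return one-row data.frame: mean, sd (sample), min, max, cv_pct
#'   (sd/mean x 100, NA with a warning if the mean is 0), skewness and excess
#'   kurtosis by moment estimators.
#' @export
descriptiveStats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 values")
  m <- mean(values); s <- sd(values)
  cv <- if (abs(m) < .Machine$double.eps^0.5) {
    warning("zero mean: CV undefined"); NA_real_
  } else 100 * s / m
  ctr <- values - m
  m2 <- mean(ctr^2)
  skew <- if (m2 > 0) mean(ctr^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(ctr^4) / m2^2 - 3 else 0
  data.frame(mean = m, sd = s, min = min(values), max = max(values),
             cv_pct = cv, skewness = skew, excess_kurtosis = kurt)
}

#' Pairwise Pearson correlations with significance stars
#'
#' @param mat numeric matrix or data.frame, lines in rows, traits/conditions
#'   in columns; pairwise complete observations are used.
#' @return list of matrices: \code{r} (Pearson correlations), \code{p}
#'   (two-sided p-values) and \code{stars} ("***" p < 0.001, "**" p < 0.01,
#'   "*" p < 0.05, "" otherwise). Pairs with fewer than 3 shared lines get NA.
#' @export
traitCorrelations <- function(mat) {
  mat <- as.matrix(mat)
  k <- ncol(mat)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(mat), colnames(mat)))
  stars <- matrix("", k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- is.finite(mat[, i]) & is.finite(mat[, j])
    if (sum(ok) < 3) next
    ct <- cor.test(mat[ok, i], mat[ok, j])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- if (i == j) NA else ct$p.value
    stars[i, j] <- if (i == j) "" else
      if (ct$p.value < 0.001) "***" else if (ct$p.value < 0.01) "**" else
      if (ct$p.value < 0.05) "*" else ""
  }
  list(r = r, p = p, stars = stars)
}

#' Per-line trait means, optionally restricted to one environment
#'
#' @param phen phenotype data.frame.
#' @param env optional value of \code{env_col} to subset on.
#' @param value,line,env_col column names.
#' @return named numeric vector of line means.
#' @export
lineMeans <- function(phen, env = NULL, value = "value", line = "line",
                      env_col = "env") {
  if (!is.null(env)) phen <- phen[phen[[env_col]] == env, , drop = FALSE]
  out <- tapply(phen[[value]], phen[[line]], mean)
  setNames(as.numeric(out), names(out))
}
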