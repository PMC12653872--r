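#' Fisher's method for combining p-values
#'
#' \eqn{\chi^2 = -2 \sum_i \ln p_i}, referred to a chi-square distribution
#' with 2k degrees of freedom (k = number of studies).  For k = 2 the
#' combined p has the closed form \eqn{e^{-x/2}(1 + x/2)}.
#'
#' @param p_values numeric vector of p-values in (0, 1]; zeros are clamped
#'   to the smallest positive double with a warning (permutation p-values
#'   can be exactly 0 at finite permutation depth).
#' @return list with `chisq` and `p` (combined p-value).
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) < 1L) stop("need at least one p-value")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("p-value of 0 clamped to the smallest positive double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  chisq <- -2 * sum(log(p_values))
  list(chisq = chisq,
       p = pchisq(chisq, df = 2 * length(p_values), lower.tail = FALSE))
}

## vectorized k=2 variant for tables
fisher_combine2 <- function(p1, p2) {
  p1 <- pmax(p1, .Machine$double.xmin)
  p2 <- pmax(p2, .Machine$double.xmin)
  chisq <- -2 * (log(p1) + log(p2))
  list(chisq = chisq, p = pchisq(chisq, df = 4, lower.tail = FALSE))
}

#' Consensus master regulators across two cohorts
#'
#' For every regulator scored in both cohorts, combines the activity
#' p-values by Fisher's method, BH-adjusts across the tested regulators,
#' and attaches the mean NES and sign concordance.  Concordance is recorded
#' but never used as a filter; the consensus call is FDR < `alpha` alone.
#'
#' @param act_a,act_b `tmr_activity` tables from [score_activity()].
#' @param alpha consensus FDR level (default 0.05).
#' @return a `data.frame` of class `tmr_meta_regulators` with columns
#'   `regulator`, `p_a`, `p_b`, `chisq`, `p_meta`, `fdr`, `nes_a`, `nes_b`,
#'   `mean_nes`, `concordant`, `strong_mean_nes` (|mean NES| > 1, reporting
#'   only) and `consensus`.
#' @export
consensus_tmrs <- function(act_a, act_b, alpha = 0.05) {
  shared <- intersect(act_a$regulator, act_b$regulator)
  if (length(shared) == 0L) stop("no regulator scored in both cohorts")
  a <- act_a[match(shared, act_a$regulator), ]
  b <- act_b[match(shared, act_b$regulator), ]
  fc <- fisher_combine2(a$p, b$p)
  fdr <- bh_adjust(fc$p)
  res <- data.frame(
    regulator = shared, p_a = a$p, p_b = b$p,
    chisq = fc$chisq, p_meta = fc$p, fdr = fdr,
    nes_a = a$nes, nes_b = b$nes,
    mean_nes = (a$nes + b$nes) / 2,
    concordant = sign(a$nes) == sign(b$nes),
    strong_mean_nes = abs((a$nes + b$nes) / 2) > 1,
    consensus = fdr < alpha,
    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$fdr, res$p_meta), ]
  rownames(res) <- NULL
  class(res) <- c("tmr_meta_regulators", "data.frame")
  res
}

#' Fixed-effect inverse-variance-weighted meta-analysis of logFC
#'
#' Pools per-gene log2 fold changes across the two cohorts with weights
#' \eqn{w_i = 1/SE_i^2}: \eqn{\hat\beta_{meta} = \sum_i w_i \beta_i /
#' \sum_i w_i}, pooled SE \eqn{1/\sqrt{\sum_i w_i}},
#' \eqn{Z = \hat\beta_{meta} \sqrt{\sum_i w_i}}, two-sided normal p, BH
#' FDR, and a direction-concordance flag (same sign of the per-cohort
#' logFC).  Genes absent from either cohort, or with a non-positive SE, are
#' excluded and counted in attribute `n_dropped`.
#'
#' @param de_a,de_b `tmr_de` tables for the two cohorts.
#' @return a `data.frame` of class `tmr_effect_meta` with columns `gene`,
#'   `beta_a`, `beta_b`, `se_a`, `se_b`, `beta_meta`, `se_meta`, `z`, `p`,
#'   `fdr`, `concordant`.
#' @export
ivw_meta <- function(de_a, de_b) {
  shared <- intersect(de_a$gene, de_b$gene)
  n_dropped <- length(union(de_a$gene, de_b$gene)) - length(shared)
  a <- de_a[match(shared, de_a$gene), ]
  b <- de_b[match(shared, de_b$gene), ]
  ok <- is.finite(a$se) & is.finite(b$se) & a$se > 0 & b$se > 0
  n_dropped <- n_dropped + sum(!ok)
  a <- a[ok, ]; b <- b[ok, ]
  wa <- 1 / a$se^2; wb <- 1 / b$se^2
  sw <- wa + wb
  beta <- (wa * a$logFC + wb * b$logFC) / sw
  se <- 1 / sqrt(sw)
  z <- beta * sqrt(sw)
  p <- 2 * pnorm(-abs(z))
  res <- data.frame(
    gene = a$gene, beta_a = a$logFC, beta_b = b$logFC,
    se_a = a$se, se_b = b$se,
    beta_meta = beta, se_meta = se, z = z, p = p, fdr = bh_adjust(p),
    concordant = sign(a$logFC) == sign(b$logFC),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "n_dropped") <- n_dropped
  class(res) <- c("tmr_effect_meta", "data.frame")
  res
}
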