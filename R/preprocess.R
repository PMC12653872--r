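#' Filter a counts cohort by detection rate
#'
#' Retains a gene iff it has at least 10 reads in more than 80% of samples
#' (strict inequality: 4 of 5 samples does not qualify).
#'
#' @param mat a counts [expression_matrix()].
#' @param min_count minimum read count (default 10).
#' @param min_fraction detection fraction that must be exceeded (default 0.8).
#' @return the filtered [expression_matrix()].
#' @export
filter_counts <- function(mat, min_count = 10, min_fraction = 0.8) {
  stopifnot(inherits(mat, "tmr_expr"))
  if (mat$platform != "counts") stop("filter_counts expects a counts cohort")
  frac <- rowMeans(mat$values >= min_count)
  keep <- frac > min_fraction
  if (!any(keep))
    stop("no gene passes the detection filter; review min_count/min_fraction")
  expression_matrix(mat$values[keep, , drop = FALSE], mat$groups, "counts")
}

#' TMM-normalize counts and transform to log2 CPM
#'
#' Computes trimmed-mean-of-M-values scaling factors (via
#' \code{edgeR::calcNormFactors}: reference sample chosen by 75th-percentile
#' count fraction closest to the mean, 30% trim on M, 5% on A,
#' inverse-variance weighting; factors normalized to geometric mean 1), then
#' returns \code{log2(CPM + 0.5)} on the effective (TMM-scaled) library
#' sizes.  Factors are attached as attribute \code{"norm_factors"} for audit.
#'
#' @param mat a filtered counts [expression_matrix()].
#' @param prior_count offset added to CPM before the log (default 0.5).
#' @return a log-scale [expression_matrix()] with platform `"logcpm"`.
#' @export
normalize_counts <- function(mat, prior_count = 0.5) {
  stopifnot(inherits(mat, "tmr_expr"))
  if (mat$platform != "counts")
    stop("normalize_counts expects a counts cohort")
  lib <- colSums(mat$values)
  if (any(lib == 0)) stop("sample with zero library size")
  f <- edgeR::calcNormFactors(mat$values, method = "TMM")
  eff <- lib * f
  cpm <- sweep(mat$values, 2, eff / 1e6, "/")
  out <- expression_matrix(log2(cpm + prior_count), mat$groups, "logcpm")
  attr(out, "norm_factors") <- setNames(f, mat$samples)
  out
}

#' Filter an intensity cohort by abundance and variability
#'
#' Removes genes with mean log2 intensity <= 4, then drops the bottom 25%
#' of the remaining genes by variance.  The variance cut is the linearly
#' interpolated quantile; genes tied with the cut value are retained.
#'
#' @param mat an intensity [expression_matrix()] (already log2 scale).
#' @param min_mean abundance floor on the log2 scale (default 4).
#' @param var_quantile fraction of low-variance genes to drop (default 0.25).
#' @return the filtered [expression_matrix()].
#' @export
filter_intensity <- function(mat, min_mean = 4, var_quantile = 0.25) {
  stopifnot(inherits(mat, "tmr_expr"))
  if (!mat$platform %in% c("intensity", "logcpm"))
    stop("filter_intensity expects a log-scale cohort")
  keep1 <- rowMeans(mat$values) > min_mean
  v <- apply(mat$values[keep1, , drop = FALSE], 1, var)
  if (length(v) == 0L) stop("no gene passes the abundance filter")
  cut <- quantile_lin(v, var_quantile)
  keep2 <- names(v)[v >= cut]
  if (length(keep2) == 0L) stop("no gene passes the variance filter")
  expression_matrix(mat$values[keep2, , drop = FALSE], mat$groups,
                    mat$platform)
}

#' Moderated two-group differential expression
#'
#' Fits a gene-wise tumor-versus-normal contrast on log2-scale data with
#' empirical-Bayes variance shrinkage: the pooled per-gene variance s^2 (d
#' residual df) is shrunk toward a common prior (d0, s0^2), fit by method of
#' moments on the per-gene variances under the scaled-F marginal
#' \eqn{s^2/s_0^2 \sim F(d, d_0)}.  The moderated statistic
#' \eqn{t = logFC / \sqrt{\tilde s^2 (1/n_1 + 1/n_2)}} with
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)} is referred to a t
#' distribution on d0 + d df.  Standard errors satisfy SE * t = logFC
#' wherever t is nonzero.
#'
#' @param mat a log2-scale [expression_matrix()] with both groups present.
#' @param fdr_cut,lfc_cut significance thresholds: a gene is flagged iff
#'   FDR < `fdr_cut` and |logFC| >= `lfc_cut` (defaults 0.05 and 1).
#' @return a `data.frame` of class `tmr_de` with columns `gene`, `logFC`
#'   (log2 units, tumor - normal), `t`, `p`, `fdr`, `se`, `significant`;
#'   the fitted prior is attached as attributes `d0` and `s02`.
#' @export
differential_expression <- function(mat, fdr_cut = 0.05, lfc_cut = 1) {
  stopifnot(inherits(mat, "tmr_expr"))
  if (mat$platform == "counts")
    stop("differential_expression expects log2-scale data; normalize first")
  tum <- mat$groups == "tumor"
  nor <- mat$groups == "normal"
  n1 <- sum(tum); n2 <- sum(nor)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")

  st <- mod_t_stats(mat$values, mat$values^2, tum, nor)
  if (st$all_zero_var)
    warning("zero within-group variance everywhere; ",
            "falling back to ordinary pooled-variance t")
  logFC <- st$logFC; t <- st$t; se <- st$se
  d0 <- st$d0; s02 <- st$s02
  p <- 2 * pt(-abs(t), df = st$df)
  p[is.nan(p)] <- 1      # t = 0/0 degenerate rows
  fdr <- bh_adjust(p)
  res <- data.frame(gene = mat$genes, logFC = logFC, t = t, p = p,
                    fdr = fdr, se = se,
                    significant = fdr < fdr_cut & abs(logFC) >= lfc_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  class(res) <- c("tmr_de", "data.frame")
  res
}

## Moderated-t core shared by differential_expression() and the
## sample-permutation activity null.  `x2 = x^2` is passed in so repeated
## calls under label permutation avoid re-squaring the matrix.
mod_t_stats <- function(x, x2, tum, nor) {
  n1 <- sum(tum); n2 <- sum(nor)
  s1 <- rowSums(x[, tum, drop = FALSE])
  s2_ <- rowSums(x[, nor, drop = FALSE])
  q1 <- rowSums(x2[, tum, drop = FALSE])
  q2 <- rowSums(x2[, nor, drop = FALSE])
  m1 <- s1 / n1; m2 <- s2_ / n2
  v1 <- pmax(0, (q1 - n1 * m1^2) / (n1 - 1))
  v2 <- pmax(0, (q2 - n2 * m2^2) / (n2 - 1))
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  logFC <- m1 - m2
  prior <- fit_variance_prior(s2, d)
  d0 <- prior$d0; s02 <- prior$s02
  all_zero <- all(s2 == 0)
  if (all_zero) {
    s2t <- s2; df <- d
  } else if (is.infinite(d0)) {
    s2t <- rep(s02, length(s2)); df <- Inf
  } else {
    s2t <- (d0 * s02 + d * s2) / (d0 + d); df <- d0 + d
  }
  se <- sqrt(s2t * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, logFC / se, ifelse(logFC == 0, 0, Inf * sign(logFC)))
  list(logFC = logFC, t = t, se = se, df = df, d0 = d0, s02 = s02,
       all_zero_var = all_zero)
}

## Method-of-moments fit of the variance prior (d0, s02) under
## s^2 / s0^2 ~ F(d, d0):  E[s^2] = s0^2 d0/(d0-2),
## Var[s^2]/E[s^2]^2 = 2 (d + d0 - 2) / (d (d0 - 4)).
fit_variance_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2)]
  m <- mean(s2)
  v <- var(s2)
  if (!is.finite(v) || v <= 0 || m <= 0)
    return(list(d0 = Inf, s02 = max(m, .Machine$double.eps)))
  cv2 <- v / m^2
  denom <- cv2 * d - 2
  if (denom <= 0) return(list(d0 = Inf, s02 = m))
  d0 <- (2 * d - 4 + 4 * cv2 * d) / denom
  if (!is.finite(d0) || d0 <= 0) return(list(d0 = Inf, s02 = m))
  s02 <- if (d0 > 2) m * (d0 - 2) / d0 else m
  list(d0 = d0, s02 = s02)
}

#' Write / read a differential-expression table
#'
#' TSV with columns `gene, logFC, t, p, fdr, se, significant`.
#'
#' @param de a `tmr_de` table.
#' @param path file path.
#' @return `write_de` invisibly returns `path`; `read_de` the table.
#' @export
write_de <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de
#' @export
read_de <- function(path) {
  res <- read.delim(path, stringsAsFactors = FALSE)
  class(res) <- c("tmr_de", "data.frame")
  res
}
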