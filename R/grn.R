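#' Adaptive-partitioning mutual information
#'
#' Estimates MI (nats) between two sample vectors by the adaptive-
#' partitioning scheme: both vectors are copula-transformed to (0,1) by
#' rank/(n+1), and the unit square is recursively split into four
#' equal-area quadrants at the midpoint of the current cell while the
#' chi-square statistic of the quadrant occupancy exceeds `chi2_crit`
#' (default 7.815, df = 3 at alpha = 0.05) and the cell holds at least
#' `min_cell` points.  MI is summed over leaves as
#' \eqn{(n_c/N)\,\ln((n_c/N)/area_c)}.  The estimator is symmetric and,
#' through the rank step, invariant under strictly monotone transforms of
#' either argument.  Ties are broken by random ranks, reproducible under the
#' caller's RNG state.
#'
#' @param x,y numeric vectors of equal length (n >= 8).
#' @param chi2_crit recursion threshold for the quadrant chi-square.
#' @param min_cell minimum points in a cell eligible for splitting.
#' @return MI estimate in nats (non-negative up to estimator bias).
#' @export
mutual_information <- function(x, y, chi2_crit = 7.815, min_cell = 8L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 8L) stop("need at least 8 paired samples")
  u <- rank(x, ties.method = "random") / (n + 1)
  v <- rank(y, ties.method = "random") / (n + 1)
  mi_ap_cpp(u, v, chi2_crit, min_cell)
}

## copula-transform every row of a matrix; ties broken randomly under the
## current RNG state
copula_rows <- function(m) {
  n <- ncol(m)
  t(apply(m, 1, function(r) rank(r, ties.method = "random"))) / (n + 1)
}

#' Calibrate the MI significance threshold
#'
#' Draws `n_null` MI values between independent rank permutations at sample
#' size `n_samples` (the copula step makes the null depend on n only) and
#' returns the MI value exceeded with probability `p_cutoff` under
#' independence.  For p_cutoff * n_null >= 10 the empirical
#' (1 - p_cutoff) quantile is used; deeper tails are extrapolated from an
#' exponential fit to the top 1% of the null
#' (\eqn{\ln S(mi) \approx a - b\,mi}).
#'
#' @param n_samples sample size of the cohort the threshold is for.
#' @param p_cutoff tail probability (e.g. 1e-4 for a small cohort, 1e-8 for
#'   a large one).
#' @param n_null null sample size (>= 1e4 recommended for tail fits).
#' @param seed RNG seed.
#' @param bootstrap when `TRUE`, the null mirrors the bootstrap
#'   resampling used during network consolidation: each null pair shares a
#'   with-replacement index draw (independent values), so the duplicate
#'   ties that inflate the MI of resampled data are present in the null
#'   too.  Use `FALSE` (default) for thresholds applied to un-resampled
#'   data.
#' @param chi2_crit,min_cell passed to the MI estimator.
#' @return an object of class `tmr_mi_threshold` with fields `threshold`
#'   (nats), `p_cutoff`, `n_null`, `n_samples` and the tail-fit
#'   coefficients `fit = c(a, b)`.
#' @export
calibrate_threshold <- function(n_samples, p_cutoff, n_null = 1e4,
                                seed = 1L, bootstrap = FALSE,
                                chi2_crit = 7.815, min_cell = 8L) {
  stopifnot(p_cutoff > 0, p_cutoff < 1, n_samples >= 8)
  null <- with_seed(seed, {
    if (bootstrap) {
      n <- as.integer(n_samples)
      vapply(seq_len(n_null), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        a <- runif(n)[idx]
        y <- runif(n)[idx]
        mi_ap_cpp(rank(a, ties.method = "random") / (n + 1),
                  rank(y, ties.method = "random") / (n + 1),
                  chi2_crit, min_cell)
      }, numeric(1))
    } else {
      mi_null_cpp(as.integer(n_samples), as.integer(n_null),
                  chi2_crit, min_cell)
    }
  })
  if (max(null) == min(null))
    stop("degenerate MI null (all values equal)")
  srt <- sort(null, decreasing = TRUE)
  k <- max(ceiling(0.01 * n_null), 50L)
  k <- min(k, length(srt))
  surv <- seq_len(k) / n_null
  fit <- lm(log(surv) ~ srt[seq_len(k)])
  a <- coef(fit)[[1]]; b <- -coef(fit)[[2]]
  if (p_cutoff * n_null >= 10) {
    thr <- quantile_lin(null, 1 - p_cutoff)
    ## the estimator has an atom at 0 (cells that never split); a lenient
    ## cutoff can land on it -- floor at the smallest positive null value
    ## to honor the threshold > 0 invariant
    if (thr <= 0) thr <- min(null[null > 0])
  } else {
    if (b <= 0) stop("exponential tail fit failed (non-positive rate)")
    thr <- (a - log(p_cutoff)) / b
  }
  structure(list(threshold = as.numeric(thr), p_cutoff = p_cutoff,
                 n_null = n_null, n_samples = n_samples,
                 fit = c(a = a, b = b)),
            class = "tmr_mi_threshold")
}

#' @export
print.tmr_mi_threshold <- function(x, ...) {
  cat(sprintf(
    "<tmr_mi_threshold> MI >= %.4f nats at p = %g (n = %d, null = %g)\n",
    x$threshold, x$p_cutoff, x$n_samples, x$n_null))
  invisible(x)
}

## Construct an MI network edge table
mi_network <- function(edges, regulators, p_cutoff = NA_real_,
                       n_boot = NA_integer_, threshold = NA_real_) {
  stopifnot(all(c("regulator", "target", "mi") %in% names(edges)))
  if (!"support" %in% names(edges)) edges$support <- NA_integer_
  edges <- edges[edges$regulator != edges$target, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, regulators = regulators,
                 p_cutoff = p_cutoff, n_boot = n_boot,
                 threshold = threshold),
            class = "tmr_mi_network")
}

#' @export
print.tmr_mi_network <- function(x, ...) {
  cat(sprintf("<tmr_mi_network> %d edges, %d regulators (p_cutoff = %g, %s bootstraps)\n",
              nrow(x$edges), length(x$regulators), x$p_cutoff,
              ifelse(is.na(x$n_boot), "no", x$n_boot)))
  invisible(x)
}

#' Data-processing-inequality pruning
#'
#' For every fully connected triple of nodes the edge with the smallest MI
#' is removed (tolerance 0; ties keep all tied edges).  Regulator-target
#' direction is ignored when detecting triangles; the surviving edge set is
#' always a subset of the input, and a second application changes nothing.
#'
#' @param net a `tmr_mi_network` (or a data.frame with columns
#'   `regulator`, `target`, `mi`).
#' @return the pruned network, same type as the input.
#' @export
apply_dpi <- function(net) {
  edges <- if (inherits(net, "tmr_mi_network")) net$edges else net
  if (nrow(edges) == 0L) return(net)
  nodes <- unique(c(edges$regulator, edges$target))
  idx <- setNames(seq_along(nodes), nodes)
  M <- matrix(NA_real_, length(nodes), length(nodes))
  i <- idx[edges$regulator]; j <- idx[edges$target]
  ## undirected MI lookup; duplicate orientations keep the larger MI
  M[cbind(i, j)] <- pmax(M[cbind(i, j)], edges$mi, na.rm = TRUE)
  M[cbind(j, i)] <- pmax(M[cbind(j, i)], edges$mi, na.rm = TRUE)
  drop <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    mij <- edges$mi[e]
    third <- which(M[i[e], ] > mij & M[j[e], ] > mij)
    if (length(third) > 0L) drop[e] <- TRUE
  }
  kept <- edges[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  if (inherits(net, "tmr_mi_network")) {
    net$edges <- kept
    net
  } else kept
}

## One network reconstruction on a (possibly resampled) matrix: all
## TF-vs-gene MI, thresholding, DPI.  `vals` is genes x samples on the log
## scale; consumes the current RNG (tie-breaking ranks).
infer_network_once <- function(vals, regulators, threshold,
                               chi2_crit = 7.815, min_cell = 8L) {
  U <- copula_rows(vals)
  genes <- rownames(vals)
  tgt_mat <- t(U)               # samples x genes for mi_batch
  out <- vector("list", length(regulators))
  for (k in seq_along(regulators)) {
    tf <- regulators[k]
    mi <- mi_batch_cpp(U[tf, ], tgt_mat, chi2_crit, min_cell)
    keep <- mi >= threshold & genes != tf
    if (any(keep))
      out[[k]] <- data.frame(regulator = tf, target = genes[keep],
                             mi = mi[keep], stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  if (is.null(edges))
    edges <- data.frame(regulator = character(), target = character(),
                        mi = numeric(), stringsAsFactors = FALSE)
  apply_dpi(edges)
}

#' Bootstrap-consolidated MI network
#'
#' Runs `n_boot` network reconstructions, each on a resample of the samples
#' with replacement (run i seeded from `seed + i`): adaptive-partitioning MI
#' of every regulator against every other gene, thresholding at the
#' permutation-calibrated MI cutoff for `p_cutoff`, then DPI pruning.  An
#' edge's support is the number of runs containing it; edges are retained
#' when an exact binomial test of the support against the mean per-run
#' edge-retention probability gives BH FDR < `support_fdr`.  The reported MI
#' is the mean over supporting runs.
#'
#' @param mat a log-scale [expression_matrix()].
#' @param regulators character vector of regulator gene ids (must be rows of
#'   `mat`).
#' @param p_cutoff significance level for the MI threshold.
#' @param n_boot number of bootstrap reconstructions (>= 2; 1 returns the
#'   single run with a warning).
#' @param seed master seed; run i uses `seed + i`.
#' @param n_null null size for threshold calibration.
#' @param support_fdr BH FDR level of the binomial support test.
#' @param threshold optional pre-calibrated `tmr_mi_threshold` to reuse.
#' @param chi2_crit,min_cell MI estimator settings.
#' @return a `tmr_mi_network` whose `edges` carry `regulator`, `target`,
#'   `mi` (mean over supporting runs) and `support`.
#' @export
consolidate_bootstraps <- function(mat, regulators, p_cutoff = 1e-4,
                                   n_boot = 50L, seed = 1L, n_null = 1e4,
                                   support_fdr = 0.05, threshold = NULL,
                                   chi2_crit = 7.815, min_cell = 8L) {
  stopifnot(inherits(mat, "tmr_expr"))
  if (mat$platform == "counts")
    stop("network inference expects log-scale expression; normalize first")
  regulators <- intersect(regulators, mat$genes)
  if (length(regulators) == 0L) stop("no regulator is present in the matrix")
  n <- ncol(mat$values)
  if (is.null(threshold))
    threshold <- calibrate_threshold(n, p_cutoff, n_null,
                                     seed = derive_seed(seed, 9001L),
                                     chi2_crit = chi2_crit,
                                     min_cell = min_cell)
  thr <- threshold$threshold

  if (n_boot < 2L) {
    warning("n_boot < 2: returning a single unconsolidated run")
    edges <- with_seed(derive_seed(seed, 1L),
      infer_network_once(mat$values, regulators, thr, chi2_crit, min_cell))
    edges$support <- 1L
    return(mi_network(edges, regulators, p_cutoff, 1L, thr))
  }

  counts <- new.env(hash = TRUE, parent = emptyenv())
  n_edges_run <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    run <- with_seed(derive_seed(seed, b), {
      cols <- sample.int(n, n, replace = TRUE)
      infer_network_once(mat$values[, cols, drop = FALSE], regulators, thr,
                         chi2_crit, min_cell)
    })
    n_edges_run[b] <- nrow(run)
    if (nrow(run) > 0L) {
      keys <- paste(run$regulator, run$target, sep = "\r")
      for (e in seq_len(nrow(run))) {
        prev <- counts[[keys[e]]]
        if (is.null(prev)) counts[[keys[e]]] <- c(1, run$mi[e])
        else counts[[keys[e]]] <- c(prev[1] + 1, prev[2] + run$mi[e])
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0L)
    return(mi_network(data.frame(regulator = character(),
                                 target = character(), mi = numeric(),
                                 support = integer()),
                      regulators, p_cutoff, n_boot, thr))
  supp <- vapply(keys, function(k) counts[[k]][1], numeric(1))
  mi_sum <- vapply(keys, function(k) counts[[k]][2], numeric(1))
  n_possible <- length(regulators) * (nrow(mat$values) - 1L)
  p0 <- mean(n_edges_run) / n_possible
  keep <- support_keep(supp, n_boot, p0, support_fdr)
  parts <- strsplit(keys[keep], "\r", fixed = TRUE)
  edges <- data.frame(
    regulator = vapply(parts, `[`, character(1), 1L),
    target = vapply(parts, `[`, character(1), 2L),
    mi = mi_sum[keep] / supp[keep],
    support = as.integer(supp[keep]),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  mi_network(edges, regulators, p_cutoff, as.integer(n_boot), thr)
}

## Bootstrap support rule: keep an edge when the exact binomial upper tail
## of its support against the mean per-run retention probability p0 clears
## BH FDR < fdr.
support_keep <- function(support, n_boot, p0, fdr = 0.05) {
  pval <- pbinom(support - 1, n_boot, p0, lower.tail = FALSE)
  bh_adjust(pval) < fdr
}

#' Write / read an MI network
#'
#' Four-column TSV: `regulator`, `target`, `mi` (nats), `support`.
#'
#' @param net a `tmr_mi_network`.
#' @param path file path.
#' @return `write_network` invisibly returns `path`; `read_network` the
#'   network object.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "tmr_mi_network"))
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @param regulators regulator list for the restored object (defaults to the
#'   regulators present in the edge file).
#' @export
read_network <- function(path, regulators = NULL) {
  edges <- read.delim(path, stringsAsFactors = FALSE)
  mi_network(edges, regulators %||% unique(edges$regulator))
}
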