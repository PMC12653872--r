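#' Distill signed, weighted regulons from an MI network
#'
#' One regulon per regulator with at least `min_size` targets.  The mode of
#' each interaction is the Spearman correlation between regulator and target
#' expression across all samples (sign-carrying, in [-1, 1]); the weight is
#' the edge MI rescaled so the strongest interaction in the regulon has
#' weight 1.
#'
#' @param net a `tmr_mi_network`.
#' @param mat the [expression_matrix()] the network was inferred from (log
#'   scale).
#' @param min_size minimum number of scorable targets (default 10).
#' @return a named list of `tmr_regulon` objects (fields `regulator`,
#'   `targets` with columns `target`, `mode`, `weight`).
#' @export
build_regulons <- function(net, mat, min_size = 10L) {
  stopifnot(inherits(net, "tmr_mi_network"), inherits(mat, "tmr_expr"))
  edges <- net$edges
  edges <- edges[edges$target %in% mat$genes, , drop = FALSE]
  out <- list()
  for (tf in unique(edges$regulator)) {
    if (!tf %in% mat$genes) {
      warning("regulator ", tf, " absent from the matrix; regulon skipped")
      next
    }
    sub <- edges[edges$regulator == tf, , drop = FALSE]
    if (nrow(sub) < min_size) next
    x <- mat$values[tf, ]
    modes <- vapply(sub$target, function(g)
      cor(x, mat$values[g, ], method = "spearman"), numeric(1))
    modes[is.na(modes)] <- 0
    modes <- pmin(1, pmax(-1, modes))
    out[[tf]] <- structure(
      list(regulator = tf,
           targets = data.frame(target = sub$target, mode = modes,
                                weight = sub$mi / max(sub$mi),
                                row.names = NULL,
                                stringsAsFactors = FALSE)),
      class = "tmr_regulon")
  }
  out
}

#' @export
print.tmr_regulon <- function(x, ...) {
  cat(sprintf("<tmr_regulon> %s: %d targets (%d activating)\n",
              x$regulator, nrow(x$targets), sum(x$targets$mode > 0)))
  invisible(x)
}

#' Score regulator activity against a differential-expression signature
#'
#' The signature value of gene g is the normal quantile of its moderated-t
#' rank, \eqn{q_g = \Phi^{-1}(rank(t_g)/(G+1))}.  The raw regulon score is
#' the weighted, mode-aligned mean \eqn{S = \sum_i w_i m_i q_{g_i} / \sum_i
#' w_i}.  Significance comes from a permutation null scored with the same
#' weights and modes; the normalized enrichment score is
#' \eqn{NES = (S - \mu_0)/\sigma_0} and the two-sided p-value the normal
#' tail of the NES.
#'
#' Two null models are available.  The default (`null = "sample"`) permutes
#' the tumor/normal labels, recomputes the moderated-t signature and
#' rescores the regulon; because a regulon's targets share their
#' regulator's activity, their signature values are correlated, and the
#' label-permutation null preserves that correlation, keeping the NES
#' calibrated.  `null = "geneset"` scores `n_perm` random gene sets of the
#' same size instead; it is cheaper but anti-conservative for co-regulated
#' regulons and is kept for diagnostics.
#'
#' @param regulons a list from [build_regulons()].
#' @param signature a `tmr_de` table covering the regulon targets.
#' @param n_perm number of permutations (>= 1000 recommended).
#' @param seed RNG seed; the same seed reproduces the NES to machine
#'   precision.
#' @param null null model, `"sample"` (default) or `"geneset"`.
#' @param mat the log-scale [expression_matrix()] the signature was
#'   computed from; required for the sample-permutation null.
#' @return a `data.frame` of class `tmr_activity` with columns `regulator`,
#'   `nes`, `p`, `size`.
#' @export
score_activity <- function(regulons, signature, n_perm = 1000L, seed = 1L,
                           null = c("sample", "geneset"), mat = NULL) {
  stopifnot(inherits(signature, "data.frame"))
  null <- match.arg(null)
  if (n_perm < 100L) stop("n_perm too small for a stable null")
  G <- nrow(signature)
  q <- qnorm(rank(signature$t, ties.method = "average") / (G + 1))
  names(q) <- signature$gene

  if (null == "sample") {
    if (is.null(mat) || !inherits(mat, "tmr_expr"))
      stop("the sample-permutation null needs the expression matrix ",
           "(`mat`) the signature came from")
    if (!all(signature$gene %in% mat$genes))
      stop("signature genes missing from `mat`")
    X <- mat$values[signature$gene, , drop = FALSE]
    X2 <- X^2
    tum <- mat$groups == "tumor"
    Q <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        ptum <- sample(tum)
        st <- mod_t_stats(X, X2, ptum, !ptum)
        qnorm(rank(st$t, ties.method = "average") / (G + 1))
      }, numeric(G))
    })
    rownames(Q) <- signature$gene
  }

  rows <- list()
  with_seed(derive_seed(seed, 13L), {
    for (tf in names(regulons)) {
      reg <- regulons[[tf]]
      tab <- reg$targets[reg$targets$target %in% names(q), , drop = FALSE]
      if (nrow(tab) == 0L) {
        warning("regulon ", tf, " has no target in the signature; dropped")
        next
      }
      w <- tab$weight; m <- tab$mode
      sw <- sum(w)
      S <- sum(w * m * q[tab$target]) / sw
      size <- nrow(tab)
      nullS <- if (null == "sample") {
        as.numeric(crossprod(Q[tab$target, , drop = FALSE], w * m)) / sw
      } else {
        vapply(seq_len(n_perm), function(b)
          sum(w * m * q[sample.int(G, size)]) / sw, numeric(1))
      }
      nes <- (S - mean(nullS)) / sd(nullS)
      rows[[tf]] <- data.frame(regulator = tf, nes = nes,
                               p = 2 * pnorm(-abs(nes)),
                               size = size, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(regulator = character(), nes = numeric(),
                      p = numeric(), size = integer())
  rownames(res) <- NULL
  class(res) <- c("tmr_activity", "data.frame")
  res
}

#' Write / read regulons
#'
#' Four-column TSV: `regulator`, `target`, `mode`, `weight`.
#'
#' @param regulons list from [build_regulons()].
#' @param path file path.
#' @return `write_regulons` invisibly returns `path`; `read_regulons` the
#'   regulon list.
#' @export
write_regulons <- function(regulons, path) {
  tab <- do.call(rbind, lapply(regulons, function(r)
    data.frame(regulator = r$regulator, r$targets,
               stringsAsFactors = FALSE)))
  if (is.null(tab))
    tab <- data.frame(regulator = character(), target = character(),
                      mode = numeric(), weight = numeric())
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regulons
#' @export
read_regulons <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$regulator), function(sub)
    structure(list(regulator = sub$regulator[1],
                   targets = data.frame(target = sub$target,
                                        mode = sub$mode,
                                        weight = sub$weight,
                                        row.names = NULL,
                                        stringsAsFactors = FALSE)),
              class = "tmr_regulon"))
  out[order(names(out))]
}
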