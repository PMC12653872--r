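#' Read / write gene-set collections (GMT)
#'
#' `read_gmt` parses a standard GMT file (set name, description, then
#' tab-separated gene ids) via `fgsea::gmtPathways`; `write_gmt` emits one.
#'
#' @param path GMT file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in ", path)
  if (any(lengths(sets) == 0L)) stop("empty gene set in ", path)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description description field per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Meta-regulon: union of consensus-TMR targets
#'
#' Union over both cohorts of the targets of every consensus TMR's regulon.
#' The TMRs themselves appear only when they are targets of another
#' consensus regulon.
#'
#' @param regulons_a,regulons_b regulon lists from [build_regulons()].
#' @param consensus consensus TMR ids.
#' @return character vector of gene ids.
#' @export
meta_regulon <- function(regulons_a, regulons_b, consensus) {
  if (length(consensus) == 0L) stop("consensus list is empty")
  grab <- function(regs) unlist(lapply(regs[intersect(names(regs),
                                                      consensus)],
                                       function(r) r$targets$target),
                                use.names = FALSE)
  sort(unique(c(grab(regulons_a), grab(regulons_b))))
}

#' Over-representation analysis against a gene-set collection
#'
#' Hypergeometric upper-tail test per set: with universe size N, set size K
#' (after intersecting the set with the universe), query size n and overlap
#' x, \eqn{p = P(X \ge x)} for \eqn{X \sim Hypergeom(N, K, n)}.  Fold
#' enrichment is \eqn{(x/n)/(K/N)}.
#'
#' @param query character vector of gene ids (must lie in `universe`).
#' @param collection named list of gene sets.
#' @param universe background gene ids (the cohort's expressed genes).
#' @param min_overlap minimum overlap required to test a set (default 1;
#'   smaller overlaps report p = 1).
#' @return data.frame of class `tmr_ora` with columns `set`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `p`, `fold`.
#' @export
ora <- function(query, collection, universe, min_overlap = 1L) {
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0L) stop("empty query")
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    K <- length(set)
    x <- length(intersect(set, query))
    p <- if (K == 0L || x < min_overlap) 1
         else phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (K == 0L) 0 else (x / n) / (K / N)
    data.frame(set = nm, overlap = x, set_size = K, query_size = n,
               universe_size = N, p = p, fold = fold,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("tmr_ora", "data.frame")
  res
}

#' Combine per-cohort ORA results across cohorts
#'
#' Per shared gene set, combines the two hypergeometric p-values with
#' Fisher's method and BH-adjusts over sets.  The `retained` flag applies
#' the strict both-cohorts rule (per-cohort p < `alpha` in both cohorts AND
#' meta FDR < `alpha`); `significant` is the meta-FDR-only call used for
#' per-regulon reports.
#'
#' @param res_a,res_b `tmr_ora` tables over the same collection.
#' @param alpha significance level (default 0.05).
#' @return data.frame of class `tmr_ora_meta` with columns `set`, `p_a`,
#'   `p_b`, `chisq`, `p_meta`, `fdr`, `mean_fold`, `significant`,
#'   `retained`.
#' @export
combine_ora <- function(res_a, res_b, alpha = 0.05) {
  shared <- intersect(res_a$set, res_b$set)
  if (length(shared) == 0L) stop("no shared gene set between cohorts")
  a <- res_a[match(shared, res_a$set), ]
  b <- res_b[match(shared, res_b$set), ]
  fc <- fisher_combine2(a$p, b$p)
  fdr <- bh_adjust(fc$p)
  res <- data.frame(
    set = shared, p_a = a$p, p_b = b$p, chisq = fc$chisq, p_meta = fc$p,
    fdr = fdr, mean_fold = (a$fold + b$fold) / 2,
    significant = fdr < alpha,
    retained = a$p < alpha & b$p < alpha & fdr < alpha,
    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$fdr, res$p_meta), ]
  rownames(res) <- NULL
  class(res) <- c("tmr_ora_meta", "data.frame")
  res
}

#' Per-TMR enrichment bubble matrix
#'
#' Runs per-regulon ORA in both cohorts for every consensus TMR, combines
#' across cohorts, and returns the TMR x gene-set matrix of
#' -log10(meta FDR) used for bubble-style reporting.
#'
#' @param regulons_a,regulons_b regulon lists.
#' @param consensus consensus TMR ids.
#' @param collection named list of gene sets.
#' @param universe_a,universe_b per-cohort expressed-gene universes.
#' @param alpha significance level.
#' @param path optional TSV output path for the matrix.
#' @return list with `matrix` (TMR x set, -log10 meta FDR) and `tables`
#'   (per-TMR `tmr_ora_meta` tables).
#' @export
regulon_enrichment_matrix <- function(regulons_a, regulons_b, consensus,
                                      collection, universe_a, universe_b,
                                      alpha = 0.05, path = NULL) {
  tables <- list()
  mat <- matrix(0, length(consensus), length(collection),
                dimnames = list(consensus, names(collection)))
  for (tf in consensus) {
    qa <- if (tf %in% names(regulons_a))
      intersect(regulons_a[[tf]]$targets$target, universe_a) else character()
    qb <- if (tf %in% names(regulons_b))
      intersect(regulons_b[[tf]]$targets$target, universe_b) else character()
    if (length(qa) == 0L || length(qb) == 0L) next
    meta <- combine_ora(ora(qa, collection, universe_a),
                        ora(qb, collection, universe_b), alpha)
    tables[[tf]] <- meta
    mat[tf, meta$set] <- -log10(pmax(meta$fdr, .Machine$double.xmin))
  }
  if (!is.null(path))
    write.table(data.frame(tmr = rownames(mat), mat, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mat, tables = tables)
}
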