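#' Sensitivity sweep over network p-cutoffs and bootstrap depths
#'
#' Re-runs the network -> regulon -> activity -> meta stack for every cell
#' of a (p_cutoff, n_boot) grid, with seeds derived from the cell
#' parameters, and quantifies the stability of the result: pairwise
#' Jaccard overlap of the consensus TMR sets, pairwise Spearman
#' correlation of the mean NES over regulators shared by each pair of
#' cells, and the per-regulator persistence (fraction of successful cells
#' where the regulator's combined p-value is below `persist_p`).
#'
#' @param mat_a,mat_b log-scale, filtered [expression_matrix()] cohorts.
#' @param regulators regulator gene ids.
#' @param grid data.frame with columns `p_cutoff` and `n_boot`, one row per
#'   cell (cells may repeat, e.g. for self-comparison checks).
#' @param seed master seed.
#' @param min_regulon,n_perm,alpha downstream parameters (see
#'   [build_regulons()], [score_activity()], [consensus_tmrs()]).
#' @param persist_p per-cell significance level (on the Fisher-combined p)
#'   used for the persistence fraction.
#' @param n_null null size for MI threshold calibration.
#' @return an object of class `tmr_sweep` with fields `grid`, `cells`
#'   (per-cell list: `consensus`, `meta`, `failed`), `jaccard`, `spearman`,
#'   `persistence`.
#' @export
sweep_stability <- function(mat_a, mat_b, regulators, grid, seed = 1L,
                            min_regulon = 10L, n_perm = 1000L,
                            alpha = 0.05, persist_p = 0.05, n_null = 1e4) {
  stopifnot(nrow(grid) > 0L, all(c("p_cutoff", "n_boot") %in% names(grid)))
  de_a <- differential_expression(mat_a)
  de_b <- differential_expression(mat_b)

  cells <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p_cutoff[i]; nb <- grid$n_boot[i]
    ## the derived seed depends on the cell parameters, not the row index,
    ## so identical grid rows reproduce identical cells
    cell_seed <- derive_seed(seed, round(-log10(p) * 1000 + nb))
    cells[[i]] <- tryCatch({
      net_a <- consolidate_bootstraps(mat_a, regulators, p, nb,
                                      seed = cell_seed, n_null = n_null)
      net_b <- consolidate_bootstraps(mat_b, regulators, p, nb,
                                      seed = derive_seed(cell_seed, 5L),
                                      n_null = n_null)
      if (nrow(net_a$edges) == 0L || nrow(net_b$edges) == 0L)
        stop("empty network")
      reg_a <- build_regulons(net_a, mat_a, min_regulon)
      reg_b <- build_regulons(net_b, mat_b, min_regulon)
      act_a <- score_activity(reg_a, de_a, n_perm,
                              seed = derive_seed(cell_seed, 7L),
                              mat = mat_a)
      act_b <- score_activity(reg_b, de_b, n_perm,
                              seed = derive_seed(cell_seed, 8L),
                              mat = mat_b)
      meta <- consensus_tmrs(act_a, act_b, alpha)
      list(consensus = meta$regulator[meta$consensus], meta = meta,
           failed = FALSE)
    }, error = function(e)
      list(consensus = character(), meta = NULL, failed = TRUE,
           message = conditionMessage(e)))
  }

  k <- nrow(grid)
  jac <- matrix(NA_real_, k, k)
  spear <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (cells[[i]]$failed || cells[[j]]$failed) next
    jac[i, j] <- jaccard(cells[[i]]$consensus, cells[[j]]$consensus)
    mi <- cells[[i]]$meta; mj <- cells[[j]]$meta
    shared <- intersect(mi$regulator, mj$regulator)
    vi <- mi$mean_nes[match(shared, mi$regulator)]
    vj <- mj$mean_nes[match(shared, mj$regulator)]
    spear[i, j] <- if (length(shared) >= 1L && identical(vi, vj)) 1
    else if (length(shared) >= 3L) cor(vi, vj, method = "spearman")
    else NA_real_
  }
  ## persistence: share of successful cells where the regulator's combined
  ## p-value is below `persist_p` (a per-run significance call, looser than
  ## the FDR-based consensus flag)
  ok <- !vapply(cells, `[[`, logical(1), "failed")
  persistence <- if (any(ok)) {
    sig <- unlist(lapply(cells[ok], function(cell)
      cell$meta$regulator[cell$meta$p_meta < persist_p]))
    hits <- table(sig)
    setNames(as.numeric(hits) / sum(ok), names(hits))
  } else setNames(numeric(0), character(0))

  structure(list(grid = grid, cells = cells, jaccard = jac,
                 spearman = spear, persistence = persistence),
            class = "tmr_sweep")
}

#' @export
print.tmr_sweep <- function(x, ...) {
  ok <- sum(!vapply(x$cells, `[[`, logical(1), "failed"))
  cat(sprintf("<tmr_sweep> %d cells (%d ok); median Jaccard %.2f\n",
              nrow(x$grid), ok,
              median(x$jaccard[upper.tri(x$jaccard)], na.rm = TRUE)))
  invisible(x)
}

#' Write a sweep result directory
#'
#' One TSV per cell (consensus meta table) plus `jaccard.tsv`,
#' `spearman.tsv` and `persistence.tsv`.
#'
#' @param sweep a `tmr_sweep`.
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(sweep$cells)) {
    cell <- sweep$cells[[i]]
    if (!cell$failed)
      write.table(cell$meta,
                  file.path(dir, sprintf("cell_%02d.tsv", i)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  lab <- sprintf("p%g_b%d", sweep$grid$p_cutoff, sweep$grid$n_boot)
  wm <- function(m, f) {
    dimnames(m) <- list(lab, lab)
    write.table(data.frame(cell = lab, m, check.names = FALSE),
                file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wm(sweep$jaccard, "jaccard.tsv")
  wm(sweep$spearman, "spearman.tsv")
  write.table(data.frame(regulator = names(sweep$persistence),
                         persistence = as.numeric(sweep$persistence)),
              file.path(dir, "persistence.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
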