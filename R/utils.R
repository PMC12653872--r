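## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' package functions never perturb the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## derive a child seed from a master seed; stays below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] kept as a single audited entry point
#' for every FDR correction in the package.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

## statistical mode of a vector (first value on ties)
stat_mode <- function(x) {
  tab <- table(x)
  names(tab)[which.max(tab)]
}

## Consolidate duplicate gene ids: keep, within each duplicate group, the row
## whose entries agree with the per-cell statistical mode most often; first
## row on ties.
consolidate_duplicates <- function(values) {
  ids <- rownames(values)
  if (!anyDuplicated(ids)) return(values)
  keep <- logical(nrow(values))
  for (g in unique(ids)) {
    rows <- which(ids == g)
    if (length(rows) == 1L) {
      keep[rows] <- TRUE
      next
    }
    sub <- values[rows, , drop = FALSE]
    modes <- apply(sub, 2, function(col) as.numeric(stat_mode(col)))
    agree <- rowSums(sweep(sub, 2, modes, "==") * 1)
    keep[rows[which.max(agree)]] <- TRUE
  }
  values[keep, , drop = FALSE]
}

## quantile with linear interpolation between order statistics
quantile_lin <- function(x, probs) {
  as.numeric(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

## Jaccard index of two sets
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}
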