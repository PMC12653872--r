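test_that("detection filter applies the strict >80% rule", {
  counts <- rbind(allpass = c(10, 10, 10, 10, 10),
                  border = c(10, 10, 10, 10, 2),
                  allfail = c(9, 9, 9, 9, 9))
  colnames(counts) <- paste0("s", 1:5)
  mat <- make_expr(counts, 3, 2, platform = "counts")
  kept <- filter_counts(mat)
  expect_identical(kept$genes, "allpass")
  expect_error(filter_counts(make_expr(counts["allfail", , drop = FALSE],
                                       3, 2, platform = "counts")),
               "no gene passes")
})

test_that("TMM normalization is depth-invariant with unit factors on symmetric input", {
  set.seed(42)
  base <- matrix(rnbinom(50 * 6, mu = 200, size = 10), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))

  same <- make_expr(matrix(base[, 1], 50, 6,
                           dimnames = dimnames(base)), 3, 3, "counts")
  f_same <- attr(normalize_counts(same), "norm_factors")
  expect_equal(unname(f_same), rep(1, 6))

  two <- make_expr(cbind(s1 = base[, 1], s2 = 2L * base[, 1]), 1, 1,
                   "counts")
  lc <- normalize_counts(two)
  expect_equal(lc$values[, 1], lc$values[, 2])

  f <- attr(normalize_counts(make_expr(base, 3, 3, "counts")),
            "norm_factors")
  expect_lt(abs(exp(mean(log(f))) - 1), 1e-12)
})

test_that("intensity filter drops low-abundance genes then the bottom variance quartile", {
  set.seed(7)
  n <- 100
  vals <- matrix(rnorm(n * 10, sd = sqrt(seq_len(n))), nrow = n,
                 dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:10)))
  vals <- vals - rowMeans(vals) + 8          # all pass the abundance rule
  low <- matrix(3.9, 1, 10, dimnames = list("dim", paste0("s", 1:10)))
  mat <- make_expr(rbind(vals, low), 5, 5)
  kept <- filter_intensity(mat)
  expect_false("dim" %in% kept$genes)
  expect_identical(nrow(kept$values), 75L)   # exactly 75 of 100 retained
  vmax <- names(which.max(apply(vals, 1, var)))
  expect_true(vmax %in% kept$genes)
})

test_that("moderated t recovers planted shifts and behaves at the null", {
  ## null case: identical group means
  set.seed(1)
  null_vals <- matrix(rnorm(40 * 20), 40, 20,
                      dimnames = list(sprintf("g%02d", 1:40),
                                      paste0("s", 1:20)))
  null_vals <- null_vals - rowMeans(null_vals[, 1:10]) %o% rep(1, 20) * 0
  m0 <- make_expr(null_vals, 10, 10)
  de0 <- differential_expression(m0)
  flat <- make_expr(matrix(5, 10, 8, dimnames = list(paste0("g", 1:10),
                                                     paste0("s", 1:8))),
                    4, 4)
  expect_warning(de_flat <- differential_expression(flat), "zero within")
  expect_true(all(de_flat$logFC == 0))
  expect_false(any(de_flat$significant))

  ## Monte-Carlo: planted log2 shift 2.0, n = 30+30, noise SD 0.5
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    vals <- matrix(rnorm(50 * 60, mean = 6, sd = 0.5), 50, 60,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   paste0("s", 1:60)))
    vals["g01", 1:30] <- vals["g01", 1:30] + 2
    de <- differential_expression(make_expr(vals, 30, 30))
    row <- de[de$gene == "g01", ]
    hits <- hits + (row$logFC > 1.5 && row$logFC < 2.5 && row$significant)
  }
  expect_gte(hits, 98L)
})

test_that("infinite prior df collapses the moderated t to a z with the prior scale", {
  set.seed(3)
  vals <- matrix(rnorm(30 * 12), 30, 12,
                 dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:12)))
  st <- tmrnet:::mod_t_stats(vals, vals^2, rep(c(TRUE, FALSE), each = 6),
                             rep(c(FALSE, TRUE), each = 6))
  prior <- tmrnet:::fit_variance_prior(
    ((6 - 1) * apply(vals[, 1:6], 1, var) +
     (6 - 1) * apply(vals[, 7:12], 1, var)) / 10, 10)
  if (is.infinite(prior$d0)) {
    expect_equal(st$t, unname(st$logFC / sqrt(prior$s02 * (1 / 6 + 1 / 6))))
    expect_identical(st$df, Inf)
  } else {
    ## shrunken variance lies between the prior and the observed variance
    expect_true(all(st$se > 0))
  }
})

test_that("DE invariants hold: BH brute force, SE*t identity, label swap", {
  set.seed(11)
  vals <- matrix(rnorm(60 * 16, mean = 7), 60, 16,
                 dimnames = list(sprintf("g%02d", 1:60), paste0("s", 1:16)))
  vals[1:10, 1:8] <- vals[1:10, 1:8] + rnorm(10)
  mat <- make_expr(vals, 8, 8)
  de <- differential_expression(mat)

  expect_identical(de$fdr, bh_brute(de$p))
  nz <- de$t != 0
  expect_equal(de$se[nz] * de$t[nz], abs(de$logFC[nz]) * sign(de$t[nz]) *
                 sign(de$logFC[nz]) * sign(de$t[nz]))
  expect_equal(abs(de$se[nz] * de$t[nz]), abs(de$logFC[nz]))

  swapped <- expression_matrix(vals, c(rep("normal", 8), rep("tumor", 8)),
                               "intensity")
  de2 <- differential_expression(swapped)
  expect_equal(de2$logFC, -de$logFC)
  expect_equal(de2$t, -de$t)
  expect_equal(de2$p, de$p)
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(19)
  vals <- matrix(rnorm(80 * 20, mean = 6), 80, 20,
                 dimnames = list(sprintf("g%02d", 1:80), paste0("s", 1:20)))
  vals[1:15, 1:10] <- vals[1:15, 1:10] + rnorm(15, sd = 1.5)
  mat <- make_expr(vals, 10, 10)
  de <- differential_expression(mat)

  design <- cbind(1, rep(c(1, 0), each = 10))
  fit <- limma::eBayes(limma::lmFit(vals, design))
  expect_equal(de$logFC, unname(fit$coefficients[, 2]))
  ## shrinkage details differ (moments vs F-dist fit on log variances), but
  ## the moderated statistics must agree closely
  expect_gt(cor(de$t, fit$t[, 2]), 0.999)
})

test_that("duplicate gene ids are consolidated by per-cell mode", {
  vals <- rbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(1, 2, 3, 9))
  rownames(vals) <- c("dup", "other", "dup")
  colnames(vals) <- paste0("s", 1:4)
  mat <- expression_matrix(vals, c("tumor", "tumor", "normal", "normal"),
                           "intensity")
  expect_identical(nrow(mat$values), 2L)
  ## first dup row matches the cell-wise mode in 3 of 4 cells, second in 3;
  ## tie resolved in favor of the first row
  expect_equal(unname(mat$values["dup", ]), c(1, 2, 3, 4))
})

test_that("DE tables survive a TSV round trip", {
  set.seed(2)
  vals <- matrix(rnorm(20 * 8, mean = 6), 20, 8,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:8)))
  de <- differential_expression(make_expr(vals, 4, 4))
  path <- tempfile(fileext = ".tsv")
  write_de(de, path)
  back <- read_de(path)
  expect_equal(back$logFC, de$logFC, tolerance = 1e-12)
  expect_identical(back$significant, de$significant)
})
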