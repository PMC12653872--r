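test_that("regulon modes are signed Spearman correlations, exact in the noiseless limit", {
  set.seed(1)
  x <- rnorm(40)
  vals <- rbind(TF01 = x, up = x, down = -x,
                noisy = 0.7 * x + rnorm(40, sd = 0.4))
  ## pad with unrelated genes so min_size can be satisfied
  pad <- matrix(rnorm(40 * 10), 10, 40,
                dimnames = list(sprintf("pad%02d", 1:10), NULL))
  vals <- rbind(vals, pad)
  colnames(vals) <- paste0("s", 1:40)
  mat <- make_expr(vals, 20, 20)
  edges <- data.frame(regulator = "TF01",
                      target = c("up", "down", "noisy"),
                      mi = c(0.8, 0.8, 0.4), stringsAsFactors = FALSE)
  regs <- build_regulons(manual_network(edges), mat, min_size = 3)
  tab <- regs[["TF01"]]$targets
  expect_equal(tab$mode[tab$target == "up"], 1)
  expect_equal(tab$mode[tab$target == "down"], -1)
  expect_equal(tab$weight[tab$target == "up"], 1)     # max-MI normalization
  expect_equal(tab$weight[tab$target == "noisy"], 0.5)
})

test_that("planted regulation signs are recovered from simulated expression", {
  set.seed(2)
  n <- 60
  a <- rnorm(n)
  vals <- rbind(TF01 = 0.9 * a + rnorm(n, sd = sqrt(1 - 0.81)),
                t1 = 0.8 * a + rnorm(n, sd = 0.3),
                t2 = 0.7 * a + rnorm(n, sd = 0.3),
                t3 = -0.8 * a + rnorm(n, sd = 0.3))
  colnames(vals) <- paste0("s", 1:n)
  mat <- make_expr(vals, 30, 30)
  edges <- data.frame(regulator = "TF01", target = c("t1", "t2", "t3"),
                      mi = c(0.5, 0.45, 0.5), stringsAsFactors = FALSE)
  regs <- build_regulons(manual_network(edges), mat, min_size = 3)
  modes <- setNames(regs[["TF01"]]$targets$mode,
                    regs[["TF01"]]$targets$target)
  expect_true(all(sign(modes) == c(t1 = 1, t2 = 1, t3 = -1)))
})

test_that("regulons below the size floor are absent and missing regulators warn", {
  set.seed(3)
  vals <- matrix(rnorm(5 * 20), 5, 20,
                 dimnames = list(c("TF01", paste0("g", 1:4)),
                                 paste0("s", 1:20)))
  mat <- make_expr(vals, 10, 10)
  edges <- data.frame(regulator = c("TF01", "TF01", "TF99"),
                      target = c("g1", "g2", "g3"),
                      mi = c(0.3, 0.2, 0.4), stringsAsFactors = FALSE)
  expect_warning(
    regs <- build_regulons(manual_network(edges), mat, min_size = 3),
    "TF99")
  expect_length(regs, 0)
  regs2 <- suppressWarnings(
    build_regulons(manual_network(edges), mat, min_size = 2))
  expect_named(regs2, "TF01")
})

make_null_signature <- function(G, n, seed) {
  set.seed(seed)
  vals <- matrix(rnorm(G * n, mean = 6), G, n,
                 dimnames = list(sprintf("g%04d", 1:G), paste0("s", 1:n)))
  mat <- make_expr(vals, n / 2, n / 2)
  list(mat = mat, de = differential_expression(mat))
}

test_that("NES is calibrated on random regulons over a null signature", {
  ns <- make_null_signature(300, 40, seed = 5)
  set.seed(6)
  regs <- lapply(1:1000, function(i)
    manual_regulon(paste0("R", i),
                   sample(ns$de$gene, 15),
                   modes = sample(c(-1, 1), 15, replace = TRUE),
                   weights = runif(15, 0.5, 1)))
  names(regs) <- paste0("R", 1:1000)
  act <- score_activity(regs, ns$de, n_perm = 300, seed = 7,
                        null = "geneset")
  expect_lt(abs(mean(act$nes)), 0.1)
  expect_lt(abs(sd(act$nes) - 1), 0.1)
})

test_that("the sample-permutation null is calibrated on real but inactive regulons", {
  ## co-regulated targets with no group shift: NES must stay near N(0,1)
  set.seed(8)
  G <- 150; n <- 40
  acts <- matrix(rnorm(10 * n), 10)
  vals <- matrix(rnorm(G * n, mean = 6, sd = 0.5), G, n,
                 dimnames = list(sprintf("g%04d", 1:G), paste0("s", 1:n)))
  regs <- list()
  for (k in 1:10) {
    idx <- ((k - 1) * 12 + 1):(k * 12)
    vals[idx, ] <- vals[idx, ] + outer(runif(12, 0.6, 1) *
                                         sample(c(-1, 1), 12, TRUE),
                                       acts[k, ])
    regs[[paste0("R", k)]] <- manual_regulon(
      paste0("R", k), rownames(vals)[idx],
      modes = rep(1, 12), weights = rep(1, 12))
  }
  mat <- make_expr(vals, n / 2, n / 2)
  de <- differential_expression(mat)
  act <- score_activity(regs, de, n_perm = 1000, seed = 9, mat = mat)
  expect_lt(max(abs(act$nes)), 3.5)
  expect_lt(abs(mean(act$nes)), 0.8)
})

test_that("scoring is deterministic, linear in modes, and weight-split invariant", {
  ns <- make_null_signature(200, 30, seed = 10)
  reg <- list(R1 = manual_regulon("R1", ns$de$gene[1:10],
                                  modes = rep(c(1, -1), 5),
                                  weights = runif(10, 0.5, 1)))
  a1 <- score_activity(reg, ns$de, n_perm = 500, seed = 11, mat = ns$mat)
  a2 <- score_activity(reg, ns$de, n_perm = 500, seed = 11, mat = ns$mat)
  expect_identical(a1$nes, a2$nes)

  flipped <- reg
  flipped$R1$targets$mode <- -flipped$R1$targets$mode
  a3 <- score_activity(flipped, ns$de, n_perm = 500, seed = 11,
                       mat = ns$mat)
  expect_equal(a3$nes, -a1$nes)

  split <- reg
  tab <- split$R1$targets
  split$R1$targets <- rbind(
    transform(tab[1, ], weight = weight / 2),
    transform(tab[1, ], weight = weight / 2),
    tab[-1, ])
  a4 <- score_activity(split, ns$de, n_perm = 500, seed = 11,
                       mat = ns$mat)
  expect_equal(a4$nes, a1$nes)
})

test_that("regulators without scorable targets are dropped with a warning", {
  ns <- make_null_signature(50, 20, seed = 12)
  regs <- list(
    ok = manual_regulon("ok", ns$de$gene[1:5], rep(1, 5), rep(1, 5)),
    gone = manual_regulon("gone", paste0("absent", 1:5), rep(1, 5),
                          rep(1, 5)))
  expect_warning(act <- score_activity(regs, ns$de, n_perm = 200,
                                       seed = 13, mat = ns$mat),
                 "gone")
  expect_identical(act$regulator, "ok")
})

test_that("regulons survive a TSV round trip", {
  regs <- list(TF01 = manual_regulon("TF01", c("a", "b"), c(1, -0.5),
                                     c(1, 0.4)),
               TF02 = manual_regulon("TF02", c("c"), c(0.8), c(1)))
  path <- tempfile(fileext = ".tsv")
  write_regulons(regs, path)
  back <- read_regulons(path)
  expect_equal(back$TF01$targets, regs$TF01$targets)
  expect_equal(back$TF02$targets, regs$TF02$targets)
})
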