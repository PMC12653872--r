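test_that("PFM to PWM conversion apportions the pseudocount by background", {
  counts <- matrix(c(10, 0, 0, 0), 4, 5,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- pfm_motif("MA0001.1", "TFX", counts)
  expect_equal(unname(m$prob[, 1]),
               c(10.2, 0.2, 0.2, 0.2) / 10.8, tolerance = 1e-12)
  expect_equal(m$pwm, log2(m$prob / 0.25))
  expect_error(pfm_motif("bad", "TFX", counts[, 1:3]), "at least 4")
})

test_that("JASPAR text files round trip and malformed records are named", {
  set.seed(1)
  motifs <- make_motif_set(c("TFA", "TFB"), length = 8)
  path <- tempfile(fileext = ".jaspar")
  write_jaspar_pfm(motifs, path)
  loaded <- load_motifs(path)
  expect_setequal(names(loaded), c("TFA", "TFB"))
  expect_equal(loaded$TFA$counts, motifs$TFA$counts)
  expect_identical(motif_consensus(loaded$TFA), motif_consensus(motifs$TFA))

  bad <- tempfile(fileext = ".jaspar")
  writeLines(c(">MA9999.1 BROKEN", "A [ 1 2 x ]", "C [ 1 2 3 ]",
               "G [ 1 2 3 ]", "T [ 1 2 3 ]"), bad)
  expect_error(load_motifs(bad), "MA9999.1")
})

test_that("one motif per TF is chosen by source priority then version", {
  counts <- matrix(c(10, 0, 0, 0), 4, 6,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  path <- tempfile(fileext = ".jaspar")
  write_jaspar_pfm(list(pfm_motif("MA0001.1", "TFX", counts),
                        pfm_motif("MA0002.2", "TFX", counts + 1),
                        pfm_motif("MA0003.3", "TFX", counts + 2)), path)
  picked <- load_motifs(path, tiers = c(MA0001.1 = "automatic",
                                        MA0002.2 = "manual",
                                        MA0003.3 = "manual"))
  expect_identical(picked$TFX$id, "MA0003.3")  # manual tier, latest version
  expect_identical(picked$TFX$tier, "manual")

  picked2 <- load_motifs(path, tiers = c(MA0001.1 = "manual",
                                         MA0002.2 = "automatic",
                                         MA0003.3 = "secondary"))
  expect_identical(picked2$TFX$id, "MA0001.1")

  res <- load_motifs(path, tf_list = c("TFX", "NOMOTIF"))
  expect_identical(attr(res, "no_motif"), "NOMOTIF")
})

test_that("promoter windows implement the asymmetric strand-aware interval", {
  tss <- data.frame(gene = c("gp", "gm"), chrom = "chr1",
                    pos = c(10000L, 20000L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  seqs <- setNames(c(strrep("A", 2200), strrep("C", 2200)), c("gp", "gm"))
  w <- promoter_windows(tss, seqs)
  expect_identical(w$end - w$start, c(2200L, 2200L))
  expect_identical(w$start[1], 10000L - 1L - 2000L)
  expect_identical(w$end[1], 10000L - 1L + 200L)
  expect_identical(w$start[2], 20000L - 1L - 200L)
  expect_identical(w$end[2], 20000L - 1L + 2000L)
  expect_error(promoter_windows(tss, setNames(c(strrep("A", 100),
                                                strrep("C", 2200)),
                                              c("gp", "gm"))),
               "width")
})

test_that("a planted consensus scores relative 1.0 at its offset, both strands", {
  set.seed(2)
  motifs <- make_motif_set("TFX", length = 12)
  cons <- motif_consensus(motifs$TFX)
  bg <- paste(sample(c("A", "C", "G", "T"), 2200, replace = TRUE),
              collapse = "")
  planted <- bg
  substr(planted, 137, 148) <- cons
  win <- list(gene = "g1", sequence = planted)
  hits <- scan_promoter(motifs$TFX, win)
  top <- hits[hits$relative == 1, ]
  expect_true(any(top$position == 137 & top$orientation == "+"))

  rc <- tmrnet:::revcomp(cons)
  planted2 <- bg
  substr(planted2, 400, 411) <- rc
  hits2 <- scan_promoter(motifs$TFX, list(gene = "g1",
                                          sequence = planted2))
  top2 <- hits2[hits2$relative == 1, ]
  expect_true(any(top2$position == 400 & top2$orientation == "-"))
})

test_that("relative scores are invariant to adding a constant to the PWM", {
  set.seed(3)
  motifs <- make_motif_set("TFX", length = 10)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  win <- list(gene = "g", sequence = seq)
  h1 <- scan_promoter(motifs$TFX, win, min_rel_score = 0.6)
  shifted <- motifs$TFX
  shifted$pwm <- shifted$pwm + 3.7
  h2 <- scan_promoter(shifted, win, min_rel_score = 0.6)
  expect_equal(h1$relative, h2$relative)
  expect_identical(h1$position, h2$position)
})

test_that("N bases score as the background expectation", {
  counts <- matrix(c(10, 0, 0, 0), 4, 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- pfm_motif("MA0009.1", "TFN", counts)
  hitA <- scan_promoter(m, list(gene = "g", sequence = "AAAACCCC"),
                        min_rel_score = 0.01)
  hitN <- scan_promoter(m, list(gene = "g", sequence = "AAANCCCC"),
                        min_rel_score = 0.01)
  rawA <- hitA$raw[hitA$position == 1 & hitA$orientation == "+"]
  rawN <- hitN$raw[hitN$position == 1 & hitN$orientation == "+"]
  expect_equal(rawN - rawA,
               unname(sum(0.25 * m$pwm[, 4]) - m$pwm["A", 4]),
               tolerance = 1e-12)
})

test_that("background hit counts match the exact score-distribution oracle", {
  ## soft 8-nt motif so the 0.85 threshold admits a measurable tail
  set.seed(4)
  counts <- matrix(2, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(sample.int(4, 8, TRUE), 1:8)] <- 12
  m <- pfm_motif("MA0010.1", "TFS", counts)

  ## exact p(hit) per position by convolving per-column score distributions
  dist <- data.frame(score = 0, prob = 1)
  for (j in seq_len(ncol(m$pwm))) {
    grid <- expand.grid(s = dist$score, v = m$pwm[, j])
    grid$p <- rep(dist$prob, times = 4) * 0.25
    s <- round(grid$s + grid$v, 9)
    dist <- aggregate(list(prob = grid$p), list(score = s), sum)
  }
  min_att <- sum(apply(m$pwm, 2, min))
  max_att <- sum(apply(m$pwm, 2, max))
  thr_raw <- min_att + 0.85 * (max_att - min_att)
  p_hit <- sum(dist$prob[dist$score >= thr_raw])

  W <- 2200
  n_win <- 60
  expected <- p_hit * (W - 8 + 1) * 2 * n_win
  observed <- 0
  for (i in seq_len(n_win)) {
    seq <- paste(sample(c("A", "C", "G", "T"), W, replace = TRUE),
                 collapse = "")
    observed <- observed + nrow(scan_promoter(m, list(gene = "g",
                                                      sequence = seq)))
  }
  expect_gt(expected, 10)   # the check is only meaningful with real mass
  expect_lt(observed, 2 * expected + 3 * sqrt(expected))
  expect_gt(observed, expected / 2 - 3 * sqrt(expected))
})

test_that("the dual-support graph applies the at-least-one-cohort rule", {
  hits <- data.frame(
    motif_id = "M", tf = c("T1", "T1", "T2", "T3"),
    gene = c("T2", "T3", "T3", "T1"),
    position = c(10L, 20L, 30L, 40L), orientation = "+",
    raw = 1, relative = c(0.9, 0.95, 0.88, 0.99),
    stringsAsFactors = FALSE)
  net_a <- manual_network(data.frame(regulator = "T1", target = "T2",
                                     mi = 0.5, stringsAsFactors = FALSE))
  net_b <- manual_network(data.frame(regulator = c("T1", "T2"),
                                     target = c("T2", "T3"),
                                     mi = c(0.4, 0.3),
                                     stringsAsFactors = FALSE))
  g <- build_tmr_graph(hits, list(a = net_a, b = net_b),
                       consensus = c("T1", "T2", "T3"))
  keys <- paste(g$edges$source, g$edges$target)
  expect_setequal(keys, c("T1 T2", "T2 T3"))   # T1->T3, T3->T1 unsupported
  expect_true(g$edges$support_a[keys == "T1 T2"])
  expect_true(g$edges$support_b[keys == "T1 T2"])
  expect_false(g$edges$support_a[keys == "T2 T3"])
  expect_identical(unname(g$out_degree[c("T1", "T2", "T3")]), c(1L, 1L, 0L))
  expect_identical(unname(g$in_degree[c("T1", "T2", "T3")]), c(0L, 1L, 1L))
})

test_that("hub calls follow the quartile rule and its degenerate cases", {
  ## star graph: center with 9 leaves
  edges <- data.frame(source = "C", target = paste0("L", 1:9),
                      relative = 1, position = 1L, orientation = "+",
                      support_a = TRUE, stringsAsFactors = FALSE)
  g <- structure(list(edges = edges, nodes = c("C", paste0("L", 1:9)),
                      out_degree = setNames(c(9L, rep(0L, 9)),
                                            c("C", paste0("L", 1:9))),
                      in_degree = setNames(c(0L, rep(1L, 9)),
                                           c("C", paste0("L", 1:9)))),
                 class = "tmr_graph")
  hubs <- call_hubs(g)
  ## the center is a hub with the top out-degree; with interpolated
  ## quartiles over this degenerate degree list (Q3 = 0, Q1 = 1) the
  ## inclusive boundaries let every leaf tie-qualify as well
  expect_true(hubs$hub[hubs$node == "C"])
  expect_identical(hubs$node[1], "C")
  expect_identical(hubs$hub, unname(hub_brute(g$out_degree,
                                              g$in_degree))[match(hubs$node, g$nodes)])

  empty <- structure(list(edges = edges[0, ], nodes = c("a", "b"),
                          out_degree = c(a = 0L, b = 0L),
                          in_degree = c(a = 0L, b = 0L)),
                     class = "tmr_graph")
  expect_warning(h0 <- call_hubs(empty), "no edges")
  expect_false(any(h0$hub))
})

test_that("hub calls equal brute force and are permutation-equivariant", {
  set.seed(5)
  for (i in 1:100) {
    n <- 50
    nodes <- sprintf("N%02d", 1:n)
    adj <- matrix(runif(n * n) < 0.1, n, n)
    diag(adj) <- FALSE
    out_deg <- setNames(as.integer(rowSums(adj)), nodes)
    in_deg <- setNames(as.integer(colSums(adj)), nodes)
    idx <- which(adj, arr.ind = TRUE)
    g <- structure(list(
      edges = data.frame(source = nodes[idx[, 1]],
                         target = nodes[idx[, 2]], relative = 1,
                         position = 1L, orientation = "+",
                         stringsAsFactors = FALSE),
      nodes = nodes, out_degree = out_deg, in_degree = in_deg),
      class = "tmr_graph")
    hubs <- call_hubs(g)
    oracle <- hub_brute(out_deg, in_deg)
    expect_identical(hubs$hub[match(nodes, hubs$node)], unname(oracle))
  }

  perm <- sample(50)
  relabel <- setNames(sprintf("M%02d", perm), sprintf("N%02d", 1:50))
  g2 <- g
  g2$nodes <- unname(relabel[g$nodes])
  g2$edges$source <- unname(relabel[g$edges$source])
  g2$edges$target <- unname(relabel[g$edges$target])
  names(g2$out_degree) <- unname(relabel[names(g$out_degree)])
  names(g2$in_degree) <- unname(relabel[names(g$in_degree)])
  h1 <- call_hubs(g)
  h2 <- call_hubs(g2)
  expect_setequal(unname(relabel[h1$node[h1$hub]]), h2$node[h2$hub])
})

test_that("adjacency export matches the edge list", {
  edges <- data.frame(source = c("A", "B"), target = c("B", "C"),
                      relative = 1, position = 1L, orientation = "+",
                      stringsAsFactors = FALSE)
  g <- structure(list(edges = edges, nodes = c("A", "B", "C"),
                      out_degree = c(A = 1L, B = 1L, C = 0L),
                      in_degree = c(A = 0L, B = 1L, C = 1L)),
                 class = "tmr_graph")
  adj <- tmr_adjacency(g)
  expect_identical(adj["A", "B"], 1L)
  expect_identical(adj["B", "C"], 1L)
  expect_identical(sum(adj), 2L)
})
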