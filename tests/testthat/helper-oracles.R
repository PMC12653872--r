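## Independent oracles and small fixture builders shared across tests.

## brute-force Benjamini-Hochberg: sort, cummin of scaled p, restore order
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

## Fisher combined p for k = 2, closed form exp(-x/2) * (1 + x/2)
fisher2_closed <- function(p1, p2) {
  x <- -2 * (log(p1) + log(p2))
  exp(-x / 2) * (1 + x / 2)
}

## exact hypergeometric upper tail by enumeration over achievable overlaps
hyper_enum <- function(overlap, set_size, query_size, universe_size) {
  js <- 0:min(set_size, query_size)
  probs <- choose(set_size, js) *
    choose(universe_size - set_size, query_size - js) /
    choose(universe_size, query_size)
  sum(probs[js >= overlap])
}

## brute-force degree-quantile hub rule
hub_brute <- function(out_deg, in_deg) {
  q3 <- as.numeric(quantile(out_deg, 0.75, type = 7))
  q1 <- as.numeric(quantile(in_deg, 0.25, type = 7))
  out_deg >= q3 & in_deg <= q1
}

edge_keys <- function(edges) paste(edges$regulator, edges$target)

planted_keys <- function(truth) {
  unlist(lapply(names(truth$regulons), function(tf)
    paste(tf, truth$regulons[[tf]]$target)), use.names = FALSE)
}

## expression container around a plain matrix with default labels
make_expr <- function(values, n_tumor, n_normal,
                      platform = "intensity") {
  expression_matrix(values,
                    c(rep("tumor", n_tumor), rep("normal", n_normal)),
                    platform)
}

## one regulator, hand-specified targets, as build_regulons() output
manual_regulon <- function(tf, targets, modes, weights) {
  structure(list(regulator = tf,
                 targets = data.frame(target = targets, mode = modes,
                                      weight = weights,
                                      stringsAsFactors = FALSE)),
            class = "tmr_regulon")
}

## minimal mi-network from a plain edge data.frame
manual_network <- function(edges, regulators = unique(edges$regulator)) {
  edges$support <- edges$support %||% NA_integer_
  tmrnet:::mi_network(edges, regulators)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## query of size n with exactly x genes inside `set` (first K universe genes)
ora_query <- function(universe, K, n, x) {
  c(universe[seq_len(x)],
    if (n - x > 0) universe[K + seq_len(n - x)])
}

## minimal DE table for meta-analysis fixtures
fake_de_acc <- function(genes, logFC, se) {
  structure(data.frame(gene = genes, logFC = logFC, t = logFC / se,
                       p = 0.5, fdr = 0.5, se = se, significant = FALSE,
                       stringsAsFactors = FALSE),
            class = c("tmr_de", "data.frame"))
}
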