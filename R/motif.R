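BASES <- c("A", "C", "G", "T")

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x)
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE))
}

#' Construct a position-frequency-matrix motif
#'
#' Converts a 4 x L count matrix into a log2-odds position weight matrix.
#' A total pseudocount of `pseudocount` per column is apportioned by the
#' background frequencies before normalization:
#' \eqn{p_{b,j} = (c_{b,j} + 0.8\,bg_b) / (\sum_b c_{b,j} + 0.8)}, and
#' \eqn{PWM_{b,j} = \log_2(p_{b,j}/bg_b)}.
#'
#' @param id motif identifier (e.g. `MA0001.1`).
#' @param tf transcription factor name the motif belongs to.
#' @param counts 4 x L numeric matrix with rownames A, C, G, T (L >= 4).
#' @param background background base frequencies (default uniform).
#' @param tier source tier, one of `"manual"`, `"automatic"`,
#'   `"secondary"` (priority in that order when several motifs exist for
#'   one TF).
#' @param pseudocount total pseudocount per column (default 0.8).
#' @return an object of class `tmr_pwm` with fields `id`, `tf`, `counts`,
#'   `prob`, `pwm`, `background`, `tier`.
#' @export
pfm_motif <- function(id, tf, counts, background = rep(0.25, 4),
                      tier = "manual", pseudocount = 0.8) {
  if (!is.matrix(counts) || nrow(counts) != 4L)
    stop("motif ", id, ": counts must be a 4-row matrix")
  if (ncol(counts) < 4L)
    stop("motif ", id, ": motif length must be at least 4")
  rownames(counts) <- BASES
  background <- background / sum(background)
  prob <- sweep(counts + pseudocount * background, 2,
                colSums(counts) + pseudocount, "/")
  pwm <- log2(sweep(prob, 1, background, "/"))
  structure(list(id = id, tf = tf, counts = counts, prob = prob, pwm = pwm,
                 background = background, tier = tier),
            class = "tmr_pwm")
}

#' @export
print.tmr_pwm <- function(x, ...) {
  cat(sprintf("<tmr_pwm> %s (%s, %s): %d nt, consensus %s\n",
              x$id, x$tf, x$tier, ncol(x$pwm), motif_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a motif
#'
#' @param motif a `tmr_pwm`.
#' @return the consensus string (highest-count base per column).
#' @export
motif_consensus <- function(motif) {
  paste(BASES[apply(motif$counts, 2, which.max)], collapse = "")
}

#' Generate a synthetic motif set
#'
#' One information-rich motif per TF: a random consensus with count 18 on
#' the consensus base and 0 elsewhere.  Consumes the current RNG state.
#'
#' @param tf_ids character vector of TF names.
#' @param length motif length in nt.
#' @return named list of `tmr_pwm` objects (one per TF).
#' @export
make_motif_set <- function(tf_ids, length = 10L) {
  out <- lapply(seq_along(tf_ids), function(i) {
    cons <- sample.int(4L, length, replace = TRUE)
    counts <- matrix(0, 4, length, dimnames = list(BASES, NULL))
    counts[cbind(cons, seq_len(length))] <- 18
    pfm_motif(sprintf("MA%04d.1", i), tf_ids[i], counts)
  })
  names(out) <- tf_ids
  out
}

#' Write motifs in JASPAR text format
#'
#' @param motifs list of `tmr_pwm` objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$id, m$tf), con)
    for (b in BASES)
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

## Parse one JASPAR text file into raw records (id, name, counts)
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no JASPAR record found in ", path)
  recs <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    hdr <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) hdr[2] else id
    if (i + 4 > length(lines) ||
        (h < length(heads) && heads[h + 1] < i + 5))
      stop("malformed PFM record '", id, "': expected 4 count rows")
    rows <- lines[(i + 1):(i + 4)]
    parsed <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", trimws(r))
      r <- gsub("\\[|\\]", " ", r)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
      if (anyNA(vals) || length(vals) == 0L)
        stop("malformed PFM record '", id, "': non-numeric counts")
      vals
    })
    if (length(unique(lengths(parsed))) != 1L)
      stop("malformed PFM record '", id, "': ragged count rows")
    counts <- do.call(rbind, parsed)
    rownames(counts) <- BASES
    recs[[length(recs) + 1L]] <- list(id = id, name = name, counts = counts)
  }
  recs
}

#' Load motifs from JASPAR-format PFM files
#'
#' Reads the PFM records, converts counts to probabilities with a total
#' pseudocount of 0.8 per column apportioned by the background, builds
#' log2-odds PWMs, and resolves one motif per TF by source priority
#' (manual > automatic > secondary collection), then by latest version
#' (numeric suffix of the motif id).
#'
#' @param files character vector of JASPAR text files.
#' @param tf_list optional TF names to restrict to; TFs in this list with
#'   no motif are reported in attribute `"no_motif"`.
#' @param tiers optional named character vector, motif id -> tier; records
#'   not listed default to `"manual"`.
#' @param background background base frequencies.
#' @param pseudocount total per-column pseudocount.
#' @return named list (by TF) of `tmr_pwm` objects.
#' @export
load_motifs <- function(files, tf_list = NULL, tiers = NULL,
                        background = rep(0.25, 4), pseudocount = 0.8) {
  recs <- do.call(c, lapply(files, read_jaspar_pfm))
  tier_rank <- c(manual = 1L, automatic = 2L, secondary = 3L)
  cand <- lapply(recs, function(r) {
    tier <- unname(tiers[r$id] %||% NA_character_)
    if (is.na(tier)) tier <- "manual"
    if (!tier %in% names(tier_rank)) stop("unknown tier '", tier, "'")
    version <- suppressWarnings(as.numeric(sub("^[^.]*\\.?", "", r$id)))
    list(rec = r, tier = tier, rank = tier_rank[[tier]],
         version = ifelse(is.na(version), 0, version))
  })
  tfs <- vapply(cand, function(x) x$rec$name, character(1))
  out <- list()
  for (tf in unique(tfs)) {
    sub <- cand[tfs == tf]
    ord <- order(vapply(sub, `[[`, integer(1), "rank"),
                 -vapply(sub, `[[`, numeric(1), "version"))
    best <- sub[[ord[1]]]
    out[[tf]] <- pfm_motif(best$rec$id, tf, best$rec$counts,
                           background = background, tier = best$tier,
                           pseudocount = pseudocount)
  }
  if (!is.null(tf_list)) {
    missing <- setdiff(tf_list, names(out))
    out <- out[intersect(tf_list, names(out))]
    attr(out, "no_motif") <- missing
  }
  out
}

#' Promoter windows around annotated TSSs
#'
#' The window is asymmetric around the transcription start site:
#' `[TSS - 2000, TSS + 200)` on the `+` strand and `[TSS - 200, TSS + 2000)`
#' on the `-` strand (0-based half-open genomic coordinates computed from
#' the 1-based TSS), width 2200 in both cases.  Sequences are taken from
#' `sequences` keyed by gene id and are expected transcription-oriented and
#' window-length.
#'
#' @param tss data.frame with columns `gene`, `chrom`, `pos` (1-based TSS),
#'   `strand`.
#' @param sequences named character vector (or `Biostrings::DNAStringSet`)
#'   of window sequences per gene.
#' @param upstream,downstream window extents (defaults 2000 and 200).
#' @return a `data.frame` of class `tmr_windows` with columns `gene`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open) and `sequence`.
#' @export
promoter_windows <- function(tss, sequences, upstream = 2000L,
                             downstream = 200L) {
  if (!is.character(sequences)) sequences <- as.character(sequences)
  width <- upstream + downstream
  tss0 <- tss$pos - 1L
  start <- ifelse(tss$strand == "+", tss0 - upstream, tss0 - downstream)
  end <- start + width
  seqs <- unname(sequences[tss$gene])
  if (anyNA(seqs)) stop("missing promoter sequence for some genes")
  bad <- nchar(seqs) != width
  if (any(bad))
    stop("promoter sequences must have width ", width, "; offending gene: ",
         tss$gene[which(bad)[1]])
  res <- data.frame(gene = tss$gene, chrom = tss$chrom, strand = tss$strand,
                    start = start, end = end, sequence = seqs,
                    stringsAsFactors = FALSE)
  class(res) <- c("tmr_windows", "data.frame")
  res
}

## numeric encoding A=1..T=4, N=5 (scored as background expectation)
encode_seq <- function(s) {
  code <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
                c(BASES, "N"))
  if (anyNA(code)) stop("sequence contains characters outside A/C/G/T/N")
  code
}

scan_one_orientation <- function(code, pwm5) {
  L <- ncol(pwm5)
  W <- length(code)
  if (L > W) return(numeric(0))
  scores <- numeric(W - L + 1L)
  for (j in seq_len(L))
    scores <- scores + pwm5[code[j:(j + W - L)], j]
  scores
}

#' Scan a promoter window with a PWM
#'
#' Slides the PWM over both orientations of the transcription-oriented
#' window sequence.  The raw score is the sum of PWM lookups; the relative
#' score normalizes it to the attainable range,
#' \eqn{(raw - min)/(max - min)}, so it is invariant to adding a constant
#' to every PWM cell.  Positions holding `N` contribute the background
#' expectation of the PWM column.  Hits with relative score >=
#' `min_rel_score` are reported with their 1-based start position in the
#' window and orientation (`-` hits are positions where the reverse
#' complement of the motif occurs in the window sequence).
#'
#' @param motif a `tmr_pwm`.
#' @param window one row of [promoter_windows()] output (or any list with
#'   `gene` and `sequence`).
#' @param min_rel_score relative-score threshold in (0, 1] (default 0.85).
#' @return data.frame with columns `motif_id`, `tf`, `gene`, `position`,
#'   `orientation`, `raw`, `relative`.
#' @export
scan_promoter <- function(motif, window, min_rel_score = 0.85) {
  stopifnot(inherits(motif, "tmr_pwm"),
            min_rel_score > 0, min_rel_score <= 1)
  seq <- window$sequence
  gene <- window$gene
  pwm <- motif$pwm
  L <- ncol(pwm)
  W <- nchar(seq)
  empty <- data.frame(motif_id = character(), tf = character(),
                      gene = character(), position = integer(),
                      orientation = character(), raw = numeric(),
                      relative = numeric(), stringsAsFactors = FALSE)
  if (L > W) {
    warning("motif ", motif$id, " longer than the window; no hits")
    return(empty)
  }
  pwm5 <- rbind(pwm, colSums(pwm * motif$background))
  min_att <- sum(apply(pwm, 2, min))
  max_att <- sum(apply(pwm, 2, max))
  rng <- max_att - min_att

  code_f <- encode_seq(seq)
  code_r <- rev(c(4L, 3L, 2L, 1L, 5L)[code_f])   # reverse complement
  raw_f <- scan_one_orientation(code_f, pwm5)
  raw_r <- scan_one_orientation(code_r, pwm5)
  rel_f <- (raw_f - min_att) / rng
  rel_r <- (raw_r - min_att) / rng

  hit_f <- which(rel_f >= min_rel_score)
  hit_r <- which(rel_r >= min_rel_score)
  res <- rbind(
    if (length(hit_f))
      data.frame(motif_id = motif$id, tf = motif$tf, gene = gene,
                 position = hit_f, orientation = "+",
                 raw = raw_f[hit_f], relative = rel_f[hit_f],
                 stringsAsFactors = FALSE),
    if (length(hit_r))
      data.frame(motif_id = motif$id, tf = motif$tf, gene = gene,
                 position = W - (hit_r + L - 1L) + 1L, orientation = "-",
                 raw = raw_r[hit_r], relative = rel_r[hit_r],
                 stringsAsFactors = FALSE))
  if (is.null(res)) empty else res[order(res$position), , drop = FALSE]
}

#' Scan all promoter windows with all motifs
#'
#' @param motifs named list of `tmr_pwm` (by TF).
#' @param windows a [promoter_windows()] table.
#' @param min_rel_score relative-score threshold.
#' @return combined hit table (columns of [scan_promoter()], with `tf` as
#'   the source TF and `gene` the promoter's gene).
#' @export
scan_promoters <- function(motifs, windows, min_rel_score = 0.85) {
  out <- list()
  for (m in motifs)
    for (r in seq_len(nrow(windows)))
      out[[length(out) + 1L]] <-
        scan_promoter(m, windows[r, , drop = FALSE], min_rel_score)
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(motif_id = character(), tf = character(),
                      gene = character(), position = integer(),
                      orientation = character(), raw = numeric(),
                      relative = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Build the dual-support TMR-TMR graph
#'
#' Restricts motif hits to source and target in the consensus TMR list and
#' keeps a directed edge source -> target only when the pair also carries a
#' mutual-information edge in at least one cohort network.  Per-cohort
#' support flags are recorded; when a pair has several hits the best
#' relative score is kept.  Degrees are computed over the retained
#' (MI-supported) edges for all consensus nodes.
#'
#' @param hits a hit table from [scan_promoters()].
#' @param networks list of `tmr_mi_network` (one per cohort, named).
#' @param consensus character vector of consensus TMR ids.
#' @return an object of class `tmr_graph` with fields `edges` (source,
#'   target, relative, position, orientation, one `support_*` flag per
#'   cohort), `nodes`, `out_degree`, `in_degree`.
#' @export
build_tmr_graph <- function(hits, networks, consensus) {
  if (is.null(names(networks)))
    names(networks) <- paste0("cohort", seq_along(networks))
  hits <- hits[hits$tf %in% consensus & hits$gene %in% consensus, ,
               drop = FALSE]
  ## best hit per (source, target)
  if (nrow(hits) > 0L) {
    key <- paste(hits$tf, hits$gene)
    hits <- hits[order(key, -hits$relative), , drop = FALSE]
    hits <- hits[!duplicated(paste(hits$tf, hits$gene)), , drop = FALSE]
  }
  edge_key <- function(net) paste(net$edges$regulator, net$edges$target)
  support <- lapply(networks, function(net)
    paste(hits$tf, hits$gene) %in% edge_key(net))
  any_support <- Reduce(`|`, support) | logical(nrow(hits))
  edges <- data.frame(source = hits$tf, target = hits$gene,
                      relative = hits$relative, position = hits$position,
                      orientation = hits$orientation,
                      stringsAsFactors = FALSE)
  for (nm in names(networks)) edges[[paste0("support_", nm)]] <- support[[nm]]
  edges <- edges[any_support, , drop = FALSE]
  rownames(edges) <- NULL
  out_deg <- setNames(integer(length(consensus)), consensus)
  in_deg <- out_deg
  if (nrow(edges) > 0L) {
    ot <- table(factor(edges$source, levels = consensus))
    it <- table(factor(edges$target, levels = consensus))
    out_deg[] <- as.integer(ot)
    in_deg[] <- as.integer(it)
  }
  structure(list(edges = edges, nodes = consensus,
                 out_degree = out_deg, in_degree = in_deg),
            class = "tmr_graph")
}

#' @export
print.tmr_graph <- function(x, ...) {
  cat(sprintf("<tmr_graph> %d nodes, %d dual-support edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Call top-of-cascade hubs by the degree-quantile rule
#'
#' A node is a hub iff its out-degree is at least the upper quartile (Q3)
#' of the out-degree distribution and its in-degree is at most the lower
#' quartile (Q1) of the in-degree distribution, both quartiles computed
#' with linear interpolation over all graph nodes and with inclusive
#' boundaries.
#'
#' @param graph a `tmr_graph`.
#' @return data.frame of class `tmr_hubs` with columns `node`,
#'   `out_degree`, `in_degree`, `hub`, sorted by out-degree descending then
#'   in-degree ascending; quartiles attached as attributes `q3_out` and
#'   `q1_in`.
#' @export
call_hubs <- function(graph) {
  stopifnot(inherits(graph, "tmr_graph"))
  if (length(graph$nodes) == 0L) stop("graph has no nodes")
  out <- graph$out_degree
  inn <- graph$in_degree
  q3 <- quantile_lin(out, 0.75)
  q1 <- quantile_lin(inn, 0.25)
  if (nrow(graph$edges) == 0L) {
    warning("graph has no edges; no hub called")
    hub <- rep(FALSE, length(out))
  } else {
    if (length(unique(c(out, inn))) == 1L)
      warning("all degrees equal; every node satisfies the hub rule")
    hub <- out >= q3 & inn <= q1
  }
  res <- data.frame(node = graph$nodes, out_degree = as.integer(out),
                    in_degree = as.integer(inn), hub = hub,
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(-res$out_degree, res$in_degree, res$node), ]
  rownames(res) <- NULL
  attr(res, "q3_out") <- q3
  attr(res, "q1_in") <- q1
  class(res) <- c("tmr_hubs", "data.frame")
  res
}

#' Export the TMR graph
#'
#' `write_tmr_graph` writes the edge list with support flags;
#' `tmr_adjacency` returns (and optionally writes) the dense source x
#' target adjacency matrix for external chord-style plotting.
#'
#' @param graph a `tmr_graph`.
#' @param path output TSV path.
#' @return invisibly `path` (writer) or the adjacency matrix.
#' @export
write_tmr_graph <- function(graph, path) {
  write.table(graph$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_tmr_graph
#' @export
tmr_adjacency <- function(graph, path = NULL) {
  adj <- matrix(0L, length(graph$nodes), length(graph$nodes),
                dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0L)
    adj[cbind(graph$edges$source, graph$edges$target)] <- 1L
  if (!is.null(path))
    write.table(data.frame(source = rownames(adj), adj,
                           check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  adj
}
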