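#' Configuration for the two-cohort simulator
#'
#' Defines the study conditions emulated by the generator: a shared
#' ground-truth regulatory network drives a count-like cohort (bulk RNA-seq
#' style, negative-binomial counts at a sampled sequencing depth) and a
#' log-intensity cohort (array style, Gaussian on the log2 scale).  A subset
#' of regulators is "active": their latent activity is shifted in tumor
#' samples, in units of the latent-activity SD.
#'
#' @param n_genes total number of genes, including the `n_tfs` regulator
#'   genes themselves.
#' @param n_tfs number of transcription factors.
#' @param targets_per_tf regulon size planted for each TF; regulons are
#'   disjoint subsets of the non-TF genes (so `targets_per_tf * n_tfs`
#'   must not exceed `n_genes - n_tfs`); the only TF-to-TF regulation is
#'   the planted cascade (see `tf_fanout`).
#' @param n_active number of TFs with tumor-shifted activity.
#' @param activity_shift tumor shift of active-TF latent activity,
#'   dimensionless (units of the N(0,1) activity SD).
#' @param n_tumor,n_normal integer vectors of length 2: samples per group in
#'   each cohort.
#' @param noise_sd per-cohort SD of target-level log2 noise.
#' @param platform per-cohort platform kind, `"counts"` or `"intensity"`.
#' @param depth_range sequencing-depth range (uniform) for counts cohorts.
#' @param dispersion negative-binomial dispersion for counts cohorts.
#' @param tf_readout_cor correlation between a TF's transcript and its latent
#'   activity (the transcript is an imperfect readout of protein activity).
#' @param baseline_log2_mean,baseline_log2_sd gene-level baseline abundance
#'   on the log2 scale, shared across cohorts.
#' @param strength_range range of planted regulation strengths in (0,1].
#' @param sign_prob_pos probability that a planted regulation is activating.
#' @param tf_fanout number of other TFs regulated by the first active TF
#'   (the planted top-of-cascade regulator); its motif is planted in their
#'   promoters.
#' @param promoter_length promoter window length in nt.
#' @param motif_length length of the synthetic binding motifs.
#' @param seed RNG seed; a fixed seed makes all outputs bit-reproducible.
#' @return a list of class `tmr_sim_config`.
#' @export
simulation_config <- function(n_genes = 200L, n_tfs = 10L,
                              targets_per_tf = 19L,
                              n_active = 3L, activity_shift = 2.0,
                              n_tumor = c(30L, 30L), n_normal = c(30L, 30L),
                              noise_sd = c(0.5, 0.5),
                              platform = c("counts", "intensity"),
                              depth_range = c(8e5, 1.2e6),
                              dispersion = 0.1,
                              tf_readout_cor = 0.8,
                              baseline_log2_mean = 8,
                              baseline_log2_sd = 0.5,
                              strength_range = c(0.6, 1),
                              sign_prob_pos = 0.5,
                              tf_fanout = 2L,
                              promoter_length = 2200L,
                              motif_length = 12L,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              n_active = as.integer(n_active),
              activity_shift = activity_shift,
              n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              noise_sd = noise_sd, platform = platform,
              depth_range = depth_range, dispersion = dispersion,
              tf_readout_cor = tf_readout_cor,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              strength_range = strength_range,
              sign_prob_pos = sign_prob_pos,
              tf_fanout = as.integer(tf_fanout),
              promoter_length = as.integer(promoter_length),
              motif_length = as.integer(motif_length),
              seed = as.integer(seed))
  if (any(c(cfg$n_genes, cfg$n_tfs, cfg$targets_per_tf,
            cfg$n_tumor, cfg$n_normal) <= 0L))
    stop("all counts in the simulation config must be positive")
  if (cfg$targets_per_tf * cfg$n_tfs > cfg$n_genes)
    stop("targets_per_tf * n_tfs exceeds n_genes: regulons cannot be disjoint")
  if (cfg$n_active > cfg$n_tfs) stop("n_active exceeds n_tfs")
  if (cfg$tf_fanout > cfg$n_tfs - 1L) stop("tf_fanout exceeds n_tfs - 1")
  class(cfg) <- "tmr_sim_config"
  cfg
}

## Build the shared ground truth: regulons, signs, strengths, active set,
## motifs, planted promoter sites, TSS table.  Consumes the current RNG.
build_ground_truth <- function(cfg) {
  tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  n_other <- cfg$n_genes - cfg$n_tfs
  gene_ids <- c(tf_ids, if (n_other > 0) sprintf("G%04d", seq_len(n_other)))
  active <- tf_ids[seq_len(cfg$n_active)]
  cascade_tf <- if (cfg$n_active > 0L) active[1L] else tf_ids[1L]
  fanout_tfs <- setdiff(tf_ids, cascade_tf)[seq_len(cfg$tf_fanout)]

  ## Disjoint regulon assignment over the non-TF gene pool, so a TF
  ## transcript is a clean readout of its own activity.  The only planted
  ## TF->TF regulation is the cascade: the top-of-cascade TF additionally
  ## drives the fan-out TFs (transcript and motif site).
  pool <- sample(if (n_other > 0) setdiff(gene_ids, tf_ids) else character())
  if (cfg$targets_per_tf * cfg$n_tfs > length(pool))
    stop("configuration error: targets_per_tf * n_tfs exceeds the ",
         "available non-TF gene pool")
  regulons <- vector("list", cfg$n_tfs)
  names(regulons) <- tf_ids
  cursor <- 1L
  for (tf in tf_ids) {
    block <- pool[cursor:(cursor + cfg$targets_per_tf - 1L)]
    sgn <- ifelse(runif(cfg$targets_per_tf) < cfg$sign_prob_pos, 1, -1)
    regulons[[tf]] <- data.frame(
      target = block,
      sign = sgn,
      strength = runif(cfg$targets_per_tf, cfg$strength_range[1],
                       cfg$strength_range[2]),
      stringsAsFactors = FALSE)
    cursor <- cursor + cfg$targets_per_tf
  }
  if (length(fanout_tfs) > 0L)
    regulons[[cascade_tf]] <- rbind(
      regulons[[cascade_tf]],
      data.frame(target = fanout_tfs, sign = 1,
                 ## master regulators drive their downstream TFs strongly
                 strength = rep(cfg$strength_range[2], length(fanout_tfs)),
                 stringsAsFactors = FALSE))

  motifs <- make_motif_set(tf_ids, length = cfg$motif_length)

  ## plant the cascade TF's motif in the promoters of the TFs it regulates
  sites <- data.frame(gene = character(), motif_id = character(),
                      tf = character(), offset = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  L <- cfg$motif_length
  for (tgt in fanout_tfs) {
    off <- sample.int(cfg$promoter_length - L + 1L, 1L)
    sites <- rbind(sites, data.frame(
      gene = tgt, motif_id = motifs[[cascade_tf]]$id, tf = cascade_tf,
      offset = off, strand = sample(c("+", "-"), 1L),
      stringsAsFactors = FALSE))
  }

  tss <- data.frame(gene = gene_ids, chrom = "chr1",
                    pos = 100000L + (seq_along(gene_ids) - 1L) * 10000L,
                    strand = sample(c("+", "-"), length(gene_ids),
                                    replace = TRUE),
                    stringsAsFactors = FALSE)

  structure(
    list(regulators = tf_ids, genes = gene_ids, regulons = regulons,
         active_tfs = setNames(rep(cfg$activity_shift, length(active)),
                               active),
         cascade_tf = cascade_tf, fanout_tfs = fanout_tfs,
         motifs = motifs, planted_sites = sites, tss_table = tss,
         baseline = setNames(rnorm(length(gene_ids), cfg$baseline_log2_mean,
                                   cfg$baseline_log2_sd), gene_ids),
         activities = list()),
    class = "tmr_ground_truth")
}

simulate_one_cohort <- function(truth, cfg, i) {
  n_t <- cfg$n_tumor[i]; n_n <- cfg$n_normal[i]
  n <- n_t + n_n
  groups <- c(rep("tumor", n_t), rep("normal", n_n))
  samples <- sprintf("C%d_S%03d", i, seq_len(n))

  A <- matrix(rnorm(cfg$n_tfs * n), nrow = cfg$n_tfs,
              dimnames = list(truth$regulators, samples))
  for (tf in names(truth$active_tfs))
    A[tf, groups == "tumor"] <- A[tf, groups == "tumor"] +
      truth$active_tfs[[tf]]

  sig <- matrix(0, nrow = length(truth$genes), ncol = n,
                dimnames = list(truth$genes, samples))
  for (tf in truth$regulators) {
    reg <- truth$regulons[[tf]]
    for (r in seq_len(nrow(reg)))
      sig[reg$target[r], ] <- sig[reg$target[r], ] +
        reg$sign[r] * reg$strength[r] * A[tf, ]
  }
  ## TF transcripts: noisy readout of own activity (marginal SD 1 before
  ## cascade input), with correlation tf_readout_cor to the latent activity
  rho <- cfg$tf_readout_cor
  for (tf in truth$regulators)
    sig[tf, ] <- sig[tf, ] + rho * A[tf, ] + sqrt(1 - rho^2) * rnorm(n)
  ## non-TF targets: additive measurement noise
  non_tf <- setdiff(truth$genes, truth$regulators)
  if (length(non_tf) > 0 && cfg$noise_sd[i] > 0)
    sig[non_tf, ] <- sig[non_tf, ] +
      matrix(rnorm(length(non_tf) * n, sd = cfg$noise_sd[i]),
             nrow = length(non_tf))

  logexpr <- sig + truth$baseline[truth$genes]

  if (cfg$platform[i] == "counts") {
    depth <- runif(n, cfg$depth_range[1], cfg$depth_range[2])
    prop <- 2^logexpr
    prop <- sweep(prop, 2, colSums(prop), "/")
    mu <- sweep(prop, 2, depth, "*")
    vals <- if (cfg$dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
             nrow = nrow(mu), dimnames = dimnames(mu))
    } else {
      matrix(stats::rpois(length(mu), lambda = mu),
             nrow = nrow(mu), dimnames = dimnames(mu))
    }
    list(mat = expression_matrix(vals, groups, "counts"), activity = A)
  } else {
    list(mat = expression_matrix(logexpr, groups, "intensity"), activity = A)
  }
}

#' Simulate two expression cohorts with shared planted truth
#'
#' Draws latent TF activities per sample (standard normal, plus the planted
#' tumor shift for active TFs), propagates them through the planted signed
#' regulons to target log2 expression, and renders the two cohorts on their
#' respective platforms: the counts cohort exponentiates to per-gene means
#' and draws negative-binomial counts at a sampled depth; the intensity
#' cohort returns log2-scale values directly.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `cohort_a`, `cohort_b` (see
#'   [expression_matrix()]) and `truth`, the ground truth holding regulons,
#'   active TFs, planted promoter sites, the TSS table and the simulated
#'   latent activity matrices (`truth$activities`).
#' @export
simulate_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "tmr_sim_config"))
  with_seed(cfg$seed, {
    truth <- build_ground_truth(cfg)
    a <- simulate_one_cohort(truth, cfg, 1L)
    b <- simulate_one_cohort(truth, cfg, 2L)
    truth$activities <- list(a$activity, b$activity)
    list(cohort_a = a$mat, cohort_b = b$mat, truth = truth)
  })
}

#' Emit promoter sequences and the TSS table
#'
#' Generates an i.i.d. uniform A/C/G/T background sequence per gene spanning
#' the full asymmetric promoter window, then overwrites planted sites with
#' the motif consensus (reverse-complemented when the planted strand is
#' `-`).  Sequences are transcription-oriented, matching the window
#' convention used by the scanner.
#'
#' @param truth a ground truth from [simulate_cohorts()].
#' @param cfg the matching [simulation_config()].
#' @param fasta optional output FASTA path.
#' @param tss optional output TSS TSV path (gene, chrom, pos, strand).
#' @return list with `sequences` (named character vector) and `tss_table`.
#' @export
emit_promoters <- function(truth, cfg, fasta = NULL, tss = NULL) {
  stopifnot(inherits(truth, "tmr_ground_truth"))
  if (length(truth$motifs) == 0L) stop("motif set is empty")
  W <- cfg$promoter_length
  seqs <- with_seed(derive_seed(cfg$seed, 77L), {
    s <- vapply(truth$genes, function(g)
      paste(sample(c("A", "C", "G", "T"), W, replace = TRUE), collapse = ""),
      character(1))
    names(s) <- truth$genes
    s
  })
  sites <- truth$planted_sites
  for (r in seq_len(nrow(sites))) {
    cons <- motif_consensus(truth$motifs[[sites$tf[r]]])
    if (sites$strand[r] == "-") cons <- revcomp(cons)
    L <- nchar(cons)
    if (sites$offset[r] < 1L || sites$offset[r] + L - 1L > W)
      stop("planted site at offset ", sites$offset[r],
           " falls outside the promoter window")
    substr(seqs[[sites$gene[r]]], sites$offset[r],
           sites$offset[r] + L - 1L) <- cons
  }
  if (!is.null(fasta)) {
    dna <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(dna, fasta)
  }
  if (!is.null(tss))
    write.table(truth$tss_table, tss, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(sequences = seqs, tss_table = truth$tss_table)
}

#' Serialize / restore ground truth as JSON
#'
#' @param truth a ground truth object.
#' @param path output JSON path.
#' @return `write_ground_truth` invisibly returns `path`;
#'   `read_ground_truth` returns the deserialized list (motif matrices and
#'   latent activities are restored as plain matrices).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "tmr_ground_truth"))
  out <- unclass(truth)
  out$motifs <- lapply(truth$motifs, function(m)
    list(id = m$id, tf = m$tf, counts = m$counts))
  ## named atomic vectors lose their names as JSON arrays; emit objects
  out$active_tfs <- as.list(truth$active_tfs)
  out$baseline <- as.list(truth$baseline)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$motifs <- lapply(x$motifs, function(m) {
    cts <- as.matrix(m$counts)
    rownames(cts) <- c("A", "C", "G", "T")
    pfm_motif(m$id, m$tf, cts)
  })
  x$regulons <- lapply(x$regulons, as.data.frame)
  x$active_tfs <- unlist(x$active_tfs)
  x$planted_sites <- as.data.frame(x$planted_sites)
  x$tss_table <- as.data.frame(x$tss_table)
  x$baseline <- unlist(x$baseline)
  x$activities <- lapply(x$activities, as.matrix)
  class(x) <- "tmr_ground_truth"
  x
}
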