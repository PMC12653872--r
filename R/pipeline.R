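#' Pipeline configuration
#'
#' Bundles all stage parameters and output locations for
#' [run_pipeline()].  Network significance cutoffs default to the
#' cohort-size rule used throughout: `1e-8` for cohorts with at least
#' `large_cohort_n` samples, `1e-4` otherwise (small cohorts need the more
#' lenient threshold to retain statistical power).
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param sim a [simulation_config()] for the `simulate` stage (defaults to
#'   the standard synthetic study conditions with the master seed).
#' @param p_cutoff length-2 numeric of per-cohort MI significance levels,
#'   or `NULL` for the cohort-size rule.
#' @param large_cohort_n sample count from which the strict `1e-8` cutoff
#'   applies.
#' @param n_boot bootstrap depth for network consolidation.
#' @param n_null null size for MI threshold calibration.
#' @param min_regulon minimum regulon size.
#' @param n_perm activity-null permutations.
#' @param min_rel_score PWM relative-score threshold.
#' @param alpha FDR level for consensus and enrichment calls.
#' @param sweep_grid data.frame (`p_cutoff`, `n_boot`) for the sensitivity
#'   sweep; default 2x2 desk-scale grid.
#' @return a list of class `tmr_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = NULL,
                            p_cutoff = NULL, large_cohort_n = 100L,
                            n_boot = 50L, n_null = 1e4,
                            min_regulon = 10L, n_perm = 1000L,
                            min_rel_score = 0.85, alpha = 0.05,
                            sweep_grid = expand.grid(
                              p_cutoff = c(1e-2, 1e-4),
                              n_boot = c(20L, 50L))) {
  sim <- sim %||% simulation_config(seed = derive_seed(seed, 11L))
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 p_cutoff = p_cutoff, large_cohort_n = large_cohort_n,
                 n_boot = as.integer(n_boot), n_null = n_null,
                 min_regulon = as.integer(min_regulon),
                 n_perm = as.integer(n_perm),
                 min_rel_score = min_rel_score, alpha = alpha,
                 sweep_grid = sweep_grid),
            class = "tmr_pipeline_config")
}

PIPELINE_STAGES <- c("simulate", "de", "network", "activity", "meta",
                     "motifscan", "graph", "hubs", "ora", "sweep")

apath <- function(cfg, ...) file.path(cfg$out_dir, ...)

read_manifest <- function(cfg) {
  p <- apath(cfg, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p) else list()
}

record_stage <- function(cfg, stage, params, inputs, outputs) {
  man <- read_manifest(cfg)
  man[[stage]] <- list(
    stage = stage, params = params,
    seed = cfg$seed,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = outputs)
  jsonlite::write_json(man, apath(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

stage_current <- function(cfg, stage, params, inputs, outputs, force) {
  if (force) return(FALSE)
  if (!all(file.exists(outputs))) return(FALSE)
  man <- read_manifest(cfg)
  ent <- man[[stage]]
  if (is.null(ent)) return(FALSE)
  same_params <- identical(jsonlite::toJSON(params, auto_unbox = TRUE,
                                            digits = NA),
                           jsonlite::toJSON(ent$params, auto_unbox = TRUE,
                                            digits = NA))
  same_inputs <- identical(as.list(tools::md5sum(inputs)), ent$inputs)
  isTRUE(same_params) && isTRUE(same_inputs) && identical(ent$seed %||% NA,
                                                          cfg$seed)
}

require_artifact <- function(paths, stage_needed) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("missing artifact ", missing[1],
         ": run stage '", stage_needed, "' first", call. = FALSE)
}

#' Run the consensus-TMR pipeline
#'
#' Executes the requested stages in dependency order
#' (`simulate -> de -> network -> activity -> meta -> motifscan -> graph ->
#' hubs -> ora -> sweep`), writing every artifact as TSV/FASTA/JSON under
#' `cfg$out_dir` together with a manifest recording each stage's
#' parameters, seed and input checksums.  Re-runs skip stages whose outputs
#' are up to date (same parameters, same input checksums) unless
#' `force = TRUE`.  The whole run is deterministic under a fixed
#' configuration and seed.
#'
#' @param cfg a [pipeline_config()].
#' @param stages character vector of stage names, or `"all"`.
#' @param force rerun stages even when up to date.
#' @return invisibly, a list of class `tmr_pipeline_result` with the key
#'   result tables (`consensus`, `meta_regulators`, `effect_meta`, `hubs`)
#'   and all artifact paths.
#' @export
run_pipeline <- function(cfg, stages = "all", force = FALSE) {
  stopifnot(inherits(cfg, "tmr_pipeline_config"))
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0L) stop("unknown stage: ", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  paths <- list(
    cohort_a = apath(cfg, "cohort_a.tsv"),
    cohort_a_samples = apath(cfg, "cohort_a.samples.tsv"),
    cohort_b = apath(cfg, "cohort_b.tsv"),
    cohort_b_samples = apath(cfg, "cohort_b.samples.tsv"),
    truth = apath(cfg, "truth.json"),
    promoters = apath(cfg, "promoters.fasta"),
    tss = apath(cfg, "tss.tsv"),
    motifs = apath(cfg, "motifs.jaspar"),
    regulators = apath(cfg, "regulators.txt"),
    collections = apath(cfg, "collections.gmt"),
    norm_a = apath(cfg, "norm_a.tsv"),
    norm_a_samples = apath(cfg, "norm_a.samples.tsv"),
    norm_b = apath(cfg, "norm_b.tsv"),
    norm_b_samples = apath(cfg, "norm_b.samples.tsv"),
    de_a = apath(cfg, "de_a.tsv"),
    de_b = apath(cfg, "de_b.tsv"),
    network_a = apath(cfg, "network_a.tsv"),
    network_b = apath(cfg, "network_b.tsv"),
    regulons_a = apath(cfg, "regulons_a.tsv"),
    regulons_b = apath(cfg, "regulons_b.tsv"),
    activity_a = apath(cfg, "activity_a.tsv"),
    activity_b = apath(cfg, "activity_b.tsv"),
    meta_regulators = apath(cfg, "meta_regulators.tsv"),
    consensus = apath(cfg, "consensus_tmrs.txt"),
    effect_meta = apath(cfg, "effect_meta.tsv"),
    hits = apath(cfg, "motif_hits.tsv"),
    graph = apath(cfg, "tmr_graph.tsv"),
    adjacency = apath(cfg, "tmr_adjacency.tsv"),
    hubs = apath(cfg, "hubs.tsv"),
    ora_meta = apath(cfg, "ora_meta_regulon.tsv"),
    bubble = apath(cfg, "ora_bubble.tsv"),
    sweep_dir = apath(cfg, "sweep"))

  log_stage <- function(stage, what) {
    t0 <- Sys.time()
    message(sprintf("[%s] %s", stage, what))
    t0
  }
  done_stage <- function(stage, t0)
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))

  if ("simulate" %in% stages) {
    outs <- unlist(paths[c("cohort_a", "cohort_a_samples", "cohort_b",
                           "cohort_b_samples", "truth", "promoters", "tss",
                           "motifs", "regulators", "collections")])
    params <- unclass(cfg$sim)
    if (!stage_current(cfg, "simulate", params, character(), outs, force)) {
      t0 <- log_stage("simulate", "generating two cohorts + promoters")
      sim <- simulate_cohorts(cfg$sim)
      write_expression(sim$cohort_a, paths$cohort_a)
      write_expression(sim$cohort_b, paths$cohort_b)
      write_ground_truth(sim$truth, paths$truth)
      emit_promoters(sim$truth, cfg$sim, fasta = paths$promoters,
                     tss = paths$tss)
      write_jaspar_pfm(sim$truth$motifs, paths$motifs)
      writeLines(sim$truth$regulators, paths$regulators)
      ## synthetic gene-set collections: planted regulon targets plus
      ## size-matched random sets drawn from the simulated gene pool
      sets <- lapply(sim$truth$regulons, function(r) r$target)
      names(sets) <- paste0("PLANTED_", names(sets))
      rand <- with_seed(derive_seed(cfg$seed, 21L),
        lapply(1:5, function(i)
          sample(sim$truth$genes, length(sets[[1]]))))
      names(rand) <- paste0("RANDOM_", seq_along(rand))
      write_gmt(c(sets, rand), paths$collections)
      record_stage(cfg, "simulate", params, character(), outs)
      done_stage("simulate", t0)
    } else message("[simulate] up to date, skipping")
  }

  if ("de" %in% stages) {
    ins <- unlist(paths[c("cohort_a", "cohort_a_samples", "cohort_b",
                          "cohort_b_samples")])
    require_artifact(ins, "simulate")
    outs <- unlist(paths[c("norm_a", "norm_a_samples", "norm_b",
                           "norm_b_samples", "de_a", "de_b")])
    params <- list(alpha = cfg$alpha)
    if (!stage_current(cfg, "de", params, ins, outs, force)) {
      t0 <- log_stage("de", "filtering, normalizing, testing")
      raw_a <- read_expression(paths$cohort_a, paths$cohort_a_samples,
                               "counts")
      raw_b <- read_expression(paths$cohort_b, paths$cohort_b_samples,
                               "intensity")
      norm_a <- normalize_counts(filter_counts(raw_a))
      norm_b <- filter_intensity(raw_b)
      write_expression(norm_a, paths$norm_a)
      write_expression(norm_b, paths$norm_b)
      write_de(differential_expression(norm_a), paths$de_a)
      write_de(differential_expression(norm_b), paths$de_b)
      record_stage(cfg, "de", params, ins, outs)
      done_stage("de", t0)
    } else message("[de] up to date, skipping")
  }

  if ("network" %in% stages) {
    ins <- unlist(paths[c("norm_a", "norm_a_samples", "norm_b",
                          "norm_b_samples", "regulators")])
    require_artifact(ins, "de")
    outs <- unlist(paths[c("network_a", "network_b")])
    norm_a <- read_expression(paths$norm_a, paths$norm_a_samples, "logcpm")
    norm_b <- read_expression(paths$norm_b, paths$norm_b_samples,
                              "intensity")
    pc <- cfg$p_cutoff %||% ifelse(
      c(ncol(norm_a$values), ncol(norm_b$values)) >= cfg$large_cohort_n,
      1e-8, 1e-4)
    params <- list(p_cutoff = pc, n_boot = cfg$n_boot, n_null = cfg$n_null)
    if (!stage_current(cfg, "network", params, ins, outs, force)) {
      t0 <- log_stage("network", sprintf(
        "MI networks (p = %g / %g, %d bootstraps)", pc[1], pc[2],
        cfg$n_boot))
      regs <- readLines(paths$regulators)
      net_a <- consolidate_bootstraps(norm_a, regs, pc[1], cfg$n_boot,
                                      seed = derive_seed(cfg$seed, 101L),
                                      n_null = cfg$n_null)
      net_b <- consolidate_bootstraps(norm_b, regs, pc[2], cfg$n_boot,
                                      seed = derive_seed(cfg$seed, 102L),
                                      n_null = cfg$n_null)
      write_network(net_a, paths$network_a)
      write_network(net_b, paths$network_b)
      record_stage(cfg, "network", params, ins, outs)
      done_stage("network", t0)
    } else message("[network] up to date, skipping")
  }

  if ("activity" %in% stages) {
    ins <- unlist(paths[c("network_a", "network_b", "norm_a", "norm_b",
                          "norm_a_samples", "norm_b_samples",
                          "de_a", "de_b")])
    require_artifact(ins, "network")
    outs <- unlist(paths[c("regulons_a", "regulons_b", "activity_a",
                           "activity_b")])
    params <- list(min_regulon = cfg$min_regulon, n_perm = cfg$n_perm)
    if (!stage_current(cfg, "activity", params, ins, outs, force)) {
      t0 <- log_stage("activity", "regulons + NES scoring")
      norm_a <- read_expression(paths$norm_a, paths$norm_a_samples,
                                "logcpm")
      norm_b <- read_expression(paths$norm_b, paths$norm_b_samples,
                                "intensity")
      reg_a <- build_regulons(read_network(paths$network_a), norm_a,
                              cfg$min_regulon)
      reg_b <- build_regulons(read_network(paths$network_b), norm_b,
                              cfg$min_regulon)
      write_regulons(reg_a, paths$regulons_a)
      write_regulons(reg_b, paths$regulons_b)
      act_a <- score_activity(reg_a, read_de(paths$de_a), cfg$n_perm,
                              seed = derive_seed(cfg$seed, 201L),
                              mat = norm_a)
      act_b <- score_activity(reg_b, read_de(paths$de_b), cfg$n_perm,
                              seed = derive_seed(cfg$seed, 202L),
                              mat = norm_b)
      write.table(act_a, paths$activity_a, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(act_b, paths$activity_b, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      record_stage(cfg, "activity", params, ins, outs)
      done_stage("activity", t0)
    } else message("[activity] up to date, skipping")
  }

  if ("meta" %in% stages) {
    ins <- unlist(paths[c("activity_a", "activity_b", "de_a", "de_b")])
    require_artifact(ins, "activity")
    outs <- unlist(paths[c("meta_regulators", "consensus", "effect_meta")])
    params <- list(alpha = cfg$alpha)
    if (!stage_current(cfg, "meta", params, ins, outs, force)) {
      t0 <- log_stage("meta", "Fisher + IVW meta-analysis")
      act_a <- read.delim(paths$activity_a, stringsAsFactors = FALSE)
      act_b <- read.delim(paths$activity_b, stringsAsFactors = FALSE)
      meta <- consensus_tmrs(act_a, act_b, cfg$alpha)
      write.table(meta, paths$meta_regulators, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      writeLines(meta$regulator[meta$consensus], paths$consensus)
      eff <- ivw_meta(read_de(paths$de_a), read_de(paths$de_b))
      write.table(eff, paths$effect_meta, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      record_stage(cfg, "meta", params, ins, outs)
      done_stage("meta", t0)
    } else message("[meta] up to date, skipping")
  }

  if ("motifscan" %in% stages) {
    ins <- unlist(paths[c("motifs", "promoters", "tss", "consensus")])
    require_artifact(ins, "meta")
    outs <- unlist(paths["hits"])
    params <- list(min_rel_score = cfg$min_rel_score)
    if (!stage_current(cfg, "motifscan", params, ins, outs, force)) {
      t0 <- log_stage("motifscan", "PWM scan of consensus-TMR promoters")
      consensus <- readLines(paths$consensus)
      motifs <- load_motifs(paths$motifs, tf_list = consensus)
      seqs <- as.character(Biostrings::readDNAStringSet(paths$promoters))
      names(seqs) <- sub("\\s.*", "", names(seqs))
      tss <- read.delim(paths$tss, stringsAsFactors = FALSE)
      tss <- tss[tss$gene %in% consensus, , drop = FALSE]
      wins <- promoter_windows(tss, seqs)
      hits <- scan_promoters(motifs, wins, cfg$min_rel_score)
      write.table(hits, paths$hits, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      record_stage(cfg, "motifscan", params, ins, outs)
      done_stage("motifscan", t0)
    } else message("[motifscan] up to date, skipping")
  }

  if ("graph" %in% stages) {
    ins <- unlist(paths[c("hits", "network_a", "network_b", "consensus")])
    require_artifact(ins, "motifscan")
    outs <- unlist(paths[c("graph", "adjacency")])
    params <- list()
    if (!stage_current(cfg, "graph", params, ins, outs, force)) {
      t0 <- log_stage("graph", "dual-support TMR-TMR graph")
      hits <- read.delim(paths$hits, stringsAsFactors = FALSE)
      nets <- list(a = read_network(paths$network_a),
                   b = read_network(paths$network_b))
      graph <- build_tmr_graph(hits, nets, readLines(paths$consensus))
      write_tmr_graph(graph, paths$graph)
      tmr_adjacency(graph, paths$adjacency)
      record_stage(cfg, "graph", params, ins, outs)
      done_stage("graph", t0)
    } else message("[graph] up to date, skipping")
  }

  if ("hubs" %in% stages) {
    ins <- unlist(paths[c("graph", "consensus")])
    require_artifact(ins, "graph")
    outs <- unlist(paths["hubs"])
    params <- list()
    if (!stage_current(cfg, "hubs", params, ins, outs, force)) {
      t0 <- log_stage("hubs", "degree-quantile hub calls")
      graph <- rebuild_graph_from_files(paths)
      hubs <- call_hubs(graph)
      write.table(hubs, paths$hubs, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      record_stage(cfg, "hubs", params, ins, outs)
      done_stage("hubs", t0)
    } else message("[hubs] up to date, skipping")
  }

  if ("ora" %in% stages) {
    ins <- unlist(paths[c("regulons_a", "regulons_b", "consensus",
                          "collections", "norm_a", "norm_b")])
    require_artifact(ins, "meta")
    outs <- unlist(paths[c("ora_meta", "bubble")])
    params <- list(alpha = cfg$alpha)
    if (!stage_current(cfg, "ora", params, ins, outs, force)) {
      t0 <- log_stage("ora", "meta-regulon + per-TMR enrichment")
      reg_a <- read_regulons(paths$regulons_a)
      reg_b <- read_regulons(paths$regulons_b)
      consensus <- readLines(paths$consensus)
      collection <- read_gmt(paths$collections)
      uni_a <- read.delim(paths$norm_a, check.names = FALSE)[[1]]
      uni_b <- read.delim(paths$norm_b, check.names = FALSE)[[1]]
      mr <- meta_regulon(reg_a, reg_b, consensus)
      meta <- combine_ora(
        ora(intersect(mr, uni_a), collection, uni_a),
        ora(intersect(mr, uni_b), collection, uni_b), cfg$alpha)
      write.table(meta, paths$ora_meta, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      regulon_enrichment_matrix(reg_a, reg_b, consensus, collection,
                                uni_a, uni_b, cfg$alpha,
                                path = paths$bubble)
      record_stage(cfg, "ora", params, ins, outs)
      done_stage("ora", t0)
    } else message("[ora] up to date, skipping")
  }

  if ("sweep" %in% stages) {
    ins <- unlist(paths[c("norm_a", "norm_b", "norm_a_samples",
                          "norm_b_samples", "regulators")])
    require_artifact(ins, "de")
    outs <- file.path(paths$sweep_dir,
                      c("jaccard.tsv", "spearman.tsv", "persistence.tsv"))
    params <- list(grid = cfg$sweep_grid, min_regulon = cfg$min_regulon,
                   n_perm = cfg$n_perm, alpha = cfg$alpha)
    if (!stage_current(cfg, "sweep", params, ins, outs, force)) {
      t0 <- log_stage("sweep", sprintf("sensitivity grid (%d cells)",
                                       nrow(cfg$sweep_grid)))
      norm_a <- read_expression(paths$norm_a, paths$norm_a_samples,
                                "logcpm")
      norm_b <- read_expression(paths$norm_b, paths$norm_b_samples,
                                "intensity")
      sw <- sweep_stability(norm_a, norm_b, readLines(paths$regulators),
                            cfg$sweep_grid,
                            seed = derive_seed(cfg$seed, 301L),
                            min_regulon = cfg$min_regulon,
                            n_perm = cfg$n_perm, alpha = cfg$alpha,
                            n_null = cfg$n_null)
      write_sweep(sw, paths$sweep_dir)
      record_stage(cfg, "sweep", params, ins, outs)
      done_stage("sweep", t0)
    } else message("[sweep] up to date, skipping")
  }

  res <- structure(list(paths = paths, config = cfg),
                   class = "tmr_pipeline_result")
  if (file.exists(paths$consensus))
    res$consensus <- readLines(paths$consensus)
  if (file.exists(paths$meta_regulators))
    res$meta_regulators <- read.delim(paths$meta_regulators,
                                      stringsAsFactors = FALSE)
  if (file.exists(paths$hubs))
    res$hubs <- read.delim(paths$hubs, stringsAsFactors = FALSE)
  invisible(res)
}

## hubs stage reloads the graph from the edge list + consensus file
rebuild_graph_from_files <- function(paths) {
  edges <- read.delim(paths$graph, stringsAsFactors = FALSE)
  consensus <- readLines(paths$consensus)
  g <- structure(list(edges = edges, nodes = consensus), class = "tmr_graph")
  out_deg <- setNames(integer(length(consensus)), consensus)
  in_deg <- out_deg
  if (nrow(edges) > 0L) {
    out_deg[] <- as.integer(table(factor(edges$source, levels = consensus)))
    in_deg[] <- as.integer(table(factor(edges$target, levels = consensus)))
  }
  g$out_degree <- out_deg
  g$in_degree <- in_deg
  g
}

#' @export
print.tmr_pipeline_result <- function(x, ...) {
  cat("<tmr_pipeline_result>\n")
  if (!is.null(x$consensus))
    cat("  consensus TMRs:", paste(x$consensus, collapse = ", "), "\n")
  if (!is.null(x$hubs) && any(x$hubs$hub))
    cat("  top-of-cascade:",
        paste(x$hubs$node[x$hubs$hub], collapse = ", "), "\n")
  cat("  artifacts under:", x$config$out_dir, "\n")
  invisible(x)
}
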