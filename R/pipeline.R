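#' Assemble (or load) a run configuration
#'
#' A run configuration bundles the stage parameters and input paths for
#' [run_pipeline()].  It can be given as an R list or as a YAML file with
#' the same keys.  Two input modes are supported: `simulate = TRUE` runs on
#' a synthetic cohort generated from `cohort` parameters; otherwise
#' `fasta`, `hits` and optionally `ghost_hits`, `annotations`, `metadata`
#' and `score_matrix` paths must point at existing files.
#'
#' @param config list or path to a YAML file.
#' @return validated list of class `"run_config"`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    simulate = TRUE,
    seed = 1L,
    cohort = list(),
    classify = list(),
    metric = list(),
    thresholds = seq(50, 95, by = 5),
    analysis_threshold = 85,
    algorithms = community_algorithms(),
    min_core_size = 3,
    vote_fraction = 0.5,
    stability = list(perturb_fraction = 0.05, replicates = 100L),
    fasta = NULL, hits = NULL, ghost_hits = NULL, annotations = NULL,
    metadata = NULL, score_matrix = NULL, score_higher_is_similar = TRUE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!isTRUE(cfg$simulate)) {
    for (key in c("fasta", "hits")) {
      if (is.null(cfg[[key]]))
        stop("run_config: '", key, "' path required when simulate is FALSE")
    }
    for (key in c("fasta", "hits", "ghost_hits", "annotations", "metadata",
                  "score_matrix")) {
      if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
        stop("run_config: input file does not exist: ", cfg[[key]])
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full conservation-analysis pipeline
#'
#' Stages: cohort simulation (or input loading) -> classification ->
#' pairwise similarity (built-in metric, or an ingested external matrix) ->
#' density curves -> consensus communities at the analysis threshold ->
#' bootstrap stability of each consensus cluster -> Wilcoxon comparison of
#' intra-group edge weights per context.  Every stage output is written as
#' CSV/TSV under `out_dir` and listed, with its MD5 hash, in
#' `manifest.csv`; a YAML echo of the configuration is stored alongside.
#' Reruns with the same configuration and seed produce identical hashes.
#'
#' @param config a [run_config()] (list or YAML path accepted).
#' @param out_dir output directory, created if missing.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest data.frame.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config)
                    else config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_csv_output(x, p)
    paths[[name]] <<- p
    p
  }
  ccfg <- do.call(classify_config, cfg$classify)
  mcfg <- do.call(metric_config, cfg$metric)

  # --- inputs -------------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    cohort <- generate_cohort(do.call(cohort_params,
                                      utils::modifyList(list(seed = cfg$seed),
                                                        cfg$cohort)))
    seqs <- cohort$sequences; hits <- cohort$hits
    ghost_hits <- cohort$ghost_hits; annotations <- cohort$annotations
    metadata <- cohort$metadata
    fasta_path <- file.path(out_dir, "sequences.fasta")
    write_fasta(seqs, fasta_path)
    paths[["sequences.fasta"]] <- fasta_path
    emit(cohort$truth, "truth.csv")
  } else {
    seqs <- read_fasta(cfg$fasta)
    hits <- utils::read.delim(cfg$hits, stringsAsFactors = FALSE)
    ghost_hits <- if (!is.null(cfg$ghost_hits))
      utils::read.delim(cfg$ghost_hits, stringsAsFactors = FALSE) else NULL
    annotations <- if (!is.null(cfg$annotations))
      read_gene_annotations(cfg$annotations) else NULL
    metadata <- if (!is.null(cfg$metadata)) read_metadata(cfg$metadata) else
      NULL
  }

  # --- classify -----------------------------------------------------------
  records <- classify_aptamers(hits, ghost_hits, annotations, metadata, ccfg)
  emit(records, "records.csv")

  # --- similarity ---------------------------------------------------------
  sm <- if (!isTRUE(cfg$simulate) && !is.null(cfg$score_matrix)) {
    read_score_matrix(cfg$score_matrix, cfg$score_higher_is_similar)
  } else {
    pairwise_matrix(seqs[records$id], mcfg)
  }
  mat_path <- file.path(out_dir, "similarity.tsv")
  write_score_matrix(sm, mat_path)
  paths[["similarity.tsv"]] <- mat_path

  # --- network + density --------------------------------------------------
  short <- c(tandem_apt1 = "apt1", tandem_apt2 = "apt2",
             singleton_type1 = "sing1", singleton_type2 = "sing2",
             singleton_type0 = "sing0")
  groups <- stats::setNames(paste0(short[records$role], "/", records$context),
                            records$id)
  net <- build_network(sm, groups)
  grp_tab <- table(groups)
  grp_ok <- names(grp_tab)[grp_tab >= 2]
  pairs <- if (length(grp_ok) >= 2) utils::combn(grp_ok, 2, simplify = FALSE)
           else NULL
  curve <- density_curve(net, cfg$thresholds, groups = grp_ok, pairs = pairs)
  emit(curve, "density_curve.csv")

  # --- communities --------------------------------------------------------
  tg <- threshold_graph(net, cfg$analysis_threshold)
  partitions <- lapply(cfg$algorithms, function(a) detect(tg, a))
  part_df <- do.call(rbind, lapply(partitions, function(p)
    data.frame(algorithm = p$algorithm, id = names(p$membership),
               community = unname(p$membership))))
  emit(part_df, "partitions.csv")
  clusters <- consensus_core(partitions, cfg$min_core_size, cfg$vote_fraction)
  cons_df <- if (length(clusters)) do.call(rbind, lapply(seq_along(clusters),
    function(ci) {
      cl <- clusters[[ci]]
      data.frame(cluster = ci, id = cl$augmented,
                 membership = ifelse(cl$augmented %in% cl$core, "core",
                                     "augmented"),
                 votes = unname(cl$votes[cl$augmented]))
    })) else data.frame(cluster = integer(), id = character(),
                        membership = character(), votes = integer())
  emit(cons_df, "consensus_clusters.csv")

  # --- stability ----------------------------------------------------------
  scfg <- stability_config(
    perturb_fraction = cfg$stability$perturb_fraction %||% 0.05,
    replicates = cfg$stability$replicates %||% 100L,
    seed = cfg$seed)
  stab_df <- do.call(rbind, lapply(seq_along(clusters), function(ci) {
    do.call(rbind, lapply(cfg$algorithms, function(a) {
      rep <- bootstrap_stability(tg, clusters[[ci]]$augmented, a, scfg)
      data.frame(cluster = ci, algorithm = a,
                 mean_jaccard = rep$mean_jaccard,
                 replicates = length(rep$jaccard), seed = rep$seed)
    }))
  }))
  if (is.null(stab_df))
    stab_df <- data.frame(cluster = integer(), algorithm = character(),
                          mean_jaccard = numeric(), replicates = integer(),
                          seed = integer())
  emit(stab_df, "stability.csv")

  # --- wilcoxon: conserved vs degraded intra-group weights per context ----
  wil <- list()
  for (ctx in unique(records$context)) {
    g1 <- paste0("apt1/", ctx); g2 <- paste0("apt2/", ctx)
    if (all(c(g1, g2) %in% grp_ok)) {
      w <- wilcoxon_rank_sum(group_edge_weights(net, g1),
                             group_edge_weights(net, g2))
      wil[[length(wil) + 1L]] <- data.frame(
        context = ctx, group_a = g1, group_b = g2, statistic = w$statistic,
        n1 = w$n1, n2 = w$n2, p_two_sided = w$p_two_sided, method = w$method)
    }
  }
  wil_df <- if (length(wil)) do.call(rbind, wil) else
    data.frame(context = character(), group_a = character(),
               group_b = character(), statistic = numeric(), n1 = integer(),
               n2 = integer(), p_two_sided = numeric(), method = character())
  emit(wil_df, "wilcoxon.csv")

  # --- manifest + config echo --------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  manifest <- data.frame(file = names(paths),
                         md5 = unname(tools::md5sum(unlist(paths))))
  manifest <- manifest[order(manifest$file), ]
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(records = records, matrix = sm, network = net,
                 curve = curve, partitions = partitions, clusters = clusters,
                 stability = stab_df, wilcoxon = wil_df, manifest = manifest,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
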