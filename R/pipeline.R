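#' Run the full pairwise-rank survival pipeline
#'
#' Wires the stages together: load (or accept) the network, expression and
#' survival inputs; sample walk neighborhoods for the measured panel; encode
#' the requested feature representations; evaluate each under paired
#' repeated holdout; compare representations; and, optionally, compute
#' summed permutation importances with per-protein rank differences. All
#' outputs are written to `outdir` together with a manifest that echoes every
#' parameter and seed, so a run is reproducible from the manifest alone.
#'
#' @param config a named list or the path of a YAML file. Recognised entries
#'   (defaults in parentheses): `network` (path or `ppi_network`),
#'   `expression` (path or matrix), `survival` (path or `survival_data`),
#'   `mapping` (optional path or data.frame), `outdir`,
#'   `confidence_threshold` (0.1), `walk` = list(`p` 0.25, `q` 0.25, `l` 100,
#'   `r` 18), `representations` (`c("individual", "prer")`; also
#'   `"prer-ternary"`, `"propagated"`), `ternary_threshold` (0.1),
#'   `propagation_alpha` (0.5), `evaluation` = list(`repeats` 100,
#'   `train_frac` 0.8, `n_trees` 1000, `n_split` 10, `filter_alpha` 0.05),
#'   `importance` = list(`enabled` FALSE, `n_perm` 1, `top_k` 50), `seed`
#'   (required).
#' @return invisibly, a list with the evaluated `results`, the comparison
#'   `report`, the `neighborhoods`, `pairs` and (if computed) `importance`
#'   tables; side effect: files under `outdir`.
#' @export
run_prer_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(config)
  if (is.null(cfg$seed)) stop("config must set a `seed` for reproducible runs")
  outdir <- cfg$outdir
  if (is.null(outdir)) stop("config must set `outdir`")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(fmt, ...) message(sprintf(paste0("[prer] ", fmt), ...))

  # --- inputs -------------------------------------------------------------
  net <- if (inherits(cfg$network, "ppi_network")) cfg$network else
    load_edge_list(cfg$network, confidence_threshold = cfg$confidence_threshold)
  expr <- if (is.matrix(cfg$expression)) cfg$expression else
    read_expression_tsv(cfg$expression)
  surv <- if (inherits(cfg$survival, "survival_data")) cfg$survival else
    read_survival_tsv(cfg$survival)
  if (!identical(rownames(expr), surv$patient_id)) {
    idx <- match(surv$patient_id, rownames(expr))
    if (anyNA(idx)) stop("expression and survival tables cover different patients")
    expr <- expr[idx, , drop = FALSE]
  }
  mapping <- cfg$mapping
  if (is.character(mapping)) mapping <- read_protein_mapping(mapping)
  stage("network: %d nodes, %d edges (density %.4g)",
        length(net$nodes), nrow(net$edges), edge_density(net))

  # --- neighborhoods ------------------------------------------------------
  mm <- map_measured(colnames(expr), mapping, net)
  if (length(mm$unmapped)) {
    stage("unmapped measured ids: %s", paste(mm$unmapped, collapse = ", "))
  }
  U <- sort(unique(unname(mm$mapped)))
  wcfg <- walk_config(p = cfg$walk$p, q = cfg$walk$q, l = cfg$walk$l,
                      r = cfg$walk$r, seed = cfg$seed)
  nbhd <- sample_neighborhoods(net, U, wcfg, U = U)
  write_neighborhoods(nbhd, file.path(outdir, "neighborhoods.tsv"))
  stage("neighborhoods: %d sources, median size %d", length(nbhd),
        as.integer(stats::median(lengths(lapply(nbhd, `[[`, "members")))))

  # --- representations ----------------------------------------------------
  measured_mapped <- names(mm$mapped)
  pairs <- build_feature_pairs(nbhd, measured_mapped, mapping)
  stage("feature pairs: %d", nrow(pairs))
  reps <- list()
  for (r in cfg$representations) {
    reps[[r]] <- switch(
      r,
      "individual" = expr,
      "prer" = encode_binary(expr, pairs),
      "prer-ternary" = encode_ternary(expr, pairs,
                                      rel_threshold = cfg$ternary_threshold),
      "propagated" = propagate_expression(expr, net,
                                          alpha = cfg$propagation_alpha),
      stop(sprintf("unknown representation '%s'", r))
    )
    write_matrix_tsv(reps[[r]], file.path(outdir, paste0("features_", gsub("-", "_", r), ".tsv")))
  }

  # --- evaluation ---------------------------------------------------------
  ev <- cfg$evaluation
  results <- list()
  for (r in names(reps)) {
    stage("evaluating '%s' (%d features, %d repeats)", r, ncol(reps[[r]]), ev$repeats)
    results[[r]] <- repeated_holdout(reps[[r]], surv, repeats = ev$repeats,
                                     train_frac = ev$train_frac, seed = cfg$seed,
                                     n_trees = ev$n_trees, n_split = ev$n_split,
                                     filter_alpha = ev$filter_alpha,
                                     keep_models = isTRUE(cfg$importance$enabled))
  }
  cidx <- do.call(rbind, lapply(names(results), function(r) {
    data.frame(representation = r, split = seq_len(ev$repeats),
               split_seed = results[[r]]$split_seed,
               c_index = results[[r]]$c_index, stringsAsFactors = FALSE)
  }))
  utils::write.table(cidx, file.path(outdir, "cindex.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  report <- NULL
  if (length(results) >= 2L) {
    report <- compare_representations(results)
    utils::write.table(as.data.frame(report), file.path(outdir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- importance ---------------------------------------------------------
  importance <- NULL
  if (isTRUE(cfg$importance$enabled)) {
    importance <- list()
    for (r in names(results)) {
      stage("permutation importance for '%s'", r)
      res <- results[[r]]
      imps <- lapply(seq_len(ev$repeats), function(i) {
        te <- res$test_idx[[i]]
        permutation_importance(res$models[[i]], reps[[r]][te, , drop = FALSE],
                               subset_surv(surv, te),
                               n_perm = cfg$importance$n_perm,
                               seed = cfg$seed + i)
      })
      agg <- aggregate_importance(imps)
      utils::write.table(agg, file.path(outdir, paste0("importance_", gsub("-", "_", r), ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      importance[[r]] <- agg
    }
    if (all(c("prer", "individual") %in% names(importance))) {
      sp <- protein_scores(importance$prer)
      si <- importance$individual$importance
      names(si) <- importance$individual$feature
      ranks <- rank_difference(sp, si)
      utils::write.table(ranks, file.path(outdir, "protein_ranks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      importance$protein_ranks <- ranks
      importance$prer_top_network <- prer_network(
        importance$prer, k = min(cfg$importance$top_k, nrow(importance$prer)))
      utils::write.table(importance$prer_top_network,
                         file.path(outdir, "prer_network.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("prer")),
    seed = cfg$seed,
    confidence_threshold = cfg$confidence_threshold,
    walk = cfg$walk,
    representations = cfg$representations,
    ternary_threshold = cfg$ternary_threshold,
    propagation_alpha = cfg$propagation_alpha,
    evaluation = ev,
    importance = cfg$importance,
    n_patients = nrow(expr),
    n_measured = ncol(expr),
    n_nodes = length(net$nodes),
    n_edges = nrow(net$edges),
    n_feature_pairs = nrow(pairs),
    split_seeds = results[[1L]]$split_seed
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  stage("done; outputs in %s", outdir)

  invisible(list(results = results, report = report, neighborhoods = nbhd,
                 pairs = pairs, importance = importance, manifest = manifest))
}

merge_config <- function(config) {
  defaults <- list(
    confidence_threshold = 0.1,
    walk = list(p = 0.25, q = 0.25, l = 100L, r = 18L),
    representations = c("individual", "prer"),
    ternary_threshold = 0.1,
    propagation_alpha = 0.5,
    evaluation = list(repeats = 100L, train_frac = 0.8, n_trees = 1000L,
                      n_split = 10L, filter_alpha = 0.05),
    importance = list(enabled = FALSE, n_perm = 1L, top_k = 50L),
    mapping = NULL
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      for (kk in names(defaults[[k]])) {
        if (is.null(config[[k]][[kk]])) config[[k]][[kk]] <- defaults[[k]][[kk]]
      }
    }
  }
  config
}
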