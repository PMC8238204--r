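#' Permutation importance on held-out data
#'
#' For each feature, the drop in held-out concordance when that feature's
#' test-set column is randomly permuted (`n_perm` permutations, averaged),
#' relative to the unpermuted baseline. A feature the model never relies on
#' scores approximately 0; permuting a constant column scores exactly 0.
#'
#' @param model a `prer_rsf` from [fit_survival_forest()]
#' @param test_features numeric matrix of held-out patients x features
#' @param test_surv a [survival_data()] aligned with `test_features`
#' @param feature_ids features to assess (default: all model features)
#' @param n_perm permutations per feature (default 1)
#' @param seed integer seed; results are reproducible
#' @return named numeric vector of importances (baseline C-index minus mean
#'   permuted C-index)
#' @export
permutation_importance <- function(model, test_features, test_surv,
                                   feature_ids = NULL, n_perm = 1L, seed = 1L) {
  stopifnot(inherits(model, "prer_rsf"))
  test_features <- as.matrix(test_features)
  if (is.null(feature_ids)) feature_ids <- model$feature_names
  baseline <- concordance_index(predict_risk(model, test_features), test_surv)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  n <- nrow(test_features)
  imp <- numeric(length(feature_ids))
  names(imp) <- feature_ids
  for (f in feature_ids) {
    if (length(unique(test_features[, f])) < 2L) { imp[f] <- 0; next }
    drop_sum <- 0
    perm <- test_features
    for (k in seq_len(n_perm)) {
      perm[, f] <- test_features[sample.int(n), f]
      drop_sum <- drop_sum + (baseline -
        concordance_index(predict_risk(model, perm), test_surv))
    }
    imp[f] <- drop_sum / n_perm
  }
  imp
}

#' Aggregate per-model importances across repeated-holdout models
#'
#' The overall importance of a feature is the *sum* of its per-model
#' permutation importances over all models in which it was retained; a
#' display-oriented normalized variant divides by the maximum summed
#' importance.
#'
#' @param imp_list list of named numeric vectors, one per model (features
#'   absent from a model contribute 0)
#' @return data.frame of class `feature_importance` with columns `feature`,
#'   `importance` (summed) and `importance_norm`, sorted by decreasing
#'   importance with ties broken by feature name
#' @export
aggregate_importance <- function(imp_list) {
  all_feats <- sort(unique(unlist(lapply(imp_list, names), use.names = FALSE)))
  if (!length(all_feats)) stop("no importances to aggregate")
  total <- numeric(length(all_feats))
  names(total) <- all_feats
  for (imp in imp_list) total[names(imp)] <- total[names(imp)] + imp
  mx <- max(total)
  out <- data.frame(feature = all_feats, importance = unname(total),
                    importance_norm = if (mx > 0) unname(total) / mx else NA_real_,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_importance", "data.frame")
  out
}

importance_vector <- function(imp) {
  if (inherits(imp, "feature_importance") || is.data.frame(imp)) {
    v <- imp$importance
    names(v) <- imp$feature
    v
  } else if (is.numeric(imp) && !is.null(names(imp))) {
    imp
  } else {
    stop("expected a feature_importance table or a named numeric vector")
  }
}

split_pair_names <- function(feats) {
  parts <- strsplit(feats, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop(sprintf("feature name(s) not of the form 'I|J': %s",
                 paste(utils::head(feats[bad], 3L), collapse = ", ")))
  }
  data.frame(left = vapply(parts, `[[`, character(1), 1L),
             right = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Per-protein importance scores from pair importances
#'
#' A protein's score is the mean importance of all pairwise features in
#' which it participates, `s_i = (1/|P_i|) * sum_j f_{i,j}`.
#'
#' @param imp a `feature_importance` table (or named numeric vector) keyed
#'   by `"I|J"` pair names
#' @return named numeric vector of per-protein scores
#' @export
protein_scores <- function(imp) {
  v <- importance_vector(imp)
  pairs <- split_pair_names(names(v))
  prot <- c(pairs$left, pairs$right)
  val <- c(unname(v), unname(v))
  s <- tapply(val, prot, mean)
  out <- as.numeric(s)
  names(out) <- names(s)
  out[sort(names(out))]
}

#' @rdname protein_scores
#' @param protein single protein identifier
#' @return `protein_score()`: that protein's mean pair importance
#' @export
protein_score <- function(imp, protein) {
  s <- protein_scores(imp)
  if (!protein %in% names(s)) {
    warning(sprintf("protein '%s' participates in no pair; score undefined", protein))
    return(NA_real_)
  }
  unname(s[protein])
}

dense_rank_desc <- function(scores) {
  # 1-based ranks by descending score; ties broken lexicographically by name
  ord <- order(-scores, names(scores))
  rk <- integer(length(scores))
  rk[ord] <- seq_along(scores)
  names(rk) <- names(scores)
  rk
}

#' Rank differences between two per-protein importance rankings
#'
#' Ranks proteins by descending score in each representation (rank 1 = most
#' important; score ties broken lexicographically by protein id) and reports
#' the difference `r_q - r_p` between the individual-expression rank `r_q`
#' and the pairwise-rank-representation rank `r_p`. Large positive
#' differences mark proteins that are important only through their relative
#' expression against their network neighbors.
#'
#' @param prer_scores named numeric vector of per-protein scores from the
#'   pairwise-rank models (see [protein_scores()])
#' @param individual_scores named numeric vector from the
#'   individual-expression models
#' @return data.frame of class `protein_rank_table` with columns `protein`,
#'   `score_prer`, `score_individual`, `rank_prer`, `rank_individual`,
#'   `rank_diff`, sorted by decreasing `rank_diff`
#' @export
rank_difference <- function(prer_scores, individual_scores) {
  shared <- intersect(names(prer_scores), names(individual_scores))
  if (!length(shared)) stop("the two rankings share no proteins")
  sp <- prer_scores[shared]
  si <- individual_scores[shared]
  rp <- dense_rank_desc(sp)
  rq <- dense_rank_desc(si)
  out <- data.frame(protein = shared, score_prer = unname(sp),
                    score_individual = unname(si),
                    rank_prer = unname(rp), rank_individual = unname(rq),
                    rank_diff = unname(rq - rp), stringsAsFactors = FALSE)
  out <- out[order(-out$rank_diff, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_rank_table", "data.frame")
  out
}

#' Network of the top-k most important feature pairs
#'
#' Takes the `k` pairwise features with the largest summed importance and
#' returns them as an edge list: nodes are the participating proteins, one
#' edge per top-`k` pair.
#'
#' @param imp a `feature_importance` table (or named numeric vector)
#' @param k number of top features (default 50); if larger than the number
#'   of features, all are used with a warning
#' @return data.frame with columns `protein_a`, `protein_b`, `importance`
#' @export
prer_network <- function(imp, k = 50L) {
  v <- importance_vector(imp)
  if (k > length(v)) {
    warning(sprintf("k = %d exceeds the %d available features; using all", k, length(v)))
    k <- length(v)
  }
  ord <- order(-v, names(v))[seq_len(k)]
  pairs <- split_pair_names(names(v)[ord])
  data.frame(protein_a = pairs$left, protein_b = pairs$right,
             importance = unname(v[ord]), stringsAsFactors = FALSE)
}

#' Kaplan-Meier comparison of the two groups induced by a single pair feature
#'
#' Splits patients by the value of one binary pairwise feature (+1 vs -1)
#' and compares the groups' survival distributions with the two-group
#' log-rank test.
#'
#' @param feature numeric/character vector of per-patient feature values with
#'   exactly two distinct values
#' @param surv a [survival_data()] aligned with `feature`
#' @return list of class `km_groups`: `p_value` (log-rank), `fit` (a
#'   [survival::survfit] object with one stratum per group), `groups`
#' @export
km_groups <- function(feature, surv) {
  if (length(feature) != nrow(surv)) stop("feature and survival data are misaligned")
  grp <- factor(feature)
  if (nlevels(grp) < 2L) stop("feature induces a single group; comparison undefined")
  if (nlevels(grp) > 2L) stop("expected a binary feature (two groups)")
  ev_per_group <- tapply(surv$event, grp, sum)
  if (any(ev_per_group == 0L)) stop("each group needs at least one observed event")
  df <- data.frame(time = surv$time, event = surv$event, grp = grp)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ grp, data = df)
  structure(list(p_value = p, fit = fit, groups = grp), class = "km_groups")
}

#' @export
print.km_groups <- function(x, ...) {
  cat(sprintf("<km_groups> log-rank p = %.4g; group sizes %s\n", x$p_value,
              paste(table(x$groups), collapse = "/")))
  invisible(x)
}
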