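#' Construct a survival dataset
#'
#' Per-patient observed time and event indicator for right-censored survival
#' analysis: `event = 1` when the death was observed at `time`, `event = 0`
#' when follow-up ended (censoring) at `time`.
#'
#' @param time positive observed times
#' @param event event indicators in `{0, 1}`
#' @param patient_id optional patient identifiers (default `PT1...PTn`)
#' @return data.frame of class `survival_data` with columns `patient_id`,
#'   `time`, `event`
#' @export
survival_data <- function(time, event, patient_id = NULL) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) != length(event)) stop("`time` and `event` differ in length")
  if (anyNA(time) || any(time <= 0)) stop("times must be positive and non-missing")
  if (anyNA(event) || !all(event %in% c(0L, 1L))) stop("`event` must be 0 or 1")
  if (is.null(patient_id)) patient_id <- paste0("PT", seq_along(time))
  if (anyDuplicated(patient_id)) stop("duplicate patient ids")
  structure(data.frame(patient_id = as.character(patient_id), time = time,
                       event = event, stringsAsFactors = FALSE),
            class = c("survival_data", "data.frame"))
}

subset_surv <- function(surv, idx) {
  structure(surv[idx, , drop = FALSE], class = c("survival_data", "data.frame"))
}

#' Univariate Cox proportional-hazards screening
#'
#' Fits one single-covariate Cox model per feature column (Efron tie
#' handling) and retains features whose Wald p-value is at most `alpha`
#' (boundary included). Constant features carry no information and are
#' skipped; features whose fit fails or yields a non-finite coefficient
#' (e.g. monotone-likelihood separation) are skipped with a warning.
#'
#' @param features numeric matrix, patients x features, rows aligned with
#'   `surv`
#' @param surv a [survival_data()] with at least 2 events
#' @param alpha significance cutoff (default 0.05)
#' @return character vector of retained feature names
#' @export
cox_univariate_filter <- function(features, surv, alpha = 0.05) {
  features <- as.matrix(features)
  if (nrow(features) != nrow(surv)) stop("features and survival data are misaligned")
  if (sum(surv$event) < 2L) stop("need at least 2 observed events")
  y <- survival::Surv(surv$time, surv$event)
  ctrl <- survival::coxph.control()
  pvals <- rep(NA_real_, ncol(features))
  skipped <- character(0)
  for (j in seq_len(ncol(features))) {
    x <- features[, j]
    if (length(unique(x)) < 2L) next   # constant: no information
    fit <- tryCatch(
      suppressWarnings(
        survival::coxph.fit(matrix(x, ncol = 1L), y, strata = NULL,
                            offset = NULL, init = 0, control = ctrl,
                            weights = NULL, method = "efron", rownames = NULL)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) { skipped <- c(skipped, colnames(features)[j]); next }
    beta <- fit$coefficients[1L]
    se <- sqrt(fit$var[1L, 1L])
    if (!is.finite(beta) || !is.finite(se) || se == 0 || abs(beta) > 15) {
      skipped <- c(skipped, colnames(features)[j])
      next
    }
    pvals[j] <- 2 * stats::pnorm(-abs(beta / se))
  }
  if (length(skipped)) {
    warning(sprintf("skipped %d feature(s) with degenerate Cox fits", length(skipped)))
  }
  retained <- colnames(features)[!is.na(pvals) & pvals <= alpha]
  if (!length(retained)) {
    stop("no features pass the univariate Cox filter; fall back to the full feature set")
  }
  retained
}

#' Fit a random survival forest
#'
#' Ensemble of survival trees grown on bootstrap samples; at each node a
#' random feature subset is considered and, per candidate feature,
#' `n_split` randomly drawn split points are evaluated with the log-rank
#' statistic. Predictions are per-patient risk scores (higher = shorter
#' predicted survival), defined as the summed ensemble cumulative hazard.
#' Backed by [ranger::ranger()].
#'
#' @param features numeric matrix, patients x features
#' @param surv a [survival_data()] aligned with `features`; at least 2
#'   observed events required
#' @param n_trees number of trees (default 1000)
#' @param n_split random split points considered per candidate feature
#'   (default 10)
#' @param seed integer seed; the same seed and data reproduce the model
#'   exactly
#' @return object of class `prer_rsf` wrapping the fitted forest
#' @export
fit_survival_forest <- function(features, surv, n_trees = 1000L,
                                n_split = 10L, seed = 1L) {
  features <- as.matrix(features)
  if (ncol(features) < 1L) stop("need at least one feature")
  if (nrow(features) != nrow(surv)) stop("features and survival data are misaligned")
  if (sum(surv$event) < 2L) stop("need at least 2 observed events to grow survival trees")
  safe <- paste0("f", seq_len(ncol(features)))
  df <- as.data.frame(features)
  names(df) <- safe
  df$..time <- surv$time
  df$..status <- surv$event
  fit <- ranger::ranger(
    dependent.variable.name = "..time",
    status.variable.name = "..status",
    data = df,
    num.trees = as.integer(n_trees),
    splitrule = "extratrees",
    num.random.splits = as.integer(n_split),
    seed = as.integer(seed),
    num.threads = 1L,
    verbose = FALSE
  )
  structure(list(fit = fit, feature_names = colnames(features), safe_names = safe),
            class = "prer_rsf")
}

#' Predict per-patient risk scores
#'
#' @param model a `prer_rsf` from [fit_survival_forest()]
#' @param features numeric matrix with the model's feature columns
#' @return numeric vector of risk scores (summed ensemble cumulative
#'   hazard); higher values predict shorter survival
#' @export
predict_risk <- function(model, features) {
  stopifnot(inherits(model, "prer_rsf"))
  features <- as.matrix(features)
  miss <- setdiff(model$feature_names, colnames(features))
  if (length(miss)) {
    stop(sprintf("missing feature column(s): %s", paste(miss, collapse = ", ")))
  }
  df <- as.data.frame(features[, model$feature_names, drop = FALSE])
  names(df) <- model$safe_names
  pred <- stats::predict(model$fit, data = df, num.threads = 1L, verbose = FALSE)
  unname(rowSums(pred$chf))
}

#' Harrell's concordance index
#'
#' Over all comparable patient pairs — `(a, b)` with `S_a < S_b` and the
#' earlier time an observed event (`delta_a = 1`) — the fraction for which
#' the predicted risks agree with the observed ordering (`risk_a > risk_b`),
#' with risk ties credited 0.5. Pairs tied on time are not comparable.
#'
#' @param risk numeric vector of predicted risk scores
#' @param surv a [survival_data()] aligned with `risk`
#' @return concordance in `[0, 1]`
#' @export
concordance_index <- function(risk, surv) {
  if (length(risk) != nrow(surv)) stop("risk scores and survival data are misaligned")
  tm <- surv$time; ev <- surv$event
  comp <- outer(tm, tm, "<") & (ev == 1L)  # row a earlier, event observed
  n_comp <- sum(comp)
  if (n_comp == 0L) stop("no comparable pairs: concordance undefined")
  dr <- outer(risk, risk, "-")
  conc <- sum(dr[comp] > 0) + 0.5 * sum(dr[comp] == 0)
  conc / n_comp
}

#' Repeated-holdout evaluation of a feature representation
#'
#' Repeats `repeats` times: draw a random 80/20 train/test split, screen
#' features with the univariate Cox filter on the training data only, fit a
#' random survival forest on the retained features, and score the held-out
#' patients with the concordance index. The splits depend only on the global
#' seed, the repeat number, the cohort size and the train fraction, so two
#' representations evaluated with the same `seed` see identical splits — the
#' paired design required for signed-rank comparison. If no feature passes
#' the filter the model falls back to all non-constant features (logged).
#'
#' @param features numeric matrix, patients x features
#' @param surv a [survival_data()] aligned with `features`
#' @param repeats number of random splits (default 100)
#' @param train_frac training fraction (default 0.8)
#' @param seed global seed
#' @param n_trees,n_split forest hyperparameters (see
#'   [fit_survival_forest()])
#' @param filter_alpha Cox screening cutoff; `NULL` disables screening
#' @param keep_models retain fitted models and test indices for downstream
#'   permutation importance (default `FALSE`)
#' @return object of class `model_result`: list with `c_index` (numeric
#'   vector of length `repeats`), `retained` (list of feature sets),
#'   `split_seed`, `test_idx`, and `models` when requested
#' @export
repeated_holdout <- function(features, surv, repeats = 100L, train_frac = 0.8,
                             seed = 1L, n_trees = 1000L, n_split = 10L,
                             filter_alpha = 0.05, keep_models = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n != nrow(surv)) stop("features and survival data are misaligned")
  repeats <- as.integer(repeats)
  cidx <- numeric(repeats)
  retained <- vector("list", repeats)
  split_seeds <- integer(repeats)
  test_sets <- vector("list", repeats)
  models <- if (keep_models) vector("list", repeats) else NULL
  n_train <- round(train_frac * n)

  for (i in seq_len(repeats)) {
    split_seed <- as.integer((as.double(seed) * 2654435761 + i * 97561) %% (2^31 - 1))
    split_seeds[i] <- split_seed
    set.seed(split_seed)
    for (try in 1:100) {
      train_idx <- sort(sample.int(n, n_train))
      test_idx <- setdiff(seq_len(n), train_idx)
      if (sum(surv$event[train_idx]) >= 2L && sum(surv$event[test_idx]) >= 2L) break
      if (try == 100) stop("could not draw a split with >= 2 events per fold")
      message(sprintf("repeat %d: redrawing split with too few events", i))
    }
    tr_feat <- features[train_idx, , drop = FALSE]
    tr_surv <- subset_surv(surv, train_idx)
    feats <- colnames(features)
    if (!is.null(filter_alpha)) {
      feats <- tryCatch(
        cox_univariate_filter(tr_feat, tr_surv, alpha = filter_alpha),
        error = function(e) {
          message(sprintf("repeat %d: %s", i, conditionMessage(e)))
          keep <- apply(tr_feat, 2L, function(x) length(unique(x)) > 1L)
          colnames(features)[keep]
        }
      )
    }
    retained[[i]] <- feats
    model <- fit_survival_forest(tr_feat[, feats, drop = FALSE], tr_surv,
                                 n_trees = n_trees, n_split = n_split,
                                 seed = split_seed)
    te_feat <- features[test_idx, feats, drop = FALSE]
    te_surv <- subset_surv(surv, test_idx)
    cidx[i] <- concordance_index(predict_risk(model, te_feat), te_surv)
    test_sets[[i]] <- test_idx
    if (keep_models) models[[i]] <- model
  }
  structure(
    list(c_index = cidx, retained = retained, split_seed = split_seeds,
         test_idx = test_sets, models = models, repeats = repeats,
         seed = as.integer(seed), train_frac = train_frac),
    class = "model_result"
  )
}

#' @export
print.model_result <- function(x, ...) {
  q <- stats::quantile(x$c_index, c(0.25, 0.5, 0.75))
  cat(sprintf("<model_result> %d repeats; test C-index median %.3f (IQR %.3f-%.3f)\n",
              x$repeats, q[2L], q[1L], q[3L]))
  invisible(x)
}

wilcoxon_greater <- function(a, b) {
  d <- a - b
  if (all(d == 0)) return(1)
  stats::wilcox.test(a, b, paired = TRUE, alternative = "greater",
                     exact = FALSE, correct = TRUE)$p.value
}

#' Compare feature representations across paired evaluations
#'
#' For every pair of representations (optionally across several scenarios,
#' e.g. cancer types or simulated cohorts) a one-sided Wilcoxon signed-rank
#' test asks whether the first representation's paired C-indices exceed the
#' second's, and vice versa. Benjamini-Hochberg correction is applied across
#' *all* one-sided tests in the report. A comparison is a "win" for the first
#' representation when its adjusted one-sided p-value falls below `alpha`, a
#' "loss" when the reverse test does, and a "tie" otherwise.
#'
#' @param results either a named list of `model_result` objects (single
#'   scenario) or a named list of such lists (one element per scenario). All
#'   results within a scenario must come from identical splits (same seed,
#'   cohort and repeat count).
#' @param alpha significance level after correction (default 0.05)
#' @return data.frame of class `comparison_report` with columns `scenario`,
#'   `rep_a`, `rep_b`, `p_a_gt_b`, `p_b_gt_a`, `p_adj_a_gt_b`,
#'   `p_adj_b_gt_a`, `verdict` (win/tie/loss from `rep_a`'s perspective)
#' @export
compare_representations <- function(results, alpha = 0.05) {
  single <- all(vapply(results, inherits, logical(1), "model_result"))
  scenarios <- if (single) list(all = results) else results
  rows <- list()
  for (sc in names(scenarios)) {
    res <- scenarios[[sc]]
    if (length(res) < 2L) stop("need at least two representations to compare")
    nm <- names(res)
    for (u in seq_len(length(res) - 1L)) {
      for (v in seq((u + 1L), length(res))) {
        a <- res[[u]]; b <- res[[v]]
        if (length(a$c_index) != length(b$c_index) ||
            !identical(a$split_seed, b$split_seed)) {
          stop(sprintf("results '%s' and '%s' are not paired (different splits)",
                       nm[u], nm[v]))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, rep_a = nm[u], rep_b = nm[v],
          p_a_gt_b = wilcoxon_greater(a$c_index, b$c_index),
          p_b_gt_a = wilcoxon_greater(b$c_index, a$c_index),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  report <- do.call(rbind, rows)
  adj <- stats::p.adjust(c(report$p_a_gt_b, report$p_b_gt_a), method = "BH")
  m <- nrow(report)
  report$p_adj_a_gt_b <- adj[seq_len(m)]
  report$p_adj_b_gt_a <- adj[m + seq_len(m)]
  report$verdict <- ifelse(report$p_adj_a_gt_b < alpha, "win",
                           ifelse(report$p_adj_b_gt_a < alpha, "loss", "tie"))
  class(report) <- c("comparison_report", "data.frame")
  report
}
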