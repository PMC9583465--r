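# Evaluation harness: rank-based AUC, stratified nested cross-validation
# with grid search, recursive feature elimination, group-comparison
# statistics and selection-frequency reporting.

#' Rank-based AUC
#'
#' Area under the ROC curve computed from mid-ranks, identical to the
#' normalized Mann-Whitney U statistic `U / (n1 * n0)`.
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param labels binary labels (positive class = 1).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_oscml("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @inheritParams auc_score
#' @return data.frame with `threshold`, `fpr`, `tpr`, ordered from (0,0)
#'   to (1,1).
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  fpr <- vapply(th, function(t) mean(scores[y == 0L] >= t), 0)
  tpr <- vapply(th, function(t) mean(scores[y == 1L] >= t), 0)
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

#' Univariate feature AUC
#'
#' Discriminative power of a single raw feature used as a score,
#' orientation-corrected to `max(AUC, 1 - AUC)` since either direction of
#' effect counts as discrimination.
#'
#' @param x feature values.
#' @param labels binary labels.
#' @return AUC in \[0.5, 1\].
#' @export
univariate_auc <- function(x, labels) {
  a <- auc_score(x, labels)
  max(a, 1 - a)
}

#' Stratified fold assignment
#'
#' @param labels binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold id (1..k) per observation; class proportions are
#'   balanced across folds.
#' @export
stratified_folds <- function(labels, k, seed = 7L) {
  y <- as_binary_labels(labels)
  set.seed(derive_seed(seed, "stratified_folds"))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# --- train-only preprocessing -------------------------------------------

fit_preprocessor <- function(train, representation) {
  num <- names(train)[vapply(train, is.numeric, TRUE)]
  if (representation == "normalized") {
    mu <- vapply(train[num], mean, 0)
    sdv <- vapply(train[num], sd, 0)
    sdv[sdv == 0] <- 1
    list(kind = "zscore", features = num, mu = mu, sd = sdv)
  } else {
    list(kind = "fuzzy", scheme = fit_fuzzification(train[num]))
  }
}

apply_preprocessor <- function(pp, table) {
  if (pp$kind == "zscore") {
    out <- table[pp$features]
    for (f in pp$features) out[[f]] <- (out[[f]] - pp$mu[[f]]) / pp$sd[[f]]
    out
  } else {
    out <- fuzzify(pp$scheme, table[pp$scheme$features])
    out[fuzzy_feature_names(pp$scheme$features)]
  }
}

# Pooled AUC of one configuration under stratified k-fold CV (the inner
# loop of the nested scheme). Preprocessing is refit inside each fold.
inner_cv_auc <- function(algorithm, params, data, y, inner_folds,
                         representation, dialect, seed,
                         feature_subset = NULL) {
  fold <- stratified_folds(y, inner_folds, seed = derive_seed(seed, "inner"))
  scores <- numeric(length(y))
  for (k in seq_len(inner_folds)) {
    tr <- fold != k
    pp <- fit_preprocessor(data[tr, , drop = FALSE], representation)
    xtr <- apply_preprocessor(pp, data[tr, , drop = FALSE])
    xte <- apply_preprocessor(pp, data[!tr, , drop = FALSE])
    if (!is.null(feature_subset)) {
      xtr <- xtr[feature_subset]
      xte <- xte[feature_subset]
    }
    scores[!tr] <- fit_score(algorithm, params, xtr, y[tr], xte,
                             dialect = dialect, seed = seed)
  }
  auc_score(scores, y)
}

#' Recursive feature elimination path
#'
#' Backward elimination from the full (post-preprocessing) feature set:
#' at each round the feature whose removal least degrades the inner-CV
#' pooled AUC of the given configuration is dropped (ties drop the later
#' column). The importance signal is the model-agnostic score drop, so the
#' same procedure serves learners without native importances.
#'
#' @param algorithm,params classifier configuration (see [fit_score()]).
#' @param data crisp training table (preprocessing is refit inside each
#'   inner fold).
#' @param labels training labels.
#' @param representation `"normalized"` or `"fuzzy"` (determines the
#'   candidate feature space: 16 crisp or 48 membership columns).
#' @param inner_folds,seed inner-CV settings.
#' @param min_features stop eliminating once this many features remain
#'   (elimination below the smallest subset ever requested is wasted
#'   work).
#' @return Character vector: features in elimination order (first dropped
#'   first); the final `min_features` entries are the survivors, in
#'   elimination order of the rounds that never ran.
#' @export
rfe_path <- function(algorithm, params, data, labels,
                     representation = "normalized", inner_folds = 5L,
                     seed = 7L, min_features = 1L) {
  y <- as_binary_labels(labels)
  dialect <- if (representation == "fuzzy") "fuzzy" else "arithmetic"
  all_feats <- if (representation == "fuzzy") {
    num <- names(data)[vapply(data, is.numeric, TRUE)]
    fuzzy_feature_names(num)
  } else {
    names(data)[vapply(data, is.numeric, TRUE)]
  }
  remaining <- all_feats
  dropped <- character(0)
  while (length(remaining) > max(1L, min_features)) {
    aucs <- vapply(seq_along(remaining), function(i) {
      inner_cv_auc(algorithm, params, data, y, inner_folds,
                   representation, dialect, seed,
                   feature_subset = remaining[-i])
    }, 0)
    # least loss of information = highest AUC after removal; ties drop
    # the later column
    best <- max(aucs)
    i_drop <- max(which(aucs == best))
    dropped <- c(dropped, remaining[i_drop])
    remaining <- remaining[-i_drop]
  }
  c(dropped, remaining)
}

#' Select a feature subset of a given size
#'
#' Cuts an elimination path at `n_features` surviving features.
#'
#' @inheritParams rfe_path
#' @param n_features subset size, `1 <= n_features < total`.
#' @param path optionally a precomputed [rfe_path()].
#' @return Character vector of the selected features (original column
#'   order).
#' @export
rfe_select <- function(algorithm, params, data, labels, n_features,
                       representation = "normalized", inner_folds = 5L,
                       seed = 7L, path = NULL) {
  path <- path %||% rfe_path(algorithm, params, data, labels,
                             representation, inner_folds, seed)
  total <- length(path)
  if (n_features < 1L || n_features >= total)
    stop_oscml("n_features must lie in [1, ", total - 1L, "] (got ",
               n_features, ")")
  path[(total - n_features + 1L):total]
}

#' Default subset-size options for feature selection
#'
#' All sizes 1..(p-1) for the fast learners; a coarse triple for the
#' evolutionary engines, whose fits dominate run time.
#'
#' @param algorithm algorithm key.
#' @param representation data representation.
#' @return Integer vector of `n_features` options.
#' @export
rfe_n_options <- function(algorithm, representation = "normalized") {
  evolutionary <- algorithm %in% c("GP", "GE")
  if (representation == "fuzzy") {
    if (evolutionary) c(12L, 24L, 36L) else 1:47
  } else {
    if (evolutionary) c(4L, 8L, 12L) else 1:15
  }
}

#' Nested cross-validation of one classifier
#'
#' Stratified outer folds estimate generalization; inside each outer fold
#' the preprocessing (z-score normalization or fuzzification) is fitted on
#' the outer-training rows only, an exhaustive inner-CV grid search picks
#' the hyperparameters (optionally jointly with a feature-subset size via
#' recursive elimination), the winner is refit on the full outer-training
#' set and scores the outer-test rows. All ten test folds are pooled into
#' a single ROC curve and AUC.
#'
#' @param data data.frame of crisp feature columns (only numeric columns
#'   are used).
#' @param labels binary labels, one per row.
#' @param spec a [classifier_spec()].
#' @param representation `"normalized"` or `"fuzzy"`.
#' @param n_features `NULL` for no feature selection, or an integer vector
#'   of subset-size options to include in the grid.
#' @param outer_folds,inner_folds fold counts.
#' @param seed global seed; every random element derives from it.
#' @return Object of class `nested_cv_result`: per-fold chosen
#'   hyperparameters, selected features and test scores; pooled scores,
#'   ROC points and AUC; collected `model_info` per fold.
#' @export
nested_cv <- function(data, labels, spec, representation = "normalized",
                      n_features = NULL, outer_folds = 10L,
                      inner_folds = 5L, seed = 7L) {
  stopifnot(inherits(spec, "classifier_spec"))
  data <- as.data.frame(data)
  num <- names(data)[vapply(data, is.numeric, TRUE)]
  data <- data[num]
  y <- as_binary_labels(labels)
  dialect <- if (representation == "fuzzy") "fuzzy" else "arithmetic"
  fold <- stratified_folds(y, outer_folds, seed = derive_seed(seed, "outer"))
  for (k in seq_len(outer_folds))
    if (length(unique(y[fold == k])) < 2L)
      stop_oscml("outer fold ", k, " contains a single class; ",
                 "reduce outer_folds or rebalance")

  combos <- grid_combinations(spec$grid)
  pooled <- numeric(length(y))
  folds_out <- vector("list", outer_folds)

  for (k in seq_len(outer_folds)) {
    tr <- fold != k
    dtr <- data[tr, , drop = FALSE]
    ytr <- y[tr]
    fold_seed <- derive_seed(seed, paste0("fold", k))

    best <- NULL
    if (length(combos) == 1L && is.null(n_features)) {
      # degenerate grid: nothing to tune, no inner search needed
      best <- list(auc = NA_real_, params = combos[[1]], subset = NULL)
    }
    for (ci in if (is.null(best)) seq_along(combos) else integer(0)) {
      params <- combos[[ci]]
      if (is.null(n_features)) {
        a <- inner_cv_auc(spec$algorithm, params, dtr, ytr, inner_folds,
                          representation, dialect, fold_seed)
        cand <- list(auc = a, params = params, subset = NULL)
        if (is.null(best) || a > best$auc) best <- cand
      } else {
        path <- rfe_path(spec$algorithm, params, dtr, ytr, representation,
                         inner_folds, fold_seed,
                         min_features = min(n_features))
        for (nf in n_features) {
          if (nf >= length(path)) next
          subset <- rfe_select(spec$algorithm, params, dtr, ytr, nf,
                               representation, inner_folds, fold_seed,
                               path = path)
          a <- inner_cv_auc(spec$algorithm, params, dtr, ytr, inner_folds,
                            representation, dialect, fold_seed,
                            feature_subset = subset)
          cand <- list(auc = a, params = params, subset = subset)
          if (is.null(best) || a > best$auc) best <- cand
        }
      }
    }

    pp <- fit_preprocessor(dtr, representation)
    xtr <- apply_preprocessor(pp, dtr)
    xte <- apply_preprocessor(pp, data[!tr, , drop = FALSE])
    if (!is.null(best$subset)) {
      xtr <- xtr[best$subset]
      xte <- xte[best$subset]
    }
    scores <- fit_score(spec$algorithm, best$params, xtr, ytr, xte,
                        dialect = dialect, seed = fold_seed)
    pooled[!tr] <- as.numeric(scores)
    folds_out[[k]] <- list(fold = k, test_idx = which(!tr),
                           params = best$params,
                           inner_auc = best$auc,
                           selected_features = best$subset %||%
                             colnames(xtr),
                           preprocessor = pp,
                           model_info = attr(scores, "model_info"))
  }

  structure(list(algorithm = spec$algorithm,
                 representation = representation,
                 with_rfe = !is.null(n_features),
                 folds = folds_out,
                 fold_assignment = fold,
                 pooled_scores = pooled,
                 labels = y,
                 roc = roc_points(pooled, y),
                 auc = auc_score(pooled, y),
                 seed = seed),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("Nested CV: %s on %s data%s | pooled AUC = %.3f (%d folds)\n",
              x$algorithm, x$representation,
              if (x$with_rfe) " + feature selection" else "",
              x$auc, length(x$folds)))
  invisible(x)
}

#' Selection-frequency table
#'
#' Percentage of (algorithm, outer fold) sub-experiments in which each
#' feature was selected; the denominator is `algorithms x folds`.
#'
#' @param results list of `nested_cv_result`s run with feature selection.
#' @return data.frame with `feature` and `percent`, sorted descending.
#' @export
selection_frequency <- function(results) {
  subsets <- unlist(lapply(results, function(r)
    lapply(r$folds, `[[`, "selected_features")), recursive = FALSE)
  denom <- length(subsets)
  if (denom == 0L) stop_oscml("no sub-experiments in results")
  counts <- table(unlist(subsets))
  out <- data.frame(feature = names(counts),
                    percent = 100 * as.numeric(counts) / denom)
  out[order(-out$percent, out$feature), , drop = FALSE]
}

#' Group comparison statistics
#'
#' Per feature: Shapiro-Wilk normality check within each group and a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test between groups, with
#' significance flagged at p <= 0.05. Zero-variance features are reported
#' with p = 1 and flagged rather than erroring. Membership (fuzzy) columns
#' are compared on their membership values like any other column.
#'
#' @param data data.frame of numeric feature columns.
#' @param labels binary labels.
#' @return data.frame with `feature`, `p_value`, `significant`,
#'   `shapiro_p_g0`, `shapiro_p_g1`, `degenerate`.
#' @export
group_compare <- function(data, labels) {
  data <- as.data.frame(data)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop_oscml("both groups must be non-empty")
  num <- names(data)[vapply(data, is.numeric, TRUE)]
  rows <- lapply(num, function(f) {
    x <- data[[f]]
    degenerate <- sd(x) == 0
    shap <- function(v) {
      if (length(unique(v)) < 3L) return(NA_real_)
      tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
    }
    p <- if (degenerate) 1 else
      suppressWarnings(wilcox.test(x[y == 1L], x[y == 0L],
                                   exact = FALSE)$p.value)
    data.frame(feature = f, p_value = p, significant = p <= 0.05,
               shapiro_p_g0 = shap(x[y == 0L]),
               shapiro_p_g1 = shap(x[y == 1L]),
               degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- experiment drivers --------------------------------------------------

#' Analysis subsets of a cohort feature table
#'
#' The study design compares controls against each disease group
#' separately.
#'
#' @param features table from [cohort_features()].
#' @param analysis `"normal"` (control vs disease-with-normal-spirometry)
#'   or `"altered"`.
#' @return The subset rows, with a `label` column (`control` / `disease`).
#' @export
analysis_subset <- function(features, analysis = c("normal", "altered")) {
  analysis <- match.arg(analysis)
  keep <- features$group %in%
    c("control", paste0("disease_", analysis))
  features[keep, , drop = FALSE]
}

#' Default algorithm set of the evaluation harness
#'
#' Nine score-producing families; the full registry additionally carries
#' the LGBM key (see [algorithm_registry()]).
#' @return Character vector of algorithm keys.
#' @export
experiment_algorithms <- function()
  c("KNN", "SVM", "ADAB", "RF", "XGB", "LR", "DT", "GP", "GE")

#' Experiment 1: univariate feature AUC
#'
#' Orientation-corrected rank AUC of each raw feature, per analysis.
#'
#' @param features table from [cohort_features()].
#' @param analyses which analyses to run.
#' @return data.frame with `analysis`, `feature`, `auc`.
#' @export
experiment1 <- function(features, analyses = c("normal", "altered")) {
  rows <- lapply(analyses, function(an) {
    sub <- analysis_subset(features, an)
    data.frame(analysis = an, feature = feature_names(),
               auc = vapply(feature_names(), function(f)
                 univariate_auc(sub[[f]], sub$label), 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Experiments 2 and 3: nested-CV comparison of classifiers
#'
#' Runs [nested_cv()] for every algorithm and analysis on one data
#' representation. `experiment3` adds recursive feature elimination with
#' the [rfe_n_options()] subset-size grids.
#'
#' @param features table from [cohort_features()].
#' @param representation `"normalized"` or `"fuzzy"`.
#' @param algorithms algorithm keys to run.
#' @param grids named list of hyperparameter grids (defaults to
#'   [default_grids()]); supply reduced grids for quick runs.
#' @param analyses which analyses to run.
#' @param n_features named list (per algorithm) of subset-size options;
#'   only used by `experiment3` (defaults per [rfe_n_options()]).
#' @param outer_folds,inner_folds,seed cross-validation settings.
#' @return Object of class `experiment_result`: list with `auc_table`
#'   (analysis x algorithm AUCs), `runs` (all `nested_cv_result`s, keyed
#'   `<analysis>.<algorithm>`), `representation` and `n_subexperiments`
#'   (algorithms x analyses x outer folds).
#' @export
experiment2 <- function(features, representation = "normalized",
                        algorithms = experiment_algorithms(),
                        grids = default_grids(),
                        analyses = c("normal", "altered"),
                        outer_folds = 10L, inner_folds = 5L, seed = 7L) {
  run_experiment(features, representation, algorithms, grids, analyses,
                 n_features = NULL, outer_folds, inner_folds, seed)
}

#' @rdname experiment2
#' @export
experiment3 <- function(features, representation = "normalized",
                        algorithms = experiment_algorithms(),
                        grids = default_grids(),
                        analyses = c("normal", "altered"),
                        n_features = NULL,
                        outer_folds = 10L, inner_folds = 5L, seed = 7L) {
  n_features <- n_features %||%
    stats::setNames(lapply(algorithms, rfe_n_options, representation),
                    algorithms)
  run_experiment(features, representation, algorithms, grids, analyses,
                 n_features, outer_folds, inner_folds, seed)
}

run_experiment <- function(features, representation, algorithms, grids,
                           analyses, n_features, outer_folds, inner_folds,
                           seed) {
  runs <- list()
  rows <- list()
  for (an in analyses) {
    sub <- analysis_subset(features, an)
    x <- sub[feature_names()]
    y <- sub$label
    for (alg in algorithms) {
      spec <- classifier_spec(alg, grids[[alg]])
      nf <- if (is.null(n_features)) NULL else n_features[[alg]]
      res <- nested_cv(x, y, spec, representation = representation,
                       n_features = nf, outer_folds = outer_folds,
                       inner_folds = inner_folds,
                       seed = derive_seed(seed, paste0(an, "_", alg)))
      runs[[paste(an, alg, sep = ".")]] <- res
      rows[[length(rows) + 1L]] <-
        data.frame(analysis = an, algorithm = alg, auc = res$auc)
    }
  }
  structure(list(auc_table = do.call(rbind, rows),
                 runs = runs,
                 representation = representation,
                 n_subexperiments =
                   length(algorithms) * length(analyses) * outer_folds),
            class = "experiment_result")
}

#' Average absolute LR weights across folds
#'
#' The logistic-regression importance report: per analysis, the mean of
#' the absolute per-fold coefficient of each feature.
#'
#' @param experiment an `experiment_result` containing LR runs.
#' @return data.frame with `analysis`, `feature`, `mean_abs_weight`.
#' @export
lr_weight_averages <- function(experiment) {
  rows <- list()
  for (key in names(experiment$runs)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (parts[2] != "LR") next
    res <- experiment$runs[[key]]
    ws <- lapply(res$folds, function(f) abs(f$model_info$weights))
    feats <- unique(unlist(lapply(ws, names)))
    avg <- vapply(feats, function(f)
      mean(vapply(ws, function(w) {
        v <- w[f]
        if (is.na(v)) 0 else v
      }, 0)), 0)
    rows[[length(rows) + 1L]] <-
      data.frame(analysis = parts[1], feature = feats,
                 mean_abs_weight = unname(avg))
  }
  if (length(rows) == 0L) stop_oscml("experiment contains no LR runs")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interpretable expressions of an experiment
#'
#' Collects the rendered DT / GP / GE models chosen in every outer fold.
#'
#' @param experiment an `experiment_result`.
#' @return data.frame with `analysis`, `algorithm`, `fold`, `expression`.
#' @export
interpretable_expressions <- function(experiment) {
  rows <- list()
  for (key in names(experiment$runs)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (!(parts[2] %in% c("DT", "GP", "GE"))) next
    res <- experiment$runs[[key]]
    for (f in res$folds) {
      expr <- f$model_info$expression
      if (is.null(expr)) next
      rows[[length(rows) + 1L]] <-
        data.frame(analysis = parts[1], algorithm = parts[2],
                   fold = f$fold, expression = expr)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(analysis = character(0), algorithm = character(0),
                      fold = integer(0), expression = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
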