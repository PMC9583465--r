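# Uniform fit/score adapters around the off-the-shelf learners plus the
# two bespoke evolutionary engines. Every adapter sees only training
# labels; test rows are scored with a continuous class-"disease"
# score suitable for ROC analysis.
#
# Availability notes (documented design choices):
#  * ADAB is a discrete AdaBoost (SAMME) built on depth-limited rpart
#    trees.
#  * LGBM denotes a leaf-wise ("lossguide") histogram gradient-boosting
#    adapter backed by xgboost; leaf-wise growth is the defining LightGBM
#    strategy.
#  * DT's split criterion grid collapses to rpart's {gini, information}.

#' Registered classifier algorithms
#'
#' @return Character vector of algorithm keys.
#' @export
algorithm_registry <- function()
  c("KNN", "SVM", "ADAB", "RF", "LGBM", "XGB", "LR", "DT", "GP", "GE")

#' Default hyperparameter grids
#'
#' The grid-search option lists used by the evaluation harness, one named
#' list per algorithm. The gradient-boosting grids are exposed in a
#' corrected orientation by default (estimator counts 10-400, depths 1-60,
#' matching the other ensembles); `corrected = FALSE` swaps LGBM/XGB back
#' to the transposed orientation.
#'
#' @param corrected orientation of the LGBM/XGB grids.
#' @return Named list of grids (algorithm -> named list of option vectors).
#' @export
default_grids <- function(corrected = TRUE) {
  ens_n <- c(10, 30, 60, 100, 200, 400)
  ens_d <- c(1, 2, 3, 4, 5, 10, 15, 30, 60)
  boost <- if (corrected) list(n_estimators = ens_n, max_depth = ens_d)
           else list(n_estimators = ens_d, max_depth = ens_n)
  list(
    KNN = list(k = c(1, 3, 5, 7, 9, 11, 13)),
    SVM = list(cost = c(1, 2, 5, 7, 10, 50, 100, 200, 400),
               gamma = c(0.001, 0.01, 0.05, 0.1, 1)),
    ADAB = list(n_estimators = ens_n, max_depth = ens_d),
    RF = list(n_estimators = ens_n, max_depth = ens_d),
    LGBM = boost,
    XGB = boost,
    LR = list(C = c(0.001, 0.01, 0.1, 1, 10, 100, 1000)),
    DT = list(max_depth = c(2, 3, 4, 5, 10, 50),
              criterion = c("gini", "information")),
    GP = list(population_size = c(100, 300, 500, 1000, 3000),
              generations = c(20, 50, 100, 200),
              init_depth_max = c(2, 6),
              tournament_size = c(2, 7, 20)),
    GE = list(population_size = c(100, 300, 500, 1000, 3000),
              generations = c(50, 100, 200))
  )
}

#' Classifier specification
#'
#' Binds an algorithm key to a hyperparameter grid (defaulting to the
#' algorithm's entry in [default_grids()]).
#'
#' @param algorithm one of [algorithm_registry()].
#' @param grid named list of option vectors; names must be valid
#'   hyperparameters of the algorithm.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm, grid = NULL) {
  if (!(algorithm %in% algorithm_registry()))
    stop_oscml("unknown algorithm '", algorithm, "'; registered: ",
               paste(algorithm_registry(), collapse = ", "))
  grid <- grid %||% default_grids()[[algorithm]]
  known <- names(default_grids()[[algorithm]])
  bad <- setdiff(names(grid), known)
  if (length(bad) > 0)
    stop_oscml("unknown hyperparameter(s) for ", algorithm, ": ",
               paste(bad, collapse = ", "))
  structure(list(algorithm = algorithm, grid = grid),
            class = "classifier_spec")
}

grid_combinations <- function(grid) {
  if (length(grid) == 0L) return(list(list()))
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) as.list(combos[i, , drop = FALSE]))
}

# Discrete AdaBoost (SAMME) with rpart base learners.
fit_adaboost <- function(x, y, n_estimators, max_depth) {
  df <- data.frame(x, .y = factor(y))
  n <- nrow(df)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = max_depth, cp = 0, xval = 0,
                          minsplit = 2, minbucket = 1))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(learners = learners, alphas = alphas)
}

predict_adaboost <- function(model, newx) {
  newdf <- data.frame(newx)
  if (length(model$learners) == 0L) return(rep(0.5, nrow(newdf)))
  votes <- vapply(seq_along(model$learners), function(m) {
    p <- as.integer(as.character(
      predict(model$learners[[m]], newdf, type = "class")))
    model$alphas[m] * ifelse(p == 1, 1, -1)
  }, numeric(nrow(newdf)))
  margin <- if (is.matrix(votes)) rowSums(votes) else sum(votes)
  sigmoid(2 * margin / sum(model$alphas))
}

#' Fit one configuration and score test rows
#'
#' The single entry point the evaluation harness uses: fit `algorithm`
#' with hyperparameters `params` on the training rows and return a
#' continuous class-`1` (disease) score for every test row. Adapters never
#' see test labels. Deterministic given `seed`.
#'
#' @param algorithm one of [algorithm_registry()].
#' @param params named list with one value per hyperparameter (a single
#'   cell of the algorithm's grid).
#' @param train,test numeric feature data.frames sharing columns.
#' @param labels training labels (see [evolve_gp()] for accepted forms).
#' @param dialect expression dialect for GP/GE (`"arithmetic"` on
#'   normalized data, `"fuzzy"` on membership data); ignored otherwise.
#' @param seed integer seed for the stochastic learners.
#' @return Numeric score vector, one per test row, with attribute
#'   `model_info`: a list that may carry `weights` (LR coefficients),
#'   `importance` (native feature importances) or `expression` (rendered
#'   DT/GP/GE model).
#' @export
fit_score <- function(algorithm, params, train, labels, test,
                      dialect = "arithmetic", seed = 7L) {
  if (!(algorithm %in% algorithm_registry()))
    stop_oscml("unknown algorithm '", algorithm, "'")
  train <- as.data.frame(train)
  test <- as.data.frame(test)
  if (!identical(names(train), names(test)))
    stop_oscml("train and test tables must share identical columns")
  y <- as_binary_labels(labels)
  set.seed(derive_seed(seed, paste0("fit_", algorithm)))
  info <- list()
  xtr <- as.matrix(train)
  xte <- as.matrix(test)

  scores <- switch(algorithm,
    KNN = {
      k <- as.integer(params$k)
      pred <- class::knn(xtr, xte, cl = factor(y), k = k, prob = TRUE)
      p_win <- attr(pred, "prob")
      ifelse(pred == "1", p_win, 1 - p_win)
    },
    SVM = {
      fit <- e1071::svm(xtr, factor(y), kernel = "radial",
                        cost = params$cost, gamma = params$gamma,
                        scale = FALSE)
      dec_tr <- attr(predict(fit, xtr, decision.values = TRUE),
                     "decision.values")[, 1]
      flip <- auc_score(dec_tr, y) < 0.5
      dec <- attr(predict(fit, xte, decision.values = TRUE),
                  "decision.values")[, 1]
      if (flip) -dec else dec
    },
    ADAB = {
      model <- fit_adaboost(train, y, as.integer(params$n_estimators),
                            as.integer(params$max_depth))
      predict_adaboost(model, test)
    },
    RF = {
      fit <- ranger::ranger(x = train, y = factor(y),
                            num.trees = as.integer(params$n_estimators),
                            max.depth = as.integer(params$max_depth),
                            probability = TRUE, importance = "impurity",
                            seed = derive_seed(seed, "ranger"),
                            num.threads = 1L)
      info$importance <- fit$variable.importance
      predict(fit, data = test, num.threads = 1L)$predictions[, "1"]
    },
    LGBM = ,
    XGB = {
      grow <- if (algorithm == "LGBM") "lossguide" else "depthwise"
      dtr <- xgboost::xgb.DMatrix(xtr, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = as.integer(params$max_depth),
                      tree_method = "hist", grow_policy = grow,
                      eta = 0.3, nthread = 1L,
                      seed = derive_seed(seed, "xgb")),
        data = dtr, nrounds = as.integer(params$n_estimators),
        verbose = 0)
      imp <- tryCatch(xgboost::xgb.importance(model = fit),
                      error = function(e) NULL)
      if (!is.null(imp)) info$importance <- stats::setNames(imp$Gain, imp$Feature)
      predict(fit, xte)
    },
    LR = {
      n <- nrow(xtr)
      lam <- 1 / (n * params$C)
      if (all(apply(xtr, 2, stats::var) == 0)) {
        # no usable predictor: intercept-only model
        info$weights <- stats::setNames(rep(0, ncol(xtr)), colnames(xtr))
        return(structure(rep(mean(y), nrow(xte)),
                         model_info = info))
      }
      # glmnet requires >= 2 columns; pad with an inert zero column when
      # scoring a single-feature subset
      pad <- ncol(xtr) < 2L
      xtr_g <- if (pad) cbind(xtr, .pad = 0) else xtr
      xte_g <- if (pad) cbind(xte, .pad = 0) else xte
      fit <- glmnet::glmnet(xtr_g, y, family = "binomial", alpha = 0,
                            lambda = lam, standardize = FALSE)
      cf <- as.numeric(stats::coef(fit, s = lam))
      w <- stats::setNames(cf[-1], colnames(xtr_g))
      info$weights <- w[colnames(xtr)]
      as.numeric(stats::predict(fit, xte_g, s = lam, type = "response"))
    },
    DT = {
      df <- data.frame(train, .y = factor(y))
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = params$criterion %||% "gini"),
                          control = rpart::rpart.control(
                            maxdepth = as.integer(params$max_depth),
                            cp = 0, xval = 0, minsplit = 2, minbucket = 1))
      info$expression <- paste(utils::capture.output(print(fit)),
                               collapse = "\n")
      predict(fit, data.frame(test), type = "prob")[, "1"]
    },
    GP = {
      cfg <- gp_config(
        population_size = as.integer(params$population_size %||% 100L),
        generations = as.integer(params$generations %||% 20L),
        init_depth = c(2L, as.integer(params$init_depth_max %||% 6L)),
        tournament_size = as.integer(params$tournament_size %||% 7L),
        seed = derive_seed(seed, "gp"))
      model <- evolve_gp(train, y, cfg, dialect = dialect)
      info$expression <- model$expression
      predict(model, test)
    },
    GE = {
      cfg <- ge_config(
        population_size = as.integer(params$population_size %||% 100L),
        generations = as.integer(params$generations %||% 20L),
        seed = derive_seed(seed, "ge"))
      model <- evolve_ge(train, y, cfg, dialect = dialect,
                         grammar = make_grammar(names(train), dialect))
      info$expression <- model$expression
      predict(model, test)
    })

  scores <- as.numeric(scores)
  attr(scores, "model_info") <- info
  scores
}
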