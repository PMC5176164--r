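FAMILIES <- c("penalised_logistic", "svm", "random_forest", "gbm")

HYPER_NAMES <- list(
  penalised_logistic = c("mixing", "strength"),
  svm = c("cost", "gamma", "coef0", "degree"),
  random_forest = c("n_trees", "vars_per_split", "min_node_size"),
  gbm = c("learning_rate", "max_depth", "n_rounds", "subsample")
)

#' Construct a validated model configuration
#'
#' @param family one of penalised_logistic, svm, random_forest, gbm.
#' @param kernel SVM kernel (linear, polynomial, radial, sigmoid); SVM only.
#' @param hyperparameters named list; allowed names per family:
#'   penalised_logistic: mixing (elastic-net mixing in \[0,1\]) and strength
#'   (penalty strength lambda); svm: cost, gamma, coef0, degree;
#'   random_forest: n_trees, vars_per_split, min_node_size; gbm:
#'   learning_rate, max_depth, n_rounds, subsample.
#' @param seed integer seed used at fit time.
#' @return object of class `model_config`.
#' @export
model_config <- function(family, kernel = NULL, hyperparameters = list(), seed = 1) {
  family <- match.arg(family, FAMILIES)
  if (family == "svm") {
    kernel <- match.arg(kernel, c("linear", "polynomial", "radial", "sigmoid"))
  } else if (!is.null(kernel)) {
    stop("kernel is only meaningful for the svm family", call. = FALSE)
  }
  unknown <- setdiff(names(hyperparameters), HYPER_NAMES[[family]])
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hp <- hyperparameters
  pos <- intersect(names(hp), c("cost", "gamma", "n_trees", "n_rounds",
                                "max_depth", "degree", "strength",
                                "learning_rate", "vars_per_split", "min_node_size"))
  for (nm in pos) {
    if (hp[[nm]] <= 0) stop("hyperparameter ", nm, " must be strictly positive", call. = FALSE)
  }
  if (!is.null(hp$subsample) && (hp$subsample <= 0 || hp$subsample > 1)) {
    stop("subsample must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(hp$mixing) && (hp$mixing < 0 || hp$mixing > 1)) {
    stop("mixing must be in [0, 1]", call. = FALSE)
  }
  structure(list(family = family, kernel = kernel, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_config")
}

# Predictor matrix in schema order, with validation.
.predictor_matrix <- function(data, schema) {
  missing <- setdiff(schema, names(data))
  extra <- setdiff(predictor_columns(data), schema)
  if (length(missing) || length(extra)) {
    stop("predictor schema mismatch; missing: [",
         paste(missing, collapse = ", "), "] extra: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  X <- as.matrix(data[, schema, drop = FALSE])
  bad <- colnames(X)[!apply(is.finite(X), 2, all)]
  if (length(bad)) {
    stop("non-finite predictor value(s) in column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

# Columns treated as continuous (standardised for scale-sensitive families):
# anything that is not a 0/1 indicator.
.continuous_cols <- function(X) {
  which(apply(X, 2, function(v) any(v != 0 & v != 1)))
}

#' Fit a classifier from one model family
#'
#' Penalised multinomial logistic regression (glmnet elastic-net), SVM
#' (e1071; one-vs-one with probability calibration), random forest
#' (randomForest) or stochastic gradient-boosted trees (xgboost,
#' multi:softprob). Continuous predictors are standardised at fit time for
#' the scale-sensitive families (logistic, SVM) with the constants stored in
#' the model; tree families consume raw features.
#'
#' @param config a [model_config()].
#' @param train labelled feature table with encoded predictors and a
#'   `category` column with at least two classes.
#' @return object of class `trained_model`.
#' @export
fit_model <- function(config, train) {
  stopifnot(inherits(config, "model_config"))
  schema <- predictor_columns(train)
  X <- .predictor_matrix(train, schema)
  classes <- if (all(unique(train$category) %in% CLASS_ORDER)) {
    intersect(CLASS_ORDER, unique(train$category))
  } else sort(unique(train$category))
  if (length(classes) < 2) {
    stop("training data has a single class: ", classes, call. = FALSE)
  }
  y <- factor(train$category, levels = classes)
  hp <- config$hyperparameters

  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  if (config$family %in% c("penalised_logistic", "svm")) {
    cc <- .continuous_cols(X)
    center[cc] <- colMeans(X[, cc, drop = FALSE])
    s <- apply(X[, cc, drop = FALSE], 2, stats::sd)
    scale[cc] <- ifelse(s > 0, s, 1)
    X <- sweep(sweep(X, 2, center), 2, scale, "/")
  }

  set.seed(config$seed)
  fit <- switch(config$family,
    penalised_logistic = {
      lambda <- if (is.null(hp$strength)) 0.001 else hp$strength
      alpha <- if (is.null(hp$mixing)) 0.5 else hp$mixing
      # decreasing warm-start path ending at the target penalty strength
      path <- exp(seq(log(max(1, lambda * 100)), log(lambda), length.out = 30))
      f <- glmnet::glmnet(X, y, family = "multinomial", alpha = alpha,
                          lambda = path)
      attr(f, "target_lambda") <- lambda
      f
    },
    svm = {
      e1071::svm(X, y, kernel = config$kernel,
                 cost = if (is.null(hp$cost)) 1 else hp$cost,
                 gamma = if (is.null(hp$gamma)) 1 / ncol(X) else hp$gamma,
                 coef0 = if (is.null(hp$coef0)) 0 else hp$coef0,
                 degree = if (is.null(hp$degree)) 3 else hp$degree,
                 probability = TRUE, scale = FALSE)
    },
    random_forest = {
      randomForest::randomForest(
        X, y,
        ntree = if (is.null(hp$n_trees)) 500 else hp$n_trees,
        mtry = min(if (is.null(hp$vars_per_split)) floor(sqrt(ncol(X)))
                   else hp$vars_per_split, ncol(X)),
        nodesize = if (is.null(hp$min_node_size)) 1 else hp$min_node_size)
    },
    gbm = {
      dm <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = length(classes),
                      eta = if (is.null(hp$learning_rate)) 0.1 else hp$learning_rate,
                      max_depth = if (is.null(hp$max_depth)) 4 else hp$max_depth,
                      subsample = if (is.null(hp$subsample)) 1 else hp$subsample,
                      nthread = 1, seed = config$seed),
        data = dm,
        nrounds = if (is.null(hp$n_rounds)) 100 else hp$n_rounds,
        verbose = 0)
    })

  structure(
    list(config = config, fit = fit, schema = schema, classes = classes,
         center = center, scale = scale,
         class_counts = table(y)),
    class = "trained_model"
  )
}

#' Predict classes and class probabilities
#'
#' @param model a [fit_model()] result.
#' @param data feature table whose predictor schema matches training.
#' @return data.frame with `class` and one probability column per class
#'   (columns in fixed class order; rows sum to 1). Argmax ties break by
#'   class order.
#' @export
predict_model <- function(model, data) {
  stopifnot(inherits(model, "trained_model"))
  if (nrow(data) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(model$classes)))
    names(out) <- model$classes
    return(cbind(data.frame(class = character(0)), out))
  }
  X <- .predictor_matrix(data, model$schema)
  if (model$config$family %in% c("penalised_logistic", "svm")) {
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  }
  prob <- switch(model$config$family,
    penalised_logistic = {
      p <- predict(model$fit, X, type = "response",
                   s = attr(model$fit, "target_lambda"))
      p[, , 1, drop = TRUE]
    },
    svm = {
      pr <- predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")
    },
    random_forest = predict(model$fit, X, type = "prob"),
    gbm = {
      p <- predict(model$fit, xgboost::xgb.DMatrix(X))
      if (!is.matrix(p)) {
        p <- matrix(p, nrow(X), length(model$classes), byrow = TRUE)
      }
      dimnames(p) <- list(NULL, model$classes)
      p
    })
  if (nrow(X) == 1 && is.null(dim(prob))) {
    prob <- matrix(prob, 1, dimnames = list(NULL, names(prob)))
  }
  prob <- prob[, model$classes, drop = FALSE]
  prob <- prob / rowSums(prob)
  cls <- model$classes[max.col(prob, ties.method = "first")]
  out <- data.frame(class = cls, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(prob))
}

#' Hyperparameter grids
#'
#' `published_grids()` ships the best reported parameter points per family for
#' each feature arm (these are the published best parameters, including the
#' polynomial SVM at degree 4, gamma 0.01, coef0 4). `protocol_grids()` is
#' the scaled-down default used by [run_protocol()] on synthetic cohorts:
#' same families and structure, fewer boosting rounds and trees so a full
#' cross-validated comparison runs in minutes.
#'
#' @param with_features which feature arm the grid targets.
#' @return named list: family -> list of [model_config()] argument lists.
#' @export
published_grids <- function(with_features = TRUE) {
  path <- system.file("extdata", "published_grids.yaml", package = "sealgram")
  load_grids(path, arm = if (with_features) "features_true" else "features_false")
}

#' @rdname published_grids
#' @export
protocol_grids <- function(with_features = TRUE) {
  list(
    gbm = list(list(hyperparameters = list(learning_rate = 0.1, max_depth = 4,
                                           n_rounds = 150, subsample = 0.8))),
    random_forest = list(list(hyperparameters = list(vars_per_split = 8,
                                                     n_trees = 300,
                                                     min_node_size = 3))),
    penalised_logistic = list(list(hyperparameters = list(mixing = 0.10,
                                                          strength = 0.0018))),
    svm = list(list(kernel = "polynomial",
                    hyperparameters = list(cost = 1, coef0 = 4,
                                           gamma = 0.01, degree = 4)))
  )
}

#' Grid search with inner 70/30 split and 10-fold cross-validation
#'
#' The training table is split 70/30 at the epoch level (folds may mix
#' subjects). Every grid point is scored by mean out-of-fold accuracy of
#' 10-fold cross-validation on the 70% split; the best point is refit on
#' the full 70% and its accuracy reported on the 30% validation split.
#' Fold assignment is keyed to sorted (subject, epoch) identity, not row
#' position, so shuffling the input rows does not change the result.
#'
#' @param grids named list family -> list of config argument lists (see
#'   [published_grids()]).
#' @param train labelled, encoded feature table.
#' @param n_folds number of CV folds (default 10).
#' @param inner_fraction fraction used for CV (default 0.70).
#' @param seed integer seed.
#' @return named list per family: `best_config`, `cv_accuracy`,
#'   `validation_accuracy`, `trace` (data.frame of all grid points).
#' @export
grid_search <- function(grids, train, n_folds = 10, inner_fraction = 0.70,
                        seed = 1) {
  if (length(grids) == 0 || any(vapply(grids, length, integer(1)) == 0)) {
    stop("grid must be non-empty for every family", call. = FALSE)
  }
  n <- nrow(train)
  if (n_folds > n) stop("n_folds exceeds number of rows", call. = FALSE)
  # canonical epoch-identity order -> permutation invariance
  ord <- order(train$subject_id, train$epoch_index)
  train <- train[ord, , drop = FALSE]
  set.seed(derive_seed(seed, "grid"))
  perm <- sample(n)
  n_inner <- floor(inner_fraction * n)
  inner <- train[perm[seq_len(n_inner)], , drop = FALSE]
  valid <- train[perm[-seq_len(n_inner)], , drop = FALSE]
  folds <- sample(rep(seq_len(n_folds), length.out = n_inner))

  out <- list()
  for (family in names(grids)) {
    trace <- list()
    for (gi in seq_along(grids[[family]])) {
      args <- grids[[family]][[gi]]
      cfg <- model_config(family, kernel = args$kernel,
                          hyperparameters = args$hyperparameters,
                          seed = derive_seed(seed, paste0(family, "/", gi)))
      accs <- vapply(seq_len(n_folds), function(f) {
        tr <- inner[folds != f, , drop = FALSE]
        te <- inner[folds == f, , drop = FALSE]
        m <- fit_model(cfg, tr)
        mean(predict_model(m, te)$class == te$category)
      }, numeric(1))
      trace[[gi]] <- data.frame(family = family, grid_index = gi,
                                cv_accuracy = mean(accs))
    }
    trace <- do.call(rbind, trace)
    best <- which.max(trace$cv_accuracy)
    args <- grids[[family]][[best]]
    cfg <- model_config(family, kernel = args$kernel,
                        hyperparameters = args$hyperparameters,
                        seed = derive_seed(seed, paste0(family, "/final")))
    m <- fit_model(cfg, inner)
    val_acc <- mean(predict_model(m, valid)$class == valid$category)
    out[[family]] <- list(best_config = cfg,
                          cv_accuracy = trace$cv_accuracy[best],
                          validation_accuracy = val_acc,
                          trace = trace)
  }
  out
}
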