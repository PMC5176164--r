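test_that("model configurations are validated", {
  expect_error(model_config("svm", kernel = "radial",
                            hyperparameters = list(bandwidth = 1)), "unknown hyperparameter")
  expect_error(model_config("random_forest",
                            hyperparameters = list(n_trees = -5)), "strictly positive")
  expect_error(model_config("gbm",
                            hyperparameters = list(subsample = 1.5)), "subsample")
  expect_error(model_config("random_forest", kernel = "linear"), "svm")
  cfg <- model_config("svm", kernel = "polynomial",
                      hyperparameters = list(cost = 1, gamma = 0.01,
                                             coef0 = 4, degree = 4))
  expect_s3_class(cfg, "model_config")
})

test_that("a linear SVM separates linearly separable classes perfectly", {
  ft <- make_toy_features(sep = 4)
  cfg <- model_config("svm", kernel = "linear",
                      hyperparameters = list(cost = 100))
  m <- fit_model(cfg, ft)
  p <- predict_model(m, ft)
  expect_equal(mean(p$class == ft$category), 1)
})

test_that("every family beats the majority baseline on its training data", {
  ft <- make_toy_features(n_per_class = 50,
                          classes = c("foraging", "grooming", "resting", "travelling"),
                          sep = 1.5)
  baseline <- max(table(ft$category)) / nrow(ft)
  for (family in c("penalised_logistic", "svm", "random_forest", "gbm")) {
    cfg <- model_config(family, kernel = if (family == "svm") "radial" else NULL,
                        seed = 2)
    m <- fit_model(cfg, ft)
    acc <- mean(predict_model(m, ft)$class == ft$category)
    expect_gte(acc, baseline)
  }
})

test_that("fits are deterministic given the seed", {
  ft <- make_toy_features(n_per_class = 40, sep = 1)
  probe <- make_toy_features(n_per_class = 15, sep = 1, seed = 123)
  for (family in c("penalised_logistic", "svm", "random_forest", "gbm")) {
    cfg <- model_config(family, kernel = if (family == "svm") "radial" else NULL,
                        seed = 7)
    p1 <- predict_model(fit_model(cfg, ft), probe)
    p2 <- predict_model(fit_model(cfg, ft), probe)
    expect_identical(p1, p2)
  }
})

test_that("predicted probabilities live on the simplex", {
  ft <- make_toy_features(n_per_class = 40,
                          classes = c("foraging", "resting", "travelling"), sep = 1)
  for (family in c("penalised_logistic", "svm", "random_forest", "gbm")) {
    cfg <- model_config(family, kernel = if (family == "svm") "radial" else NULL)
    m <- fit_model(cfg, ft)
    p <- predict_model(m, ft)
    probs <- as.matrix(p[, m$classes])
    expect_true(all(probs >= 0))
    expect_equal(unname(rowSums(probs)), rep(1, nrow(p)), tolerance = 1e-9)
    expect_equal(p$class, m$classes[apply(probs, 1, which.max)])
  }
})

test_that("degenerate inputs are rejected with clear messages", {
  ft <- make_toy_features()
  one <- ft[ft$category == "foraging", ]
  attr(one, "epoch_len") <- 13L; attr(one, "stride") <- 13L
  expect_error(fit_model(model_config("random_forest"), one), "single class")
  bad <- ft; bad$f1[3] <- NA
  expect_error(fit_model(model_config("random_forest"), bad), "f1")
  m <- fit_model(model_config("random_forest"), ft)
  probe <- ft; probe$f3 <- 1; probe$f1 <- NULL
  expect_error(predict_model(m, probe), "missing: \\[f1\\].*extra: \\[f3\\]")
})

test_that("empty prediction sets are vacuously valid", {
  ft <- make_toy_features()
  m <- fit_model(model_config("random_forest"), ft)
  p <- predict_model(m, ft[0, ])
  expect_equal(nrow(p), 0)
  expect_named(p, c("class", m$classes))
})

test_that("a duplicated training row is recalled by a deep forest", {
  ft <- make_toy_features(n_per_class = 30, sep = 0.5, seed = 11)
  # plant a far-out probe duplicated many times with one fixed class
  probe_row <- ft[1, ]
  probe_row$f1 <- 25; probe_row$f2 <- 25; probe_row$category <- "travelling"
  planted <- do.call(rbind, replicate(30, probe_row, simplify = FALSE))
  planted$epoch_index <- max(ft$epoch_index) + seq_len(nrow(planted))
  aug <- rbind(ft, planted)
  attr(aug, "epoch_len") <- 13L; attr(aug, "stride") <- 13L
  cfg <- model_config("random_forest",
                      hyperparameters = list(n_trees = 200, min_node_size = 1))
  m <- fit_model(cfg, aug)
  p <- predict_model(m, planted[1, ])
  expect_equal(p$class, "travelling")
})

test_that("standardisation constants are stored and applied for scale-sensitive families", {
  ft <- make_toy_features(sep = 2)
  m <- fit_model(model_config("penalised_logistic"), ft)
  cont <- which(m$schema %in% c("f1", "f2"))
  expect_equal(m$center[cont], colMeans(as.matrix(ft[, c("f1", "f2")])),
               ignore_attr = TRUE)
  shifted <- ft
  shifted$f1 <- shifted$f1 * 1000  # schema same, scale wildly different
  m2 <- fit_model(model_config("penalised_logistic"), shifted)
  p2 <- predict_model(m2, shifted)
  expect_gt(mean(p2$class == shifted$category), 0.9)
})

test_that("grid search returns the single point of a degenerate grid", {
  ft <- make_toy_features(n_per_class = 60, sep = 2)
  grids <- list(random_forest = list(list(hyperparameters = list(n_trees = 50))))
  gs <- grid_search(grids, ft, n_folds = 4, seed = 1)
  expect_named(gs, "random_forest")
  expect_equal(gs$random_forest$best_config$hyperparameters$n_trees, 50)
  expect_true(gs$random_forest$validation_accuracy >= 0 &&
                gs$random_forest$validation_accuracy <= 1)
  expect_error(grid_search(grids, ft, n_folds = 10000), "n_folds")
  expect_error(grid_search(list(random_forest = list()), ft), "non-empty")
})

test_that("grid search is invariant to row order", {
  ft <- make_toy_features(n_per_class = 60, sep = 1)
  grids <- list(
    random_forest = list(list(hyperparameters = list(n_trees = 50)),
                         list(hyperparameters = list(n_trees = 100))))
  gs1 <- grid_search(grids, ft, n_folds = 4, seed = 5)
  set.seed(77)
  shuffled <- ft[sample(nrow(ft)), ]
  attr(shuffled, "epoch_len") <- 13L; attr(shuffled, "stride") <- 13L
  gs2 <- grid_search(grids, shuffled, n_folds = 4, seed = 5)
  expect_equal(gs1$random_forest$trace, gs2$random_forest$trace)
  expect_equal(gs1$random_forest$validation_accuracy,
               gs2$random_forest$validation_accuracy)
})

test_that("the published best-parameter grid points are shipped", {
  g <- published_grids(with_features = TRUE)
  svm_pt <- g$svm[[1]]
  expect_equal(svm_pt$kernel, "polynomial")
  expect_equal(svm_pt$hyperparameters,
               list(cost = 0.1, coef0 = 4, gamma = 0.01, degree = 4))
  expect_equal(g$gbm[[1]]$hyperparameters$n_rounds, 5000)
  expect_equal(g$random_forest[[1]]$hyperparameters$n_trees, 1000)
  g0 <- published_grids(with_features = FALSE)
  expect_equal(g0$svm[[1]]$hyperparameters,
               list(degree = 4, gamma = 0.01, coef0 = 4, cost = 1))
  expect_equal(g0$penalised_logistic[[1]]$hyperparameters,
               list(mixing = 0.810, strength = 0.0012))
})

test_that("the logistic baseline does not beat the best nonlinear family on ring data", {
  # nonlinearly separable: class by radius
  set.seed(21)
  n <- 300
  r <- sqrt(runif(n)) * 2
  th <- runif(n, 0, 2 * pi)
  ft <- data.frame(epoch_index = 1:n, subject_id = "S01",
                   f1 = r * cos(th), f2 = r * sin(th),
                   category = ifelse(r < 1.2, "resting", "travelling"),
                   stringsAsFactors = FALSE)
  attr(ft, "epoch_len") <- 13L; attr(ft, "stride") <- 13L
  probe <- ft[sample(n, 100), ]
  acc <- function(family, kernel = NULL) {
    cfg <- model_config(family, kernel = kernel, seed = 3)
    mean(predict_model(fit_model(cfg, ft), probe)$class == probe$category)
  }
  best_nonlinear <- max(acc("svm", "radial"), acc("random_forest"), acc("gbm"))
  expect_lte(acc("penalised_logistic"), best_nonlinear)
})
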