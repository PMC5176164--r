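MODEL_ARCHIVE_VERSION <- 1L

#' Save / load a trained model as a versioned archive
#'
#' The archive is a directory holding `schema.json` (format version, family,
#' kernel, hyperparameters, class labels, predictor schema and
#' standardisation constants) plus the serialized fitted state
#' (`state.rds`; boosted trees are stored in the booster's own raw format
#' inside it). `load_model` refuses archives with a different format
#' version.
#'
#' @param model a [fit_model()] result.
#' @param dir archive directory (created if needed).
#' @return `save_model`: the directory, invisibly. `load_model`: the
#'   restored `trained_model`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "trained_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  schema <- list(
    version = MODEL_ARCHIVE_VERSION,
    family = model$config$family,
    kernel = model$config$kernel,
    hyperparameters = model$config$hyperparameters,
    seed = model$config$seed,
    classes = model$classes,
    predictor_schema = model$schema,
    center = model$center,
    scale = model$scale,
    class_counts = as.list(model$class_counts)
  )
  jsonlite::write_json(schema, file.path(dir, "schema.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state <- if (model$config$family == "gbm") {
    list(kind = "xgb_raw", raw = xgboost::xgb.save.raw(model$fit),
         target_lambda = NULL)
  } else {
    list(kind = "rds", fit = model$fit)
  }
  saveRDS(state, file.path(dir, "state.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  sfile <- file.path(dir, "schema.json")
  if (!file.exists(sfile)) stop("not a model archive: missing ", sfile, call. = FALSE)
  schema <- jsonlite::read_json(sfile, simplifyVector = TRUE)
  if (!identical(as.integer(schema$version), MODEL_ARCHIVE_VERSION)) {
    stop("unsupported model archive version: ", schema$version, call. = FALSE)
  }
  if (length(schema$kernel) == 0) schema$kernel <- NULL
  state <- readRDS(file.path(dir, "state.rds"))
  fit <- if (identical(state$kind, "xgb_raw")) {
    xgboost::xgb.load.raw(state$raw)
  } else {
    state$fit
  }
  cfg <- model_config(schema$family, kernel = schema$kernel,
                      hyperparameters = as.list(schema$hyperparameters),
                      seed = schema$seed)
  structure(
    list(config = cfg, fit = fit, schema = schema$predictor_schema,
         classes = schema$classes, center = schema$center,
         scale = schema$scale,
         class_counts = unlist(schema$class_counts)),
    class = "trained_model"
  )
}

#' Load hyperparameter grids from a YAML definition
#'
#' The file maps arm names to family grids; each family holds a list of
#' grid points (`kernel` where applicable plus a `hyperparameters` map).
#' The published best-parameter grids ship with the package as
#' `system.file("extdata", "published_grids.yaml", package = "sealgram")`.
#'
#' @param path YAML file path.
#' @param arm which top-level arm entry to return; NULL returns all.
#' @return named list: family -> list of config argument lists.
#' @export
load_grids <- function(path, arm = NULL) {
  g <- yaml::read_yaml(path)
  if (!is.null(arm)) {
    if (!arm %in% names(g)) {
      stop("no grid arm named '", arm, "' in ", path, call. = FALSE)
    }
    g <- g[[arm]]
  }
  g
}
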