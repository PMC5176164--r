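#' Label epochs from a per-sample label track
#'
#' Each epoch is labelled with the majority category of its samples. Exact
#' majority ties are broken by precedence foraging > grooming > travelling >
#' resting > 'other' (grooming and foraging take precedence over travelling
#' and resting, and foraging over grooming on a direct tie). Epochs whose
#' assigned category is 'other' are dropped; the count of dropped epochs is
#' recorded in the `dropped_epochs` attribute and reported via a message.
#'
#' @param features feature table from [epoch_features()] (its `epoch_len`
#'   and `stride` attributes define the sample window of each epoch).
#' @param labels per-sample label data.frame with a `category` column (as
#'   from [simulate_session()]).
#' @return the feature table with a `category` column, 'other' epochs removed.
#' @export
label_epochs <- function(features, labels) {
  epoch_len <- attr(features, "epoch_len")
  stride <- attr(features, "stride")
  if (is.null(epoch_len) || is.null(stride)) {
    stop("features must carry epoch_len/stride attributes", call. = FALSE)
  }
  n_epochs <- nrow(features)
  if (n_epochs == 0) return(cbind(features, category = character(0)))
  starts <- (features$epoch_index - 1L) * stride + 1L
  ends <- starts + epoch_len - 1L
  if (max(ends) > nrow(labels)) {
    stop("label track does not cover every sample of epoch ",
         features$epoch_index[which.max(ends)], call. = FALSE)
  }
  cat_col <- labels$category
  if (anyNA(cat_col)) {
    first_bad <- which(vapply(seq_len(n_epochs), function(i)
      anyNA(cat_col[starts[i]:ends[i]]), logical(1)))[1]
    stop("unlabelled samples in epoch ", features$epoch_index[first_bad], call. = FALSE)
  }
  assigned <- vapply(seq_len(n_epochs), function(i) {
    counts <- table(factor(cat_col[starts[i]:ends[i]], levels = CATEGORY_PRECEDENCE))
    # which.max on precedence-ordered levels implements the tie rule
    names(counts)[which.max(counts)]
  }, character(1))
  keep <- assigned != "other"
  dropped <- sum(!keep)
  out <- features[keep, , drop = FALSE]
  out$category <- assigned[keep]
  rownames(out) <- NULL
  for (a in c("epoch_len", "stride", "n_samples")) {
    attr(out, a) <- attr(features, a)
  }
  attr(out, "dropped_epochs") <- dropped
  if (dropped > 0) message(dropped, " epoch(s) in category 'other' dropped")
  out
}

# Predictor columns = everything except identifiers and the label.
ID_COLUMNS <- c("epoch_index", "subject_id", "category")

#' Predictor column names of a feature table
#' @param features a (labelled) feature table.
#' @return character vector of predictor column names.
#' @export
predictor_columns <- function(features) {
  setdiff(names(features), c(ID_COLUMNS, "place"))
}

PLACE_LEVELS <- c("surface", "underwater", "land")
SPECIES_LEVELS <- c("AFS", "NZFS", "SFS", "ASL")

one_hot <- function(x, levels, prefix) {
  m <- outer(x, levels, `==`) * 1L
  colnames(m) <- paste0(prefix, "_", gsub("[^A-Za-z0-9]", "_", levels))
  as.data.frame(m)
}

#' Attach place indicators and optional subject covariates
#'
#' The epoch's place (surface / underwater / land) is always one-hot
#' encoded into the predictors. When `enabled`, five subject covariate
#' groups are added from the cohort profiles: attachment method, age, mass,
#' sex and species, with categorical groups one-hot encoded in a fixed
#' column order.
#'
#' @param features labelled feature table with a `place` column.
#' @param cohort data.frame of subject profiles ([generate_cohort()]).
#' @param enabled add the five subject covariate groups?
#' @return feature table with encoded covariates replacing the raw `place`.
#' @export
attach_subject_features <- function(features, cohort, enabled = FALSE) {
  if (!all(features$subject_id %in% cohort$subject_id)) {
    missing <- setdiff(unique(features$subject_id), cohort$subject_id)
    stop("no profile for subject(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(features$place %in% PLACE_LEVELS)) {
    stop("unknown place value(s): ",
         paste(setdiff(unique(features$place), PLACE_LEVELS), collapse = ", "),
         call. = FALSE)
  }
  out <- features[, setdiff(names(features), "place"), drop = FALSE]
  out <- cbind(out, one_hot(features$place, PLACE_LEVELS, "place"))
  if (enabled) {
    prof <- cohort[match(features$subject_id, cohort$subject_id), ]
    if (!all(prof$species %in% SPECIES_LEVELS)) {
      stop("unknown species value(s): ",
           paste(setdiff(unique(prof$species), SPECIES_LEVELS), collapse = ", "),
           call. = FALSE)
    }
    if (!all(prof$attachment %in% c("harness", "tape"))) {
      stop("unknown attachment value(s)", call. = FALSE)
    }
    if (!all(prof$sex %in% c("female", "male"))) {
      stop("unknown sex value(s)", call. = FALSE)
    }
    out <- cbind(out,
                 one_hot(prof$attachment, c("harness", "tape"), "attachment"),
                 age = prof$age, mass = prof$mass,
                 one_hot(prof$sex, c("female", "male"), "sex"),
                 one_hot(prof$species, SPECIES_LEVELS, "species"))
  }
  for (a in c("epoch_len", "stride")) attr(out, a) <- attr(features, a)
  rownames(out) <- NULL
  out
}

#' Split a feature table into training and held-out subjects
#'
#' Two subjects are held out entirely. By default the pair is stratified to
#' represent the cohort's range: one female sea lion (ASL) and one male fur
#' seal (AFS/NZFS/SFS) when available, otherwise a seeded random pair.
#'
#' @param features labelled feature table.
#' @param cohort subject profiles.
#' @param seed integer seed for the (stratified or random) choice.
#' @param stratified use the female-sea-lion / male-fur-seal default?
#' @return list with `train`, `holdout` (feature tables) and
#'   `holdout_subjects` (character vector of length 2).
#' @export
split_subjects <- function(features, cohort, seed = 1, stratified = TRUE) {
  subjects <- unique(features$subject_id)
  if (length(subjects) < 3) stop("need >= 3 subjects to split", call. = FALSE)
  cohort <- cohort[cohort$subject_id %in% subjects, ]
  set.seed(derive_seed(seed, "split"))
  holdout <- NULL
  if (stratified) {
    fem_asl <- cohort$subject_id[cohort$species == "ASL" & cohort$sex == "female"]
    male_fur <- cohort$subject_id[cohort$species != "ASL" & cohort$sex == "male"]
    if (length(fem_asl) > 0 && length(male_fur) > 0) {
      holdout <- c(sample(fem_asl, 1), sample(male_fur, 1))
    }
  }
  if (is.null(holdout)) holdout <- sample(subjects, 2)
  in_hold <- features$subject_id %in% holdout
  train <- features[!in_hold, , drop = FALSE]
  test <- features[in_hold, , drop = FALSE]
  for (a in c("epoch_len", "stride")) {
    attr(train, a) <- attr(features, a); attr(test, a) <- attr(features, a)
  }
  list(train = train, holdout = test, holdout_subjects = holdout)
}

#' Under-sample over-represented classes in a training table
#'
#' Classes above `class_cap` are reduced to exactly the cap by seeded
#' uniform sampling without replacement; classes at or below the cap are
#' untouched. Rows are then shuffled deterministically. Apply to training
#' data only — held-out data stays unbalanced.
#'
#' @param train labelled feature table.
#' @param class_cap maximum epochs per class (default 3000).
#' @param seed integer seed.
#' @return the balanced feature table.
#' @export
undersample <- function(train, class_cap = 3000, seed = 1) {
  if (class_cap <= 0) stop("class_cap must be positive", call. = FALSE)
  set.seed(derive_seed(seed, "undersample"))
  keep <- unlist(lapply(split(seq_len(nrow(train)), train$category), function(idx) {
    if (length(idx) > class_cap) sample(idx, class_cap) else idx
  }), use.names = FALSE)
  keep <- sample(keep)  # deterministic shuffle under the seed above
  out <- train[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("epoch_len", "stride")) attr(out, a) <- attr(train, a)
  out
}
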