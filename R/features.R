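#' Names of the 52 epoch-level movement statistics, in stable column order
#'
#' Ten statistics per raw axis (30), four raw-magnitude (q) summaries,
#' three pairwise axis correlations, mean inclination and azimuth, three
#' per-axis PDBA means, four ODBA and four VeDBA summaries, and the
#' trapezoidal AUC of ODBA and VeDBA.
#'
#' @return character vector of length 52.
#' @export
feature_names <- function() {
  per_axis <- c("mean", "median", "sd", "skew", "kurt", "min", "max",
                "absmean", "icv", "ar1")
  c(as.vector(t(outer(c("x", "y", "z"), per_axis, paste, sep = "_"))),
    paste0("q_", c("mean", "sd", "min", "max")),
    c("corr_xy", "corr_yz", "corr_xz"),
    c("incl_mean", "azim_mean"),
    paste0("pdba_", c("x", "y", "z"), "_mean"),
    paste0("odba_", c("mean", "sd", "min", "max")),
    paste0("vedba_", c("mean", "sd", "min", "max")),
    c("auc_odba", "auc_vedba"))
}

# Column-wise helpers over an epoch matrix (rows = samples within epoch).
.col_sd <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  sqrt(colSums((M - rep(mu, each = n))^2) / (n - 1))
}
.col_moment_stats <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  C <- M - rep(mu, each = n)
  m2 <- colMeans(C^2); m3 <- colMeans(C^3); m4 <- colMeans(C^4)
  zero <- m2 <= 0
  skew <- ifelse(zero, 0, m3 / m2^1.5)
  kurt <- ifelse(zero, 0, m4 / m2^2 - 3)
  list(mean = mu, m2 = m2, skew = skew, kurt = kurt, zero = zero)
}
# AR(1) regression slope within each epoch: slope of x[t] ~ x[t-1].
.col_ar1 <- function(M) {
  n <- nrow(M)
  a <- M[-n, , drop = FALSE]; b <- M[-1, , drop = FALSE]
  va <- colMeans(a^2) - colMeans(a)^2
  cv <- colMeans(a * b) - colMeans(a) * colMeans(b)
  ifelse(va <= 0, 0, cv / va)
}
.col_cor <- function(A, B) {
  n <- nrow(A)
  va <- colMeans(A^2) - colMeans(A)^2
  vb <- colMeans(B^2) - colMeans(B)^2
  cv <- colMeans(A * B) - colMeans(A) * colMeans(B)
  ifelse(va <= 0 | vb <= 0, 0, cv / sqrt(va * vb))
}
# Trapezoidal AUC down each column with spacing dt.
.col_auc <- function(M, dt) {
  n <- nrow(M)
  dt * (colSums(M) - (M[1, ] + M[n, ]) / 2)
}

#' Summarise a decomposed trace into epoch-level feature vectors
#'
#' Cuts the trace into epochs of `epoch_len` samples taken every `stride`
#' samples (defaults: non-overlapping 13-sample epochs, about 0.5 s at
#' 25 Hz) and computes the 52 movement statistics per epoch: per raw axis
#' mean, median, sd, skewness, excess kurtosis, min, max, mean absolute
#' value, inverse coefficient of variation (mean/sd) and the AR(1)
#' regression slope (30); mean/sd/min/max of the raw magnitude q (4);
#' pairwise axis correlations (3); mean inclination and azimuth (2); mean
#' per-axis PDBA (3); mean/sd/min/max of ODBA (4) and of VeDBA (4); and
#' trapezoidal AUC of ODBA and VeDBA with dt = 1/rate (2).
#'
#' Degenerate epochs (zero-variance axis) get skewness, kurtosis, AR(1),
#' correlations and inverse CV set to 0 and are flagged in the
#' `degenerate` attribute.
#'
#' @param dec a [decompose_acceleration()] result.
#' @param trace the trace the decomposition came from (for place/subject).
#' @param epoch_len epoch length in samples (>= 3).
#' @param stride step between epoch starts in samples (>= 1).
#' @return data.frame with columns epoch_index, subject_id, place and the
#'   52 statistics; attributes epoch_len, stride, n_samples.
#' @export
epoch_features <- function(dec, trace, epoch_len = 13, stride = 13) {
  stopifnot(inherits(dec, "dba_decomposition"))
  if (epoch_len < 3) stop("epoch_len must be >= 3 (skewness/kurtosis undefined)", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  n <- nrow(dec$raw)
  if (epoch_len > n) {
    warning("epoch_len exceeds trace length; returning empty feature table")
    out <- data.frame(epoch_index = integer(0), subject_id = character(0),
                      place = character(0))
    for (nm in feature_names()) out[[nm]] <- numeric(0)
    attr(out, "epoch_len") <- epoch_len; attr(out, "stride") <- stride
    attr(out, "n_samples") <- n
    return(out)
  }
  n_epochs <- (n - epoch_len) %/% stride + 1L
  starts <- (seq_len(n_epochs) - 1L) * stride + 1L
  idx <- outer(0:(epoch_len - 1L), starts, `+`)  # epoch_len x n_epochs

  ax <- function(v) matrix(v[idx], epoch_len, n_epochs)
  X <- ax(dec$raw[, 1]); Y <- ax(dec$raw[, 2]); Z <- ax(dec$raw[, 3])
  dt <- 1 / dec$sampling_rate

  axis_block <- function(M) {
    ms <- .col_moment_stats(M)
    sd <- .col_sd(M)
    cbind(mean = ms$mean,
          median = apply(M, 2, stats::median),
          sd = sd,
          skew = ms$skew,
          kurt = ms$kurt,
          min = apply(M, 2, min),
          max = apply(M, 2, max),
          absmean = colMeans(abs(M)),
          icv = ifelse(sd <= 0, 0, ms$mean / sd),
          ar1 = .col_ar1(M))
  }
  bx <- axis_block(X); by <- axis_block(Y); bz <- axis_block(Z)

  Q <- ax(dec$q); O <- ax(dec$odba); V <- ax(dec$vedba)
  PX <- ax(dec$pdba[, 1]); PY <- ax(dec$pdba[, 2]); PZ <- ax(dec$pdba[, 3])
  IN <- matrix(dec$inclination[idx], epoch_len, n_epochs)
  AZ <- matrix(dec$azimuth[idx], epoch_len, n_epochs)

  out <- cbind(
    bx, by, bz,
    q_mean = colMeans(Q), q_sd = .col_sd(Q),
    q_min = apply(Q, 2, min), q_max = apply(Q, 2, max),
    corr_xy = .col_cor(X, Y), corr_yz = .col_cor(Y, Z), corr_xz = .col_cor(X, Z),
    incl_mean = colMeans(IN, na.rm = TRUE), azim_mean = colMeans(AZ, na.rm = TRUE),
    pdba_x_mean = colMeans(PX), pdba_y_mean = colMeans(PY), pdba_z_mean = colMeans(PZ),
    odba_mean = colMeans(O), odba_sd = .col_sd(O),
    odba_min = apply(O, 2, min), odba_max = apply(O, 2, max),
    vedba_mean = colMeans(V), vedba_sd = .col_sd(V),
    vedba_min = apply(V, 2, min), vedba_max = apply(V, 2, max),
    auc_odba = .col_auc(O, dt), auc_vedba = .col_auc(V, dt)
  )
  colnames(out) <- feature_names()

  place_col <- if (!is.null(trace$place)) {
    apply(matrix(trace$place[idx], epoch_len, n_epochs), 2, modal_value,
          levels_order = c("surface", "underwater", "land"))
  } else rep("surface", n_epochs)
  subject <- attr(trace, "subject_id")
  if (is.null(subject)) subject <- "unknown"

  degenerate <- (.col_sd(X) <= 0) | (.col_sd(Y) <= 0) | (.col_sd(Z) <= 0)
  res <- data.frame(epoch_index = seq_len(n_epochs), subject_id = subject,
                    place = place_col, stringsAsFactors = FALSE)
  res <- cbind(res, as.data.frame(out))
  attr(res, "epoch_len") <- as.integer(epoch_len)
  attr(res, "stride") <- as.integer(stride)
  attr(res, "n_samples") <- n
  attr(res, "degenerate") <- which(degenerate)
  res
}

#' Write / read a feature table CSV
#'
#' @param features feature table from [epoch_features()] (optionally after
#'   labelling); epoch geometry attributes are stored as commented header
#'   lines are not used — geometry is re-supplied on read via arguments.
#' @param path CSV path.
#' @return `read_features`: the feature table data.frame.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @param epoch_len,stride epoch geometry to attach on read.
#' @export
read_features <- function(path, epoch_len = 13, stride = 13) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(df, "epoch_len") <- as.integer(epoch_len)
  attr(df, "stride") <- as.integer(stride)
  df
}
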