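#' @keywords internal
"_PACKAGE"

# Fixed class order used everywhere a 4-class object is built (confusion
# matrices, probability columns, argmax tie-breaks).
CLASS_ORDER <- c("foraging", "grooming", "resting", "travelling")

# Full category set; 'other' exists in label tracks but is dropped before
# modelling.
CATEGORIES <- c(CLASS_ORDER, "other")

# Tie precedence for epoch labelling: consulted only on exact majority ties.
CATEGORY_PRECEDENCE <- c("foraging", "grooming", "travelling", "resting", "other")

#' Derive a per-stage random seed from a global seed
#'
#' One global seed fans out to independent per-stage / per-subject seeds by
#' stable string hashing, so every stage is reproducible in isolation without
#' seed bookkeeping. The result always fits a 32-bit integer.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the stage or subject.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  code <- utf8ToInt(paste(label, collapse = "/"))
  h <- sum(code * seq_along(code)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# Centered running mean with symmetric truncation at the edges: at sample i
# the half-width shrinks to min(h, i-1, n-i) so the window stays centered.
running_mean <- function(x, window) {
  n <- length(x)
  if (window >= 2 * n) window <- 2 * n - 1
  h <- window %/% 2L
  i <- seq_len(n)
  w <- pmin(h, i - 1L, n - i)
  cs <- cumsum(c(0, x))
  (cs[i + w + 1L] - cs[i - w]) / (2L * w + 1L)
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
#' Stationary distribution of a category transition matrix
#' @param P row-stochastic square matrix.
#' @return named numeric vector summing to 1.
#' @export
stationary_distribution <- function(P) {
  check_transition_matrix(P)
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- v / sum(v)
  stats::setNames(v, rownames(P))
}

check_transition_matrix <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop("transition_matrix must be square", call. = FALSE)
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("each transition_matrix row must be non-negative and sum to 1 (tol 1e-9)",
         call. = FALSE)
  }
  invisible(P)
}

# Modal value with first-in-level-order tie break.
modal_value <- function(x, levels_order) {
  tab <- table(factor(x, levels = levels_order))
  names(tab)[which.max(tab)]
}
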