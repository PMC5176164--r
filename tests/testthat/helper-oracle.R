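# Brute-force oracle for the epoch statistics: everything recomputed from
# first principles with explicit loops, sharing no code with the package.

oracle_running_mean <- function(v, window) {
  n <- length(v)
  h <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- min(h, i - 1, n - i)   # symmetric truncation at the edges
    acc <- 0
    for (j in (i - w):(i + w)) acc <- acc + v[j]
    out[i] <- acc / (2 * w + 1)
  }
  out
}

oracle_mean <- function(v) { s <- 0; for (a in v) s <- s + a; s / length(v) }
oracle_sd <- function(v) {
  m <- oracle_mean(v); s <- 0
  for (a in v) s <- s + (a - m)^2
  sqrt(s / (length(v) - 1))
}
oracle_median <- function(v) {
  s <- sort(v); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
oracle_moment <- function(v, k) {
  m <- oracle_mean(v); s <- 0
  for (a in v) s <- s + (a - m)^k
  s / length(v)
}
oracle_skew <- function(v) {
  m2 <- oracle_moment(v, 2)
  if (m2 <= 0) return(0)
  oracle_moment(v, 3) / m2^1.5
}
oracle_kurt <- function(v) {
  m2 <- oracle_moment(v, 2)
  if (m2 <= 0) return(0)
  oracle_moment(v, 4) / m2^2 - 3
}
oracle_absmean <- function(v) { s <- 0; for (a in v) s <- s + abs(a); s / length(v) }
oracle_icv <- function(v) {
  s <- oracle_sd(v)
  if (s <= 0) 0 else oracle_mean(v) / s
}
# slope of least-squares regression of v[t] on v[t-1]
oracle_ar1 <- function(v) {
  n <- length(v)
  a <- v[1:(n - 1)]; b <- v[2:n]
  ma <- oracle_mean(a); mb <- oracle_mean(b)
  num <- 0; den <- 0
  for (i in seq_along(a)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    den <- den + (a[i] - ma)^2
  }
  if (den <= 0) 0 else num / den
}
oracle_cor <- function(u, v) {
  mu <- oracle_mean(u); mv <- oracle_mean(v)
  su <- 0; sv <- 0; suv <- 0
  for (i in seq_along(u)) {
    su <- su + (u[i] - mu)^2
    sv <- sv + (v[i] - mv)^2
    suv <- suv + (u[i] - mu) * (v[i] - mv)
  }
  if (su <= 0 || sv <= 0) 0 else suv / sqrt(su * sv)
}
oracle_auc <- function(v, dt) {
  s <- 0
  for (i in 1:(length(v) - 1)) s <- s + (v[i] + v[i + 1]) / 2 * dt
  s
}

# Full 52-statistic recomputation for one epoch of raw samples (matrices
# raw/static n x 3), mirroring the documented inventory.
oracle_epoch_stats <- function(raw, rate, static) {
  dyn <- raw - static
  odba <- numeric(nrow(raw)); vedba <- numeric(nrow(raw)); q <- numeric(nrow(raw))
  incl <- numeric(nrow(raw)); azim <- numeric(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    odba[i] <- abs(dyn[i, 1]) + abs(dyn[i, 2]) + abs(dyn[i, 3])
    vedba[i] <- sqrt(dyn[i, 1]^2 + dyn[i, 2]^2 + dyn[i, 3]^2)
    q[i] <- sqrt(raw[i, 1]^2 + raw[i, 2]^2 + raw[i, 3]^2)
    smag <- sqrt(static[i, 1]^2 + static[i, 2]^2 + static[i, 3]^2)
    incl[i] <- acos(static[i, 3] / smag)
    azim[i] <- atan2(static[i, 2], static[i, 1])
  }
  out <- c()
  for (ai in 1:3) {
    v <- raw[, ai]
    out <- c(out, oracle_mean(v), oracle_median(v), oracle_sd(v),
             oracle_skew(v), oracle_kurt(v), min(v), max(v),
             oracle_absmean(v), oracle_icv(v), oracle_ar1(v))
  }
  out <- c(out,
           oracle_mean(q), oracle_sd(q), min(q), max(q),
           oracle_cor(raw[, 1], raw[, 2]), oracle_cor(raw[, 2], raw[, 3]),
           oracle_cor(raw[, 1], raw[, 3]),
           oracle_mean(incl), oracle_mean(azim),
           oracle_absmean(dyn[, 1]), oracle_absmean(dyn[, 2]), oracle_absmean(dyn[, 3]),
           oracle_mean(odba), oracle_sd(odba), min(odba), max(odba),
           oracle_mean(vedba), oracle_sd(vedba), min(vedba), max(vedba),
           oracle_auc(odba, 1 / rate), oracle_auc(vedba, 1 / rate))
  names(out) <- feature_names()
  out
}

# Small labelled random-walk trace fixture (not a simulator output).
make_random_trace <- function(n, rate = 25, seed = 42) {
  set.seed(seed)
  df <- data.frame(
    time_s = (seq_len(n) - 1) / rate,
    x = cumsum(rnorm(n, 0, 0.1)) + 0.1,
    y = cumsum(rnorm(n, 0, 0.1)) - 0.2,
    z = 1 + cumsum(rnorm(n, 0, 0.1)),
    place = sample(c("surface", "underwater", "land"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  attr(df, "sampling_rate") <- rate
  attr(df, "subject_id") <- "T01"
  df
}

# Tiny labelled feature table for model tests: two Gaussian blobs per class.
make_toy_features <- function(n_per_class = 60, classes = c("foraging", "travelling"),
                              sep = 3, seed = 99) {
  set.seed(seed)
  rows <- lapply(seq_along(classes), function(k) {
    data.frame(
      epoch_index = seq_len(n_per_class) + (k - 1) * n_per_class,
      subject_id = sprintf("S%02d", rep(1:3, length.out = n_per_class)),
      f1 = rnorm(n_per_class, k * sep), f2 = rnorm(n_per_class, -k * sep),
      category = classes[k], stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "epoch_len") <- 13L
  attr(out, "stride") <- 13L
  out
}
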