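#' Simulate one accelerometer session for a subject
#'
#' Generates a labelled tri-axial trace with a semi-Markov bout schedule:
#' the bout's category is drawn from the transition matrix, the behaviour
#' uniformly within the category, and the duration from the behaviour's
#' bounded log-normal. Within a bout the signal is the unit gravity vector
#' for the behaviour's orientation plus its sinusoidal dynamic components
#' (frequency scaled by subject mass, amplitude by species) plus Gaussian
#' noise; raw values are clipped to the logger's +/- 8 g range.
#'
#' The bout schedule and all random draws are independent of `separability`,
#' which only rescales oscillator amplitudes towards/away from their grand
#' mean, so two runs with the same seed and different separability share a
#' bit-identical schedule.
#'
#' @param profile one-row data.frame as returned by [generate_cohort()].
#' @param specs named list of [behaviour_spec()] objects.
#' @param config a [simulation_config()].
#' @return list with `trace` (data.frame time_s, x, y, z, place; attributes
#'   sampling_rate, subject_id) and `labels` (data.frame behaviour, category).
#' @export
simulate_session <- function(profile, specs, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(specs) == 0) stop("specs must be non-empty", call. = FALSE)
  if (is.data.frame(profile)) profile <- as.list(profile[1, ])

  cats_present <- sort(unique(vapply(specs, `[[`, character(1), "category")))
  P <- config$transition_matrix
  if (!all(cats_present %in% rownames(P))) {
    stop("transition matrix rows must cover the categories present in specs: ",
         paste(setdiff(cats_present, rownames(P)), collapse = ", "), call. = FALSE)
  }
  P <- P[cats_present, cats_present, drop = FALSE]
  P <- P / rowSums(P)
  check_transition_matrix(P)

  rate <- config$sampling_rate
  n <- round(config$session_length * rate)
  mods <- subject_modifiers(profile)
  set.seed(derive_seed(config$seed, paste0("session/", profile$subject_id)))

  ## 1. Bout schedule (categories, behaviours, durations) --------------------
  by_cat <- split(names(specs), vapply(specs, `[[`, character(1), "category"))
  pi0 <- stationary_distribution(P)
  sched <- list(); total <- 0; cat_cur <- NULL
  while (total < config$session_length) {
    cat_cur <- if (is.null(cat_cur)) {
      sample(cats_present, 1, prob = pi0)
    } else {
      sample(cats_present, 1, prob = P[cat_cur, ])
    }
    beh <- if (length(by_cat[[cat_cur]]) == 1) by_cat[[cat_cur]] else
      sample(by_cat[[cat_cur]], 1)
    sp <- specs[[beh]]
    dur <- stats::rlnorm(1, sp$dur_meanlog, sp$dur_sdlog)
    dur <- min(max(dur, sp$dur_bounds[1]), sp$dur_bounds[2])
    sched[[length(sched) + 1]] <- list(behaviour = beh, dur = dur)
    total <- total + dur
  }

  ## 2. Per-bout randomness: oscillator phases plus bout-level intensity and
  ## tempo multipliers (movement varies between bouts of the same behaviour),
  ## then per-sample noise. Draw counts are independent of separability, so
  ## the schedule and draws are bit-identical across separability settings.
  bout_draws <- lapply(sched, function(b) {
    sp <- specs[[b$behaviour]]
    list(
      phase = vapply(sp$oscillators, function(o) {
        stats::runif(1, 0, 2 * pi) + stats::rnorm(1, 0, o$phase_jitter_sd)
      }, numeric(1)),
      amp_jit = stats::rlnorm(1, 0, 0.25),
      freq_jit = stats::rlnorm(1, 0, 0.12)
    )
  })
  noise <- matrix(stats::rnorm(3 * n), n, 3)

  ## 3. Assemble the signal (deterministic given the draws above) ------------
  # Separability geometrically blends each behaviour's dynamic magnitude and
  # noise level toward the cohort grand means: identity at 1, signatures
  # converge as it approaches 0. Applied after all draws, so the schedule is
  # unaffected.
  s_exp <- 1 - config$separability
  A_spec <- vapply(specs, function(sp)
    sum(vapply(sp$oscillators, `[[`, numeric(1), "amp")), numeric(1))
  A_bar <- if (any(A_spec > 0)) mean(A_spec[A_spec > 0]) else 0
  n_bar <- mean(vapply(specs, `[[`, numeric(1), "noise_sd"))
  sig_mult <- ifelse(A_spec > 0, (A_bar / A_spec)^s_exp, 1)

  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  behaviour <- character(n); place <- character(n)
  t_all <- (seq_len(n) - 1) / rate
  pos <- 1L
  for (k in seq_along(sched)) {
    if (pos > n) break
    b <- sched[[k]]
    sp <- specs[[b$behaviour]]
    len <- max(1L, round(b$dur * rate))
    idx <- pos:min(n, pos + len - 1L)
    tt <- t_all[idx]
    g <- gravity_vector(sp$pitch, sp$roll)
    ax <- rep(g["x"], length(idx)); ay <- rep(g["y"], length(idx))
    az <- rep(g["z"], length(idx))
    for (j in seq_along(sp$oscillators)) {
      o <- sp$oscillators[[j]]
      amp_eff <- o$amp * sig_mult[[b$behaviour]] * mods$amp_mult *
        bout_draws[[k]]$amp_jit
      freq_eff <- o$freq * mods$freq_mult * bout_draws[[k]]$freq_jit
      wave <- amp_eff * sin(2 * pi * freq_eff * tt + bout_draws[[k]]$phase[j])
      if (o$axis == "x") ax <- ax + wave
      else if (o$axis == "y") ay <- ay + wave
      else az <- az + wave
    }
    nsd <- sp$noise_sd^config$separability * n_bar^s_exp * mods$noise_mult
    x[idx] <- ax + nsd * noise[idx, 1]
    y[idx] <- ay + nsd * noise[idx, 2]
    z[idx] <- az + nsd * noise[idx, 3]
    behaviour[idx] <- sp$behaviour
    place[idx] <- sp$place
    pos <- pos + len
  }

  clip <- function(v) pmin(pmax(v, -8), 8)
  trace <- data.frame(time_s = t_all, x = clip(x), y = clip(y), z = clip(z),
                      place = place, stringsAsFactors = FALSE)
  attr(trace, "sampling_rate") <- rate
  attr(trace, "subject_id") <- profile$subject_id
  map <- behaviour_category_map()
  labels <- data.frame(behaviour = behaviour,
                       category = unname(map[behaviour]),
                       stringsAsFactors = FALSE)
  list(trace = trace, labels = labels)
}

#' Simulate a full cohort of sessions
#'
#' @inheritParams simulate_session
#' @param cohort data.frame from [generate_cohort()]; generated from
#'   `config` when NULL.
#' @return list with `cohort` and named list `sessions` (one
#'   [simulate_session()] result per subject).
#' @export
simulate_cohort <- function(config, specs = default_behaviour_specs(),
                            cohort = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  sessions <- lapply(seq_len(nrow(cohort)), function(i) {
    simulate_session(cohort[i, ], specs, config)
  })
  names(sessions) <- cohort$subject_id
  list(cohort = cohort, sessions = sessions)
}

#' Write simulated sessions to disk
#'
#' One CSV per session (timestamp_s, x, y, z, behaviour, category, place),
#' a cohort metadata CSV, and a JSON sidecar echoing the configuration and
#' seed so a run can be re-executed identically.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param config the [simulation_config()] used (echoed to JSON).
#' @return invisibly, the paths written.
#' @export
write_sessions <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (id in names(sim$sessions)) {
    s <- sim$sessions[[id]]
    df <- data.frame(timestamp_s = s$trace$time_s,
                     x = s$trace$x, y = s$trace$y, z = s$trace$z,
                     behaviour = s$labels$behaviour,
                     category = s$labels$category,
                     place = s$trace$place)
    p <- file.path(dir, paste0("session_", id, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  cp <- file.path(dir, "cohort.csv")
  utils::write.csv(sim$cohort, cp, row.names = FALSE)
  paths <- c(paths, cp)
  if (!is.null(config)) {
    jp <- file.path(dir, "config.json")
    cfg <- unclass(config)
    cfg$transition_matrix <- as.data.frame(cfg$transition_matrix)
    jsonlite::write_json(cfg, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, jp)
  }
  invisible(paths)
}

#' Read a session CSV back into a trace + label track
#'
#' Accepts any CSV with columns time (or timestamp_s), x, y, z and optional
#' behaviour, category, place.
#'
#' @param path CSV path.
#' @param sampling_rate sampling rate in Hz; inferred from timestamps when NULL.
#' @param subject_id subject identifier; inferred from the filename when NULL.
#' @return list with `trace` and `labels` (NULL when unlabelled).
#' @export
read_session <- function(path, sampling_rate = NULL, subject_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("timestamp_s", "time_s", "time"), names(df))[1]
  if (is.na(tcol) || !all(c("x", "y", "z") %in% names(df))) {
    stop("session CSV needs columns time (or timestamp_s), x, y, z", call. = FALSE)
  }
  if (is.null(sampling_rate)) {
    dt <- stats::median(diff(df[[tcol]]))
    sampling_rate <- round(1 / dt)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("^session_", "", sub("\\.csv$", "", basename(path)))
  }
  trace <- data.frame(time_s = df[[tcol]], x = df$x, y = df$y, z = df$z,
                      place = if ("place" %in% names(df)) df$place else "surface",
                      stringsAsFactors = FALSE)
  attr(trace, "sampling_rate") <- sampling_rate
  attr(trace, "subject_id") <- subject_id
  labels <- NULL
  if ("behaviour" %in% names(df)) {
    map <- behaviour_category_map()
    labels <- data.frame(behaviour = df$behaviour,
                         category = if ("category" %in% names(df)) df$category
                                    else unname(map[df$behaviour]),
                         stringsAsFactors = FALSE)
  }
  list(trace = trace, labels = labels)
}
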