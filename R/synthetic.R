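#' Synthetic infant-cohort simulation configuration
#'
#' Defines the statistical shape of a simulated laboratory cohort: short
#' daytime recordings from about ten infants, roughly 28% wake, movement
#' concentrated in wake-time bursts with occasional "motionless wake"
#' stretches adjacent to bursts, and sparse sleep movement that is more
#' frequent in REM than in NREM sleep.
#'
#' Bout durations are lognormal in minutes. The wake bout mean is derived
#' from `sleep_bout_mean_min` and `wake_fraction`
#' (`sleep * wf / (1 - wf)`) so the realized wake share fluctuates around
#' the target by construction.
#'
#' @param n_subjects number of infants. Default 10.
#' @param recording_minutes_mean,recording_minutes_sd normal
#'   recording-length distribution in minutes (truncated at
#'   `recording_minutes_min`). Defaults 70 / 26.
#' @param recording_minutes_min shortest allowed recording. Default 20.
#' @param wake_fraction target share of wake epochs. Default 0.28.
#' @param sleep_bout_mean_min mean sleep bout length (minutes). Default 20
#'   (consolidated sleep periods; the derived wake bout mean is then about
#'   8 min, matching consolidated wake periods rather than fragmented
#'   seconds-scale arousals).
#' @param bout_sdlog lognormal sdlog shared by wake and sleep bouts.
#'   Default 0.6.
#' @param rem_share stationary share of sleep epochs labelled REM.
#'   Default 0.4 (infant active sleep is a large fraction of sleep).
#' @param rem_run_mean_epochs mean REM run length in epochs. Default 10.
#' @param burst_rate mean activity (blocks/frame) while a wake movement
#'   burst is on. Default 8.
#' @param quiet_rate mean activity between bursts within normal wake.
#'   Default 0.2.
#' @param p_burst_on,p_burst_off per-frame Markov switching probabilities of
#'   the wake burst process. Defaults 0.02 / 0.05.
#' @param motionless_wake_prob probability that a wake bout (of at least 4
#'   epochs) contains a motionless stretch adjacent to its bursty part.
#'   Default 0.8: quiet wakefulness is common, so a substantial minority of
#'   wake epochs (roughly a quarter) shows little or no movement and is
#'   invisible to a pure activity-count feature.
#' @param motionless_len_epochs range (min, max) of motionless stretch
#'   lengths in epochs. Default `c(3, 6)`.
#' @param rem_event_rate,nrem_event_rate mean number of brief movement
#'   events per 30-s sleep epoch. Defaults 0.5 (REM) / 0.15 (NREM).
#' @param event_len_mean_frames mean event duration in frames. Default 5.
#' @param event_amp_rate event amplitude is `1 + Poisson(event_amp_rate)`
#'   blocks/frame. Default 2.
#' @param rem_jerk_prob,nrem_jerk_prob per-epoch probability of a vigorous
#'   movement burst (jerk/startle) at wake-like intensity during sleep;
#'   such epochs overlap the wake mACT range, as sleep movements do in real
#'   recordings. Defaults 0.08 (REM) / 0.03 (NREM).
#' @param jerk_len_mean_frames mean jerk duration in frames. Default 20
#'   (2 s at 10 Hz).
#' @param wake_intensity_sdlog lognormal spread of a per-bout multiplier on
#'   `burst_rate`. Default 0 (every wake bout bursts at the same intensity,
#'   so each wake period contains recording-level high-activity epochs;
#'   wake/sleep overlap comes from motionless and quiet wake stretches and
#'   from sleep jerks instead). Set above 0 to model bouts of unequal
#'   vigor.
#' @param unscored_fraction share of epochs relabelled unable-to-score
#'   (`U`). Default 0.007.
#' @param frame_rate actigraphy rate in Hz. Default 10.
#' @param epoch_length_s scoring epoch in seconds. Default 30.
#' @param render_width,render_height,render_blob_rx,render_blob_ry,render_noise_sd,render_max_step
#'   frame-rendering geometry: image size in pixels, ellipse ("infant")
#'   semi-axes, Gaussian pixel-noise SD, and the largest per-frame
#'   translation step in pixels. Defaults give a small fast test image.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 10,
                       recording_minutes_mean = 70,
                       recording_minutes_sd = 26,
                       recording_minutes_min = 20,
                       wake_fraction = 0.28,
                       sleep_bout_mean_min = 20,
                       bout_sdlog = 0.6,
                       rem_share = 0.4,
                       rem_run_mean_epochs = 10,
                       burst_rate = 8,
                       quiet_rate = 0.2,
                       p_burst_on = 0.02,
                       p_burst_off = 0.05,
                       motionless_wake_prob = 0.8,
                       motionless_len_epochs = c(3, 6),
                       rem_event_rate = 0.5,
                       nrem_event_rate = 0.15,
                       event_len_mean_frames = 5,
                       event_amp_rate = 2,
                       rem_jerk_prob = 0.08,
                       nrem_jerk_prob = 0.03,
                       jerk_len_mean_frames = 20,
                       wake_intensity_sdlog = 0,
                       unscored_fraction = 0.007,
                       frame_rate = 10,
                       epoch_length_s = 30,
                       render_width = 80,
                       render_height = 64,
                       render_blob_rx = 18,
                       render_blob_ry = 12,
                       render_noise_sd = 2,
                       render_max_step = 3) {
  cfg <- as.list(environment())
  probs <- c(cfg$wake_fraction, cfg$rem_share, cfg$p_burst_on, cfg$p_burst_off,
             cfg$motionless_wake_prob, cfg$unscored_fraction,
             cfg$rem_jerk_prob, cfg$nrem_jerk_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  rates <- c(cfg$burst_rate, cfg$quiet_rate, cfg$rem_event_rate,
             cfg$nrem_event_rate, cfg$event_amp_rate)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  cfg$wake_bout_mean_min <- cfg$sleep_bout_mean_min * cfg$wake_fraction /
    (1 - cfg$wake_fraction)
  epl_min <- cfg$epoch_length_s / 60
  if (cfg$wake_bout_mean_min < epl_min || cfg$sleep_bout_mean_min < epl_min) {
    stop("invalid config: mean bout length shorter than one epoch", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

lognormal_pars <- function(mean, sdlog) list(meanlog = log(mean) - sdlog^2 / 2,
                                             sdlog = sdlog)

#' Simulate a hypnogram
#'
#' Alternating wake/sleep bouts with lognormal durations rounded to whole
#' 30-s epochs (minimum one epoch). Sleep epochs are sub-labelled REM (`R`)
#' versus NREM via a two-state Markov chain with stationary REM share
#' `rem_share`; each NREM run is assigned one of `N1`/`N2`/`N3` (weights
#' 0.15/0.50/0.35). Finally a fraction `unscored_fraction` of epochs is
#' relabelled `U` uniformly at random.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; fixed seed gives an identical hypnogram.
#' @return Character vector of epoch labels in `{W, N1, N2, N3, R, U}`,
#'   with attribute `bouts` (data.frame of the generating bout table).
#' @export
simulate_hypnogram <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed)
  epl_min <- config$epoch_length_s / 60
  minutes <- max(config$recording_minutes_min,
                 stats::rnorm(1, config$recording_minutes_mean,
                              config$recording_minutes_sd))
  n_epochs <- max(2L, as.integer(round(minutes / epl_min)))

  pw <- lognormal_pars(config$wake_bout_mean_min, config$bout_sdlog)
  ps <- lognormal_pars(config$sleep_bout_mean_min, config$bout_sdlog)
  # simulate a longer alternating-renewal sequence and take a random
  # window, so the recording samples the process near stationarity and the
  # realized wake share fluctuates around the target without start-of-bout
  # bias
  state <- if (stats::runif(1) < 0.5) "W" else "S"
  labels <- character(0)
  bouts <- list()
  target_len <- 2L * n_epochs + 4L * as.integer(ceiling(config$sleep_bout_mean_min / epl_min))
  while (length(labels) < target_len) {
    p <- if (state == "W") pw else ps
    len_min <- stats::rlnorm(1, p$meanlog, p$sdlog)
    len <- max(1L, as.integer(round(len_min / epl_min)))
    bouts[[length(bouts) + 1L]] <- data.frame(
      state = state, start_epoch = length(labels), n_epochs = len)
    labels <- c(labels, rep(state, len))
    state <- if (state == "W") "S" else "W"
  }
  offset <- sample.int(length(labels) - n_epochs + 1L, 1L) - 1L
  labels <- labels[offset + seq_len(n_epochs)]
  bouts <- lapply(bouts, function(b) {
    b$start_epoch <- b$start_epoch - offset
    b
  })
  bouts <- Filter(function(b) b$start_epoch + b$n_epochs > 0 &&
                    b$start_epoch < n_epochs, bouts)

  # REM/NREM substructure within sleep: 2-state chain with the target
  # stationary share; sticky runs so REM appears in contiguous stretches
  p_rn <- 1 / config$rem_run_mean_epochs
  p_nr <- min(1, config$rem_share / (1 - config$rem_share) * p_rn)
  is_sleep <- labels == "S"
  rem_state <- stats::runif(1) < config$rem_share
  sub <- character(n_epochs)
  for (i in seq_len(n_epochs)) {
    if (!is_sleep[i]) next
    flip <- stats::runif(1)
    rem_state <- if (rem_state) flip >= p_rn else flip < p_nr
    sub[i] <- if (rem_state) "R" else "N"
  }
  labels[is_sleep] <- sub[is_sleep]
  # assign one NREM stage per contiguous N run
  r <- rle(labels)
  stages <- sample(c("N1", "N2", "N3"), length(r$values), replace = TRUE,
                   prob = c(0.15, 0.50, 0.35))
  r$values[r$values == "N"] <- stages[r$values == "N"]
  labels <- inverse.rle(r)

  u <- stats::runif(n_epochs) < config$unscored_fraction
  labels[u] <- "U"
  attr(labels, "bouts") <- do.call(rbind, bouts)
  labels
}

#' Simulate state-conditional actigraphy for a hypnogram
#'
#' Generates the 10-Hz activity-count trace (blocks/frame scale, integer
#' counts) implied by a hypnogram. Wake bouts emit a two-state
#' burst/quiet Markov-modulated Poisson process at the frame level; a
#' subset of wake bouts carries a designated motionless stretch (zeros)
#' adjacent to the bursty part of the bout — the "motionless wake"
#' phenomenon the pSLP feature is designed to catch. Each wake bout draws a
#' lognormal intensity multiplier, so some bouts move much less vigorously
#' than others. Sleep epochs emit rare brief movement events, more
#' frequently in REM than NREM, and occasionally a vigorous jerk at
#' wake-like intensity, so the wake and sleep activity distributions
#' overlap rather than separating cleanly. Unable-to-score epochs are
#' generated like NREM sleep (they are excluded downstream anyway).
#'
#' @param hypnogram character labels from [simulate_hypnogram()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return An [actigraphy_signal] of length `n_epochs * frames_per_epoch`,
#'   with attribute `motionless_epochs` (0-based indices of designated
#'   motionless wake epochs).
#' @export
simulate_actigraphy <- function(hypnogram, config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed)
  fpe <- as.integer(round(config$epoch_length_s * config$frame_rate))
  n_epochs <- length(hypnogram)
  if (n_epochs == 0) stop("empty hypnogram", call. = FALSE)
  binary <- ifelse(hypnogram == "W", "wake",
                   ifelse(hypnogram == "U", "excluded", "sleep"))
  activity <- integer(n_epochs * fpe)
  motionless <- integer(0)

  # wake bouts: runs of consecutive W epochs
  r <- rle(binary == "wake")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    ep <- starts[k]:ends[k]
    len <- length(ep)
    motionless_here <- integer(0)
    if (len >= 4 && stats::runif(1) < config$motionless_wake_prob) {
      lo <- config$motionless_len_epochs[1]
      hi <- min(config$motionless_len_epochs[2], len - 2L)
      if (hi >= lo) {
        m_len <- sample(lo:hi, 1)
        # anywhere within the bout, so the quiet stretch sits adjacent to
        # (often between) the bout's movement bursts
        at <- sample.int(len - m_len + 1L, 1)
        motionless_here <- ep[at:(at + m_len - 1L)]
      }
    }
    active_ep <- setdiff(ep, motionless_here)
    n_frames <- length(active_ep) * fpe
    if (n_frames > 0) {
      # optional per-bout vigor multiplier (unit mean; degenerate at 1
      # when sdlog = 0)
      vigor <- if (config$wake_intensity_sdlog > 0) {
        stats::rlnorm(1, -config$wake_intensity_sdlog^2 / 2,
                      config$wake_intensity_sdlog)
      } else 1

      # frame-level burst/quiet chain across the bout's active part
      burst <- logical(n_frames)
      s <- stats::runif(1) < config$p_burst_on / (config$p_burst_on + config$p_burst_off)
      flips <- stats::runif(n_frames)
      for (f in seq_len(n_frames)) {
        s <- if (s) flips[f] >= config$p_burst_off else flips[f] < config$p_burst_on
        burst[f] <- s
      }
      lam <- ifelse(burst, config$burst_rate * vigor, config$quiet_rate)
      counts <- stats::rpois(n_frames, lam)
      idx <- as.vector(vapply(active_ep, function(e) ((e - 1L) * fpe + 1L):(e * fpe),
                              integer(fpe)))
      activity[idx] <- counts
    }
    motionless <- c(motionless, motionless_here)
  }

  # sleep (and unscored) epochs: sparse short events plus occasional
  # vigorous jerks at wake-like intensity (more often in REM)
  for (e in which(binary != "wake")) {
    lab <- hypnogram[e]
    rate <- if (lab == "R") config$rem_event_rate else config$nrem_event_rate
    jerk_p <- if (lab == "R") config$rem_jerk_prob else config$nrem_jerk_prob
    base <- (e - 1L) * fpe
    n_ev <- stats::rpois(1, rate)
    for (j in seq_len(n_ev)) {
      start <- sample.int(fpe, 1)
      dur <- 1L + stats::rpois(1, max(config$event_len_mean_frames - 1, 0))
      amp <- 1L + stats::rpois(1, config$event_amp_rate)
      span <- start:min(start + dur - 1L, fpe)
      activity[base + span] <- activity[base + span] + amp
    }
    if (stats::runif(1) < jerk_p) {
      start <- sample.int(fpe, 1)
      dur <- 1L + stats::rpois(1, max(config$jerk_len_mean_frames - 1, 0))
      span <- start:min(start + dur - 1L, fpe)
      activity[base + span] <- activity[base + span] +
        stats::rpois(length(span), config$burst_rate)
    }
  }

  out <- actigraphy_signal(activity, frame_rate = config$frame_rate)
  attr(out, "motionless_epochs") <- sort(motionless) - 1L
  out
}

#' Simulate a full cohort
#'
#' One hypnogram + actigraphy pair per subject, each driven by a sub-seed
#' derived deterministically from `seed` and the subject index.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for the whole cohort.
#' @return A list of recordings (class `sim_cohort`), each with `subject`,
#'   `hypnogram`, `actigraphy` and `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  lapply_named <- function(i) {
    s_h <- (seed * 1009L + 2L * i) %% 2147483647L
    s_a <- (seed * 1009L + 2L * i + 1L) %% 2147483647L
    hyp <- simulate_hypnogram(config, seed = s_h)
    act <- simulate_actigraphy(hyp, config, seed = s_a)
    list(subject = sprintf("S%02d", i), hypnogram = as.character(hyp),
         actigraphy = act,
         motionless_epochs = attr(act, "motionless_epochs"),
         seed = c(hypnogram = s_h, actigraphy = s_a))
  }
  structure(lapply(seq_len(config$n_subjects), lapply_named),
            class = "sim_cohort")
}

smooth_texture <- function(height, width, amplitude = 60, base = 90) {
  z <- matrix(stats::rnorm(height * width), height, width)
  k <- 7
  z <- t(apply(z, 1, function(r) stats::filter(r, rep(1 / k, k), circular = TRUE)))
  z <- apply(z, 2, function(cl) stats::filter(cl, rep(1 / k, k), circular = TRUE))
  z <- (z - min(z)) / (max(z) - min(z))
  round(base + amplitude * (z - 0.5) * 2)
}

#' Render synthetic video frames for an actigraphy trace
#'
#' Draws a dark noisy background with a textured ellipse (the "infant").
#' Whenever the activity value of a transition is positive the ellipse
#' translates by a random integer step (each component up to
#' `render_max_step` px, not both zero); when activity is zero it stays
#' put. Every applied displacement is logged as ground truth so the
#' block-matching estimator can be validated in a closed loop.
#'
#' @param activity numeric vector of per-transition activity values (e.g.
#'   a slice of a simulated [actigraphy_signal]).
#' @param config a [sim_config()] (rendering fields are used).
#' @param seed integer seed; fixed seed gives bit-identical frames.
#' @return A list with `frames` (a [frame_sequence] of
#'   `length(activity) + 1` frames) and `displacements` (matrix with
#'   columns `dx`, `dy`, one row per transition).
#' @export
render_frames <- function(activity, config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed)
  h <- config$render_height; w <- config$render_width
  rx <- config$render_blob_rx; ry <- config$render_blob_ry
  if (2 * rx >= w || 2 * ry >= h) {
    stop("invalid config: blob larger than image", call. = FALSE)
  }
  n <- length(activity)
  # texture in blob-local coordinates so it translates with the ellipse
  tex <- smooth_texture(2 * ry + 1, 2 * rx + 1)
  bg <- matrix(20, h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  rows <- matrix(seq_len(h), h, w)
  draw <- function(cx, cy) {
    f <- bg
    m <- ((cols - cx) / rx)^2 + ((rows - cy) / ry)^2 <= 1
    f[m] <- tex[cbind(rows[m] - cy + ry + 1, cols[m] - cx + rx + 1)]
    noisy <- round(f + matrix(stats::rnorm(h * w, 0, config$render_noise_sd), h, w))
    pmin(pmax(noisy, 0), 255)
  }
  margin <- config$render_max_step + 1
  cx <- round(w / 2); cy <- round(h / 2)
  frames <- vector("list", n + 1L)
  frames[[1L]] <- draw(cx, cy)
  disp <- matrix(0L, n, 2L, dimnames = list(NULL, c("dx", "dy")))
  steps <- seq.int(-config$render_max_step, config$render_max_step)
  for (t in seq_len(n)) {
    if (activity[t] > 0) {
      repeat {
        d <- sample(steps, 2L, replace = TRUE)
        if (any(d != 0L)) break
      }
      # keep the ellipse inside the image; reflect a step that would exit
      if (cx + d[1] < rx + margin || cx + d[1] > w - rx - margin) d[1] <- -d[1]
      if (cy + d[2] < ry + margin || cy + d[2] > h - ry - margin) d[2] <- -d[2]
      cx <- cx + d[1]; cy <- cy + d[2]
      disp[t, ] <- d
    }
    frames[[t + 1L]] <- draw(cx, cy)
  }
  list(frames = frame_sequence(frames, frame_rate = config$frame_rate),
       displacements = disp)
}
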