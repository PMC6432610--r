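#' Epoch grid
#'
#' Defines the partition of a recording into non-overlapping scoring epochs
#' (30 s by convention in sleep scoring). Epoch `i` (0-based) covers
#' frame-transition indices `[i * frames_per_epoch, (i + 1) * frames_per_epoch)`;
#' a trailing partial epoch is discarded.
#'
#' @param frame_rate sampling rate of the actigraphy signal in Hz. Default 10.
#' @param epoch_length_s epoch duration in seconds. Default 30.
#' @param n_samples optional signal length used to derive `n_epochs`.
#' @return An object of class `epoch_grid` with fields `epoch_length_s`,
#'   `frame_rate`, `frames_per_epoch` and (if `n_samples` given) `n_epochs`.
#' @export
epoch_grid <- function(frame_rate = 10, epoch_length_s = 30, n_samples = NULL) {
  fpe <- round(epoch_length_s * frame_rate)
  if (fpe < 1) stop("epoch shorter than one frame", call. = FALSE)
  n_epochs <- if (!is.null(n_samples)) as.integer(floor(n_samples / fpe)) else NA_integer_
  structure(list(epoch_length_s = epoch_length_s, frame_rate = frame_rate,
                 frames_per_epoch = as.integer(fpe), n_epochs = n_epochs),
            class = "epoch_grid")
}

#' Per-epoch mean activity count (mACT)
#'
#' The first wake/sleep feature: for each epoch, the mean of the per-frame
#' activity counts over the epoch's frame transitions. A binary variant
#' (fraction of frames with any activity) is available via `binary = TRUE`.
#'
#' @param signal an [actigraphy_signal].
#' @param grid an [epoch_grid] matching the signal's frame rate.
#' @param binary if `TRUE`, average the indicator `activity > 0` instead of
#'   the count itself. Default `FALSE`.
#' @return Numeric vector of per-epoch mACT values (blocks/frame, or a
#'   fraction in the binary variant).
#' @export
epoch_mact <- function(signal, grid, binary = FALSE) {
  stopifnot(inherits(signal, "actigraphy_signal"), inherits(grid, "epoch_grid"))
  fpe <- grid$frames_per_epoch
  n <- length(signal$activity)
  if (n < fpe) {
    stop("insufficient data: signal shorter than one epoch", call. = FALSE)
  }
  n_epochs <- floor(n / fpe)
  x <- signal$activity[seq_len(n_epochs * fpe)]
  if (binary) x <- as.numeric(x > 0)
  as.numeric(tapply(x, rep(seq_len(n_epochs), each = fpe), mean))
}

#' High-activity epochs: the 95th-percentile mask
#'
#' Epochs whose mACT exceeds the 95th percentile of the recording's mACT
#' values are flagged as high-activity; these are the movement bursts the
#' pSLP feature measures distance to. The percentile uses linear
#' interpolation between order statistics (position `p * (n - 1)`,
#' `stats::quantile` type 7) and the comparison is strict.
#'
#' @param mact_raw numeric vector of per-epoch mACT values.
#' @param probability percentile level. Default 0.95.
#' @return A list with `theta` (the threshold, same units as `mact_raw`) and
#'   `mask` (logical vector, `TRUE` where `mact_raw > theta`).
#' @export
high_activity_mask <- function(mact_raw, probability = 0.95) {
  if (length(mact_raw) < 1) stop("need at least one epoch", call. = FALSE)
  theta <- stats::quantile(mact_raw, probs = probability, type = 7, names = FALSE)
  list(theta = theta, mask = mact_raw > theta)
}

nearest_true_distance <- function(mask) {
  n <- length(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(rep(as.numeric(n), n))
  d <- rep(Inf, n)
  # forward and backward sweeps give the nearest true epoch in O(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (mask[i]) last <- i
    d[i] <- i - last
  }
  nxt <- Inf
  for (i in rev(seq_len(n))) {
    if (mask[i]) nxt <- i
    d[i] <- min(d[i], nxt - i)
  }
  d
}

#' Burst-proximity feature pSLP ("possibility of being asleep")
#'
#' The second feature targets motionless wake: an epoch close in time to a
#' movement burst is more likely wake than sleep even if it shows no motion
#' itself. For each epoch the distance (in whole epochs) to the nearest
#' high-activity epoch is log-transformed, `u = ln(1 + d)`, then smoothed
#' with a centered moving average whose half-width is
#' `round(smoothing_window_min * 60 / (2 * epoch_length_s))` epochs (10 min
#' at 30-s epochs gives a 21-epoch window); the average is truncated at the
#' recording edges. Low pSLP means "near a burst" (wake-like), high pSLP
#' means "far from any burst" (sleep-like).
#'
#' @param mask logical vector flagging high-activity epochs
#'   (see [high_activity_mask()]).
#' @param epoch_length_s epoch duration in seconds. Default 30.
#' @param smoothing_window_min moving-average window in minutes. Default 10.
#' @return Numeric vector of per-epoch pSLP values (log-epoch units), with
#'   attribute `degenerate = TRUE` when the mask has no high-activity epoch
#'   (the value is then the constant `ln(1 + n_epochs)`).
#' @export
pslp_raw <- function(mask, epoch_length_s = 30, smoothing_window_min = 10) {
  if (length(mask) == 0) stop("empty mask sequence", call. = FALSE)
  mask <- as.logical(mask)
  n <- length(mask)
  if (!any(mask)) {
    out <- rep(log(1 + n), n)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  u <- log(1 + nearest_true_distance(mask))
  h <- round(smoothing_window_min * 60 / (2 * epoch_length_s))
  width <- 2L * as.integer(h) + 1L
  out <- as.numeric(zoo::rollapply(zoo::zoo(u), width = width, FUN = mean,
                                   align = "center", partial = TRUE))
  attr(out, "degenerate") <- FALSE
  out
}

#' Min--Max normalization to [0, 1]
#'
#' Per-recording linear rescaling `(x - min) / (max - min)`, applied to each
#' feature within each infant to remove between-subject scale differences.
#' A constant vector cannot be rescaled; it is mapped to all zeros and
#' flagged degenerate.
#'
#' @param values numeric vector.
#' @return Rescaled vector in `[0, 1]` with attribute `degenerate` (`TRUE`
#'   when `max == min`).
#' @export
min_max_normalize <- function(values) {
  if (length(values) < 1) stop("need at least one value", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    out <- rep(0, length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (values - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

#' Build the per-epoch feature table for one recording
#'
#' Runs the full feature chain on an actigraphy signal: epoch-mean activity
#' (mACT), the 95th-percentile high-activity mask, the burst-proximity
#' feature pSLP, and per-recording Min--Max normalization of both features.
#' If a hypnogram is supplied its labels are attached and binarized
#' (`W` = wake; `N1`, `N2`, `N3`, `R` = sleep; `U` = excluded); the table is
#' truncated to the epochs covered by both signal and hypnogram.
#'
#' @param signal an [actigraphy_signal].
#' @param hypnogram optional character vector of 30-s stage labels
#'   (`W`, `N1`, `N2`, `N3`, `R`, `U`).
#' @param epoch_length_s epoch duration in seconds. Default 30.
#' @param percentile high-activity percentile. Default 0.95.
#' @param smoothing_window_min pSLP smoothing window in minutes. Default 10.
#' @param mact_binary use the binary mACT variant. Default `FALSE`.
#' @return A `data.frame` with columns `epoch_index`, `onset_s`, `mact_raw`,
#'   `pslp_raw`, `mact_norm`, `pslp_norm`, `high_activity` and (when labels
#'   are given) `label`, `state` (`wake`/`sleep`/`excluded`). Attributes:
#'   `theta` (high-activity threshold) and `degenerate_flags`.
#' @export
featurize_recording <- function(signal, hypnogram = NULL, epoch_length_s = 30,
                                percentile = 0.95, smoothing_window_min = 10,
                                mact_binary = FALSE) {
  grid <- epoch_grid(frame_rate = signal$frame_rate,
                     epoch_length_s = epoch_length_s,
                     n_samples = length(signal$activity))
  mact <- epoch_mact(signal, grid, binary = mact_binary)
  n_epochs <- length(mact)
  if (!is.null(hypnogram)) {
    n_epochs <- min(n_epochs, length(hypnogram))
    mact <- mact[seq_len(n_epochs)]
    hypnogram <- hypnogram[seq_len(n_epochs)]
  }
  ham <- high_activity_mask(mact, probability = percentile)
  pslp <- pslp_raw(ham$mask, epoch_length_s = epoch_length_s,
                   smoothing_window_min = smoothing_window_min)
  mact_n <- min_max_normalize(mact)
  pslp_n <- min_max_normalize(as.numeric(pslp))
  idx <- seq_len(n_epochs) - 1L
  out <- data.frame(
    epoch_index = idx,
    onset_s = idx * epoch_length_s,
    mact_raw = mact,
    pslp_raw = as.numeric(pslp),
    mact_norm = as.numeric(mact_n),
    pslp_norm = as.numeric(pslp_n),
    high_activity = ham$mask
  )
  if (!is.null(hypnogram)) {
    out$label <- hypnogram
    out$state <- binarize_labels(hypnogram)
  }
  attr(out, "theta") <- ham$theta
  attr(out, "degenerate_flags") <- c(
    pslp_all_quiet = isTRUE(attr(pslp, "degenerate")),
    mact_constant = isTRUE(attr(mact_n, "degenerate")),
    pslp_constant = isTRUE(attr(pslp_n, "degenerate"))
  )
  out
}

#' Write a feature table to CSV
#'
#' @param features data.frame from [featurize_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  cols <- c("epoch_index", "onset_s", "mact_raw", "pslp_raw",
            "mact_norm", "pslp_norm", "high_activity")
  if ("label" %in% names(features)) cols <- c(cols, "label")
  utils::write.csv(format_num_df(features[cols]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fixed-precision formatting so reports are byte-stable across runs
format_num_df <- function(df, digits = 10) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], digits = digits, format = "g")
    }
  }
  df
}
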