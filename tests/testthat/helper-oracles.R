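# Independent brute-force oracles used to validate the package's fast paths.
# These deliberately re-derive every quantity from first principles and share
# no code with the implementation.

# smooth low-frequency texture so block-matching costs have a basin around
# the true displacement (sinusoid mixture + mild noise)
make_texture <- function(height, width, seed = 1) {
  withr::with_seed(seed, {
    r <- matrix(seq_len(height), height, width)
    c <- matrix(seq_len(width), height, width, byrow = TRUE)
    z <- 60 * sin(r / 6) * cos(c / 7) + 40 * sin((r + c) / 9) +
      matrix(rnorm(height * width, 0, 3), height, width)
    round(pmin(pmax(128 + z, 0), 255))
  })
}

# frames whose content translates by (dx, dy) per transition, cut from one
# larger texture so every frame is fully textured
translated_frames <- function(n_frames, dx, dy, height = 96, width = 128,
                              seed = 1) {
  pad <- abs(dx) * n_frames + abs(dy) * n_frames + 4
  big <- make_texture(height + 2 * pad, width + 2 * pad, seed = seed)
  lapply(seq_len(n_frames) - 1L, function(k) {
    r0 <- pad - k * dy
    c0 <- pad - k * dx
    big[r0 + seq_len(height), c0 + seq_len(width)]
  })
}

# exhaustive full-search block matching with the same cost contract:
# mean-subtracted SAD per valid pixel, zero vector unless a candidate beats
# it by more than noise_threshold; ties broken toward smaller |v|
oracle_full_search <- function(cur, nxt, block_size, search_bound,
                               noise_threshold = 1) {
  h <- nrow(cur); w <- ncol(cur)
  gr <- ceiling(h / block_size); gc <- ceiling(w / block_size)
  out <- array(0L, dim = c(gr, gc, 2))
  for (bi in seq_len(gr)) for (bj in seq_len(gc)) {
    rows <- ((bi - 1) * block_size + 1):min(bi * block_size, h)
    cols <- ((bj - 1) * block_size + 1):min(bj * block_size, w)
    best <- c(0L, 0L); best_cost <- Inf; zero_cost <- Inf
    for (dy in -search_bound:search_bound) for (dx in -search_bound:search_bound) {
      tr <- rows + dy; tc <- cols + dx
      kr <- tr >= 1 & tr <= h; kc <- tc >= 1 & tc <= w
      if (!any(kr) || !any(kc)) next
      a <- cur[rows[kr], cols[kc], drop = FALSE]
      b <- nxt[tr[kr], tc[kc], drop = FALSE]
      cost <- mean(abs((a - mean(a)) - (b - mean(b))))
      if (dx == 0 && dy == 0) zero_cost <- cost
      better <- cost < best_cost ||
        (cost == best_cost && sum(abs(c(dx, dy))) < sum(abs(best)))
      if (better) { best <- c(dx, dy); best_cost <- cost }
    }
    if (!(best_cost < zero_cost - noise_threshold)) best <- c(0L, 0L)
    out[bi, bj, ] <- best
  }
  out
}

# O(n^2) nearest high-activity epoch distance
oracle_nearest_true <- function(mask) {
  n <- length(mask)
  idx <- which(mask)
  sapply(seq_len(n), function(i) {
    if (length(idx) == 0) n else min(abs(i - idx))
  })
}

# tie-corrected pairwise AUC: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auc_pairwise <- function(scores, truth) {
  sp <- scores[truth == "wake"]; sn <- scores[truth == "sleep"]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# closed-form confusion metrics, written out independently
oracle_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fn + tn) * (fp + tn)) / n^2
  list(
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = po,
    kappa = if (pe < 1) (po - pe) / (1 - pe) else 0
  )
}

# a tiny perfectly separable cohort: wake at high mact_norm, sleep at low
separable_cohort <- function(n_subjects = 3, n_epochs = 40) {
  lapply(seq_len(n_subjects), function(i) {
    withr::with_seed(100 + i, {
      state <- rep(c("wake", "sleep"), each = n_epochs / 2)
      ft <- data.frame(
        mact_norm = ifelse(state == "wake", runif(n_epochs, 0.7, 1),
                           runif(n_epochs, 0, 0.3)),
        pslp_norm = ifelse(state == "wake", runif(n_epochs, 0, 0.3),
                           runif(n_epochs, 0.7, 1)),
        state = state
      )
      list(subject = sprintf("SEP%02d", i), features = ft)
    })
  })
}

small_sim_config <- function(...) {
  sim_config(n_subjects = 4, recording_minutes_mean = 30,
             recording_minutes_sd = 5, recording_minutes_min = 20, ...)
}
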