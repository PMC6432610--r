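#' Frame sequence container
#'
#' Bundles an ordered set of grayscale frames with their frame rate. Frames
#' are integer intensity matrices (0--255), all of identical dimensions,
#' oriented rows = image height, columns = image width.
#'
#' @param frames list of numeric matrices with identical dimensions,
#'   intensities in `[0, 255]`.
#' @param frame_rate frames per second; must be positive. Default 10.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate = 10) {
  if (!is.list(frames) || length(frames) == 0) {
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop("every frame must be a matrix", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (length(frames) > 1 && (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))) {
    stop("mismatched frame dimensions: all frames must share height and width",
         call. = FALSE)
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0) {
    stop("`frame_rate` must be a single positive number", call. = FALSE)
  }
  structure(
    list(frames = frames, frame_rate = frame_rate,
         height = dims[1, 1], width = dims[2, 1]),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %d x %d px, %.3g Hz\n",
              length(x$frames), x$height, x$width, x$frame_rate))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Actigraphy signal container
#'
#' A per-frame-transition movement quantity at a fixed frame rate: the
#' video-based actigraphy trace. Values are non-negative; value `t` refers to
#' the transition from frame `t` to frame `t + 1` (0-based transitions).
#'
#' @param activity numeric vector of non-negative values.
#' @param frame_rate sampling rate in Hz. Default 10.
#' @return An object of class `actigraphy_signal`.
#' @export
actigraphy_signal <- function(activity, frame_rate = 10) {
  activity <- as.numeric(activity)
  if (length(activity) == 0) stop("empty activity sequence", call. = FALSE)
  if (any(!is.finite(activity)) || any(activity < 0)) {
    stop("activity values must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0) {
    stop("`frame_rate` must be a single positive number", call. = FALSE)
  }
  structure(list(activity = activity, frame_rate = frame_rate),
            class = "actigraphy_signal")
}

#' @export
print.actigraphy_signal <- function(x, ...) {
  cat(sprintf("<actigraphy_signal> %d samples at %.3g Hz (%.2f min), mean %.3f\n",
              length(x$activity), x$frame_rate,
              length(x$activity) / x$frame_rate / 60, mean(x$activity)))
  invisible(x)
}

#' @export
length.actigraphy_signal <- function(x) length(x$activity)

block_grid <- function(height, width, block_size) {
  list(rows = ceiling(height / block_size), cols = ceiling(width / block_size))
}

block_bounds <- function(bi, bj, block_size, height, width) {
  r0 <- (bi - 1L) * block_size + 1L
  c0 <- (bj - 1L) * block_size + 1L
  list(r = r0:min(bi * block_size, height),
       c = c0:min(bj * block_size, width))
}

# Mean-subtracted SAD per valid pixel between the block at (rows, cols) in
# `cur` and the region displaced by (dx cols, dy rows) in `nxt`. Both patches
# are cropped identically so the displaced region stays inside the image.
# Returns Inf when no pixel overlaps.
ms_sad_cost <- function(cur, nxt, rows, cols, dx, dy, height, width) {
  tr <- rows + dy
  tc <- cols + dx
  keep_r <- tr >= 1L & tr <= height
  keep_c <- tc >= 1L & tc <= width
  if (!any(keep_r) || !any(keep_c)) return(Inf)
  a <- cur[rows[keep_r], cols[keep_c], drop = FALSE]
  b <- nxt[tr[keep_r], tc[keep_c], drop = FALSE]
  mean(abs((a - mean(a)) - (b - mean(b))))
}

#' Recursive-search block-matching motion estimation
#'
#' Estimates one grid of integer displacement vectors per frame transition
#' using a recursive-search block matcher: for each block, candidate vectors
#' are the zero vector, the spatial predictors (vectors already assigned to
#' the left and upper neighbours in the current grid), the temporal predictor
#' (the same block's vector from the previous transition), and the best of
#' those predictors perturbed by small pseudo-random updates (each component
#' at most 2 px). The winning candidate minimizes a mean-subtracted
#' sum-of-absolute-differences cost per valid pixel, which makes the match
#' invariant to uniform illumination changes between frames. A non-zero
#' candidate replaces the zero vector only when it improves the per-pixel
#' cost by more than `noise_threshold`, biasing the estimator to stillness
#' under sensor noise.
#'
#' Each transition is scanned `passes` times, alternating forward and reverse
#' raster order, so predictor vectors can propagate in both directions across
#' the grid. Blocks on the right/bottom edge that extend past the image are
#' cropped to the valid region and their cost normalized per remaining pixel.
#'
#' @param frames a [frame_sequence] with at least 2 frames.
#' @param block_size block side in pixels (>= 4). Default 16.
#' @param search_bound maximum displacement per component in pixels (>= 1).
#'   Default 8.
#' @param noise_threshold per-pixel cost margin a non-zero candidate must beat
#'   the zero vector by (intensity units / pixel). Default 1.
#' @param n_updates number of pseudo-random update candidates per block per
#'   pass. Default 3.
#' @param passes raster scans per transition (alternating direction).
#'   Default 2.
#' @param seed integer seed for the pseudo-random update generator; fixed seed
#'   gives a bit-identical motion field.
#' @return An object of class `motion_field`: a list with `fields` (one
#'   `grid_rows x grid_cols x 2` array per transition; slice 1 = horizontal
#'   displacement dx in columns, slice 2 = vertical dy in rows), plus the
#'   grid geometry and parameters.
#' @seealso [motion_field_to_actigraphy()], [frame_difference_actigraphy()]
#' @export
estimate_motion_rs <- function(frames, block_size = 16, search_bound = 8,
                               noise_threshold = 1, n_updates = 3,
                               passes = 2, seed = 1) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (length(frames$frames) < 2) {
    stop("insufficient frames: motion estimation needs at least 2 frames",
         call. = FALSE)
  }
  if (block_size < 4) stop("`block_size` must be >= 4", call. = FALSE)
  if (search_bound < 1) stop("`search_bound` must be >= 1", call. = FALSE)
  h <- frames$height; w <- frames$width
  g <- block_grid(h, w, block_size)
  n_trans <- length(frames$frames) - 1L

  # block pixel index cache
  bidx <- vector("list", g$rows * g$cols)
  for (bi in seq_len(g$rows)) for (bj in seq_len(g$cols)) {
    bidx[[(bi - 1L) * g$cols + bj]] <- block_bounds(bi, bj, block_size, h, w)
  }

  withr::local_seed(seed)
  prev_field <- array(0L, dim = c(g$rows, g$cols, 2L))
  fields <- vector("list", n_trans)

  for (t in seq_len(n_trans)) {
    cur <- frames$frames[[t]]
    nxt <- frames$frames[[t + 1L]]
    field <- array(0L, dim = c(g$rows, g$cols, 2L))
    for (pass in seq_len(passes)) {
      row_order <- if (pass %% 2L == 1L) seq_len(g$rows) else rev(seq_len(g$rows))
      col_order <- if (pass %% 2L == 1L) seq_len(g$cols) else rev(seq_len(g$cols))
      for (bi in row_order) for (bj in col_order) {
        bb <- bidx[[(bi - 1L) * g$cols + bj]]
        cand <- list(c(0L, 0L))
        if (bj > 1L) cand <- c(cand, list(field[bi, bj - 1L, ]))
        if (bj < g$cols) cand <- c(cand, list(field[bi, bj + 1L, ]))
        if (bi > 1L) cand <- c(cand, list(field[bi - 1L, bj, ]))
        if (bi < g$rows) cand <- c(cand, list(field[bi + 1L, bj, ]))
        cand <- c(cand, list(prev_field[bi, bj, ]), list(field[bi, bj, ]))
        # score predictors first, then perturb the best with random updates
        cost_of <- function(v) ms_sad_cost(cur, nxt, bb$r, bb$c, v[1], v[2], h, w)
        costs <- vapply(cand, cost_of, numeric(1))
        best <- cand[[which.min(costs)]]
        upd <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), 2L * n_updates,
                             replace = TRUE), ncol = 2L)
        for (k in seq_len(n_updates)) {
          v <- pmax(pmin(best + upd[k, ], search_bound), -search_bound)
          cand <- c(cand, list(v))
          costs <- c(costs, cost_of(v))
        }
        zero_cost <- costs[1]
        nz <- which(costs < zero_cost - noise_threshold)
        field[bi, bj, ] <- if (length(nz)) cand[[nz[which.min(costs[nz])]]] else c(0L, 0L)
      }
    }
    fields[[t]] <- field
    prev_field <- field
  }

  structure(
    list(fields = fields, grid_rows = g$rows, grid_cols = g$cols,
         block_size = block_size, search_bound = search_bound,
         noise_threshold = noise_threshold, frame_rate = frames$frame_rate),
    class = "motion_field"
  )
}

#' @export
print.motion_field <- function(x, ...) {
  cat(sprintf("<motion_field> %d transitions, %d x %d blocks (block %d px, bound %d px)\n",
              length(x$fields), x$grid_rows, x$grid_cols, x$block_size,
              x$search_bound))
  invisible(x)
}

#' Reduce a motion field to an actigraphy signal
#'
#' The activity value of each frame transition is the number of blocks whose
#' displacement vector is non-zero: the per-frame "activity count" whose
#' epoch mean is the mACT feature.
#'
#' @param field a `motion_field` from [estimate_motion_rs()].
#' @return An [actigraphy_signal] with one value per transition.
#' @export
motion_field_to_actigraphy <- function(field) {
  stopifnot(inherits(field, "motion_field"))
  if (length(field$fields) == 0) stop("empty motion field", call. = FALSE)
  activity <- vapply(field$fields, function(f) {
    sum(f[, , 1] != 0 | f[, , 2] != 0)
  }, numeric(1))
  actigraphy_signal(activity, frame_rate = field$frame_rate)
}

#' Frame-differencing actigraphy (baseline motion detector)
#'
#' A low-compute backstop: activity for each transition is the count of
#' pixels whose absolute intensity change exceeds `pixel_threshold`. Unlike
#' the block matcher it is sensitive to global illumination changes; it is
#' intended for sanity checks and quick looks, not for the main pipeline.
#'
#' @param frames a [frame_sequence] with at least 2 frames.
#' @param pixel_threshold intensity difference a pixel must exceed to count.
#'   Default 10.
#' @return An [actigraphy_signal].
#' @export
frame_difference_actigraphy <- function(frames, pixel_threshold = 10) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (length(frames$frames) < 2) {
    stop("insufficient frames: need at least 2", call. = FALSE)
  }
  n <- length(frames$frames) - 1L
  activity <- vapply(seq_len(n), function(t) {
    sum(abs(frames$frames[[t + 1L]] - frames$frames[[t]]) > pixel_threshold)
  }, numeric(1))
  actigraphy_signal(activity, frame_rate = frames$frame_rate)
}

#' Read a frame sequence from a directory of image files
#'
#' Loads 8-bit grayscale frames from lexicographically ordered PNG or PGM
#' (P2/P5) files. PNG intensities are rescaled from `[0, 1]` to 0--255; RGB
#' PNGs are converted to grayscale by channel averaging.
#'
#' @param dir directory containing the frames.
#' @param pattern filename regular expression. Default matches `.png`,
#'   `.pgm`.
#' @param frame_rate frames per second of the recording. Default 10.
#' @return A [frame_sequence].
#' @export
read_frames <- function(dir, pattern = "\\.(png|pgm)$", frame_rate = 10) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0) {
    stop("no frame files found in ", dir, call. = FALSE)
  }
  frames <- lapply(files, read_gray_image)
  frame_sequence(frames, frame_rate = frame_rate)
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
    return(round(img * 255))
  }
  if (ext == "pgm") return(read_pgm(path))
  stop("unsupported image format: ", path, call. = FALSE)
}

# Minimal PGM reader (P2 ASCII and P5 binary, maxval <= 255).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval, with comment lines allowed
  while (length(tokens) < 4) {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("truncated PGM header: ", path, call. = FALSE)
    line <- sub("#.*$", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1]])
    tokens <- tokens[nzchar(tokens)]
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (is.na(w) || is.na(h) || maxval > 255) {
    stop("unsupported PGM file: ", path, call. = FALSE)
  }
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    stop("unsupported PGM magic '", magic, "' in ", path, call. = FALSE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write an actigraphy signal to CSV
#'
#' Columns `frame_index` (0-based transition index), `time_s`
#' (`frame_index / frame_rate`) and `activity`.
#'
#' @param signal an [actigraphy_signal].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_actigraphy <- function(signal, path) {
  stopifnot(inherits(signal, "actigraphy_signal"))
  idx <- seq_along(signal$activity) - 1L
  df <- data.frame(frame_index = idx, time_s = idx / signal$frame_rate,
                   activity = signal$activity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an actigraphy signal from CSV
#'
#' Expects the format written by [write_actigraphy()].
#'
#' @param path CSV file path.
#' @param frame_rate sampling rate in Hz; if `NULL` (default) it is inferred
#'   from the `time_s` column.
#' @return An [actigraphy_signal].
#' @export
read_actigraphy <- function(path, frame_rate = NULL) {
  df <- utils::read.csv(path)
  need <- c("frame_index", "time_s", "activity")
  if (!all(need %in% names(df))) {
    stop("actigraphy CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(frame_rate)) {
    if (nrow(df) < 2) stop("cannot infer frame rate from a single row", call. = FALSE)
    frame_rate <- 1 / stats::median(diff(df$time_s))
  }
  actigraphy_signal(df$activity, frame_rate = frame_rate)
}
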