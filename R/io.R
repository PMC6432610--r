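hypnogram_labels <- c("W", "N1", "N2", "N3", "R", "U")

#' Read a hypnogram CSV
#'
#' Expects columns `epoch_index` (0-based, contiguous from 0), `onset_s`
#' (`epoch_index * epoch_length_s`) and `label` (one of `W`, `N1`, `N2`,
#' `N3`, `R`, `U`). Malformed rows are rejected with the offending file
#' line number (header = line 1).
#'
#' @param path CSV file path.
#' @param epoch_length_s expected epoch duration in seconds. Default 30.
#' @return Character vector of labels, one per epoch.
#' @export
read_hypnogram <- function(path, epoch_length_s = 30) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("epoch_index", "onset_s", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("hypnogram ", path, " missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$epoch_index <- suppressWarnings(as.integer(df$epoch_index))
  df$onset_s <- suppressWarnings(as.numeric(df$onset_s))
  bad_num <- which(is.na(df$epoch_index) | is.na(df$onset_s))
  if (length(bad_num)) {
    stop("hypnogram ", path, ": non-numeric index/onset at line ",
         bad_num[1] + 1L, call. = FALSE)
  }
  lines <- seq_len(nrow(df)) + 1L  # data row i is file line i + 1
  bad_idx <- which(df$epoch_index != seq_len(nrow(df)) - 1L)
  if (length(bad_idx)) {
    stop("hypnogram ", path, ": non-contiguous epoch_index at line ",
         lines[bad_idx[1]], call. = FALSE)
  }
  bad_on <- which(abs(df$onset_s - df$epoch_index * epoch_length_s) > 1e-9)
  if (length(bad_on)) {
    stop("hypnogram ", path, ": onset_s disagrees with epoch_index at line ",
         lines[bad_on[1]], call. = FALSE)
  }
  bad_lab <- which(!df$label %in% hypnogram_labels)
  if (length(bad_lab)) {
    stop("hypnogram ", path, ": unknown label '", df$label[bad_lab[1]],
         "' at line ", lines[bad_lab[1]], call. = FALSE)
  }
  df$label
}

#' Write a hypnogram CSV
#'
#' @param labels character vector of epoch labels.
#' @param path output file path.
#' @param epoch_length_s epoch duration in seconds. Default 30.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(labels, path, epoch_length_s = 30) {
  labels <- as.character(labels)
  bad <- which(!labels %in% hypnogram_labels)
  if (length(bad)) stop("unknown label '", labels[bad[1]], "'", call. = FALSE)
  idx <- seq_along(labels) - 1L
  df <- data.frame(epoch_index = idx, onset_s = idx * epoch_length_s,
                   label = labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse sleep stages to the binary wake/sleep task
#'
#' `W` maps to wake; `N1`, `N2`, `N3` and `R` are grouped into a single
#' sleep state; `U` (unable-to-score) maps to excluded and is dropped from
#' model fitting and every metric downstream.
#'
#' @param labels character vector of stage labels.
#' @param warn warn when every epoch is excluded. Default `TRUE`.
#' @return Character vector over `{wake, sleep, excluded}` with attribute
#'   `fractions` (named shares of the three states).
#' @export
binarize_labels <- function(labels, warn = TRUE) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), hypnogram_labels)
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- ifelse(labels == "W", "wake", ifelse(labels == "U", "excluded", "sleep"))
  if (warn && all(out == "excluded")) {
    warning("every epoch is unable-to-score; nothing left to classify", call. = FALSE)
  }
  attr(out, "fractions") <- c(wake = mean(out == "wake"),
                              sleep = mean(out == "sleep"),
                              excluded = mean(out == "excluded"))
  out
}

#' Write a simulated cohort to disk
#'
#' One hypnogram CSV and one actigraphy CSV per subject plus a manifest
#' (YAML) recording the configuration and every per-subject seed.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @param config the [sim_config()] used, recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort) {
    write_hypnogram(rec$hypnogram,
                    file.path(dir, paste0(rec$subject, "_hypnogram.csv")))
    write_actigraphy(rec$actigraphy,
                     file.path(dir, paste0(rec$subject, "_actigraphy.csv")))
  }
  manifest <- list(
    subjects = lapply(cohort, function(r)
      list(subject = r$subject, seeds = as.list(r$seed),
           n_epochs = length(r$hypnogram))),
    config = if (!is.null(config)) unclass(config),
    note = paste("synthetic cohort: movement rates reproduce qualitative",
                 "wake/sleep structure, not measured infant statistics")
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `*_hypnogram.csv` and
#'   `*_actigraphy.csv` pairs.
#' @param frame_rate actigraphy rate in Hz. Default 10.
#' @return A list of recordings usable by [loocv()].
#' @export
read_cohort <- function(dir, frame_rate = 10) {
  hyps <- sort(list.files(dir, pattern = "_hypnogram\\.csv$", full.names = TRUE))
  if (length(hyps) == 0) stop("no hypnogram files in ", dir, call. = FALSE)
  lapply(hyps, function(hp) {
    subject <- sub("_hypnogram\\.csv$", "", basename(hp))
    ap <- file.path(dir, paste0(subject, "_actigraphy.csv"))
    if (!file.exists(ap)) stop("missing actigraphy file for ", subject, call. = FALSE)
    list(subject = subject,
         hypnogram = read_hypnogram(hp),
         actigraphy = read_actigraphy(ap, frame_rate = frame_rate))
  })
}

default_pipeline_config <- function() {
  list(
    command = "loocv",
    epoch_length_s = 30,
    frame_rate = 10,
    percentile = 0.95,
    smoothing_window_min = 10,
    feature_set = "mact+pslp",
    threshold = 0.5,
    seed = 1,
    simulate = list(enabled = TRUE),
    paths = list(cohort_dir = NULL, out_dir = "vactig_out")
  )
}

#' Run the wake/sleep pipeline from a configuration file
#'
#' Drives the full chain from a YAML configuration: either simulates a
#' cohort (default) or loads one from `paths.cohort_dir`, computes the
#' per-recording feature tables, runs LOOCV for the configured feature
#' set(s), and writes the report CSVs plus a manifest (config file hash,
#' seed, package version) to `paths.out_dir`. All outputs are
#' deterministic for a fixed configuration and seed.
#'
#' Recognized keys (all optional, shown with defaults):
#' `command` (`"loocv"`), `epoch_length_s` (30), `frame_rate` (10),
#' `percentile` (0.95), `smoothing_window_min` (10), `feature_set`
#' (`"mact+pslp"`, or a list of sets), `threshold` (0.5), `seed` (1),
#' `simulate:` (sim_config overrides, or `enabled: false`),
#' `paths: {cohort_dir, out_dir}`.
#'
#' @param config_path path to the YAML configuration.
#' @param quiet suppress progress messages. Default `FALSE`.
#' @return The [compare_feature_sets()] result, invisibly.
#' @export
run_pipeline <- function(config_path, quiet = FALSE) {
  if (!file.exists(config_path)) {
    stop("configuration error: config file not found: ", config_path, call. = FALSE)
  }
  user <- yaml::read_yaml(config_path)
  cfg <- utils::modifyList(default_pipeline_config(), user %||% list())
  if (cfg$epoch_length_s <= 0 || cfg$frame_rate <= 0) {
    stop("configuration error: epoch_length_s and frame_rate must be positive",
         call. = FALSE)
  }
  say <- function(...) if (!quiet) message(...)
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  simulate_on <- is.null(cfg$paths$cohort_dir) ||
    isTRUE(cfg$simulate$enabled %||% TRUE) && is.null(cfg$paths$cohort_dir)
  if (!is.null(cfg$paths$cohort_dir)) {
    say("loading cohort from ", cfg$paths$cohort_dir)
    cohort <- read_cohort(cfg$paths$cohort_dir, frame_rate = cfg$frame_rate)
  } else {
    sim_args <- cfg$simulate %||% list()
    sim_args$enabled <- NULL
    sim_args$frame_rate <- cfg$frame_rate
    sim_args$epoch_length_s <- cfg$epoch_length_s
    scfg <- do.call(sim_config, sim_args)
    say("simulating cohort of ", scfg$n_subjects, " subjects (seed ", cfg$seed, ")")
    cohort <- simulate_cohort(scfg, seed = cfg$seed)
    write_cohort(cohort, file.path(out_dir, "cohort"), config = scfg)
  }

  for (rec in cohort) {
    ft <- featurize_recording(rec$actigraphy, rec$hypnogram,
                              epoch_length_s = cfg$epoch_length_s,
                              percentile = cfg$percentile,
                              smoothing_window_min = cfg$smoothing_window_min)
    write_features(ft, file.path(out_dir, paste0(rec$subject, "_features.csv")))
  }

  feature_sets <- unlist(cfg$feature_set)
  say("running LOOCV for feature set(s): ", paste(feature_sets, collapse = ", "))
  comparison <- compare_feature_sets(
    cohort, feature_sets = feature_sets, threshold = cfg$threshold,
    epoch_length_s = cfg$epoch_length_s, percentile = cfg$percentile,
    smoothing_window_min = cfg$smoothing_window_min)
  write_cv_reports(comparison, out_dir)

  manifest <- list(
    config_file = basename(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    seed = cfg$seed,
    feature_sets = as.list(feature_sets),
    package_version = as.character(utils::packageVersion("vactig"))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  say("reports written to ", out_dir)
  invisible(comparison)
}

cli_spec <- function() {
  list(
    simulate = "simulate a synthetic cohort and write it to --out",
    motion = "estimate actigraphy from a frame directory (--frames) to --out",
    featurize = "compute epoch features from --actigraphy [--hypnogram] to --out",
    train = "fit the LDA on a featurized cohort directory (--cohort) to --out",
    predict = "score a feature CSV (--features) with a model (--model) to --out",
    loocv = "run the full LOOCV pipeline from --config"
  )
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `vactig` command-line script
#' (`inst/cli/vactig.R`). Subcommands: `simulate`, `motion`, `featurize`,
#' `train`, `predict`, `loocv`. Run with no arguments for usage.
#'
#' @param args character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = character()) {
  spec <- cli_spec()
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: vactig <command> [options]\ncommands:\n")
    for (nm in names(spec)) cat(sprintf("  %-9s %s\n", nm, spec[[nm]]))
    return(invisible(0L))
  }
  cmd <- args[1]
  if (!cmd %in% names(spec)) {
    message("unknown command '", cmd, "'")
    return(invisible(2L))
  }
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out", type = "character", default = "vactig_out"),
      optparse::make_option("--frames", type = "character", default = NULL),
      optparse::make_option("--actigraphy", type = "character", default = NULL),
      optparse::make_option("--hypnogram", type = "character", default = NULL),
      optparse::make_option("--features", type = "character", default = NULL),
      optparse::make_option("--model", type = "character", default = NULL),
      optparse::make_option("--cohort", type = "character", default = NULL),
      optparse::make_option("--feature-set", type = "character",
                            default = "mact+pslp", dest = "feature_set"),
      optparse::make_option("--verbose", action = "store_true", default = FALSE)
    )), args = args[-1])
  quiet <- !opts$verbose

  status <- tryCatch({
    switch(cmd,
      simulate = {
        cfg <- sim_config()
        write_cohort(simulate_cohort(cfg, seed = opts$seed), opts$out, config = cfg)
      },
      motion = {
        if (is.null(opts$frames)) stop("--frames is required", call. = FALSE)
        fs <- read_frames(opts$frames)
        mf <- estimate_motion_rs(fs, seed = opts$seed)
        write_actigraphy(motion_field_to_actigraphy(mf), opts$out)
      },
      featurize = {
        if (is.null(opts$actigraphy)) stop("--actigraphy is required", call. = FALSE)
        sig <- read_actigraphy(opts$actigraphy)
        hyp <- if (!is.null(opts$hypnogram)) read_hypnogram(opts$hypnogram)
        write_features(featurize_recording(sig, hyp), opts$out)
      },
      train = {
        if (is.null(opts$cohort)) stop("--cohort is required", call. = FALSE)
        cohort <- read_cohort(opts$cohort)
        cols <- feature_set_columns(opts$feature_set)
        ft <- do.call(rbind, lapply(cohort, function(r) {
          f <- featurize_recording(r$actigraphy, r$hypnogram)
          f[f$state != "excluded", c(cols, "state")]
        }))
        write_lda_model(fit_lda(as.matrix(ft[cols]), ft$state), opts$out)
      },
      predict = {
        if (is.null(opts$features) || is.null(opts$model)) {
          stop("--features and --model are required", call. = FALSE)
        }
        model <- read_lda_model(opts$model)
        ft <- utils::read.csv(opts$features)
        p <- posterior_wake(model, ft)
        out <- data.frame(epoch_index = ft$epoch_index,
                          posterior_wake = p,
                          prediction = ifelse(p >= 0.5, "wake", "sleep"))
        utils::write.csv(format_num_df(out), opts$out,
                         row.names = FALSE, quote = FALSE)
      },
      loocv = {
        if (is.null(opts$config)) stop("--config is required", call. = FALSE)
        run_pipeline(opts$config, quiet = quiet)
      })
    0L
  }, error = function(e) {
    message("error [", cmd, "]: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

feature_set_columns <- function(feature_set) {
  switch(feature_set,
         "mact" = "mact_norm",
         "pslp" = "pslp_norm",
         "mact+pslp" = c("mact_norm", "pslp_norm"),
         stop("unknown feature set '", feature_set, "'", call. = FALSE))
}
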