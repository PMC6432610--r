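#' Confusion matrix for wake/sleep predictions
#'
#' Wake is the positive class: `tp` = wake predicted wake, `fp` = sleep
#' predicted wake, `fn` = wake predicted sleep, `tn` = sleep predicted
#' sleep. Excluded (unable-to-score) epochs must be removed beforehand.
#'
#' @param pred,truth equal-length vectors of `"wake"` / `"sleep"` labels.
#' @return An object of class `confusion_matrix` (named list `tp`, `fp`,
#'   `fn`, `tn`).
#' @export
confusion <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    stop("pred and truth differ in length", call. = FALSE)
  }
  bad <- setdiff(unique(c(pred, truth)), c("wake", "sleep"))
  if (length(bad)) {
    stop("labels must be 'wake'/'sleep'; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  confusion_matrix(
    tp = sum(pred == "wake" & truth == "wake"),
    fp = sum(pred == "wake" & truth == "sleep"),
    fn = sum(pred == "sleep" & truth == "wake"),
    tn = sum(pred == "sleep" & truth == "sleep")
  )
}

#' @rdname confusion
#' @param tp,fp,fn,tn non-negative epoch counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("wake", "sleep"),
                              pred = c("wake", "sleep")))
  print(m)
  invisible(x)
}

cm_total <- function(cm) cm$tp + cm$fp + cm$fn + cm$tn

#' Classification metrics from a confusion matrix
#'
#' Precision `tp/(tp+fp)`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, accuracy `(tp+tn)/total`, and Cohen's kappa. A ratio with a
#' zero denominator is undefined for that matrix: it is reported as `NA`
#' and listed in the `undefined` attribute rather than silently set to 0.
#'
#' @param cm a [confusion_matrix].
#' @return Named numeric vector `precision`, `sensitivity`, `specificity`,
#'   `accuracy`, `kappa`, with attribute `undefined` naming any metric with
#'   a zero denominator.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm_total(cm)
  if (n == 0) stop("all-zero confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(
    precision = ratio(cm$tp, cm$tp + cm$fp),
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    accuracy = (cm$tp + cm$tn) / n,
    kappa = cohen_kappa(cm)
  )
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (tp + tn)/N` and chance agreement
#' `p_e = ((tp + fn)(tp + fp) + (fn + tn)(fp + tn)) / N^2`. Used because the
#' wake/sleep class balance is skewed, so raw accuracy overstates
#' performance. When `p_e = 1` (both rater margins degenerate) kappa is
#' reported as 0 with attribute `degenerate = TRUE`.
#'
#' @param cm a [confusion_matrix].
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm_total(cm)
  if (n == 0) stop("all-zero confusion matrix", call. = FALSE)
  p_o <- (cm$tp + cm$tn) / n
  p_e <- ((cm$tp + cm$fn) * (cm$tp + cm$fp) +
            (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  if (p_e == 1) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (p_o - p_e) / (1 - p_e)
}

#' ROC curve and AUC for wake scores
#'
#' Sweeps the decision threshold over the unique score values (plus
#' sentinels above the maximum and below the minimum) and records the false
#' and true positive rates; at threshold `t` an epoch is called wake when
#' its score is `>= t`. The AUC is the trapezoidal area under the curve,
#' which equals the tie-corrected pairwise probability
#' `(concordant + 0.5 * tied) / (n_pos * n_neg)`.
#'
#' @param scores numeric wake scores (higher = more wake-like), e.g. wake
#'   posteriors.
#' @param truth `"wake"` / `"sleep"` labels, same length as `scores`.
#' @return A list with `curve` (data.frame `threshold`, `fpr`, `tpr`,
#'   ordered from all-sleep to all-wake) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.character(truth)
  if (length(scores) != length(truth)) {
    stop("scores and truth differ in length", call. = FALSE)
  }
  pos <- truth == "wake"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("undefined AUC: need at least one wake and one sleep epoch",
         call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Mann-Whitney U test for a feature's wake/sleep difference
#'
#' Rank-sum screen used to check that a feature's pooled wake and sleep
#' distributions differ. Exact two-sided p-value (full permutation null)
#' when the combined sample size is at most 20 and there are no ties;
#' otherwise the normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples (e.g. a feature's wake epochs vs sleep
#'   epochs).
#' @return List with `U` (the statistic for `x`, i.e. the number of `(x, y)`
#'   pairs with `x > y` counting ties as 1/2), `p` (two-sided) and `exact`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  no_ties <- !anyDuplicated(c(x, y))
  exact <- (length(x) + length(y) <= 20) && no_ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact)
}

metric_names <- c("precision", "sensitivity", "specificity", "accuracy", "kappa")

#' Leave-one-subject-out cross validation
#'
#' Subject-independent evaluation of the wake/sleep classifier: one fold per
#' subject, trained on every other subject's epochs and tested on the held
#' out subject. Features are computed and Min--Max normalized within each
#' recording before pooling, so no statistic of the test subject leaks into
#' training. Unable-to-score epochs are excluded from both fitting and
#' scoring.
#'
#' @param cohort a list of recordings, each a list with either a `features`
#'   data.frame (from [featurize_recording()], with a `state` column) or an
#'   `actigraphy` signal plus `hypnogram` labels, and optionally `subject`.
#' @param feature_set which features the classifier sees: `"mact+pslp"`
#'   (default), `"mact"` or `"pslp"`.
#' @param threshold wake-posterior decision threshold. Default 0.5.
#' @param epoch_length_s,percentile,smoothing_window_min feature parameters,
#'   passed to [featurize_recording()] when recordings arrive unfeaturized.
#' @return An object of class `cv_report`: `per_subject` (data.frame of
#'   per-fold epoch counts, %wake, metrics and AUC), `summary` (mean, SD and
#'   number of defined values per metric across subjects), `fold_models`
#'   (the per-fold fitted [lda_model][fit_lda()]s, named by held-out
#'   subject), `pooled_cm`, `pooled_metrics`, `pooled_roc`, `feature_set`.
#' @export
loocv <- function(cohort, feature_set = c("mact+pslp", "mact", "pslp"),
                  threshold = 0.5, epoch_length_s = 30, percentile = 0.95,
                  smoothing_window_min = 10) {
  feature_set <- match.arg(feature_set)
  if (length(cohort) < 2) stop("LOOCV needs at least 2 subjects", call. = FALSE)
  cols <- switch(feature_set,
                 "mact" = "mact_norm",
                 "pslp" = "pslp_norm",
                 "mact+pslp" = c("mact_norm", "pslp_norm"))

  tabs <- lapply(seq_along(cohort), function(i) {
    rec <- cohort[[i]]
    ft <- rec$features
    if (is.null(ft)) {
      if (is.null(rec$actigraphy) || is.null(rec$hypnogram)) {
        stop("recording ", i, " has neither features nor actigraphy+hypnogram",
             call. = FALSE)
      }
      ft <- featurize_recording(rec$actigraphy, rec$hypnogram,
                                epoch_length_s = epoch_length_s,
                                percentile = percentile,
                                smoothing_window_min = smoothing_window_min)
    }
    if (is.null(ft$state)) stop("features lack a `state` column", call. = FALSE)
    ft <- ft[ft$state != "excluded", c(cols, "state"), drop = FALSE]
    ft$subject <- rec$subject %||% sprintf("S%02d", i)
    ft
  })
  subjects <- vapply(tabs, function(t) t$subject[1], character(1))
  if (anyDuplicated(subjects)) stop("duplicate subject ids", call. = FALSE)

  per <- vector("list", length(tabs))
  fold_models <- stats::setNames(vector("list", length(tabs)), subjects)
  pooled_scores <- numeric(0)
  pooled_truth <- character(0)
  pooled <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(tabs)) {
    test <- tabs[[i]]
    train <- do.call(rbind, tabs[-i])
    if (length(unique(train$state)) < 2) {
      stop("underdetermined model: training fold for subject ", subjects[i],
           " has a single class", call. = FALSE)
    }
    model <- fit_lda(as.matrix(train[cols]), train$state)
    fold_models[[i]] <- model
    scores <- posterior_wake(model, as.matrix(test[cols]))
    pred <- ifelse(scores >= threshold, "wake", "sleep")
    cm <- confusion(pred, test$state)
    ms <- metrics(cm)
    auc <- if (length(unique(test$state)) == 2) {
      roc_auc(scores, test$state)$auc
    } else NA_real_
    per[[i]] <- data.frame(
      subject = subjects[i],
      n_epochs = nrow(test),
      pct_wake = 100 * mean(test$state == "wake"),
      tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
      t(ms), auc = auc
    )
    pooled <- pooled + c(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
    pooled_scores <- c(pooled_scores, scores)
    pooled_truth <- c(pooled_truth, test$state)
  }
  per_subject <- do.call(rbind, per)
  summ <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(per_subject[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_names, function(m) stats::sd(per_subject[[m]], na.rm = TRUE), numeric(1)),
    n_defined = vapply(metric_names, function(m) sum(!is.na(per_subject[[m]])), integer(1)),
    row.names = NULL
  )
  pooled_cm <- confusion_matrix(pooled[["tp"]], pooled[["fp"]],
                                pooled[["fn"]], pooled[["tn"]])
  structure(
    list(per_subject = per_subject, summary = summ, fold_models = fold_models,
         pooled_cm = pooled_cm, pooled_metrics = metrics(pooled_cm),
         pooled_roc = roc_auc(pooled_scores, pooled_truth),
         feature_set = feature_set, threshold = threshold),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> feature set '%s', %d subjects, %d epochs\n",
              x$feature_set, nrow(x$per_subject), cm_total(x$pooled_cm)))
  cat(sprintf("  mean +/- SD across subjects: accuracy %.1f%% +/- %.1f%%, kappa %.3f +/- %.3f\n",
              100 * x$summary$mean[x$summary$metric == "accuracy"],
              100 * x$summary$sd[x$summary$metric == "accuracy"],
              x$summary$mean[x$summary$metric == "kappa"],
              x$summary$sd[x$summary$metric == "kappa"]))
  cat(sprintf("  pooled: TP %d FP %d FN %d TN %d, AUC %.3f\n",
              x$pooled_cm$tp, x$pooled_cm$fp, x$pooled_cm$fn, x$pooled_cm$tn,
              x$pooled_roc$auc))
  invisible(x)
}

#' Compare feature sets under LOOCV
#'
#' Runs [loocv()] once per feature set and assembles the standard
#' comparison table: pooled confusion cells plus mean and SD of each metric
#' across subjects, one column per feature set.
#'
#' @param cohort as in [loocv()].
#' @param feature_sets character vector of feature sets to compare.
#' @param ... passed to [loocv()].
#' @return A list with `table` (data.frame, rows = quantities, columns =
#'   feature sets) and `reports` (named list of `cv_report`s).
#' @export
compare_feature_sets <- function(cohort,
                                 feature_sets = c("mact", "pslp", "mact+pslp"),
                                 ...) {
  reports <- lapply(feature_sets, function(fs) loocv(cohort, feature_set = fs, ...))
  names(reports) <- feature_sets
  row_names <- c("TP", "FP", "FN", "TN",
                 paste0(metric_names, "_mean"), paste0(metric_names, "_sd"),
                 "auc_pooled")
  tab <- data.frame(quantity = row_names)
  for (fs in feature_sets) {
    r <- reports[[fs]]
    tab[[fs]] <- c(r$pooled_cm$tp, r$pooled_cm$fp, r$pooled_cm$fn, r$pooled_cm$tn,
                   r$summary$mean, r$summary$sd, r$pooled_roc$auc)
  }
  list(table = tab, reports = reports)
}

#' Write LOOCV reports to CSV
#'
#' Emits a feature-set comparison table (`table1.csv`), a per-subject table
#' for the last feature set (`table2.csv`), and pooled ROC points per
#' feature set (`roc_<set>.csv` with columns `threshold`, `fpr`, `tpr`).
#'
#' @param comparison result of [compare_feature_sets()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cv_reports <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format_num_df(comparison$table),
                   file.path(dir, "table1.csv"), row.names = FALSE, quote = FALSE)
  last <- comparison$reports[[length(comparison$reports)]]
  utils::write.csv(format_num_df(last$per_subject),
                   file.path(dir, "table2.csv"), row.names = FALSE, quote = FALSE)
  for (fs in names(comparison$reports)) {
    fn <- paste0("roc_", gsub("[^a-z]", "_", fs), ".csv")
    utils::write.csv(format_num_df(comparison$reports[[fs]]$pooled_roc$curve),
                     file.path(dir, fn), row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
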