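test_that("confusion counts the four cells with wake positive", {
  cm <- confusion(rep(c("wake", "sleep"), each = 5), rep(c("wake", "sleep"), each = 5))
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]), c(tp = 5, fp = 0, fn = 0, tn = 5))
  cm2 <- confusion(rep("sleep", 10), c(rep("wake", 3), rep("sleep", 7)))
  expect_equal(unlist(cm2[c("tp", "fp", "fn", "tn")]), c(tp = 0, fp = 0, fn = 3, tn = 7))
  withr::with_seed(91, {
    for (rep in 1:20) {
      n <- sample(5:200, 1)
      pred <- sample(c("wake", "sleep"), n, TRUE)
      truth <- sample(c("wake", "sleep"), n, TRUE)
      cm <- confusion(pred, truth)
      brute <- c(0, 0, 0, 0)
      for (i in seq_len(n)) {
        cell <- paste(pred[i], truth[i])
        brute <- brute + (cell == c("wake wake", "wake sleep",
                                    "sleep wake", "sleep sleep"))
      }
      expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
                   c(tp = brute[1], fp = brute[2], fn = brute[3], tn = brute[4]))
    }
  })
  expect_error(confusion("wake", c("wake", "sleep")), "length")
})

test_that("metrics and kappa match closed forms, undefined ratios flagged", {
  perfect <- metrics(confusion_matrix(5, 0, 0, 5))
  expect_equal(unname(perfect[c("precision", "sensitivity", "specificity", "accuracy", "kappa")]),
               c(1, 1, 1, 1, 1))
  deg <- metrics(confusion_matrix(0, 0, 3, 7))
  expect_equal(unname(deg["accuracy"]), 0.7)
  expect_equal(unname(deg["sensitivity"]), 0)
  expect_true(is.na(deg["precision"]))
  expect_identical(attr(deg, "undefined"), "precision")
  expect_error(metrics(confusion_matrix(0, 0, 0, 0)), "all-zero")
})

test_that("pooled confusion cells yield the expected accuracy and kappa", {
  cm <- confusion_matrix(318, 35, 71, 955)
  m <- metrics(cm)
  expect_equal(unname(m["accuracy"]), 1273 / 1379)
  expect_equal(unname(m["accuracy"]), 0.9231, tolerance = 1e-4)
  expect_equal(cohen_kappa(cm), 0.8047, tolerance = 1e-4)
})

test_that("kappa formula agrees with the independent closed form", {
  expect_equal(cohen_kappa(confusion_matrix(50, 0, 0, 50)), 1)
  expect_equal(cohen_kappa(confusion_matrix(50, 50, 0, 0)), 0)
  k <- cohen_kappa(confusion_matrix(10, 0, 0, 0))  # p_e = 1 convention
  expect_equal(as.numeric(k), 0)
  expect_true(attr(k, "degenerate"))
  withr::with_seed(92, {
    for (rep in 1:50) {
      cells <- sample(0:200, 4, TRUE)
      if (sum(cells) == 0) cells[1] <- 1
      cm <- confusion_matrix(cells[1], cells[2], cells[3], cells[4])
      oracle <- oracle_metrics(cells[1], cells[2], cells[3], cells[4])
      got <- metrics(cm)
      for (nm in names(oracle)) {
        expect_equal(unname(got[nm]), oracle[[nm]], tolerance = 1e-14)
      }
      # kappa = 1 iff no off-diagonal errors (both classes present)
      if (cells[2] == 0 && cells[3] == 0 && cells[1] > 0 && cells[4] > 0) {
        expect_equal(as.numeric(cohen_kappa(cm)), 1)
      }
    }
  })
})

test_that("kappa concentrates near zero under label-permuted truth", {
  withr::with_seed(93, {
    ks <- replicate(50, {
      truth <- sample(c("wake", "sleep"), 400, TRUE, prob = c(0.3, 0.7))
      pred <- sample(truth)  # permuted: marginals kept, association destroyed
      cohen_kappa(confusion(pred, truth))
    })
    expect_lt(abs(mean(ks)), 0.05)
  })
})

test_that("ROC sweep AUC equals the pairwise probability oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c("wake", "wake", "sleep", "sleep"))$auc, 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), c("wake", "wake", "sleep", "sleep"))$auc, 0)
  # six scores with a tie straddling the classes
  s <- c(0.9, 0.7, 0.5, 0.5, 0.3, 0.1)
  tr <- c("wake", "wake", "wake", "sleep", "sleep", "sleep")
  expect_equal(roc_auc(s, tr)$auc, oracle_auc_pairwise(s, tr), tolerance = 1e-12)
  withr::with_seed(94, {
    for (rep in 1:30) {
      n <- sample(4:60, 1)
      tr <- sample(c("wake", "sleep"), n, TRUE)
      if (length(unique(tr)) < 2) tr[1:2] <- c("wake", "sleep")
      s <- round(runif(n), 1)  # coarse scores force ties
      expect_equal(roc_auc(s, tr)$auc, oracle_auc_pairwise(s, tr),
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(c(0.1, 0.2), c("wake", "wake")), "undefined AUC")
})

test_that("ROC curve runs from (0,0) to (1,1) and matches pROC's AUC", {
  withr::with_seed(95, {
    tr <- sample(c("wake", "sleep"), 200, TRUE, prob = c(0.3, 0.7))
    s <- ifelse(tr == "wake", rnorm(200, 1), rnorm(200))
    roc <- roc_auc(s, tr)
    expect_equal(roc$curve$fpr[1], 0); expect_equal(roc$curve$tpr[1], 0)
    expect_equal(tail(roc$curve$fpr, 1), 1); expect_equal(tail(roc$curve$tpr, 1), 1)
    expect_true(all(diff(roc$curve$fpr) >= 0) && all(diff(roc$curve$tpr) >= 0))
    skip_if_not_installed("pROC")
    ref <- pROC::auc(pROC::roc(response = tr, predictor = s,
                               levels = c("sleep", "wake"), direction = "<",
                               quiet = TRUE))
    expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-12)
  })
})

test_that("Mann-Whitney U: exact small-sample case and shifted-sample power", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_true(res$exact)
  expect_equal(res$p, 2 / 6, tolerance = 1e-12)
  # identical tied samples: approximation, p near 1
  res2 <- mann_whitney_u(rep(1:3, 4), rep(1:3, 4))
  expect_false(res2$exact)
  expect_gt(res2$p, 0.9)
  withr::with_seed(96, {
    res3 <- mann_whitney_u(rnorm(500, 0.5), rnorm(500))
    expect_lt(res3$p, 1e-4)
  })
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("LOOCV partitions subjects and never trains on the test subject", {
  cohort <- separable_cohort(3)
  rep1 <- loocv(cohort)
  expect_equal(nrow(rep1$per_subject), 3)
  expect_setequal(rep1$per_subject$subject, c("SEP01", "SEP02", "SEP03"))
  # leakage check: mutating the held-out subject's feature values must not
  # change that fold's trained model (it is fit without them), while the
  # other folds -- which do train on the mutated subject -- must change
  mutated <- cohort
  mutated[[2]]$features$mact_norm <-
    pmin(1, mutated[[2]]$features$mact_norm + 0.21)
  rep2 <- loocv(mutated)
  m1 <- rep1$fold_models[["SEP02"]]; m2 <- rep2$fold_models[["SEP02"]]
  expect_identical(m1$mu_wake, m2$mu_wake)
  expect_identical(m1$mu_sleep, m2$mu_sleep)
  expect_identical(m1$sigma_pooled, m2$sigma_pooled)
  expect_false(identical(rep1$fold_models[["SEP01"]]$mu_wake,
                         rep2$fold_models[["SEP01"]]$mu_wake))
})

test_that("a linearly separable cohort reaches kappa 1 per subject", {
  rep <- loocv(separable_cohort(4))
  expect_true(all(rep$per_subject$kappa == 1))
  expect_equal(rep$pooled_metrics[["accuracy"]], 1)
  expect_equal(rep$pooled_roc$auc, 1)
})

test_that("pooled confusion equals the sum over subjects", {
  cfg <- small_sim_config()
  cohort <- simulate_cohort(cfg, seed = 17)
  rep <- loocv(cohort)
  expect_equal(rep$pooled_cm$tp, sum(rep$per_subject$tp))
  expect_equal(rep$pooled_cm$fn, sum(rep$per_subject$fn))
  expect_equal(cm_total <- with(rep$pooled_cm, tp + fp + fn + tn),
               sum(rep$per_subject$n_epochs))
  # epoch counts match input after exclusion of unable-to-score epochs
  n_manual <- sapply(cohort, function(r) {
    n_feat <- min(floor(length(r$actigraphy$activity) / 300), length(r$hypnogram))
    sum(r$hypnogram[seq_len(n_feat)] != "U")
  })
  expect_equal(rep$per_subject$n_epochs, unname(n_manual))
})

test_that("single-class training folds are rejected", {
  cohort <- separable_cohort(2)
  cohort[[1]]$features$state <- "sleep"
  expect_error(loocv(cohort), "single class")
})
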