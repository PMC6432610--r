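simple_model <- function() {
  # unit covariance, means (2,0) wake / (0,0) sleep, equal priors:
  # log-odds(x) = 2 x1 - 2
  structure(
    list(mu_wake = c(f1 = 2, f2 = 0), mu_sleep = c(f1 = 0, f2 = 0),
         sigma_pooled = diag(2), priors = c(wake = 0.5, sleep = 0.5),
         feature_names = c("f1", "f2"), n_train = c(wake = 2, sleep = 2),
         ridge_applied = 0),
    class = "lda_model")
}

test_that("posterior matches the closed-form logit and normalizes", {
  m <- simple_model()
  expect_equal(posterior_wake(m, c(1, 0)), 0.5)
  expect_equal(posterior_wake(m, c(2, 0)), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(posterior_wake(m, c(2, 0)), 0.8808, tolerance = 1e-4)
  withr::with_seed(71, {
    x <- matrix(rnorm(40), ncol = 2)
    p <- posterior_wake(m, x)
    expect_true(all(p > 0 & p < 1))
    # P(sleep|x) via swapped classes: posteriors must sum to 1
    m2 <- m
    m2$mu_wake <- m$mu_sleep; m2$mu_sleep <- m$mu_wake
    expect_equal(p + posterior_wake(m2, x), rep(1, 20), tolerance = 1e-12)
  })
})

test_that("decisions agree with brute-force Gaussian density comparison", {
  withr::with_seed(72, {
    x <- matrix(rnorm(2000, sd = 2), ncol = 2)
    m <- simple_model()
    pred <- predict(m, x)
    si <- solve(m$sigma_pooled)
    dens <- function(x, mu) exp(-0.5 * mahalanobis(x, mu, m$sigma_pooled))
    brute <- ifelse(dens(x, m$mu_wake) >= dens(x, m$mu_sleep), "wake", "sleep")
    expect_identical(pred, brute)
  })
})

test_that("threshold is monotone and extreme thresholds flip every decision", {
  m <- simple_model()
  withr::with_seed(73, x <- matrix(rnorm(60, sd = 3), ncol = 2))
  expect_true(all(predict(m, x, threshold = 1e-12) == "wake"))
  expect_true(all(predict(m, x, threshold = 1 - 1e-12) == "sleep"))
  expect_equal(predict(m, m$mu_wake), "wake")
  expect_error(predict(m, x, threshold = 0), "threshold")
})

test_that("fit recovers known class parameters at large n", {
  withr::with_seed(74, {
    n <- 10000
    xw <- cbind(rnorm(n, 1), rnorm(n, 1))
    xs <- cbind(rnorm(n, 0), rnorm(n, 0))
    x <- rbind(xw, xs)
    colnames(x) <- c("f1", "f2")
    model <- fit_lda(x, rep(c("wake", "sleep"), each = n))
    expect_lt(max(abs(model$mu_wake - c(1, 1))), 0.05)
    expect_lt(max(abs(model$mu_sleep - c(0, 0))), 0.05)
    expect_lt(max(abs(model$sigma_pooled - diag(2))), 0.05)
    expect_equal(unname(model$priors), c(0.5, 0.5))
  })
})

test_that("priors are equalized regardless of class frequencies", {
  withr::with_seed(75, {
    x <- rbind(cbind(rnorm(30, 2), rnorm(30)), cbind(rnorm(300), rnorm(300)))
    model <- fit_lda(x, c(rep("wake", 30), rep("sleep", 300)))
    expect_equal(unname(model$priors), c(0.5, 0.5))
    # scaling both priors equally cannot change decisions
    m2 <- model; m2$priors <- c(wake = 0.2, sleep = 0.2)
    pts <- matrix(rnorm(40), ncol = 2)
    expect_identical(predict(model, pts), predict(m2, pts))
  })
})

test_that("duplicated feature columns trigger the ridge and stay finite", {
  withr::with_seed(76, {
    a <- rnorm(50)
    x <- cbind(f1 = a, f2 = a)  # rank-1 pooled covariance
    model <- fit_lda(x, rep(c("wake", "sleep"), 25))
    expect_gt(model$ridge_applied, 0)
    p <- posterior_wake(model, x)
    expect_true(all(is.finite(p)))
  })
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_lda(x, rep("wake", 10)), "underdetermined")
  expect_error(fit_lda(x, c(rep("wake", 9), "sleep")), "underdetermined")
  x[1, 1] <- NA
  expect_error(fit_lda(x, rep(c("wake", "sleep"), 5)), "non-finite")
  m <- simple_model()
  expect_error(posterior_wake(m, c(1, 2, 3)), "dimension mismatch")
})

test_that("the 0.5-posterior decision boundary is affine", {
  withr::with_seed(77, {
    xw <- cbind(rnorm(200, 1.5, 0.7), rnorm(200, 0.5, 0.4))
    xs <- cbind(rnorm(200, 0, 0.7), rnorm(200, 1, 0.4))
    model <- fit_lda(rbind(xw, xs), rep(c("wake", "sleep"), each = 200))
    # find three boundary crossings by bisection along random segments
    crossing <- function(a, b) {
      fa <- posterior_wake(model, a) - 0.5
      for (i in 1:60) {
        mid <- (a + b) / 2
        fm <- posterior_wake(model, mid) - 0.5
        if (sign(fm) == sign(fa)) { a <- mid; fa <- fm } else b <- mid
      }
      (a + b) / 2
    }
    pts <- list()
    k <- 0
    while (length(pts) < 3 && k < 50) {
      k <- k + 1
      a <- rnorm(2, c(2, 0), 2); b <- rnorm(2, c(-1, 1), 2)
      if (sign(posterior_wake(model, a) - 0.5) !=
          sign(posterior_wake(model, b) - 0.5)) {
        pts[[length(pts) + 1]] <- crossing(a, b)
      }
    }
    expect_length(pts, 3)
    m3 <- cbind(pts[[2]] - pts[[1]], pts[[3]] - pts[[1]])
    expect_lt(abs(det(m3)), 1e-6)  # collinear crossings
  })
})

test_that("posterior is non-decreasing along the discriminant direction", {
  m <- simple_model()
  w <- solve(m$sigma_pooled, m$mu_wake - m$mu_sleep)
  base <- c(-1, 2)
  ts <- seq(-5, 5, length.out = 41)
  p <- posterior_wake(m, t(sapply(ts, function(t) base + t * w)))
  expect_true(all(diff(p) >= 0))
})

test_that("empirical error approaches the analytic Bayes error", {
  withr::with_seed(78, {
    mu_w <- c(1.2, 0); mu_s <- c(0, 0)
    delta <- sqrt(sum((mu_w - mu_s)^2))  # identity covariance
    bayes <- pnorm(-delta / 2)
    n <- 20000
    x <- rbind(cbind(rnorm(n, mu_w[1]), rnorm(n, mu_w[2])),
               cbind(rnorm(n, mu_s[1]), rnorm(n, mu_s[2])))
    truth <- rep(c("wake", "sleep"), each = n)
    model <- fit_lda(x, truth)
    err <- mean(predict(model, x) != truth)
    expect_equal(err, bayes, tolerance = 0.02)
  })
})

test_that("posteriors agree with MASS::lda as an independent cross-check", {
  skip_if_not_installed("MASS")
  withr::with_seed(79, {
    x <- rbind(cbind(rnorm(150, 1), rnorm(150, 0.5)),
               cbind(rnorm(250), rnorm(250)))
    colnames(x) <- c("f1", "f2")
    truth <- c(rep("wake", 150), rep("sleep", 250))
    ours <- fit_lda(x, truth)
    ref <- MASS::lda(x, grouping = truth, prior = c(sleep = 0.5, wake = 0.5))
    pts <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
    p_ref <- predict(ref, pts)$posterior[, "wake"]
    expect_equal(unname(posterior_wake(ours, pts)), unname(p_ref),
                 tolerance = 1e-8)
  })
})

test_that("model serialization round-trips through structured text", {
  withr::with_seed(80, {
    x <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("mact_norm", "pslp_norm")))
    model <- fit_lda(x, rep(c("wake", "sleep"), 50))
    path <- withr::local_tempfile(fileext = ".yaml")
    write_lda_model(model, path)
    back <- read_lda_model(path)
    expect_equal(back$mu_wake, model$mu_wake)
    expect_equal(back$sigma_pooled, model$sigma_pooled, ignore_attr = TRUE)
    pts <- matrix(rnorm(20), ncol = 2)
    expect_equal(posterior_wake(back, pts), posterior_wake(model, pts),
                 tolerance = 1e-12)
  })
})
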