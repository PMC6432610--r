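#' Fit a two-class Bayesian linear discriminant model
#'
#' Gaussian class-conditional model with a shared (pooled) covariance,
#' giving a linear decision boundary. Class means are the per-class feature
#' averages; the pooled covariance is
#' `((n_w - 1) S_w + (n_s - 1) S_s) / (n_w + n_s - 2)` with `S` the
#' per-class sample covariances. The class priors are equalized at
#' `(0.5, 0.5)` regardless of the training class frequencies, so the
#' decision at threshold 0.5 is driven by the feature densities alone —
#' appropriate when the deployment class balance is unknown and the
#' training balance (here, far fewer wake than sleep epochs) should not tip
#' the boundary.
#'
#' If the pooled covariance is singular or badly conditioned
#' (condition number above `1e8`), a ridge of
#' `ridge_fraction * trace / d` is added to the diagonal (escalating by
#' factors of 10 until the matrix is well-posed).
#'
#' @param x numeric matrix (epochs x features) or data.frame of features.
#' @param labels vector with exactly two distinct values; `"wake"` is the
#'   positive class. Epochs labelled anything else than `"wake"`/`"sleep"`
#'   must be removed beforehand.
#' @param ridge_fraction relative ridge added when regularization triggers.
#'   Default `1e-6`.
#' @return An object of class `lda_model`: `mu_wake`, `mu_sleep`,
#'   `sigma_pooled`, `priors`, `feature_names`, `ridge_applied`.
#' @export
fit_lda <- function(x, labels, ridge_fraction = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) {
    stop("labels and feature rows differ in length", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("wake", "sleep"))
  if (length(bad)) {
    stop("labels must be 'wake'/'sleep'; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  iw <- labels == "wake"
  n_w <- sum(iw); n_s <- sum(!iw)
  if (n_w < 2 || n_s < 2) {
    stop("underdetermined model: need at least 2 epochs per class (wake=",
         n_w, ", sleep=", n_s, ")", call. = FALSE)
  }
  xw <- x[iw, , drop = FALSE]
  xs <- x[!iw, , drop = FALSE]
  mu_w <- colMeans(xw)
  mu_s <- colMeans(xs)
  sigma <- ((n_w - 1) * stats::cov(xw) + (n_s - 1) * stats::cov(xs)) /
    (n_w + n_s - 2)
  d <- ncol(x)
  ridge_applied <- 0
  repeat {
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    ok <- min(ev) > 0 && (max(ev) / min(ev)) < 1e8
    if (ok) break
    step <- ridge_fraction * max(sum(diag(sigma)), .Machine$double.eps) / d
    if (ridge_applied > 0) step <- ridge_applied * 10
    sigma <- sigma + diag(step, d)
    ridge_applied <- ridge_applied + step
  }
  structure(
    list(mu_wake = mu_w, mu_sleep = mu_s, sigma_pooled = sigma,
         priors = c(wake = 0.5, sleep = 0.5),
         feature_names = colnames(x) %||% paste0("f", seq_len(d)),
         n_train = c(wake = n_w, sleep = n_s),
         ridge_applied = ridge_applied),
    class = "lda_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> features:", paste(x$feature_names, collapse = ", "), "\n")
  cat("  mu_wake: ", paste(signif(x$mu_wake, 4), collapse = ", "), "\n")
  cat("  mu_sleep:", paste(signif(x$mu_sleep, 4), collapse = ", "), "\n")
  cat("  priors:  ", paste(x$priors, collapse = "/"),
      if (x$ridge_applied > 0) sprintf(" (ridge %.3g)", x$ridge_applied), "\n")
  invisible(x)
}

as_feature_matrix <- function(model, x) {
  d <- length(model$mu_wake)
  if (is.data.frame(x)) x <- as.matrix(x[, model$feature_names, drop = FALSE])
  if (is.null(dim(x))) {
    if (length(x) != d) stop("feature dimension mismatch", call. = FALSE)
    x <- matrix(x, nrow = 1)
  }
  x <- as.matrix(x)
  if (ncol(x) != d) stop("feature dimension mismatch", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Posterior probability of wake
#'
#' `P(wake | x)` from the two Gaussian class-conditional densities and the
#' priors, evaluated in log space for numerical stability:
#' the posterior is the logistic of
#' `log N(x; mu_w, Sigma) - log N(x; mu_s, Sigma) + log(pi_w / pi_s)`.
#' With a shared covariance this log-odds is linear in `x`.
#'
#' @param model a fitted [lda_model][fit_lda()].
#' @param x feature vector, matrix (rows = observations) or data.frame.
#' @return Numeric vector of posteriors in `(0, 1)`;
#'   `P(wake|x) + P(sleep|x) = 1` by construction.
#' @export
posterior_wake <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  x <- as_feature_matrix(model, x)
  si <- solve(model$sigma_pooled)
  log_odds_prior <- log(model$priors[["wake"]]) - log(model$priors[["sleep"]])
  dw <- sweep(x, 2, model$mu_wake)
  ds <- sweep(x, 2, model$mu_sleep)
  # -1/2 Mahalanobis difference; the shared normalizing constant cancels
  log_odds <- -0.5 * (rowSums((dw %*% si) * dw) - rowSums((ds %*% si) * ds)) +
    log_odds_prior
  stats::plogis(log_odds)
}

#' Classify observations as wake or sleep
#'
#' Wake (the positive class) is predicted when the wake posterior is at
#' least `threshold`; ties at exactly the threshold go to wake, which keeps
#' the rule deterministic and favors sensitivity. At the default threshold
#' 0.5 with equal priors this is the Bayes maximum-posterior rule and the
#' decision boundary is the hyperplane Mahalanobis-equidistant from the two
#' class means.
#'
#' @param object a fitted [lda_model][fit_lda()].
#' @param newdata feature vector, matrix or data.frame.
#' @param threshold wake-posterior decision threshold in `(0, 1)`.
#'   Default 0.5.
#' @param ... unused.
#' @return Character vector of `"wake"` / `"sleep"` labels.
#' @export
predict.lda_model <- function(object, newdata, threshold = 0.5, ...) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly between 0 and 1", call. = FALSE)
  }
  p <- posterior_wake(object, newdata)
  ifelse(p >= threshold, "wake", "sleep")
}

#' Save a fitted LDA model as structured text
#'
#' Writes the model (means, pooled covariance, priors, feature names and the
#' normalization convention used at training time) as YAML so it can be
#' inspected and versioned as plain text.
#'
#' @param model a fitted [lda_model][fit_lda()].
#' @param path output file path.
#' @param normalization note recorded with the model (how features were
#'   scaled at training time). Default `"min-max per recording"`.
#' @return `path`, invisibly.
#' @export
write_lda_model <- function(model, path, normalization = "min-max per recording") {
  stopifnot(inherits(model, "lda_model"))
  obj <- list(
    model = "bayesian_lda",
    feature_names = as.list(model$feature_names),
    mu_wake = as.list(unname(model$mu_wake)),
    mu_sleep = as.list(unname(model$mu_sleep)),
    sigma_pooled = apply(model$sigma_pooled, 1, as.list, simplify = FALSE),
    priors = list(wake = unname(model$priors[["wake"]]),
                  sleep = unname(model$priors[["sleep"]])),
    n_train = list(wake = unname(model$n_train[["wake"]]),
                   sleep = unname(model$n_train[["sleep"]])),
    ridge_applied = model$ridge_applied,
    normalization = normalization
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Load an LDA model written by [write_lda_model()]
#'
#' @param path YAML model file.
#' @return An [lda_model][fit_lda()] object.
#' @export
read_lda_model <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$model, "bayesian_lda")) {
    stop("not a vactig LDA model file: ", path, call. = FALSE)
  }
  fn <- unlist(obj$feature_names)
  d <- length(fn)
  sigma <- do.call(rbind, lapply(obj$sigma_pooled, unlist))
  dimnames(sigma) <- list(fn, fn)
  structure(
    list(mu_wake = stats::setNames(unlist(obj$mu_wake), fn),
         mu_sleep = stats::setNames(unlist(obj$mu_sleep), fn),
         sigma_pooled = sigma,
         priors = c(wake = obj$priors$wake, sleep = obj$priors$sleep),
         feature_names = fn,
         n_train = c(wake = obj$n_train$wake, sleep = obj$n_train$sleep),
         ridge_applied = obj$ridge_applied %||% 0),
    class = "lda_model"
  )
}
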