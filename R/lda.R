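#' Univariate linear discriminant with leave-one-out training accuracy
#'
#' Fits a one-dimensional Gaussian linear discriminant to labelled annual
#' d18O signatures: per-class means, a pooled within-class variance, and
#' class priors (equal by default, matching a training set balanced by
#' construction; `priors = "proportional"` uses observed class
#' frequencies). With equal priors and the pooled variance, the decision
#' boundaries are the midpoints of adjacent class means.
#'
#' Leave-one-out accuracy is computed exactly: each sample is classified by
#' the model refitted without it, using closed-form mean and
#' sum-of-squares downdates rather than n refits, so the procedure is O(n).
#'
#' @param values numeric vector of training signatures (per mil).
#' @param labels class labels, same length; >= 2 classes with >= 2 samples
#'   each.
#' @param priors `"equal"` or `"proportional"`.
#' @return an `oto_lda` object: `means`, `pooled_sd`, `priors`, `levels`,
#'   `boundaries` (sorted midpoints under equal priors) and `loo_accuracy`
#'   (percent).
#' @export
fit_classifier_loo <- function(values, labels, priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  stopifnot(length(values) == length(labels))
  if (any(!is.finite(values))) stop_input("non-finite training values")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stop_input("need at least 2 classes")
  nk <- table(factor(labels, levels = lev))
  if (any(nk < 2L)) {
    stop_input("class '%s' has fewer than 2 samples",
               names(nk)[which(nk < 2)[1]])
  }
  k <- length(lev)
  n <- length(values)
  mu <- tapply(values, factor(labels, levels = lev), mean)
  ssw <- sum((values - mu[labels])^2)
  pooled_var <- ssw / (n - k)
  pr <- if (priors == "equal") rep(1 / k, k) else as.numeric(nk) / n
  names(pr) <- lev

  # exact LOO: downdated class mean and pooled variance per held-out sample
  nk_i <- as.numeric(nk[labels])
  mu_i <- (nk_i * as.numeric(mu[labels]) - values) / (nk_i - 1)
  ssw_i <- ssw - (values - as.numeric(mu[labels]))^2 * nk_i / (nk_i - 1)
  var_i <- ssw_i / (n - 1 - k)
  loo_pred <- character(n)
  mu_mat <- matrix(rep(as.numeric(mu), each = n), nrow = n)  # n x k
  own <- match(labels, lev)
  mu_mat[cbind(seq_len(n), own)] <- mu_i
  pr_loo <- if (priors == "equal") matrix(1 / k, n, k) else {
    m <- matrix(rep(as.numeric(nk), each = n), nrow = n)
    m[cbind(seq_len(n), own)] <- m[cbind(seq_len(n), own)] - 1
    m / (n - 1)
  }
  disc <- -(values - mu_mat)^2 / (2 * var_i) + log(pr_loo)
  loo_pred <- lev[max.col(disc, ties.method = "first")]
  loo_accuracy <- 100 * mean(loo_pred == labels)

  fit <- structure(list(
    levels = lev, means = as.numeric(mu), pooled_sd = sqrt(pooled_var),
    priors = pr, n_per_class = as.integer(nk),
    loo_accuracy = loo_accuracy), class = "oto_lda")
  ord <- order(fit$means)
  fit$boundaries <- if (priors == "equal") {
    (fit$means[ord][-k] + fit$means[ord][-1]) / 2
  } else NULL
  fit
}

#' @export
print.oto_lda <- function(x, ...) {
  cat("<oto_lda> univariate Gaussian discriminant\n")
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s (mu=%.3f, n=%d)", x$levels, x$means,
                            x$n_per_class), collapse = ", ")))
  cat(sprintf("  pooled SD %.4f; LOO accuracy %.2f%%\n",
              x$pooled_sd, x$loo_accuracy))
  invisible(x)
}

#' Assign samples to stocks with a fitted discriminant
#'
#' Computes per-class posterior scores (Gaussian class densities times
#' priors, normalised to sum to one) and the argmax label for each sample;
#' exact posterior ties break to the lower class index. When true labels
#' are supplied, overall accuracy (percent) and a confusion table are
#' reported.
#'
#' @param fit an `oto_lda` from [fit_classifier_loo()].
#' @param values numeric vector of measured signatures; must be non-empty.
#' @param truth optional true labels for accuracy assessment.
#' @return an `assignment_result`: list with `table` (data.frame of sample,
#'   predicted label and per-class scores), and, with truth, `accuracy`
#'   (percent), `n_correct` and `confusion`.
#' @export
assign_samples <- function(fit, values, truth = NULL) {
  stopifnot(inherits(fit, "oto_lda"))
  if (!length(values)) stop_input("no samples to assign")
  if (any(!is.finite(values))) stop_input("non-finite sample values")
  k <- length(fit$levels)
  disc <- vapply(seq_len(k), function(j) {
    -(values - fit$means[j])^2 / (2 * fit$pooled_sd^2) + log(fit$priors[j])
  }, numeric(length(values)))
  disc <- matrix(disc, ncol = k)
  m <- apply(disc, 1, max)
  post <- exp(disc - m)
  post <- post / rowSums(post)
  pred <- fit$levels[max.col(post, ties.method = "first")]
  tab <- data.frame(sample = seq_along(values), value = values,
                    predicted = pred)
  for (j in seq_len(k)) tab[[paste0("score_", fit$levels[j])]] <- post[, j]
  out <- list(table = tab, levels = fit$levels)
  if (!is.null(truth)) {
    truth <- as.character(truth)
    out$n_correct <- sum(pred == truth)
    out$accuracy <- 100 * out$n_correct / length(truth)
    out$confusion <- table(truth = factor(truth, levels = fit$levels),
                           predicted = factor(pred, levels = fit$levels))
  }
  structure(out, class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment_result> %d samples\n", nrow(x$table)))
  if (!is.null(x$accuracy)) {
    cat(sprintf("  accuracy %.2f%% (%d/%d correct)\n", x$accuracy,
                x$n_correct, nrow(x$table)))
    print(x$confusion)
  }
  invisible(x)
}
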