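# ROC analysis and the DeLong test for paired (correlated) AUCs.
#
# AUCs are midrank (Mann-Whitney) estimates: ties between a positive and a
# negative score count 1/2.  The empirical ROC curve is built over every
# distinct score threshold; with ties it contains diagonal segments whose
# trapezoidal area equals the midrank AUC exactly.

# DeLong structural components.  For positives X_i and negatives Y_j with
# psi(x, y) = 1{x > y} + 0.5 * 1{x == y}:
#   V10_i = mean_j psi(X_i, Y_j),  V01_j = mean_i psi(X_i, Y_j)
# computed in O(N log N) via midranks.
delong_placements <- function(labels, scores) {
  m <- sum(labels)
  n <- sum(!labels)
  x <- scores[labels]
  y <- scores[!labels]
  tz <- rank(c(x, y), ties.method = "average")
  tx <- rank(x, ties.method = "average")
  ty <- rank(y, ties.method = "average")
  v10 <- (tz[seq_len(m)] - tx) / n
  v01 <- 1 - (tz[m + seq_len(n)] - ty) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

check_roc_inputs <- function(labels, scores) {
  labels <- as.logical(labels)
  if (anyNA(labels) || anyNA(scores)) abort_data("labels/scores must not contain NA")
  if (length(labels) != length(scores)) {
    abort_usage("labels and scores must have equal length")
  }
  if (!any(labels) || all(labels)) {
    abort_data("need at least one positive and one negative label")
  }
  labels
}

#' ROC curve and midrank AUC
#'
#' Builds the empirical ROC curve of a score against a binary label
#' (higher score = more suspicious) with one operating point per distinct
#' threshold, and the midrank AUC (ties between a positive and a negative
#' count 1/2; equal to the trapezoidal area under the returned curve).
#'
#' @param labels logical vector (TRUE = positive, e.g. participant has
#'   cancer).
#' @param scores numeric vector of the same length; ordinal category ranks
#'   are fine.
#' @return An object of class `roc_result`: list with `auc`, `n_pos`,
#'   `n_neg`, and `curve`, a data.frame of (`threshold`, `fpr`, `tpr`)
#'   from (0,0) (threshold `Inf`) to (1,1).
#' @examples
#' r <- roc(c(TRUE, TRUE, FALSE, FALSE, FALSE), c(4, 2, 3, 1, 1))
#' r$auc  # 0.75
#' @export
roc <- function(labels, scores) {
  labels <- check_roc_inputs(labels, scores)
  pl <- delong_placements(labels, scores)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  structure(list(auc = pl$auc, n_pos = pl$m, n_neg = pl$n, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$curve) - 1L))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, add = FALSE, col = "black", points = TRUE, ...) {
  if (!add) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "False positive rate", ylab = "True positive rate",
                   ...)
    graphics::abline(0, 1, col = "grey70", lty = 3)
  }
  graphics::lines(x$curve$fpr, x$curve$tpr, col = col)
  if (points) {
    graphics::points(x$curve$fpr[-1L], x$curve$tpr[-1L], col = col, pch = 16,
                     cex = 0.7)
  }
  invisible(x)
}

#' Midrank AUC
#'
#' @inheritParams roc
#' @return The AUC as a single number.
#' @export
auc <- function(labels, scores) {
  labels <- check_roc_inputs(labels, scores)
  delong_placements(labels, scores)$auc
}

#' DeLong variance of a single AUC
#'
#' @inheritParams roc
#' @return Estimated variance of the midrank AUC.
#' @keywords internal
delong_auc_variance <- function(labels, scores) {
  labels <- check_roc_inputs(labels, scores)
  pl <- delong_placements(labels, scores)
  stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the *same* subjects (the
#' paired design of comparing scoring systems on one cohort), using the
#' DeLong structural-components estimate of the covariance between the
#' two correlated AUCs.  Ties are handled with midranks.  The test
#' statistic `z = (auc_a - auc_b) / sd(auc_a - auc_b)` is referred to the
#' standard normal; the p-value is two-sided.
#'
#' If the estimated variance of the difference is zero the AUCs must be
#' equal (then `z = 0`, `p = 1`); otherwise a numerical error is raised.
#'
#' @inheritParams roc
#' @param scores_a,scores_b the two score vectors, same subjects in the
#'   same order.
#' @return List with `auc_a`, `auc_b`, `var_diff`, `z`, `p`.
#' @examples
#' set.seed(1)
#' lab <- rep(c(TRUE, FALSE), c(20, 40))
#' a <- rnorm(60, mean = lab)
#' b <- rnorm(60, mean = 0.5 * lab)
#' delong_test(lab, a, b)$p
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  labels <- check_roc_inputs(labels, scores_a)
  check_roc_inputs(labels, scores_b)
  pa <- delong_placements(labels, scores_a)
  pb <- delong_placements(labels, scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = 0,
                  z = 0, p = 1))
    }
    abort_data("zero estimated variance of the AUC difference with unequal AUCs")
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}
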