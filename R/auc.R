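# ROC statistics implemented from scratch.  The AUC is the pairwise
# probability estimate: the mean over all (positive, negative) pairs of
# psi = 1 if pos > neg, 0.5 if tied, 0 otherwise, computed in O(n log n)
# with midranks.  Variances and covariances use the structural-components
# (DeLong) estimator: per-positive mean psi values V10, per-negative V01,
# var(AUC) = S10/m + S01/n with S the sample (co)variances of the
# components.

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  morfse_error("labels must be logical or 0/1", "morfse_degenerate_labels")
}

# Midrank structural components of one score vector.
delong_components <- function(scores, positive) {
  m <- sum(positive)
  n <- sum(!positive)
  if (m == 0 || n == 0)
    morfse_error("need at least one positive and one negative",
                 "morfse_degenerate_labels")
  tz <- rank(scores, ties.method = "average")
  tx <- rank(scores[positive], ties.method = "average")
  ty <- rank(scores[!positive], ties.method = "average")
  v10 <- (tz[positive] - tx) / n
  v01 <- 1 - (tz[!positive] - ty) / m
  auc <- (sum(tz[positive]) / m - (m + 1) / 2) / n
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' Binary score for the cancer-vs-rest reduction
#'
#' Reduces a three-class probability output to the binary cancer score: the
#' raw `p_cancer` component.  Truth is `diagnostic_label == "cancer"`
#' against benign and normal combined.
#'
#' @param p A [class_probabilities()], a numeric (cancer, benign, normal)
#'   triple, or a probability matrix with a `cancer` column.
#' @return Numeric score(s) in `[0, 1]`.
#' @export
cancer_score <- function(p) {
  if (inherits(p, "class_probabilities")) return(p$p_cancer)
  if (is.matrix(p)) {
    if (!"cancer" %in% colnames(p))
      morfse_error("probability matrix lacks a 'cancer' column",
                   "morfse_input_error")
    return(p[, "cancer"])
  }
  as.numeric(p)[1]
}

#' Area under the ROC curve with DeLong variance
#'
#' @param scores Numeric score vector (higher = more cancer-like).
#' @param labels Logical (or 0/1) truth vector, `TRUE` = positive.
#' @param level Confidence level for the normal-approximation interval.
#' @return An `auc_result`: `auc`, `variance`, `ci95 = c(lower, upper)`
#'   (clipped to `[0, 1]`), `n_pos`, `n_neg`.
#' @export
binary_auc <- function(scores, labels, level = 0.95) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels))
    morfse_error("scores and labels differ in length", "morfse_pairing_error")
  cmp <- delong_components(scores, labels)
  variance <- delong_var_from_components(cmp)
  res <- structure(list(auc = cmp$auc, variance = variance,
                        ci95 = NULL, n_pos = cmp$m, n_neg = cmp$n),
                   class = "auc_result")
  res$ci95 <- auc_ci(res, level)
  res
}

delong_var_from_components <- function(cmp) {
  s10 <- if (cmp$m > 1) stats::var(cmp$v10) else 0
  s01 <- if (cmp$n > 1) stats::var(cmp$v01) else 0
  s10 / cmp$m + s01 / cmp$n
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (%.4f-%.4f), var %.3g, %d pos / %d neg\n",
              x$auc, x$ci95[1], x$ci95[2], x$variance, x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong sampling variance of one AUC
#'
#' @inheritParams binary_auc
#' @return The structural-components variance estimate (non-negative; zero
#'   for perfectly separated scores).
#' @export
delong_variance <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  delong_var_from_components(delong_components(scores, labels))
}

#' Normal-approximation confidence interval for an AUC
#'
#' `auc +/- z * sqrt(variance)`, clipped to `[0, 1]`.
#'
#' @param result An `auc_result` (or a list with `auc` and `variance`).
#' @param level Confidence level (default 0.95).
#' @return `c(lower, upper)`.
#' @export
auc_ci <- function(result, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(result$variance)
  c(max(0, result$auc - half), min(1, result$auc + half))
}

#' Paired DeLong test for two correlated ROC curves
#'
#' Both score vectors must be aligned to the same labels (paired by patch:
#' the integrated out-of-fold predictions form one test set).  The variance
#' of the AUC difference includes the component covariances; by convention
#' `p = 1` when the difference and its variance are both zero.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared truth vector.
#' @return A `delong_result`: `auc_a`, `auc_b`, `var_diff`, `z` (standard
#'   normal statistic), `p` (two-sided).
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    morfse_error("paired scores and labels must have equal length",
                 "morfse_pairing_error")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- ca$m; n <- ca$n
  s10 <- function(u, v) if (m > 1) stats::cov(u, v) else 0
  s01 <- function(u, v) if (n > 1) stats::cov(u, v) else 0
  var_diff <- (s10(ca$v10, ca$v10) + s10(cb$v10, cb$v10) -
                 2 * s10(ca$v10, cb$v10)) / m +
              (s01(ca$v01, ca$v01) + s01(cb$v01, cb$v01) -
                 2 * s01(ca$v01, cb$v01)) / n
  var_diff <- max(var_diff, 0)
  d <- ca$auc - cb$auc
  if (var_diff == 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, var_diff = var_diff,
                 z = z, p = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong paired test: AUC %.4f vs %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

oof_variant <- function(oof, variant) {
  sub <- oof[oof$variant == variant, , drop = FALSE]
  if (!nrow(sub))
    morfse_error(paste0("unknown variant '", variant, "' in OOF table"),
                 "morfse_input_error")
  sub[order(sub$image_id), , drop = FALSE]
}

#' Overall cancer-vs-rest AUC of one model variant
#'
#' @param oof An `oof_table` from [run_repeated_cv()].
#' @param variant `"morfse"`, `"nognet"` or `"conventional"`.
#' @param level Confidence level.
#' @return An `auc_result`.
#' @export
overall_auc <- function(oof, variant, level = 0.95) {
  sub <- oof_variant(oof, variant)
  binary_auc(sub$p_cancer, sub$true_label == "cancer", level)
}

#' Per-finding cancer-vs-benign AUC
#'
#' Restricts to patches whose finding tags contain `finding` (a patch
#' tagged with both findings appears in both subsets): positives are
#' cancer, negatives benign.  Normal patches carry no finding tag and are
#' excluded unless `include_normals = TRUE` adds them to the negatives.
#'
#' @inheritParams overall_auc
#' @param finding `"calcification"` or `"mass"`.
#' @param include_normals Logical (default `FALSE`).
#' @return An `auc_result`.
#' @export
per_finding_auc <- function(oof, variant, finding, include_normals = FALSE,
                            level = 0.95) {
  finding <- match.arg(finding, c("calcification", "mass"))
  sub <- oof_variant(oof, variant)
  has <- vapply(strsplit(sub$finding_tags, ";", fixed = TRUE),
                function(t) finding %in% t, TRUE)
  keep <- has | (include_normals & sub$true_label == "normal")
  sub <- sub[keep, , drop = FALSE]
  binary_auc(sub$p_cancer, sub$true_label == "cancer", level)
}

#' Paired DeLong test between two variants of an OOF table
#'
#' @inheritParams overall_auc
#' @param variant_a,variant_b Variant names to compare.
#' @return A `delong_result`.
#' @export
delong_compare <- function(oof, variant_a, variant_b) {
  a <- oof_variant(oof, variant_a)
  b <- oof_variant(oof, variant_b)
  if (!identical(a$image_id, b$image_id))
    morfse_error("variants cover different patch sets", "morfse_pairing_error")
  delong_paired_test(a$p_cancer, b$p_cancer, a$true_label == "cancer")
}
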