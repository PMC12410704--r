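#' Full metrics report for an out-of-fold table
#'
#' Overall cancer-vs-rest AUC with 95% CI per variant, the pairwise DeLong
#' comparison table, per-finding AUCs, and the gate's finding-classification
#' accuracy when supplied.
#'
#' @param oof An `oof_table` from [run_repeated_cv()].
#' @param gate_accuracy Optional scalar recorded alongside the AUCs.
#' @param path Optional JSON output path.
#' @return A list (invisibly written to `path` when given).
#' @export
metrics_report <- function(oof, gate_accuracy = NULL, path = NULL) {
  variants <- unique(oof$variant)
  overall <- lapply(variants, function(v) {
    r <- overall_auc(oof, v)
    list(auc = r$auc, ci95 = r$ci95, variance = r$variance,
         n_pos = r$n_pos, n_neg = r$n_neg)
  })
  names(overall) <- variants
  per_finding <- list()
  for (f in c("calcification", "mass")) {
    per_finding[[f]] <- lapply(variants, function(v) {
      r <- tryCatch(per_finding_auc(oof, v, f), morfse_error = function(e) NULL)
      if (is.null(r)) NULL else list(auc = r$auc, ci95 = r$ci95)
    })
    names(per_finding[[f]]) <- variants
  }
  pairs <- utils::combn(variants, 2, simplify = FALSE)
  delong <- lapply(pairs, function(pr) {
    d <- delong_compare(oof, pr[1], pr[2])
    list(variant_a = pr[1], variant_b = pr[2], auc_a = d$auc_a,
         auc_b = d$auc_b, z = d$z, p = d$p)
  })
  rep <- list(overall_auc = overall, per_finding_auc = per_finding,
              delong = delong)
  if (!is.null(gate_accuracy)) rep$gate_accuracy <- gate_accuracy
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  invisible(rep)
}

#' ROC curve points for plotting
#'
#' @param scores Numeric scores.
#' @param labels Logical truth (`TRUE` = positive).
#' @param path Optional CSV output path.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, path = NULL) {
  labels <- as_binary_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  m <- sum(labels); n <- sum(!labels)
  pts <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores[!labels] >= t) / n, 0),
    tpr = vapply(thr, function(t) sum(scores[labels] >= t) / m, 0))
  if (!is.null(path))
    utils::write.csv(pts, path, row.names = FALSE, fileEncoding = "UTF-8")
  pts
}

#' Gate accuracy on finding labels
#'
#' Fraction of lesion patches whose arg-max gate output matches their
#' finding tag; patches tagged with both findings count as correct for
#' either.
#'
#' @param fit A fitted [morfse()] model.
#' @param records Lesion patches to score.
#' @return Scalar accuracy.
#' @export
gate_accuracy <- function(fit, records) {
  lesion <- Filter(function(r) length(r$finding_tags) > 0, records)
  if (!length(lesion))
    morfse_error("no lesion patches to score", "morfse_input_error")
  w <- predict(fit, lesion, variant = "gate")
  pred <- colnames(w)[max.col(w, ties.method = "first")]
  mean(mapply(function(p, r) p %in% r$finding_tags, pred, lesion))
}
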