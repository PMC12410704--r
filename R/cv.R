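#' Repeated stratified group k-fold out-of-fold evaluation
#'
#' One fixed patient-grouped, class-stratified fold partition is drawn from
#' the master seed.  For each repetition `r` and each fold `k`, the gate,
#' both experts and the conventional baseline are trained on the other
#' `K - 1` folds only (seeds derived from `(master_seed, r, k)`), and every
#' patch of fold `k` is scored by all three model variants (the equal-weight
#' ensemble reuses the repetition's experts).  Per-patch predictions are
#' averaged over repetitions.
#'
#' @param records List of [patch_record()] objects.
#' @param cfg A [train_config()] (`cfg$folds` = K, `cfg$repetitions` = R).
#' @return An `oof_table`: a data frame with one row per (patch, variant):
#'   `image_id`, `patient_id`, `variant`, `fold`, `n_rep`, mean `p_cancer`,
#'   `p_benign`, `p_normal`, `true_label`, `finding_tags`.  Attributes:
#'   `per_rep` (per-repetition probability arrays, patch x class x rep, per
#'   variant) for audit, and `provenance` (per repetition/fold, the training
#'   image ids of each network role) for leakage audits.
#' @export
run_repeated_cv <- function(records, cfg = train_config(fast_mode = TRUE)) {
  stopifnot(inherits(cfg, "train_config"))
  K <- cfg$folds
  R <- cfg$repetitions
  n <- length(records)
  assignment <- make_folds(records, K, seed = derive_seed(cfg$master_seed, 1L))
  fold_of <- record_folds(records, assignment)
  ids <- vapply(records, `[[`, "", "image_id")
  variants <- c("morfse", "nognet", "conventional")
  per_rep <- lapply(variants, function(v)
    array(NA_real_, c(n, 3L, R),
          dimnames = list(ids, c("cancer", "benign", "normal"), NULL)))
  names(per_rep) <- variants
  per_rep$gate <- array(NA_real_, c(n, 2L, R),
                        dimnames = list(ids, c("calcification", "mass"), NULL))
  provenance <- list()

  for (r in seq_len(R)) {
    for (k in 0:(K - 1L)) {
      train_idx <- which(fold_of != k)
      test_idx <- which(fold_of == k)
      train_recs <- records[train_idx]
      fit <- morfse(train_recs, cfg,
                    seed = derive_seed(cfg$master_seed, 1000L, r, k),
                    include_conventional = TRUE)
      provenance[[sprintf("r%d_k%d", r, k)]] <- list(
        repetition = r, fold = k,
        train_ids = ids[train_idx], test_ids = ids[test_idx])
      test_recs <- records[test_idx]
      for (v in variants)
        per_rep[[v]][test_idx, , r] <- predict(fit, test_recs, variant = v)
      per_rep$gate[test_idx, , r] <- predict(fit, test_recs, variant = "gate")
    }
  }

  rows <- do.call(rbind, lapply(variants, function(v) {
    mean_p <- apply(per_rep[[v]], c(1, 2), mean)
    data.frame(
      image_id = ids,
      patient_id = vapply(records, `[[`, "", "patient_id"),
      variant = v,
      fold = fold_of,
      n_rep = R,
      p_cancer = mean_p[, "cancer"],
      p_benign = mean_p[, "benign"],
      p_normal = mean_p[, "normal"],
      true_label = vapply(records, `[[`, "", "diagnostic_label"),
      finding_tags = vapply(records, function(x)
        paste(x$finding_tags, collapse = ";"), ""),
      stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(rows, per_rep = per_rep, provenance = provenance,
            fold_assignment = assignment,
            class = c("oof_table", class(rows)))
}

#' Out-of-fold gate accuracy on finding labels
#'
#' Arg-max of the mean out-of-fold gate output against the finding tags of
#' lesion patches (both-finding patches count as correct for either tag).
#' Requires the `per_rep` audit attribute, i.e. an in-memory table from
#' [run_repeated_cv()].
#'
#' @param oof An `oof_table` carrying its `per_rep` attribute.
#' @return Scalar accuracy in `[0, 1]`.
#' @export
oof_gate_accuracy <- function(oof) {
  pr <- attr(oof, "per_rep")
  if (is.null(pr$gate))
    morfse_error("OOF table lacks per-repetition gate predictions",
                 "morfse_input_error")
  w <- apply(pr$gate, c(1, 2), mean)
  sub <- oof[oof$variant == "morfse", , drop = FALSE]
  tags <- lapply(strsplit(sub$finding_tags[match(rownames(w), sub$image_id)],
                          ";", fixed = TRUE), function(t) t[nzchar(t)])
  lesion <- lengths(tags) > 0
  pred <- colnames(w)[max.col(w, ties.method = "first")]
  mean(mapply(function(p, t) p %in% t, pred[lesion], tags[lesion]))
}

#' Persist / reload an out-of-fold prediction table
#'
#' CSV dialect: UTF-8, comma-separated, header row.  The audit attributes
#' (`per_rep`, `provenance`) are not persisted; the CSV holds the
#' integrated means.
#'
#' @param oof An `oof_table` (or compatible data frame).
#' @param path CSV path.
#' @return `write_oof_csv` returns `path` invisibly; `read_oof_csv` the
#'   data frame.
#' @export
write_oof_csv <- function(oof, path) {
  utils::write.csv(as.data.frame(oof), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_oof_csv
#' @export
read_oof_csv <- function(path) {
  oof <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "variant", "fold", "p_cancer", "p_benign", "p_normal",
            "true_label", "finding_tags")
  missing_cols <- setdiff(need, names(oof))
  if (length(missing_cols))
    morfse_error(paste0("OOF table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 "morfse_schema_error")
  oof$finding_tags[is.na(oof$finding_tags)] <- ""
  structure(oof, class = c("oof_table", class(oof)))
}
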