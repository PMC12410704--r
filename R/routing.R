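#' Route training patches to a network role
#'
#' Implements the study's training-data routing rules:
#' \describe{
#'   \item{gnet}{lesion patches only (nonempty finding tags), labeled by
#'     finding; a patch tagged with both findings contributes one training
#'     instance per tag.}
#'   \item{cexp}{calcification patches plus all normals, labeled by
#'     diagnostic class.}
#'   \item{mexp}{mass patches plus all normals, labeled by diagnostic
#'     class.}
#'   \item{conventional}{every patch, labeled by diagnostic class.}
#' }
#'
#' @param records List of [patch_record()] objects with normalized tags.
#' @param role One of `"gnet"`, `"cexp"`, `"mexp"`, `"conventional"`.
#' @return A list with `records` (the routed instances) and `targets` (a
#'   factor: finding labels for the gate, diagnostic labels otherwise).
#' @export
route_training_records <- function(records,
                                   role = c("gnet", "cexp", "mexp", "conventional")) {
  role <- match.arg(role)
  labs <- vapply(records, `[[`, "", "diagnostic_label")
  tags <- lapply(records, `[[`, "finding_tags")
  out_records <- list()
  out_targets <- character()
  if (role == "gnet") {
    for (i in seq_along(records)) {
      for (tg in tags[[i]]) {       # one instance per tag
        out_records[[length(out_records) + 1L]] <- records[[i]]
        out_targets <- c(out_targets, tg)
      }
    }
    lev <- c("calcification", "mass")
  } else {
    keep <- switch(role,
      cexp = vapply(tags, function(t) "calcification" %in% t, TRUE) | labs == "normal",
      mexp = vapply(tags, function(t) "mass" %in% t, TRUE) | labs == "normal",
      conventional = rep(TRUE, length(records)))
    out_records <- records[keep]
    out_targets <- labs[keep]
    lev <- c("cancer", "benign", "normal")
  }
  if (!length(out_records))
    morfse_error(paste0("routing rule for role '", role,
                        "' produced an empty training subset"),
                 "morfse_config_error")
  list(records = out_records,
       targets = factor(out_targets, levels = lev), role = role)
}

#' Patient-grouped stratified fold assignment
#'
#' Assigns every patient to one of `K` folds: patients (not patches) are the
#' split unit, so patches of one patient never span folds, and the
#' assignment is stratified by diagnostic class (per stratum, fold sizes in
#' patients differ by at most one).  Deterministic given `seed`.
#'
#' @param records List of [patch_record()] objects.
#' @param K Number of folds.
#' @param seed Integer seed.
#' @return A `fold_assignment`: named integer vector mapping `patient_id`
#'   to a fold index in `0..K-1`.
#' @export
make_folds <- function(records, K = 5, seed = 1) {
  stopifnot(K >= 2)
  pat <- vapply(records, `[[`, "", "patient_id")
  lab <- vapply(records, `[[`, "", "diagnostic_label")
  tab <- unique(data.frame(patient_id = pat, label = lab,
                           stringsAsFactors = FALSE))
  if (anyDuplicated(tab$patient_id))
    morfse_error("a patient spans multiple diagnostic classes",
                 "morfse_stratification_error")
  fold_map <- stats::setNames(rep(NA_integer_, nrow(tab)), tab$patient_id)
  with_seed(seed, {
    for (lv in unique(tab$label)) {
      ids <- tab$patient_id[tab$label == lv]
      if (length(ids) < K)
        morfse_error(sprintf(
          "stratum '%s' has %d patient(s), fewer than K = %d folds",
          lv, length(ids), K), "morfse_stratification_error")
      ids <- sample(ids)
      folds <- (seq_along(ids) - 1L) %% K
      fold_map[ids] <- folds
    }
  })
  structure(fold_map, class = "fold_assignment", K = as.integer(K))
}

# Fold index (0-based) of each record under an assignment.
record_folds <- function(records, assignment) {
  pat <- vapply(records, `[[`, "", "patient_id")
  unknown <- setdiff(pat, names(assignment))
  if (length(unknown))
    morfse_error(paste0("patients without fold assignment: ",
                        paste(utils::head(unknown, 3), collapse = ", ")),
                 "morfse_stratification_error")
  unname(assignment[pat])
}
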