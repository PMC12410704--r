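#' Construct a patch record
#'
#' The atomic unit of training and evaluation: one square grayscale patch in
#' `[0, 1]` with its diagnostic label, radiological finding tags and
#' provenance identifiers.
#'
#' @param pixels Numeric matrix with values in `[0, 1]`; must be square.
#' @param diagnostic_label One of `"cancer"`, `"benign"`, `"normal"`.
#' @param finding_tags Character vector, subset of
#'   `c("calcification", "mass")`.  Must be empty exactly when
#'   `diagnostic_label == "normal"`.
#' @param patient_id,image_id Opaque identifier strings.
#' @param lesion_id Opaque identifier string, or `NA` for normal patches.
#' @return An object of class `patch_record`.
#' @export
patch_record <- function(pixels, diagnostic_label, finding_tags = character(),
                         patient_id, image_id, lesion_id = NA_character_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) != ncol(pixels))
    stop("patch pixels must be square, got ", nrow(pixels), "x", ncol(pixels))
  if (anyNA(pixels) || min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("patch intensities must lie in [0, 1]")
  diagnostic_label <- match.arg(diagnostic_label, c("cancer", "benign", "normal"))
  finding_tags <- as.character(finding_tags)
  bad <- setdiff(finding_tags, c("calcification", "mass"))
  if (length(bad)) stop("unknown finding tag(s): ", paste(bad, collapse = ", "))
  if (diagnostic_label == "normal" && length(finding_tags))
    stop("normal patches must carry no finding tags")
  if (diagnostic_label != "normal" && !length(finding_tags))
    stop("lesion patches must carry at least one finding tag")
  structure(
    list(pixels = pixels, diagnostic_label = diagnostic_label,
         finding_tags = finding_tags, patient_id = as.character(patient_id),
         image_id = as.character(image_id), lesion_id = as.character(lesion_id)),
    class = "patch_record")
}

#' @export
print.patch_record <- function(x, ...) {
  cat(sprintf("<patch_record %s: %dx%d, %s, tags={%s}, patient %s>\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), x$diagnostic_label,
              paste(x$finding_tags, collapse = ";"), x$patient_id))
  invisible(x)
}

#' Summarise a list of patch records as a manifest data frame
#'
#' @param records List of [patch_record()] objects.
#' @return A data frame with one row per record: `image_id`, `patient_id`,
#'   `lesion_id`, `diagnostic_label`, `finding_tags` (semicolon-joined).
#' @export
patch_manifest <- function(records) {
  stopifnot(is.list(records))
  data.frame(
    image_id = vapply(records, `[[`, "", "image_id"),
    patient_id = vapply(records, `[[`, "", "patient_id"),
    lesion_id = vapply(records, `[[`, "", "lesion_id"),
    diagnostic_label = vapply(records, `[[`, "", "diagnostic_label"),
    finding_tags = vapply(records, function(r) paste(r$finding_tags, collapse = ";"), ""),
    stringsAsFactors = FALSE)
}
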