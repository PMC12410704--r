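# On-disk patch dataset dialect: one 16-bit grayscale TIFF per patch plus a
# CSV manifest (UTF-8, comma separated, header row, RFC 4180 quoting) with
# columns image_id, patient_id, lesion_id, diagnostic_label, finding_tags
# (semicolon-joined) and file.  Both the synthetic generator and the source
# -data extractor write this dialect, so one training path reads both.

#' Write a patch dataset to a directory
#'
#' @param records List of [patch_record()] objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame (with a `file` column of paths
#'   relative to `dir`).
#' @export
write_patch_dataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- patch_manifest(records)
  man$file <- paste0(man$image_id, ".tiff")
  for (i in seq_along(records)) {
    # quantize to the 16-bit grid; lossless thereafter
    q <- round(records[[i]]$pixels * 65535) / 65535
    tiff::writeTIFF(q, file.path(dir, man$file[i]), bits.per.sample = 16,
                    compression = "none")
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(man)
}

#' Read a patch dataset written by [write_patch_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return A list of [patch_record()] objects in manifest order.
#' @export
read_patch_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv under ", dir)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("image_id", "patient_id", "lesion_id", "diagnostic_label",
            "finding_tags", "file")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols))
    stop("manifest.csv lacks column(s): ", paste(missing_cols, collapse = ", "))
  lapply(seq_len(nrow(man)), function(i) {
    pix <- tiff::readTIFF(file.path(dir, man$file[i]))
    if (length(dim(pix)) == 3) pix <- pix[, , 1]
    tags <- strsplit(man$finding_tags[i], ";", fixed = TRUE)[[1]]
    patch_record(pix, man$diagnostic_label[i], tags[nzchar(tags)],
                 man$patient_id[i], man$image_id[i],
                 if (is.na(man$lesion_id[i]) || man$lesion_id[i] %in% c("", "NA"))
                   NA_character_ else man$lesion_id[i])
  })
}
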