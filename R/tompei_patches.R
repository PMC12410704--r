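# Patch-construction rules for mammography-style source data: per-lesion
# 512x512 crops centered on the segmentation mask, distortion exclusion,
# FAD -> mass relabeling, and binarization-based sampling of normal patches.

#' Construct a lesion annotation
#'
#' @param mask Binary matrix (nonzero = lesion) congruent with its source
#'   image.
#' @param malignancy `"cancer"` or `"benign"`.
#' @param raw_tags Nonempty subset of
#'   `c("calcification", "mass", "FAD", "distortion")`.
#' @param lesion_id Identifier string.
#' @return An object of class `lesion_annotation`.
#' @export
lesion_annotation <- function(mask, malignancy, raw_tags, lesion_id) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  if (!any(mask)) morfse_error("empty lesion mask", "morfse_annotation_error")
  malignancy <- match.arg(malignancy, c("cancer", "benign"))
  if (!length(raw_tags))
    morfse_error("lesion must carry at least one raw tag", "morfse_annotation_error")
  structure(list(mask = mask, malignancy = malignancy,
                 raw_tags = as.character(raw_tags),
                 lesion_id = as.character(lesion_id)),
            class = "lesion_annotation")
}

#' Normalize raw radiological finding tags
#'
#' Applies the study's relabeling rules: focal asymmetric density (FAD) is
#' classified as mass; distortion is dropped (a lesion annotated with
#' distortion only is excluded outright).
#'
#' @param raw_tags Nonempty character vector over
#'   `c("calcification", "mass", "FAD", "distortion")`.
#' @return The normalized tag set (subset of `calcification`, `mass`), or
#'   `NULL` when the lesion is excluded.
#' @export
normalize_finding_tags <- function(raw_tags) {
  if (!length(raw_tags))
    morfse_error("raw tag set must be nonempty", "morfse_annotation_error")
  known <- c("calcification", "mass", "FAD", "distortion")
  bad <- setdiff(raw_tags, known)
  if (length(bad))
    morfse_error(paste0("unknown finding tag(s): ", paste(bad, collapse = ", ")),
                 "morfse_annotation_error")
  tags <- unique(ifelse(raw_tags == "FAD", "mass", raw_tags))
  tags <- setdiff(tags, "distortion")
  if (!length(tags)) return(NULL)
  # stable order: calcification before mass
  intersect(c("calcification", "mass"), tags)
}

# Mask centroid in 0-based pixel coordinates, rounded half-up.
mask_centroid <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  floor(colMeans(w) - 1 + 0.5)       # (row, col), 0-based
}

#' Extract a lesion-centered patch
#'
#' Crops a `crop x crop` window centered on the mask centroid (unweighted
#' mean of mask pixel coordinates, rounded half-up).  Window coordinates are
#' 0-based half-open; a window that would cross an image edge is shifted
#' inward to lie fully inside the image (no padding).  Lesions whose
#' normalized tag set is empty (distortion-only) yield `NULL`.
#'
#' @param image A [source_image()].
#' @param ann A [lesion_annotation()].
#' @param crop Window side in pixels (default 512).
#' @return A [patch_record()] with a `window` attribute `c(r0, c0)` (0-based
#'   top-left corner), or `NULL` if the lesion is excluded.
#' @export
extract_lesion_patch <- function(image, ann, crop = 512) {
  stopifnot(inherits(image, "source_image"), inherits(ann, "lesion_annotation"))
  dims <- dim(image$pixels)
  if (!all(dim(ann$mask) == dims))
    morfse_error("mask is not congruent with its source image",
                 "morfse_annotation_error")
  if (crop > dims[1] || crop > dims[2])
    morfse_error(sprintf("crop %d exceeds image dimensions %dx%d",
                         crop, dims[1], dims[2]), "morfse_dimension_error")
  tags <- normalize_finding_tags(ann$raw_tags)
  if (is.null(tags)) return(NULL)
  ctr <- mask_centroid(ann$mask)
  r0 <- as.integer(min(max(ctr[1] - crop %/% 2, 0), dims[1] - crop))
  c0 <- as.integer(min(max(ctr[2] - crop %/% 2, 0), dims[2] - crop))
  pix <- image$pixels[(r0 + 1):(r0 + crop), (c0 + 1):(c0 + crop)]
  rec <- patch_record(pix, ann$malignancy, tags,
                      patient_id = image$patient_id,
                      image_id = paste0(image$image_id, "_", ann$lesion_id),
                      lesion_id = ann$lesion_id)
  attr(rec, "window") <- c(r0 = unname(r0), c0 = unname(c0))
  rec
}

#' Split a multi-component mask into per-lesion annotations
#'
#' Each connected component of the mask becomes its own annotation (lesions
#' are individually extracted), with `_c<k>` appended to the lesion id.
#'
#' @param ann A [lesion_annotation()].
#' @return List of [lesion_annotation()] objects, one per component.
#' @export
split_mask_components <- function(ann) {
  stopifnot(inherits(ann, "lesion_annotation"))
  lab <- EBImage::bwlabel(ann$mask)
  ks <- seq_len(max(lab))
  if (length(ks) == 1) return(list(ann))
  lapply(ks, function(k)
    lesion_annotation(lab == k, ann$malignancy, ann$raw_tags,
                      paste0(ann$lesion_id, "_c", k)))
}

#' Sample a normal-tissue patch from within the breast area
#'
#' The image is binarized with Otsu's threshold to separate the breast from
#' the dark background; candidate `crop x crop` windows are drawn uniformly
#' and accepted when at least `min_foreground` of their pixels are breast
#' tissue (rejection sampling, capped at `max_draws`).
#'
#' @param image A [source_image()].
#' @param crop Window side in pixels.
#' @param seed Integer seed for the rejection-sampling stream.
#' @param min_foreground Minimum foreground fraction of an accepted window
#'   (default 0.9).
#' @param max_draws Rejection-sampling cap (default 1000).
#' @return A [patch_record()] with `diagnostic_label = "normal"`, empty
#'   finding tags and a `window` attribute.
#' @export
sample_normal_patch <- function(image, crop = 512, seed = 1,
                                min_foreground = 0.9, max_draws = 1000) {
  stopifnot(inherits(image, "source_image"))
  dims <- dim(image$pixels)
  if (crop > dims[1] || crop > dims[2])
    morfse_error(sprintf("crop %d exceeds image dimensions %dx%d",
                         crop, dims[1], dims[2]), "morfse_dimension_error")
  thr <- EBImage::otsu(image$pixels, range = c(0, 1))
  fore <- image$pixels > thr
  # Otsu always splits; when the two classes are not meaningfully darker /
  # brighter than each other (< 0.2 apart) the frame is a single tissue
  # class, so fall back to a fixed dark floor.
  weak <- !any(fore) ||
    (any(!fore) && mean(image$pixels[fore]) - mean(image$pixels[!fore]) < 0.2)
  if (weak) fore <- image$pixels > 0.1
  if (!any(fore))
    morfse_error("no breast foreground after binarization",
                 "morfse_sampling_error")
  rec <- NULL
  with_seed(seed, {
    for (i in seq_len(max_draws)) {
      r0 <- sample.int(dims[1] - crop + 1L, 1L) - 1L
      c0 <- sample.int(dims[2] - crop + 1L, 1L) - 1L
      win <- fore[(r0 + 1):(r0 + crop), (c0 + 1):(c0 + crop)]
      if (mean(win) >= min_foreground) {
        rec <- patch_record(image$pixels[(r0 + 1):(r0 + crop),
                                         (c0 + 1):(c0 + crop)],
                            "normal", character(),
                            patient_id = image$patient_id,
                            image_id = paste0(image$image_id, "_n", i))
        attr(rec, "window") <- c(r0 = r0, c0 = c0)
        break
      }
    }
  })
  if (is.null(rec))
    morfse_error(sprintf("no window with foreground fraction >= %.2f in %d draws",
                         min_foreground, max_draws), "morfse_sampling_error")
  rec
}

#' Build a patch dataset from an annotation table
#'
#' Applies the full patch-construction procedure to a source-data directory:
#' lesion rows are read, split into connected components, tag-normalized
#' (dropping distortion-only lesions) and cropped per lesion; normal rows
#' contribute `normals_per_image` sampled normal patches each.
#'
#' @param annotation_csv CSV with columns `image_path`, `mask_path`,
#'   `malignancy` (`cancer`, `benign` or `normal`), `tags`
#'   (semicolon-joined raw tags; empty for normal rows), `patient_id`.
#'   Paths are resolved relative to the CSV's directory.
#' @param crop Patch side in pixels.
#' @param normals_per_image Normal patches sampled per normal image
#'   (default 1).
#' @param seed Master seed for normal-patch sampling.
#' @param min_foreground Passed to [sample_normal_patch()].
#' @return List of [patch_record()] objects.
#' @export
build_patch_dataset <- function(annotation_csv, crop = 512,
                                normals_per_image = 1, seed = 1,
                                min_foreground = 0.9) {
  ann <- utils::read.csv(annotation_csv, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("image_path", "mask_path", "malignancy", "tags", "patient_id")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols))
    morfse_error(paste0("annotation table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 "morfse_annotation_error")
  base <- dirname(normalizePath(annotation_csv))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  records <- list()
  for (i in seq_len(nrow(ann))) {
    img <- read_source_image(resolve(ann$image_path[i]),
                             patient_id = ann$patient_id[i])
    if (ann$malignancy[i] == "normal") {
      for (j in seq_len(normals_per_image)) {
        records[[length(records) + 1L]] <-
          sample_normal_patch(img, crop, seed = derive_seed(seed, i, j),
                              min_foreground = min_foreground)
      }
      next
    }
    tags <- strsplit(ann$tags[i], ";", fixed = TRUE)[[1]]
    mask <- png::readPNG(resolve(ann$mask_path[i]))
    if (length(dim(mask)) == 3) mask <- mask[, , 1]
    lesion <- lesion_annotation(mask != 0, ann$malignancy[i], tags[nzchar(tags)],
                                lesion_id = sprintf("row%d", i))
    for (comp in split_mask_components(lesion)) {
      rec <- extract_lesion_patch(img, comp, crop)
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
    }
  }
  records
}
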