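test_that("PNG sources are rescaled to [0, 1] and reject color images", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "img.png")
  m <- matrix(seq(0, 255, length.out = 64) / 255, 8, 8)
  png::writePNG(m, f)
  img <- read_source_image(f, patient_id = "P1")
  expect_s3_class(img, "source_image")
  expect_equal(max(img$pixels), 1, tolerance = 1e-6)
  expect_equal(min(img$pixels), 0)
  expect_identical(img$patient_id, "P1")
  expect_identical(img$image_id, "img")

  fc <- file.path(dir, "color.png")
  png::writePNG(array(runif(8 * 8 * 3), c(8, 8, 3)), fc)
  expect_error(read_source_image(fc), class = "morfse_unsupported_modality")
  expect_error(read_source_image(file.path(dir, "missing.png")),
               class = "morfse_format_error")
})

test_that("monochrome DICOM reads back pixel-exactly in both VR dialects", {
  dir <- withr::local_tempdir()
  vals <- matrix(sample.int(65536, 12 * 10, replace = TRUE) - 1L, 12, 10)
  for (explicit in c(TRUE, FALSE)) {
    f <- file.path(dir, sprintf("t_%d.dcm", explicit))
    write_fixture_dicom(f, vals, patient = "PX", sop = "9.8.7",
                        explicit = explicit)
    img <- read_source_image(f)
    expect_identical(dim(img$pixels), c(12L, 10L))
    expect_equal(img$pixels, vals / 65535, tolerance = 1e-12)
    expect_identical(img$patient_id, "PX")
    expect_identical(img$image_id, "9.8.7")
    expect_identical(img$bit_depth, 16L)
  }

  # constant image, no exception
  f2 <- file.path(dir, "const.dcm")
  write_fixture_dicom(f2, matrix(1234L, 6, 6))
  expect_equal(diff(range(read_source_image(f2)$pixels)), 0)

  # MONOCHROME1 is inverted on load
  f3 <- file.path(dir, "mono1.dcm")
  write_fixture_dicom(f3, matrix(0L, 4, 4), photometric = "MONOCHROME1")
  expect_equal(unique(as.vector(read_source_image(f3)$pixels)), 1)
})

test_that("unsupported or truncated DICOM raises the right condition", {
  dir <- withr::local_tempdir()
  vals <- matrix(7L, 8, 8)
  f <- file.path(dir, "trunc.dcm")
  write_fixture_dicom(f, vals, truncate_at = 180L)
  expect_error(read_source_image(f), class = "morfse_format_error")

  f2 <- file.path(dir, "multi.dcm")
  write_fixture_dicom(f2, vals, frames = 3L)
  expect_error(read_source_image(f2), class = "morfse_unsupported_modality")

  f3 <- file.path(dir, "color.dcm")
  write_fixture_dicom(f3, vals, samples = 3L)
  expect_error(read_source_image(f3), class = "morfse_unsupported_modality")

  f4 <- file.path(dir, "notdicom.dcm")
  writeBin(as.raw(1:64), f4)
  expect_error(read_source_image(f4), class = "morfse_format_error")
})

test_that("finding tags normalize per the relabeling and exclusion rules", {
  expect_identical(normalize_finding_tags("FAD"), "mass")
  expect_null(normalize_finding_tags("distortion"))
  expect_identical(normalize_finding_tags(c("calcification", "mass")),
                   c("calcification", "mass"))
  expect_identical(normalize_finding_tags(c("mass", "distortion")), "mass")
  expect_identical(normalize_finding_tags(c("FAD", "mass")), "mass")
  expect_identical(normalize_finding_tags(c("distortion", "FAD")), "mass")
  expect_error(normalize_finding_tags("speculation"),
               class = "morfse_annotation_error")
  expect_error(normalize_finding_tags(character()),
               class = "morfse_annotation_error")
})

test_that("lesion windows are centered, clamped at edges, and labeled", {
  big <- source_image(matrix(runif(2294 * 1914), 2294, 1914), "P1", "I1")
  mask <- matrix(FALSE, 2294, 1914)
  mask[1001, 801] <- TRUE                    # centroid (1000, 800) 0-based
  ann <- lesion_annotation(mask, "cancer", "calcification", "L1")
  rec <- extract_lesion_patch(big, ann, crop = 512)
  expect_identical(unname(attr(rec, "window")), c(744L, 544L))
  expect_identical(dim(rec$pixels), c(512L, 512L))
  expect_identical(rec$pixels, big$pixels[745:1256, 545:1056])
  expect_identical(rec$diagnostic_label, "cancer")

  # centroid near the origin: window shifted inward, no padding
  mask2 <- matrix(FALSE, 2294, 1914)
  mask2[11, 11] <- TRUE
  rec2 <- extract_lesion_patch(big, lesion_annotation(mask2, "benign", "mass", "L2"),
                               crop = 512)
  expect_identical(unname(attr(rec2, "window")), c(0L, 0L))

  # distortion-only lesions are skipped
  expect_null(extract_lesion_patch(big,
    lesion_annotation(mask, "cancer", "distortion", "L3"), crop = 512))

  small <- source_image(matrix(0.5, 100, 100), "P2", "I2")
  expect_error(extract_lesion_patch(small,
    lesion_annotation(matrix(TRUE, 100, 100), "cancer", "mass", "L4"),
    crop = 512), class = "morfse_dimension_error")
})

test_that("multi-component masks are split into individually cropped lesions", {
  img <- source_image(matrix(runif(600 * 600), 600, 600), "P1", "I1")
  mask <- matrix(FALSE, 600, 600)
  mask[100:110, 100:110] <- TRUE
  mask[400:420, 450:470] <- TRUE
  ann <- lesion_annotation(mask, "cancer", "calcification", "L")
  parts <- split_mask_components(ann)
  expect_length(parts, 2)
  recs <- lapply(parts, function(a) extract_lesion_patch(img, a, crop = 128))
  ids <- vapply(recs, `[[`, "", "lesion_id")
  expect_length(unique(ids), 2)
  w1 <- attr(recs[[1]], "window")
  w2 <- attr(recs[[2]], "window")
  expect_false(identical(w1, w2))
  expect_identical(unname(w1), c(104L - 64L, 104L - 64L))  # 0-based centroid
})

test_that("normal sampling stays inside the binarized breast area", {
  # all-foreground image: first draw accepted
  allfg <- source_image(matrix(c(0.8, 0.81), 64, 64), "P1", "I1")
  rec <- sample_normal_patch(allfg, crop = 16, seed = 1)
  expect_identical(rec$diagnostic_label, "normal")
  expect_identical(rec$finding_tags, character(0))

  # all-background (constant) image: binarization finds no breast
  dark <- source_image(matrix(0, 64, 64), "P2", "I2")
  expect_error(sample_normal_patch(dark, crop = 16, seed = 1),
               class = "morfse_sampling_error")

  # left half foreground, 100% acceptance: window columns confined to 0..16,
  # i.e. centers in 8..24 (exhaustively valid windows only)
  half <- matrix(0.05, 64, 64)
  half[, 1:32] <- 0.9
  img <- source_image(half, "P3", "I3")
  for (s in 1:25) {
    r <- sample_normal_patch(img, crop = 16, seed = s, min_foreground = 1)
    c0 <- attr(r, "window")[["c0"]]
    expect_gte(c0 + 8, 8)
    expect_lte(c0 + 8, 24)
  }

  # a foreground too small for any window exhausts the draw cap
  tiny <- matrix(0.05, 64, 64)
  tiny[1:4, 1:4] <- 0.9
  expect_error(sample_normal_patch(source_image(tiny, "P4", "I4"),
                                   crop = 16, seed = 1, min_foreground = 1),
               class = "morfse_sampling_error")
})

test_that("the annotation-table pipeline reproduces predicted record counts", {
  dir <- withr::local_tempdir()
  # two lesion images, one with two components, one distortion-only row,
  # one FAD row, two normal images
  mk_img <- function(name, fg = TRUE) {
    m <- matrix(if (fg) 0.7 else 0.7, 96, 96) + matrix(runif(96 * 96, 0, 0.1), 96)
    f <- file.path(dir, name)
    png::writePNG(pmin(m, 1), f)
    f
  }
  mk_mask <- function(name, boxes) {
    m <- matrix(0, 96, 96)
    for (b in boxes) m[b[1]:b[2], b[3]:b[4]] <- 1
    f <- file.path(dir, name)
    png::writePNG(m, f)
    f
  }
  mk_img("i1.png"); mk_mask("m1.png", list(c(10, 20, 10, 20), c(60, 80, 60, 80)))
  mk_img("i2.png"); mk_mask("m2.png", list(c(30, 40, 30, 40)))
  mk_img("i3.png"); mk_mask("m3.png", list(c(50, 60, 50, 60)))
  mk_img("i4.png"); mk_img("i5.png")
  ann <- data.frame(
    image_path = c("i1.png", "i2.png", "i3.png", "i4.png", "i5.png"),
    mask_path = c("m1.png", "m2.png", "m3.png", "", ""),
    malignancy = c("cancer", "benign", "cancer", "normal", "normal"),
    tags = c("calcification", "distortion", "FAD", "", ""),
    patient_id = paste0("P", 1:5))
  csv <- file.path(dir, "annotation.csv")
  write.csv(ann, csv, row.names = FALSE)
  recs <- build_patch_dataset(csv, crop = 32, normals_per_image = 1, seed = 3)
  # i1 expands to 2 lesions, i2 is excluded, i3 relabels FAD -> mass,
  # i4/i5 contribute one normal each: 5 records
  expect_length(recs, 5)
  man <- patch_manifest(recs)
  expect_equal(sum(man$diagnostic_label == "cancer"), 3)
  expect_equal(sum(man$diagnostic_label == "normal"), 2)
  expect_equal(sum(man$finding_tags == "mass"), 1)
  expect_equal(sum(man$finding_tags == "calcification"), 2)
})
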