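test_that("patch generators set labels, tags and provenance correctly", {
  cfg <- synth_config()
  p <- gen_calcification_patch(TRUE, cfg, seed = 1)
  expect_s3_class(p, "patch_record")
  expect_identical(p$diagnostic_label, "cancer")
  expect_identical(p$finding_tags, "calcification")
  expect_identical(dim(p$pixels), c(64L, 64L))
  expect_true(all(p$pixels >= 0 & p$pixels <= 1))

  m <- gen_mass_patch(TRUE, cfg, seed = 7)
  expect_identical(m$diagnostic_label, "cancer")
  expect_identical(m$finding_tags, "mass")

  b <- gen_calcification_patch(FALSE, cfg, seed = 2)
  expect_identical(b$diagnostic_label, "benign")

  nrm <- gen_normal_patch(cfg, seed = 3)
  expect_identical(nrm$diagnostic_label, "normal")
  expect_identical(nrm$finding_tags, character(0))
})

test_that("generation is bit-for-bit deterministic in the config and seed", {
  cfg <- synth_config(seed = 42)
  expect_identical(gen_mass_patch(TRUE, cfg, seed = 9)$pixels,
                   gen_mass_patch(TRUE, cfg, seed = 9)$pixels)
  expect_identical(gen_calcification_patch(FALSE, cfg, seed = 9)$pixels,
                   gen_calcification_patch(FALSE, cfg, seed = 9)$pixels)
  cfg$n_per_cell <- 4
  d1 <- gen_dataset(cfg)
  d2 <- gen_dataset(cfg)
  expect_identical(d1, d2)
  # generator calls must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(gen_dataset(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("degenerate configurations behave as limiting cases", {
  # single benign dot, no noise: exactly one bright connected component
  cfg1 <- synth_config(noise_sd = 0, calc_dot_count_benign = c(1, 0))
  p <- gen_calcification_patch(FALSE, cfg1, seed = 4)
  expect_equal(max(EBImage::bwlabel(p$pixels > 0.5)), 1)

  # infinite-correlation background with no noise: constant image
  cfg2 <- synth_config(noise_sd = 0, background_texture_scale = 1e9)
  n <- gen_normal_patch(cfg2, seed = 5)
  expect_equal(diff(range(n$pixels)), 0)

  # invalid configurations are rejected at construction
  expect_error(synth_config(image_size = 8), "image_size")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(calc_dot_count_benign = c(3, NA)),
               "calc_dot_count_benign")
})

test_that("detected dot counts track the configured count gap", {
  # spread clusters: detection is unconfounded by dot merging, so the
  # detected gap must match the configured gap up to sampling error
  cfg <- synth_config(noise_sd = 0,
                      calc_cluster_radius_benign = 20,
                      calc_cluster_radius_malignant = 20,
                      calc_dot_size_range_malignant = c(1.2, 1.8))
  dm <- vapply(1:200, function(s)
    oracle_count_dots(gen_calcification_patch(TRUE, cfg, seed = s)$pixels), 0)
  db <- vapply(1:200, function(s)
    oracle_count_dots(gen_calcification_patch(FALSE, cfg, seed = s)$pixels), 0)
  configured_gap <- cfg$calc_dot_count_malignant[1] - cfg$calc_dot_count_benign[1]
  expect_lt(abs((mean(dm) - mean(db)) - configured_gap), 1.5)

  # default (tight-cluster) geometry: merging attenuates the count, but the
  # malignant excess must remain strong and directional
  cfg0 <- synth_config(noise_sd = 0)
  dm0 <- vapply(1:200, function(s)
    oracle_count_dots(gen_calcification_patch(TRUE, cfg0, seed = s)$pixels), 0)
  db0 <- vapply(1:200, function(s)
    oracle_count_dots(gen_calcification_patch(FALSE, cfg0, seed = s)$pixels), 0)
  expect_gt(mean(dm0) - mean(db0), configured_gap / 2)
})

test_that("benign masses are smooth and convex; malignant masses rough", {
  cfg <- synth_config(noise_sd = 0)
  rb <- vapply(1:30, function(s)
    oracle_roughness(gen_mass_patch(FALSE, cfg, seed = s)$pixels), 0)
  rm_ <- vapply(1:30, function(s)
    oracle_roughness(gen_mass_patch(TRUE, cfg, seed = s)$pixels), 0)
  expect_lt(max(rb), min(rm_))

  # benign, no spiculation, no noise: a single above-threshold region
  lab <- EBImage::bwlabel(gen_mass_patch(FALSE, cfg, seed = 11)$pixels > 0.5)
  expect_equal(max(lab), 1)
})

test_that("normal patches have less local contrast than any lesion patch", {
  cfg <- synth_config(noise_sd = 0)
  cn <- vapply(1:100, function(s)
    oracle_contrast(gen_normal_patch(cfg, seed = s)$pixels), 0)
  lesion_mins <- c(
    min(vapply(1:100, function(s)
      oracle_contrast(gen_calcification_patch(TRUE, cfg, seed = s)$pixels), 0)),
    min(vapply(1:100, function(s)
      oracle_contrast(gen_calcification_patch(FALSE, cfg, seed = s)$pixels), 0)),
    min(vapply(1:100, function(s)
      oracle_contrast(gen_mass_patch(TRUE, cfg, seed = s)$pixels), 0)),
    min(vapply(1:100, function(s)
      oracle_contrast(gen_mass_patch(FALSE, cfg, seed = s)$pixels), 0)))
  expect_lt(max(cn), min(lesion_mins))
})

test_that("gen_dataset honors per-cell counts, class mix and patient rules", {
  cfg <- synth_config(n_per_cell = 10, seed = 2)
  recs <- gen_dataset(cfg)
  expect_length(recs, 50)
  man <- patch_manifest(recs)
  expect_equal(as.vector(table(man$diagnostic_label)[c("cancer", "benign", "normal")]),
               c(20L, 20L, 10L))

  # accession-proportioned mix by largest remainder
  expect_equal(unname(synth_cell_counts(276)),
               c(73L, 73L, 13L, 12L, 105L))
  counts <- synth_cell_counts(276)
  expect_equal(counts[["cancer_calcification"]] + counts[["cancer_mass"]], 146L)
  expect_equal(counts[["benign_calcification"]] + counts[["benign_mass"]], 25L)
  expect_equal(counts[["normal"]], 105L)

  # no synthetic patient spans diagnostic classes
  agg <- tapply(man$diagnostic_label, man$patient_id,
                function(x) length(unique(x)))
  expect_true(all(agg == 1))
})

test_that("counter-based streams: growing one cell leaves other patches alone", {
  cfg_small <- synth_config(n_per_cell = 3, seed = 8)
  cfg_big <- synth_config(n_per_cell = 6, seed = 8)
  small <- gen_dataset(cfg_small)
  big <- gen_dataset(cfg_big)
  ids <- vapply(small, `[[`, "", "image_id")
  big_ids <- vapply(big, `[[`, "", "image_id")
  for (i in seq_along(small)) {
    j <- match(ids[i], big_ids)
    expect_identical(small[[i]]$pixels, big[[j]]$pixels)
  }
})

test_that("the malignancy effect-size dial moves a reference classifier's AUC", {
  # interpolate malignant calcification parameters from the benign values
  # (gap 0) to the defaults (gap 1); the dot-count statistic's AUC must rise
  # from chance to near-perfect, monotonically
  base <- synth_config(noise_sd = 0)
  dial_cfg <- function(g) {
    synth_config(noise_sd = 0,
      calc_dot_count_malignant = (1 - g) * base$calc_dot_count_benign +
        g * base$calc_dot_count_malignant,
      calc_cluster_radius_malignant = (1 - g) * base$calc_cluster_radius_benign +
        g * base$calc_cluster_radius_malignant,
      calc_dot_size_range_malignant = (1 - g) * base$calc_dot_size_range_benign +
        g * base$calc_dot_size_range_malignant)
  }
  aucs <- vapply(c(0, 0.5, 1), function(g) {
    cfg <- dial_cfg(g)
    sm <- vapply(1:100, function(s)
      oracle_count_dots(gen_calcification_patch(TRUE, cfg, seed = s)$pixels), 0)
    sb <- vapply(1:100, function(s)
      oracle_count_dots(gen_calcification_patch(FALSE, cfg, seed = s)$pixels), 0)
    oracle_auc(c(sm, sb), rep(c(TRUE, FALSE), each = 100))
  }, 0)
  expect_lt(abs(aucs[1] - 0.5), 0.08)
  expect_true(all(diff(aucs) > 0))
  expect_gt(aucs[3], 0.9)
})

test_that("a reference statistic separates calcification from mass patches", {
  cfg <- synth_config(noise_sd = 0)
  blob_area <- function(p) {
    b <- EBImage::bwlabel(p > 0.5)
    if (max(b) == 0) 0 else max(tabulate(b[b > 0]))
  }
  ac <- vapply(1:100, function(s)
    blob_area(gen_calcification_patch(s %% 2 == 0, cfg, seed = s)$pixels), 0)
  am <- vapply(1:100, function(s)
    blob_area(gen_mass_patch(s %% 2 == 0, cfg, seed = s)$pixels), 0)
  auc <- oracle_auc(c(ac, am), rep(c(FALSE, TRUE), each = 100))
  expect_gt(auc, 0.95)
})

test_that("datasets round-trip through the TIFF + CSV dialect", {
  recs <- make_cv_dataset(n_per_cell = 3, seed = 21)
  dir <- withr::local_tempdir()
  write_patch_dataset(recs, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_patch_dataset(dir)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$diagnostic_label, recs[[i]]$diagnostic_label)
    expect_identical(back[[i]]$finding_tags, recs[[i]]$finding_tags)
    expect_identical(back[[i]]$patient_id, recs[[i]]$patient_id)
    # 16-bit quantization on first write; exact thereafter
    expect_lt(max(abs(back[[i]]$pixels - recs[[i]]$pixels)), 1 / 65535)
  }
  dir2 <- withr::local_tempdir()
  write_patch_dataset(back, dir2)
  again <- read_patch_dataset(dir2)
  for (i in seq_along(back))
    expect_identical(again[[i]]$pixels, back[[i]]$pixels)
})
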