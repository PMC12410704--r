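# Independent reference implementations used as oracles.  These stay
# deliberately naive (brute-force pairwise enumeration, EBImage-based image
# measurements) and never share code with the package internals they check.

# AUC as the mean pairwise psi: 1 if pos > neg, 0.5 if tied, 0 otherwise.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(psi)
}

# Structural components and variance by brute-force enumeration.
oracle_delong <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  list(auc = mean(psi), v10 = v10, v01 = v01,
       var = stats::var(v10) / length(pos) + stats::var(v01) / length(neg))
}

# Reference dot counter: connected components of the local-maxima mask on a
# noiseless render (clipping at 1 creates plateaus, hence components).
oracle_count_dots <- function(pixels, threshold = 0.5) {
  d <- EBImage::dilate(pixels, EBImage::makeBrush(3, "box"))
  max(EBImage::bwlabel(pixels == d & pixels > threshold))
}

# Reference boundary-roughness statistic: perimeter^2 / (4 pi area) of the
# largest above-threshold component, via EBImage's contour tracer.
oracle_roughness <- function(pixels, threshold = 0.5) {
  lab <- EBImage::bwlabel(pixels > threshold)
  ft <- EBImage::computeFeatures.shape(lab)
  ft <- ft[which.max(ft[, "s.area"]), , drop = FALSE]
  ft[1, "s.perimeter"]^2 / (4 * pi * ft[1, "s.area"])
}

# Reference local-contrast statistic: max minus median intensity.
oracle_contrast <- function(pixels) max(pixels) - stats::median(pixels)

# Quick flat patch for bookkeeping tests that never look at pixels.
toy_record <- function(label, tags, patient, id, side = 32, fill = 0.5) {
  patch_record(matrix(fill, side, side), label, tags, patient, id,
               lesion_id = if (label == "normal") NA_character_ else
                 paste0(id, "_L1"))
}

# ---- minimal DICOM fixture writer (independent of the package parser) ----

u16le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

dcm_el_explicit <- function(group, elem, vr, value) {
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(u16le(group), u16le(elem), charToRaw(vr), as.raw(c(0, 0)),
      u32le(length(value)), value)
  else
    c(u16le(group), u16le(elem), charToRaw(vr), u16le(length(value)), value)
}

dcm_el_implicit <- function(group, elem, value) {
  c(u16le(group), u16le(elem), u32le(length(value)), value)
}

dcm_str <- function(s) {
  v <- charToRaw(s)
  if (length(v) %% 2 == 1) v <- c(v, charToRaw(" "))
  v
}

# Writes a monochrome 16-bit DICOM file holding `values` (integer matrix,
# row-major on disk) with BitsStored = bits.
write_fixture_dicom <- function(path, values, patient = "PAT1",
                                sop = "1.2.3.4", bits = 16L,
                                explicit = TRUE, photometric = "MONOCHROME2",
                                samples = 1L, frames = NULL,
                                truncate_at = NULL) {
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  meta <- dcm_el_explicit(2L, 16L, "UI", dcm_str(ts))
  el <- if (explicit) {
    function(g, e, vr, v) dcm_el_explicit(g, e, vr, v)
  } else {
    function(g, e, vr, v) dcm_el_implicit(g, e, v)
  }
  pix <- writeBin(as.integer(t(values)), raw(), size = 2L, endian = "little")
  body <- c(
    el(8L, 24L, "UI", dcm_str(sop)),
    el(16L, 32L, "LO", dcm_str(patient)),
    el(40L, 2L, "US", u16le(samples)),
    el(40L, 4L, "CS", dcm_str(photometric)),
    if (!is.null(frames)) el(40L, 8L, "IS", dcm_str(as.character(frames))),
    el(40L, 16L, "US", u16le(nrow(values))),
    el(40L, 17L, "US", u16le(ncol(values))),
    el(40L, 256L, "US", u16le(16L)),
    el(40L, 257L, "US", u16le(bits)),
    el(40L, 259L, "US", u16le(0L)),
    el(32736L, 16L, "OW", pix))
  out <- c(as.raw(rep(0, 128)), charToRaw("DICM"), meta, body)
  if (!is.null(truncate_at)) out <- out[seq_len(truncate_at)]
  writeBin(out, path)
  invisible(path)
}

# Small synthetic dataset shared by training-stage tests: balanced enough
# for K patient strata per class.
make_cv_dataset <- function(n_per_cell = 10, seed = 5, noise_sd = 0.02) {
  cfg <- synth_config(n_per_cell = n_per_cell, seed = seed,
                      noise_sd = noise_sd)
  gen_dataset(cfg)
}

fast_cfg <- function(...) train_config(fast_mode = TRUE, ...)
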