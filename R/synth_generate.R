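# Synthetic mammographic patch phantoms.
#
# Each generator draws from a private RNG stream (a derived seed), renders a
# lesion on a correlated fibroglandular background, adds pixel noise and
# clamps to [0, 1].  Lesions are hyperintense relative to background, as
# calcifications and dense masses appear on mammograms.

# Separable Gaussian blur with replicate boundary.  sd = 0 is the identity.
gaussian_blur <- function(m, sd) {
  if (sd <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sd)))
  k <- exp(-0.5 * ((-r:r) / sd)^2)
  k <- k / sum(k)
  blur_axis <- function(x) {           # blurs along rows (dim 1)
    n <- nrow(x)
    idx <- function(i) pmin(pmax(i, 1L), n)
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) out <- out + k[j] * x[idx(seq_len(n) + j - r - 1L), , drop = FALSE]
    out
  }
  t(blur_axis(t(blur_axis(m))))
}

# Correlated background texture around intensity 0.3.  White noise is
# blurred on a padded grid and cropped, so the field is stationary up to
# the patch edges.  Its variance shrinks as the correlation length grows;
# beyond 8x the patch side the field is taken at its constant limit.
gen_background <- function(cfg) {
  s <- cfg$image_size
  sc <- cfg$background_texture_scale
  if (sc > 8 * s) return(matrix(0.3, s, s))
  r <- max(1L, as.integer(ceiling(3 * sc)))
  noise <- matrix(stats::rnorm((s + 2 * r)^2), s + 2 * r, s + 2 * r)
  sm <- gaussian_blur(noise, sc)[(r + 1):(r + s), (r + 1):(r + s)]
  0.3 + 0.5 * sm
}

finish_patch <- function(img, cfg) {
  if (cfg$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), sd = cfg$noise_sd),
                        nrow(img), ncol(img))
  pmin(pmax(img, 0), 1)
}

# Additive anisotropic Gaussian bump at (cy, cx) with semi-axes (a, b) and
# orientation phi, peak intensity amp.
render_dot <- function(img, cy, cx, a, b, phi, amp) {
  s <- nrow(img)
  y <- matrix(seq_len(s) - cy, s, s)
  x <- matrix(seq_len(s) - cx, s, s, byrow = TRUE)
  xr <- cos(phi) * x + sin(phi) * y
  yr <- -sin(phi) * x + cos(phi) * y
  img + amp * exp(-0.5 * ((xr / a)^2 + (yr / b)^2))
}

#' Generate a synthetic calcification patch
#'
#' Renders a cluster of bright dots on textured background.  Malignant
#' clusters are tighter and contain more, smaller and more shape-variable
#' (pleomorphic) dots; benign clusters are looser with fewer, larger,
#' rounder dots.
#'
#' @param malignant Logical; `TRUE` labels the patch `cancer`, `FALSE`
#'   labels it `benign`.
#' @param cfg A [synth_config()].
#' @param seed Integer stream seed; defaults to `cfg$seed`.
#' @return A [patch_record()] with `finding_tags = "calcification"`.
#' @export
gen_calcification_patch <- function(malignant, cfg = synth_config(), seed = cfg$seed) {
  validate_synth_config(cfg)
  with_seed(seed, {
    s <- cfg$image_size
    img <- gen_background(cfg)
    cnt <- if (malignant) cfg$calc_dot_count_malignant else cfg$calc_dot_count_benign
    rad <- if (malignant) cfg$calc_cluster_radius_malignant else cfg$calc_cluster_radius_benign
    srange <- if (malignant) cfg$calc_dot_size_range_malignant else cfg$calc_dot_size_range_benign
    n_dots <- max(1L, as.integer(round(stats::rnorm(1, cnt[1], cnt[2]))))
    cy <- stats::runif(1, 0.35 * s, 0.65 * s)
    cx <- stats::runif(1, 0.35 * s, 0.65 * s)
    for (i in seq_len(n_dots)) {
      rr <- rad * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      a <- stats::runif(1, srange[1], srange[2])
      # benign dots are near-round; malignant dots pleomorphic
      ecc <- if (malignant) stats::runif(1, 0.4, 1) else stats::runif(1, 0.85, 1)
      amp <- stats::runif(1, 0.4, 0.55)
      img <- render_dot(img, cy + rr * sin(th), cx + rr * cos(th),
                        a, a * ecc, stats::runif(1, 0, pi), amp)
    }
    pix <- finish_patch(img, cfg)
    patch_record(pix, if (malignant) "cancer" else "benign", "calcification",
                 patient_id = "synth", image_id = sprintf("calc_s%d", seed),
                 lesion_id = sprintf("calc_s%d_L1", seed))
  })
}

#' Generate a synthetic mass patch
#'
#' Renders a single space-occupying lesion.  Benign masses are smooth
#' (near-elliptical) with sharp margins; malignant masses have irregular
#' boundaries, blurred (ill-defined) margins and radial spicules.
#'
#' @inheritParams gen_calcification_patch
#' @return A [patch_record()] with `finding_tags = "mass"`.
#' @export
gen_mass_patch <- function(malignant, cfg = synth_config(), seed = cfg$seed) {
  validate_synth_config(cfg)
  with_seed(seed, {
    s <- cfg$image_size
    img <- gen_background(cfg)
    blur <- if (malignant) cfg$mass_margin_sharpness_malignant else cfg$mass_margin_sharpness_benign
    spic <- if (malignant) cfg$mass_spiculation_malignant else cfg$mass_spiculation_benign
    cy <- stats::runif(1, 0.4 * s, 0.6 * s)
    cx <- stats::runif(1, 0.4 * s, 0.6 * s)
    r0 <- stats::runif(1, 0.14, 0.20) * s
    axis_ratio <- if (malignant) 1 else stats::runif(1, 0.7, 0.95)
    phi0 <- stats::runif(1, 0, pi)
    # boundary radius as a truncated Fourier series in polar angle
    harmonics <- 2:6
    amp_irr <- if (malignant) 0.22 else 0.03
    a_k <- stats::rnorm(length(harmonics), 0, amp_irr / sqrt(length(harmonics)))
    ph_k <- stats::runif(length(harmonics), 0, 2 * pi)

    y <- matrix(seq_len(s) - cy, s, s)
    x <- matrix(seq_len(s) - cx, s, s, byrow = TRUE)
    xr <- cos(phi0) * x + sin(phi0) * y
    yr <- (-sin(phi0) * x + cos(phi0) * y) / axis_ratio
    d <- sqrt(xr^2 + yr^2)
    th <- atan2(yr, xr)
    rb <- r0 * (1 + Reduce(`+`, Map(function(a, k, p) a * cos(k * th + p),
                                    a_k, harmonics, ph_k)))
    core <- 0.45 * (d <= rb)
    # margin definition: the core is blurred; spicules stay sharp (thin
    # radiating lines are a high-frequency cue in their own right)
    lesion <- gaussian_blur(core, blur)
    n_spic <- as.integer(round(spic[1]))
    if (n_spic > 0) {
      spik <- matrix(0, s, s)
      dirs <- stats::runif(n_spic, 0, 2 * pi)
      for (ang in dirs) {
        along <- cos(ang) * xr + sin(ang) * yr       # distance along spicule
        perp <- -sin(ang) * xr + cos(ang) * yr       # off-axis distance
        rb_dir <- r0 * (1 + sum(a_k * cos(harmonics * ang + ph_k)))
        ridge <- 0.4 * exp(-0.5 * (perp / 0.9)^2) *
          (along > 0.6 * rb_dir & along < rb_dir + spic[2])
        spik <- pmax(spik, ridge)
      }
      lesion <- lesion + gaussian_blur(spik, 0.5)
    }
    img <- img + lesion
    pix <- finish_patch(img, cfg)
    patch_record(pix, if (malignant) "cancer" else "benign", "mass",
                 patient_id = "synth", image_id = sprintf("mass_s%d", seed),
                 lesion_id = sprintf("mass_s%d_L1", seed))
  })
}

#' Generate a synthetic normal-tissue patch
#'
#' Background texture only; no lesion structure is inserted.
#'
#' @inheritParams gen_calcification_patch
#' @return A [patch_record()] with `diagnostic_label = "normal"` and empty
#'   finding tags.
#' @export
gen_normal_patch <- function(cfg = synth_config(), seed = cfg$seed) {
  validate_synth_config(cfg)
  with_seed(seed, {
    pix <- finish_patch(gen_background(cfg), cfg)
    patch_record(pix, "normal", character(),
                 patient_id = "synth", image_id = sprintf("norm_s%d", seed))
  })
}

#' Generate a full labeled synthetic dataset
#'
#' Produces `n_per_cell` patches for each of the five (diagnostic label x
#' finding) cells.  Generation is a pure function of the config: per-patch
#' RNG streams are derived by counter-based seed splitting, so changing one
#' cell's count never reshuffles another cell's patches.  Synthetic patients
#' are assigned within a cell (two patches per patient), so no patient ever
#' spans diagnostic classes.
#'
#' @param cfg A [synth_config()]; `cfg$n_per_cell` may be a single count or
#'   a named vector over the cells cancer_calcification, cancer_mass,
#'   benign_calcification, benign_mass, normal.
#' @return A list of [patch_record()] objects.
#' @export
gen_dataset <- function(cfg = synth_config()) {
  validate_synth_config(cfg)
  npc <- cfg$n_per_cell
  if (length(npc) == 1 && is.null(names(npc))) {
    counts <- stats::setNames(rep(as.integer(npc), 5), SYNTH_CELLS)
  } else {
    npc <- unlist(npc)
    if (!all(SYNTH_CELLS %in% names(npc)))
      stop("named n_per_cell must cover cells: ", paste(SYNTH_CELLS, collapse = ", "))
    counts <- stats::setNames(as.integer(npc[SYNTH_CELLS]), SYNTH_CELLS)
  }
  records <- vector("list", sum(counts))
  pos <- 0L
  for (ci in seq_along(SYNTH_CELLS)) {
    cell <- SYNTH_CELLS[ci]
    for (i in seq_len(counts[[cell]])) {
      sd_i <- derive_seed(cfg$seed, ci, i)
      rec <- switch(cell,
        cancer_calcification = gen_calcification_patch(TRUE, cfg, sd_i),
        cancer_mass = gen_mass_patch(TRUE, cfg, sd_i),
        benign_calcification = gen_calcification_patch(FALSE, cfg, sd_i),
        benign_mass = gen_mass_patch(FALSE, cfg, sd_i),
        normal = gen_normal_patch(cfg, sd_i))
      rec$patient_id <- sprintf("P_%s_%03d", cell, (i + 1L) %/% 2L)
      rec$image_id <- sprintf("%s_%04d", cell, i)
      rec$lesion_id <- if (cell == "normal") NA_character_ else
        sprintf("%s_%04d_L1", cell, i)
      pos <- pos + 1L
      records[[pos]] <- rec
    }
  }
  records
}
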