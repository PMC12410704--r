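#' Configuration for the synthetic mammographic patch generator
#'
#' Parameters controlling the lesion phantoms.  Malignancy cues are
#' finding-specific by construction: for calcifications the cue lives in dot
#' count, size variability and cluster tightness (malignant clusters are
#' tighter, with more, smaller, more pleomorphic dots); for masses it lives
#' in boundary irregularity, margin blur and spiculation (benign masses are
#' smooth sharp-margined ovals).  Lengths are in pixels at the configured
#' `image_size`; geometric defaults scale linearly with `image_size / 64`.
#'
#' @param image_size Patch side in pixels (>= 32).  64 keeps tests fast;
#'   512 gives full visual fidelity.
#' @param n_per_cell Patch count per (diagnostic label x finding) cell used
#'   by [gen_dataset()]: either one count for all five cells
#'   (cancer-calcification, cancer-mass, benign-calcification, benign-mass,
#'   normal) or a named vector/list with those cell names.
#' @param calc_dot_count_benign,calc_dot_count_malignant `c(mean, sd)` of
#'   the per-cluster calcification dot count.
#' @param calc_cluster_radius_benign,calc_cluster_radius_malignant Cluster
#'   radius in pixels within which dots are scattered.
#' @param calc_dot_size_range_benign,calc_dot_size_range_malignant
#'   `c(min, max)` dot radius in pixels.
#' @param mass_margin_sharpness_benign,mass_margin_sharpness_malignant
#'   Gaussian blur width (pixels) applied to the mass margin; larger means
#'   more ill-defined.
#' @param mass_spiculation_benign,mass_spiculation_malignant
#'   `c(count, length)`: number of radial spicules and their length in
#'   pixels.
#' @param background_texture_scale Correlation length (pixels) of the
#'   fibroglandular background texture.  In the large-scale limit the
#'   background becomes constant.
#' @param noise_sd Additive Gaussian pixel noise, intensity units.
#' @param seed Integer master seed; identical configs (including seed)
#'   reproduce an identical dataset bit for bit.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(image_size = 64,
                         n_per_cell = 20,
                         calc_dot_count_benign = c(5, 1.5),
                         calc_dot_count_malignant = c(12, 2.5),
                         calc_cluster_radius_benign = NULL,
                         calc_cluster_radius_malignant = NULL,
                         calc_dot_size_range_benign = NULL,
                         calc_dot_size_range_malignant = NULL,
                         mass_margin_sharpness_benign = NULL,
                         mass_margin_sharpness_malignant = NULL,
                         mass_spiculation_benign = c(0, 0),
                         mass_spiculation_malignant = NULL,
                         background_texture_scale = NULL,
                         noise_sd = 0.02,
                         seed = 1) {
  if (!is.numeric(image_size) || length(image_size) != 1 || image_size < 32)
    stop("image_size must be a single number >= 32")
  u <- image_size / 64  # geometric scale factor
  if (is.null(calc_cluster_radius_benign))    calc_cluster_radius_benign <- 22 * u
  if (is.null(calc_cluster_radius_malignant)) calc_cluster_radius_malignant <- 12 * u
  if (is.null(calc_dot_size_range_benign))    calc_dot_size_range_benign <- c(2.0, 2.8) * u
  if (is.null(calc_dot_size_range_malignant)) calc_dot_size_range_malignant <- c(0.9, 1.6) * u
  if (is.null(mass_margin_sharpness_benign))    mass_margin_sharpness_benign <- 0.8 * u
  if (is.null(mass_margin_sharpness_malignant)) mass_margin_sharpness_malignant <- 3.0 * u
  if (is.null(mass_spiculation_malignant))    mass_spiculation_malignant <- c(8, 10 * u)
  if (is.null(background_texture_scale))      background_texture_scale <- 6 * u

  cfg <- list(
    image_size = as.integer(round(image_size)),
    n_per_cell = n_per_cell,
    calc_dot_count_benign = as.numeric(calc_dot_count_benign),
    calc_dot_count_malignant = as.numeric(calc_dot_count_malignant),
    calc_cluster_radius_benign = as.numeric(calc_cluster_radius_benign),
    calc_cluster_radius_malignant = as.numeric(calc_cluster_radius_malignant),
    calc_dot_size_range_benign = as.numeric(calc_dot_size_range_benign),
    calc_dot_size_range_malignant = as.numeric(calc_dot_size_range_malignant),
    mass_margin_sharpness_benign = as.numeric(mass_margin_sharpness_benign),
    mass_margin_sharpness_malignant = as.numeric(mass_margin_sharpness_malignant),
    mass_spiculation_benign = as.numeric(mass_spiculation_benign),
    mass_spiculation_malignant = as.numeric(mass_spiculation_malignant),
    background_texture_scale = as.numeric(background_texture_scale),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  num_ok <- function(x, n) is.numeric(x) && length(x) == n && all(is.finite(x))
  for (f in c("calc_dot_count_benign", "calc_dot_count_malignant",
              "mass_spiculation_benign", "mass_spiculation_malignant",
              "calc_dot_size_range_benign", "calc_dot_size_range_malignant")) {
    if (!num_ok(cfg[[f]], 2) || any(cfg[[f]] < 0))
      stop(f, " must be two finite non-negative numbers")
  }
  for (f in c("calc_cluster_radius_benign", "calc_cluster_radius_malignant",
              "mass_margin_sharpness_benign", "mass_margin_sharpness_malignant",
              "background_texture_scale", "noise_sd")) {
    if (!num_ok(cfg[[f]], 1) || cfg[[f]] < 0)
      stop(f, " must be a single finite non-negative number")
  }
  npc <- cfg$n_per_cell
  if (!(is.numeric(npc) || is.list(npc)) || any(unlist(npc) < 0))
    stop("n_per_cell must be non-negative count(s)")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config: %dpx patches, seed %d, noise_sd %.3g>\n",
              x$image_size, x$seed, x$noise_sd))
  invisible(x)
}

# The five (diagnostic label x finding) dataset cells, in generation order.
SYNTH_CELLS <- c("cancer_calcification", "cancer_mass",
                 "benign_calcification", "benign_mass", "normal")

#' Class mix mirroring the source accession, scaled to a total
#'
#' Apportions `total` patches to the cancer / benign / normal classes in the
#' proportions 1462 : 248 : 1054 by the largest-remainder rule, then splits
#' each lesion class between the calcification and mass cells (the
#' calcification cell receives the ceiling half).
#'
#' @param total Total patch count.
#' @return Named integer vector over the five dataset cells.
#' @export
synth_cell_counts <- function(total) {
  stopifnot(total >= 0)
  ref <- c(cancer = 1462, benign = 248, normal = 1054)
  quota <- total * ref / sum(ref)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  counts <- c(
    cancer_calcification = ceiling(base[["cancer"]] / 2),
    cancer_mass = floor(base[["cancer"]] / 2),
    benign_calcification = ceiling(base[["benign"]] / 2),
    benign_mass = floor(base[["benign"]] / 2),
    normal = base[["normal"]])
  storage.mode(counts) <- "integer"
  counts
}
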