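#' Gate output
#'
#' The pair of finding-type probabilities emitted by the gate network;
#' constrained to sum to one (enforced structurally by the gate's two-class
#' softmax head, validated here to 1e-6).
#'
#' @param wc,wm Probabilities of calcification and mass.
#' @return An object of class `gate_output`.
#' @export
gate_output <- function(wc, wm) {
  if (anyNA(c(wc, wm)) || wc < -1e-9 || wm < -1e-9 || abs(wc + wm - 1) > 1e-6)
    stop("gate weights must be probabilities with wc + wm = 1 (tol 1e-6)")
  structure(list(wc = wc, wm = wm), class = "gate_output")
}

#' Three-class probabilities
#'
#' The (cancer, benign, normal) probability triple emitted by an expert, the
#' conventional baseline, or the mixture; sums to one.
#'
#' @param p_cancer,p_benign,p_normal Class probabilities.
#' @return An object of class `class_probabilities`.
#' @export
class_probabilities <- function(p_cancer, p_benign, p_normal) {
  p <- c(p_cancer, p_benign, p_normal)
  if (anyNA(p) || any(p < -1e-9) || abs(sum(p) - 1) > 1e-6)
    stop("class probabilities must be non-negative and sum to 1 (tol 1e-6)")
  structure(list(p_cancer = p_cancer, p_benign = p_benign, p_normal = p_normal),
            class = "class_probabilities")
}

as_prob_vector <- function(p) {
  if (inherits(p, "class_probabilities"))
    c(p$p_cancer, p$p_benign, p$p_normal)
  else as.numeric(p)
}

#' Mix expert outputs with gate weights
#'
#' The core mixture: `y = wc * Expert_c(x) + wm * Expert_m(x)`,
#' componentwise.  Because the gate weights sum to one and each expert
#' output sums to one, the mixture is again a probability vector; each
#' component lies between the corresponding expert components.
#'
#' @param w A [gate_output()] (or numeric `c(wc, wm)`).
#' @param p_c,p_m Expert outputs ([class_probabilities()] or numeric
#'   triples).
#' @return A [class_probabilities()].
#' @export
mix_experts <- function(w, p_c, p_m) {
  if (inherits(w, "gate_output")) w <- c(w$wc, w$wm)
  pc <- as_prob_vector(p_c)
  pm <- as_prob_vector(p_m)
  y <- w[1] * pc + w[2] * pm
  class_probabilities(y[1], y[2], y[3])
}

#' Single-patch forward passes
#'
#' `gate_forward` runs the gate on one patch and returns its
#' [gate_output()]; `expert_forward` and `conventional_predict` run a
#' three-class network and return [class_probabilities()];
#' `morfse_predict` combines the three networks through [mix_experts()];
#' `nognet_predict` is the equal-weight ensemble (`wc = wm = 0.5`) that
#' bypasses the gate.
#'
#' @param gate,expert,net,cexp,mexp Trained `morfse_net` objects with the
#'   appropriate number of output classes.
#' @param patch A [patch_record()].
#' @return See above.
#' @export
gate_forward <- function(gate, patch) {
  stopifnot(inherits(gate, "morfse_net"))
  if (gate$spec$n_out != 2L)
    morfse_error("gate network must have 2 output classes", "morfse_input_error")
  p <- net_predict(gate, list(patch))
  gate_output(p[1, 1], p[1, 2])
}

#' @rdname gate_forward
#' @export
expert_forward <- function(expert, patch) {
  stopifnot(inherits(expert, "morfse_net"))
  if (expert$spec$n_out != 3L)
    morfse_error("expert network must have 3 output classes", "morfse_input_error")
  p <- net_predict(expert, list(patch))
  class_probabilities(p[1, 1], p[1, 2], p[1, 3])
}

#' @rdname gate_forward
#' @export
morfse_predict <- function(gate, cexp, mexp, patch) {
  w <- gate_forward(gate, patch)
  mix_experts(w, expert_forward(cexp, patch), expert_forward(mexp, patch))
}

#' @rdname gate_forward
#' @export
nognet_predict <- function(cexp, mexp, patch) {
  mix_experts(c(0.5, 0.5), expert_forward(cexp, patch),
              expert_forward(mexp, patch))
}

#' @rdname gate_forward
#' @export
conventional_predict <- function(net, patch) {
  expert_forward(net, patch)
}

#' Fit the mixture-of-experts model family
#'
#' Trains the gate network on finding labels and the two experts plus the
#' conventional single-network baseline on diagnostic labels, each on its
#' routed training subset (see [route_training_records()]).  Training
#' seeds for the four networks are derived from `seed`.
#'
#' @param records Training patches (list of [patch_record()]).
#' @param cfg A [train_config()].
#' @param seed Integer seed; defaults to `cfg$master_seed`.
#' @param include_conventional Logical; also train the single-network
#'   baseline (default `TRUE`).
#' @return An object of class `morfse` holding the trained networks.
#' @export
morfse <- function(records, cfg = train_config(fast_mode = TRUE),
                   seed = cfg$master_seed, include_conventional = TRUE) {
  stopifnot(inherits(cfg, "train_config"))
  fit <- list(
    gate = train_network(route_training_records(records, "gnet"), cfg,
                         seed = derive_seed(seed, 11L)),
    cexp = train_network(route_training_records(records, "cexp"), cfg,
                         seed = derive_seed(seed, 12L)),
    mexp = train_network(route_training_records(records, "mexp"), cfg,
                         seed = derive_seed(seed, 13L)),
    conventional = if (include_conventional)
      train_network(route_training_records(records, "conventional"), cfg,
                    seed = derive_seed(seed, 14L)),
    config = cfg, seed = as.integer(seed),
    class_order = c("cancer", "benign", "normal"),
    gate_order = c("calcification", "mass"),
    training_ids = vapply(records, `[[`, "", "image_id"))
  structure(fit, class = "morfse")
}

#' Predict method for the mixture-of-experts model
#'
#' @param object A fitted [morfse()] model.
#' @param records Patches to score.
#' @param variant `"morfse"` (gated mixture), `"nognet"` (equal-weight
#'   ensemble), `"conventional"` (single-network baseline) or `"gate"`
#'   (finding probabilities).
#' @param ... Unused.
#' @return A numeric matrix, one row per record: columns `cancer`,
#'   `benign`, `normal` (or `calcification`, `mass` for the gate).
#' @export
predict.morfse <- function(object, records,
                           variant = c("morfse", "nognet", "conventional", "gate"),
                           ...) {
  variant <- match.arg(variant)
  if (inherits(records, "patch_record")) records <- list(records)
  out <- switch(variant,
    gate = net_predict(object$gate, records),
    conventional = {
      if (is.null(object$conventional))
        morfse_error("model was fitted without the conventional baseline",
                     "morfse_input_error")
      net_predict(object$conventional, records)
    },
    nognet = 0.5 * net_predict(object$cexp, records) +
             0.5 * net_predict(object$mexp, records),
    morfse = {
      w <- net_predict(object$gate, records)
      w[, 1] * net_predict(object$cexp, records) +
        w[, 2] * net_predict(object$mexp, records)
    })
  colnames(out) <- if (variant == "gate") object$gate_order else object$class_order
  rownames(out) <- vapply(records, `[[`, "", "image_id")
  out
}

#' @export
print.morfse <- function(x, ...) {
  cat("Mixture of radiological-finding-specific experts\n")
  cat(sprintf("  backbone: %s (%dpx input), trained on %d patches\n",
              x$config$backbone$name, x$gate$spec$input_side,
              length(x$training_ids)))
  cat(sprintf("  networks: gate (2-class)%s, cExp, mExp%s\n", "",
              if (!is.null(x$conventional)) ", conventional" else ""))
  invisible(x)
}

#' @export
summary.morfse <- function(object, ...) {
  nets <- c("gate", "cexp", "mexp", "conventional")
  cat("morfse fit summary\n")
  for (nm in nets) {
    nt <- object[[nm]]
    if (is.null(nt)) next
    fin <- if (length(nt$loss_history)) sprintf("final loss %.4f",
                                                utils::tail(nt$loss_history, 1))
           else "untrained"
    cat(sprintf("  %-12s %d classes, %d epochs, %s\n", nm, nt$spec$n_out,
                nt$trained_epochs, fin))
  }
  invisible(object)
}

#' Save / load a fitted model
#'
#' Network weights are serialized alongside a JSON sidecar recording the
#' backbone spec, the class ordering (cancer, benign, normal — part of the
#' on-disk contract) and an md5 hash of the training configuration.
#'
#' @param object A fitted [morfse()] model.
#' @param dir Checkpoint directory.
#' @return `save_morfse` returns `dir` invisibly; `load_morfse` returns the
#'   restored `morfse` object.
#' @export
save_morfse <- function(object, dir) {
  stopifnot(inherits(object, "morfse"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(object, file.path(dir, "weights.rds"))
  cfgfile <- tempfile()
  dput(unclass(object$config), cfgfile)
  sidecar <- list(
    backbone = unclass(object$config$backbone),
    class_order = object$class_order,
    gate_order = object$gate_order,
    config_md5 = unname(tools::md5sum(cfgfile)))
  unlink(cfgfile)
  jsonlite::write_json(sidecar, file.path(dir, "checkpoint.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_morfse
#' @export
load_morfse <- function(dir) {
  obj <- readRDS(file.path(dir, "weights.rds"))
  side <- jsonlite::read_json(file.path(dir, "checkpoint.json"))
  if (!identical(unlist(side$class_order), obj$class_order))
    morfse_error("checkpoint sidecar class order disagrees with weights",
                 "morfse_format_error")
  obj
}
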