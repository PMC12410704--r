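#' Training configuration
#'
#' Defaults follow the full-scale study protocol: Adam (learning rate 1e-5,
#' weight decay 0), cross-entropy loss, batch size 64, 30 epochs, 5
#' repetitions of 5-fold cross-validation.  `fast_mode` is the desk-scale
#' profile used throughout the test suite: it shrinks the schedule (8
#' epochs, batch 32) and raises the learning rate to 2e-3, which is what a
#' randomly initialized small CNN needs in place of fine-tuning a
#' pretrained backbone.
#'
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param learning_rate,weight_decay Adam hyperparameters.
#' @param backbone A [backbone_spec()] with `n_out = 3`; the gate reuses the
#'   same architecture with a two-class head.
#' @param repetitions Number of cross-validation repetitions (R).
#' @param folds Number of folds (K >= 2).
#' @param master_seed Master seed; every stream (folds, initialization,
#'   batch order) is derived from it.
#' @param fast_mode Logical; apply the desk-scale overrides.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 64, epochs = 30, learning_rate = 1e-5,
                         weight_decay = 0, backbone = backbone_spec("smallcnn"),
                         repetitions = 5, folds = 5, master_seed = 1,
                         fast_mode = FALSE) {
  stopifnot(inherits(backbone, "backbone_spec"))
  if (folds < 2) stop("folds (K) must be >= 2")
  if (repetitions < 1) stop("repetitions (R) must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  cfg <- list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              learning_rate = learning_rate, weight_decay = weight_decay,
              backbone = backbone, repetitions = as.integer(repetitions),
              folds = as.integer(folds), master_seed = as.integer(master_seed),
              fast_mode = isTRUE(fast_mode))
  if (cfg$fast_mode) {
    cfg$epochs <- min(cfg$epochs, 8L)
    cfg$batch_size <- min(cfg$batch_size, 32L)
    cfg$learning_rate <- max(cfg$learning_rate, 2e-3)
    cfg$backbone$input_side <- min(cfg$backbone$input_side, 32L)
  }
  structure(cfg, class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf(
    "<train_config: %s%s, %d epochs, batch %d, lr %g, K=%d, R=%d, seed %d>\n",
    x$backbone$name, if (x$fast_mode) " (fast)" else "", x$epochs,
    x$batch_size, x$learning_rate, x$folds, x$repetitions, x$master_seed))
  invisible(x)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (wd > 0) g <- g + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a network on a routed subset
#'
#' Minibatch Adam on the cross-entropy loss.  Training is fully
#' deterministic given `seed` (initialization and batch order both derive
#' from it); per-epoch mean losses are recorded on the returned network.
#' `epochs = 0` returns the untouched initialization.
#'
#' @param subset A routed subset as returned by [route_training_records()]
#'   (list with `records` and `targets`), or a list of records together
#'   with a `targets` factor argument.
#' @param cfg A [train_config()].
#' @param seed Integer training seed.
#' @param targets Optional factor of targets when `subset` is a plain list
#'   of records.
#' @return A trained `morfse_net`.
#' @export
train_network <- function(subset, cfg = train_config(fast_mode = TRUE),
                          seed = cfg$master_seed, targets = NULL) {
  if (is.null(targets)) {
    stopifnot(is.list(subset), !is.null(subset$records))
    records <- subset$records
    targets <- subset$targets
  } else {
    records <- subset
  }
  if (!length(records))
    morfse_error("empty training subset", "morfse_config_error")
  targets <- as.factor(targets)
  lev <- levels(targets)
  spec <- cfg$backbone
  spec$n_out <- length(lev)
  net <- net_init(spec, seed = derive_seed(seed, 101L))
  net$class_levels <- lev
  if (cfg$epochs == 0L) return(net)
  X <- preprocess_patches(records, spec$input_side)
  y <- as.integer(targets)
  n <- length(y)
  state <- adam_init(net$params)
  losses <- numeric(cfg$epochs)
  with_seed(derive_seed(seed, 202L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        fwd <- smallcnn_forward(net$params, X[, , , idx, drop = FALSE],
                                cache = TRUE)
        sx <- softmax_xent(fwd$logits, y[idx])
        if (!is.finite(sx$loss))
          morfse_error(sprintf(
            "training diverged (non-finite loss) at epoch %d, batch %d",
            ep, (start - 1L) %/% cfg$batch_size + 1L), "morfse_divergence_error")
        grads <- smallcnn_backward(net$params, fwd, sx$dlogits)
        up <- adam_step(net$params, grads, state, cfg$learning_rate,
                        cfg$weight_decay)
        net$params <- up$params
        state <- up$state
        batch_losses <- c(batch_losses, sx$loss)
      }
      losses[ep] <- mean(batch_losses)
    }
  })
  net$loss_history <- losses
  net$trained_epochs <- cfg$epochs
  net
}
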