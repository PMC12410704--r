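#' Backbone specification
#'
#' Describes the network architecture shared by the gate and the experts.
#' The desk-scale backbone is `smallcnn`: four 3x3 convolution blocks
#' (ReLU + 2x2 average pooling, channel widths 4-8-16-16) followed by
#' global average pooling and a linear softmax head.  `resnet18` names the
#' full-scale configuration; its pretrained weights and runtime are not
#' bundled with this package, so constructing it signals an error and it
#' exists as a spec value for interoperability of serialized configs.
#'
#' @param name `"smallcnn"` or `"resnet18"`.
#' @param pretrained Logical; only valid for `resnet18`.
#' @param input_side Network input side in pixels; patches are resized to
#'   this before the forward pass.  Default 32 for `smallcnn` (must be a
#'   multiple of 16), 224 for pretrained `resnet18`.
#' @param n_out Number of output classes: 2 for the gate, 3 for experts and
#'   the conventional single-network baseline.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = c("smallcnn", "resnet18"), pretrained = FALSE,
                          input_side = NULL, n_out = 3) {
  name <- match.arg(name)
  if (pretrained && name != "resnet18")
    morfse_error("pretrained initialization is only defined for resnet18",
                 "morfse_backbone_error")
  if (!n_out %in% c(2L, 3L))
    morfse_error("n_out must be 2 (gate) or 3 (experts/conventional)",
                 "morfse_backbone_error")
  if (is.null(input_side))
    input_side <- if (name == "resnet18" && pretrained) 224L else 32L
  input_side <- as.integer(input_side)
  if (name == "smallcnn" && (input_side < 16L || input_side %% 16L != 0L))
    morfse_error("smallcnn input_side must be a positive multiple of 16",
                 "morfse_backbone_error")
  structure(list(name = name, pretrained = isTRUE(pretrained),
                 input_side = input_side, n_out = as.integer(n_out)),
            class = "backbone_spec")
}

SMALLCNN_CHANNELS <- c(4L, 8L, 16L, 16L)

# Fixed intensity standardization applied before the forward pass.
PATCH_MEAN <- 0.5
PATCH_SD <- 0.25

#' Initialize an untrained network
#'
#' He-scaled Gaussian weights, zero biases; fully determined by `seed`.
#'
#' @param spec A [backbone_spec()].
#' @param seed Integer seed for the weight initialization stream.
#' @return An object of class `morfse_net`.
#' @export
net_init <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (spec$name == "resnet18")
    morfse_error(paste0("the resnet18 backbone needs a pretrained ",
                        "deep-learning runtime that is not bundled with this ",
                        "package; use backbone_spec(\"smallcnn\")"),
                 "morfse_backbone_error")
  with_seed(seed, {
    params <- list()
    cin <- 1L
    for (i in seq_along(SMALLCNN_CHANNELS)) {
      cout <- SMALLCNN_CHANNELS[i]
      params[[paste0("W", i)]] <- matrix(
        stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))), 9L * cin, cout)
      params[[paste0("b", i)]] <- numeric(cout)
      cin <- cout
    }
    params$Wd <- matrix(stats::rnorm(cin * spec$n_out, sd = sqrt(1 / cin)),
                        cin, spec$n_out)
    params$bd <- numeric(spec$n_out)
    structure(list(spec = spec, params = params, loss_history = numeric(),
                   trained_epochs = 0L),
              class = "morfse_net")
  })
}

#' @export
print.morfse_net <- function(x, ...) {
  cat(sprintf("<morfse_net %s: input %dpx, %d classes, %d epoch(s) trained>\n",
              x$spec$name, x$spec$input_side, x$spec$n_out, x$trained_epochs))
  invisible(x)
}

# Forward pass; with cache = TRUE also returns everything backward needs.
smallcnn_forward <- function(params, X, cache = FALSE) {
  caches <- if (cache) list() else NULL
  A <- X
  for (i in seq_along(SMALLCNN_CHANNELS)) {
    cv <- conv_forward(A, params[[paste0("W", i)]], params[[paste0("b", i)]])
    Z <- cv$out
    R <- relu_forward(Z)
    P <- avgpool_forward(R)
    if (cache) caches[[i]] <- list(conv = cv, Z = Z, r_dims = dim(R))
    A <- P
  }
  gap_dims <- dim(A)
  F <- gap_forward(A)
  logits <- F %*% params$Wd + matrix(params$bd, nrow(F), length(params$bd),
                                     byrow = TRUE)
  list(logits = logits, F = F, gap_dims = gap_dims, caches = caches)
}

smallcnn_backward <- function(params, fwd, dlogits) {
  grads <- list(Wd = crossprod(fwd$F, dlogits), bd = colSums(dlogits))
  dF <- tcrossprod(dlogits, params$Wd)
  dA <- gap_backward(dF, fwd$gap_dims)
  for (i in rev(seq_along(SMALLCNN_CHANNELS))) {
    ch <- fwd$caches[[i]]
    dR <- avgpool_backward(dA, ch$r_dims)
    dZ <- relu_backward(dR, ch$Z)
    cb <- conv_backward(dZ, ch$conv, params[[paste0("W", i)]])
    grads[[paste0("W", i)]] <- cb$dW
    grads[[paste0("b", i)]] <- cb$db
    dA <- cb$dX
  }
  grads
}

#' Preprocess patch records into a network input batch
#'
#' Resizes each patch to the backbone's input side (bilinear) and
#' standardizes intensities with fixed channel statistics (mean 0.5,
#' sd 0.25 on the `[0, 1]` scale).
#'
#' @param records List of [patch_record()] objects.
#' @param input_side Target side in pixels.
#' @return A `(side, side, 1, n)` array.
#' @export
preprocess_patches <- function(records, input_side) {
  n <- length(records)
  X <- array(0, c(input_side, input_side, 1L, n))
  for (i in seq_len(n)) {
    p <- records[[i]]$pixels
    if (nrow(p) != input_side)
      p <- EBImage::resize(p, w = input_side, h = input_side)
    X[, , 1L, i] <- (p - PATCH_MEAN) / PATCH_SD
  }
  X
}

# Class-probability matrix (one row per record) for a trained network.
net_predict <- function(net, records) {
  check_input_records(net, records)
  X <- preprocess_patches(records, net$spec$input_side)
  softmax_rows(smallcnn_forward(net$params, X)$logits)
}

check_input_records <- function(net, records) {
  if (!length(records)) morfse_error("no records to predict", "morfse_input_error")
  sides <- vapply(records, function(r) nrow(r$pixels), 0L)
  if (any(sides < 1L))
    morfse_error("degenerate patch", "morfse_input_error")
  invisible(TRUE)
}
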