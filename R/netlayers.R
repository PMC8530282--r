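# Network building blocks: Feature Selection Layer (FSL), mask-constrained
# Isoform/Gene Map Layers (IML/GML), dense stacks, and the forward/backward
# machinery they share. The effective weight of a map layer is R * W
# (elementwise), so connections absent from the annotation are structurally
# zero and receive zero gradient.

ACTIVATIONS <- c("relu", "linear", "sigmoid")

act_fun <- function(a, activation) {
  switch(activation,
         relu = pmax(a, 0),
         linear = a,
         sigmoid = sigmoid(a),
         stop("unknown activation: ", activation))
}

act_grad <- function(a, h, activation) {
  switch(activation,
         relu = (a > 0) * 1,
         linear = array(1, dim(a)),
         sigmoid = h * (1 - h),
         stop("unknown activation: ", activation))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Describe one network layer
#'
#' @param kind One of `"fsl"`, `"iml"`, `"gml"`, `"dense"`. An FSL is only
#'   allowed as the first layer; a map layer (iml/gml) only immediately
#'   after the input or an FSL — its width is fixed by its mask.
#' @param width Number of units (dense layers only).
#' @param activation `"relu"` (default), `"linear"` or `"sigmoid"`.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(kind = c("dense", "fsl", "iml", "gml"), width = NULL,
                       activation = "relu") {
  kind <- match.arg(kind)
  stopifnot(activation %in% ACTIVATIONS)
  if (kind == "dense") {
    stopifnot(is.numeric(width), length(width) == 1, width >= 1)
    width <- as.integer(width)
  }
  structure(list(kind = kind, width = width, activation = activation),
            class = "layer_spec")
}

#' Describe a full classification network
#'
#' The network maps an input feature vector through the listed layers to a
#' single sigmoid output unit (appended automatically). Dense widths must be
#' strictly decreasing along the stack; dropout is applied to hidden dense
#' activations during training only.
#'
#' @param input_dim Number of input features.
#' @param layers List of [layer_spec()] objects.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param fsl_l1 L1 penalty weight for the FSL (default 0.0005).
#' @return A `network_spec` object.
#' @export
network_spec <- function(input_dim, layers = list(), dropout = 0.2,
                         fsl_l1 = 5e-4) {
  stopifnot(input_dim >= 1, dropout >= 0, dropout < 1, fsl_l1 >= 0)
  kinds <- vapply(layers, function(l) l$kind, character(1))
  if (any(kinds == "fsl") && (sum(kinds == "fsl") > 1 || kinds[1] != "fsl")) {
    stop("an FSL is only allowed as the (single) first layer")
  }
  map_pos <- which(kinds %in% c("iml", "gml"))
  if (length(map_pos) > 1) stop("at most one map layer (iml/gml) is supported")
  if (length(map_pos) == 1) {
    before <- kinds[seq_len(map_pos - 1)]
    if (!all(before == "fsl")) {
      stop("a map layer is only allowed immediately after the input or an FSL")
    }
  }
  widths <- vapply(layers[kinds == "dense"], function(l) l$width, integer(1))
  if (length(widths) > 1 && any(diff(widths) >= 0)) {
    stop("dense widths must be strictly decreasing along the stack")
  }
  structure(list(input_dim = as.integer(input_dim), layers = layers,
                 dropout = dropout, fsl_l1 = fsl_l1),
            class = "network_spec")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build and initialize a network from its specification
#'
#' Initialization is deterministic given `seed`: Glorot-uniform weights for
#' dense and masked layers, zero biases, FSL weights at 1. Each iml/gml
#' layer requires a binary relationship matrix whose row count equals the
#' incoming dimension; its column count sets the layer width.
#'
#' @param spec A [network_spec()].
#' @param masks A single relationship matrix (when the spec has one map
#'   layer) or a list of matrices in map-layer order.
#' @param seed Integer seed for initialization.
#' @return An `isonet` model object.
#' @export
build_network <- function(spec, masks = NULL, seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  if (is.matrix(masks)) masks <- list(masks)
  layers <- list()
  dim_in <- spec$input_dim
  mask_i <- 0
  with_seed(seed, {
    for (ls in spec$layers) {
      if (ls$kind == "fsl") {
        layers[[length(layers) + 1]] <- list(
          kind = "fsl", w = rep(1, dim_in), l1_weight = spec$fsl_l1)
      } else if (ls$kind %in% c("iml", "gml")) {
        mask_i <- mask_i + 1
        if (is.null(masks) || length(masks) < mask_i) {
          stop("missing relationship matrix for ", ls$kind, " layer")
        }
        R <- masks[[mask_i]]
        validate_relationship_matrix(R)
        if (nrow(R) != dim_in) {
          stop(ls$kind, " mask has ", nrow(R), " rows but incoming dimension is ",
               dim_in)
        }
        storage.mode(R) <- "double"
        layers[[length(layers) + 1]] <- list(
          kind = ls$kind, W = glorot(nrow(R), ncol(R)) * R, R = R,
          b = rep(0, ncol(R)), activation = ls$activation)
        dim_in <- ncol(R)
      } else {
        layers[[length(layers) + 1]] <- list(
          kind = "dense", W = glorot(dim_in, ls$width), b = rep(0, ls$width),
          activation = ls$activation, hidden = TRUE)
        dim_in <- ls$width
      }
    }
    # output unit: dense width 1, sigmoid applied at prediction time
    layers[[length(layers) + 1]] <- list(
      kind = "dense", W = glorot(dim_in, 1L), b = 0, activation = "linear",
      hidden = FALSE, output = TRUE)
  })
  structure(list(spec = spec, layers = layers, feature_ids = NULL),
            class = "isonet")
}

#' Number of learnable parameters of a model
#'
#' Masked entries (R = 0) are not learnable and are not counted.
#'
#' @param model An `isonet` model.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    if (l$kind == "fsl") return(length(l$w))
    nw <- if (is.null(l$R)) length(l$W) else sum(l$R)
    nw + length(l$b)
  }, numeric(1)))
}

#' Feature Selection Layer forward pass
#'
#' Elementwise reweighting `output_k = x_k * w_k`; no bias, no activation.
#'
#' @param x Numeric vector, or matrix with samples in rows.
#' @param w Non-negative weight vector, one entry per feature.
#' @return Reweighted vector/matrix of the same shape.
#' @export
fsl_forward <- function(x, w) {
  if (is.matrix(x)) {
    if (ncol(x) != length(w)) stop("FSL weight length ", length(w),
                                   " does not match feature count ", ncol(x))
    return(sweep(x, 2, w, "*"))
  }
  if (length(x) != length(w)) stop("FSL weight length ", length(w),
                                   " does not match feature count ", length(x))
  x * w
}

#' FSL L1 penalty
#'
#' `lambda * sum(|w|)`; with the non-negativity constraint this equals
#' `lambda * sum(w)`.
#'
#' @param w FSL weight vector.
#' @param l1_weight Penalty weight lambda (default 0.0005).
#' @return Scalar penalty.
#' @export
fsl_penalty <- function(w, l1_weight = 5e-4) {
  l1_weight * sum(abs(w))
}

#' Mask-constrained layer forward pass
#'
#' `activation((R * W)' x + bias)` where `*` is elementwise; only entries
#' with `R = 1` can contribute.
#'
#' @param x Input vector (length `nrow(R)`) or matrix with samples in rows.
#' @param W Learnable weight matrix, same shape as `R`.
#' @param R Binary mask.
#' @param bias Bias vector of length `ncol(R)`.
#' @param activation Activation name (default `"relu"`).
#' @return Output vector/matrix of width `ncol(R)`.
#' @export
masked_forward <- function(x, W, R, bias = rep(0, ncol(R)),
                           activation = "relu") {
  stopifnot(all(dim(W) == dim(R)))
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(R)) stop("input length ", ncol(x),
                               " does not match mask rows ", nrow(R))
  a <- x %*% (R * W)
  a <- sweep(a, 2, bias, "+")
  h <- act_fun(a, activation)
  if (vec) h[1, ] else h
}

# Full forward pass. Returns per-layer caches needed for backprop:
# z (input), a (pre-activation), h (output), m (dropout mask).
nn_forward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$layers))
  z <- X
  p <- model$spec$dropout
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$kind == "fsl") {
      h <- sweep(z, 2, l$w, "*")
      caches[[i]] <- list(z = z, h = h)
    } else {
      Weff <- if (is.null(l$R)) l$W else l$R * l$W
      a <- sweep(z %*% Weff, 2, l$b, "+")
      h_pre <- act_fun(a, l$activation)
      h <- h_pre
      m <- NULL
      if (training && isTRUE(l$hidden) && p > 0) {
        m <- matrix(stats::rbinom(length(h), 1, 1 - p), nrow(h), ncol(h)) / (1 - p)
        h <- h_pre * m
      }
      caches[[i]] <- list(z = z, a = a, h = h, h_pre = h_pre, m = m)
    }
    z <- caches[[i]]$h
  }
  list(logit = z[, 1], caches = caches)
}

# Binary cross-entropy from logits, numerically stable.
bce_from_logit <- function(logit, y) {
  mean(pmax(logit, 0) - y * logit + log1p(exp(-abs(logit))))
}

# Loss (mean BCE + FSL L1 penalty when present) and analytic gradients for
# every learnable parameter; optionally the gradient w.r.t. the input
# (used for saliency, with `logit_grad = TRUE` to differentiate the
# pre-sigmoid output instead of the loss).
nn_loss_grad <- function(model, X, y = NULL, training = FALSE,
                         logit_grad = FALSE, input_grad = FALSE) {
  fw <- nn_forward(model, X, training = training)
  n <- nrow(X)
  L <- length(model$layers)
  grads <- vector("list", L)
  if (logit_grad) {
    g <- matrix(1, n, 1)
    loss <- NA_real_
  } else {
    p <- sigmoid(fw$logit)
    loss <- bce_from_logit(fw$logit, y)
    g <- matrix((p - y) / n, ncol = 1)
  }
  for (i in rev(seq_len(L))) {
    l <- model$layers[[i]]
    cache <- fw$caches[[i]]
    if (!is.null(cache$m)) g <- g * cache$m
    if (l$kind == "fsl") {
      gw <- colSums(cache$z * g)
      if (!logit_grad) {
        loss <- loss + fsl_penalty(l$w, l$l1_weight)
        gw <- gw + l$l1_weight * sign(l$w)
      }
      grads[[i]] <- list(w = gw)
      g <- sweep(g, 2, l$w, "*")
    } else {
      ga <- g * act_grad(cache$a, cache$h_pre, l$activation)
      gW <- crossprod(cache$z, ga)
      if (!is.null(l$R)) gW <- gW * l$R
      gb <- colSums(ga)
      grads[[i]] <- list(W = gW, b = gb)
      Weff <- if (is.null(l$R)) l$W else l$R * l$W
      g <- ga %*% t(Weff)
    }
  }
  out <- list(loss = loss, grads = grads, logit = fw$logit)
  if (input_grad) out$input_grad <- g
  out
}

#' Predict class probabilities
#'
#' Sigmoid outputs with dropout disabled. When both the model and `X` carry
#' feature ids, their order is checked.
#'
#' @param model A (trained) `isonet` model.
#' @param X Sample x feature matrix in training feature order.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$spec$input_dim) {
    stop("input has ", ncol(X), " features; model expects ", model$spec$input_dim)
  }
  if (!is.null(model$feature_ids) && !is.null(colnames(X))) {
    if (!identical(colnames(X), model$feature_ids)) {
      missing <- setdiff(model$feature_ids, colnames(X))
      extra <- setdiff(colnames(X), model$feature_ids)
      stop("feature mismatch; missing: [", paste(missing, collapse = ", "),
           "], extra: [", paste(extra, collapse = ", "), "]")
    }
  }
  as.numeric(sigmoid(nn_forward(model, X, training = FALSE)$logit))
}

#' Save / load a trained model
#'
#' Models are stored as RDS containers holding the layer list (weights,
#' biases, masks), the network spec and the training feature order.
#'
#' @param model An `isonet` model.
#' @param path File path.
#' @return `load_model` returns the model; `save_model` the path, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "isonet"))
  model
}

# Flatten/restore learnable parameters (used by finite-difference checks
# and optimizer state bookkeeping).
get_params <- function(model) {
  unlist(lapply(model$layers, function(l) {
    if (l$kind == "fsl") l$w else c(l$W, l$b)
  }))
}

set_params <- function(model, theta) {
  k <- 0
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$kind == "fsl") {
      nw <- length(l$w)
      model$layers[[i]]$w <- theta[k + seq_len(nw)]
      k <- k + nw
    } else {
      nW <- length(l$W)
      model$layers[[i]]$W <- matrix(theta[k + seq_len(nW)], nrow(l$W), ncol(l$W))
      k <- k + nW
      nb <- length(l$b)
      model$layers[[i]]$b <- theta[k + seq_len(nb)]
      k <- k + nb
    }
  }
  model
}
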