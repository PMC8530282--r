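# Optimization protocol: Adam with early stopping on validation accuracy,
# 5-fold cross-validation, greedy layer-by-layer width search, and the
# logistic-regression / elastic-net baselines.

#' Training configuration
#'
#' Defaults follow the study protocol: Adam (learning rate 0.0003,
#' beta1 = 0.9, beta2 = 0.999), 40 epochs, batch size 256, dropout 0.2,
#' FSL L1 weight 0.0005, early stopping when validation accuracy has not
#' increased for 10 epochs.
#'
#' @param epochs,batch_size,learning_rate,beta1,beta2,adam_eps Adam settings.
#' @param dropout Dropout rate for hidden dense layers.
#' @param fsl_l1 FSL L1 penalty weight.
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer seed for shuffling, dropout and initialization.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 40, batch_size = 256,
                            learning_rate = 3e-4, beta1 = 0.9, beta2 = 0.999,
                            adam_eps = 1e-8, dropout = 0.2, fsl_l1 = 5e-4,
                            patience = 10, seed = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            dropout >= 0, dropout < 1, patience >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, dropout = dropout, fsl_l1 = fsl_l1,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "training_config")
}

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    if (l$kind == "fsl") {
      list(m = list(w = numeric(length(l$w))), v = list(w = numeric(length(l$w))))
    } else {
      list(m = list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b))),
           v = list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b))))
    }
  })
}

adam_step <- function(model, grads, state, t, cfg) {
  lr <- cfg$learning_rate; b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- cfg$adam_eps
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      state[[i]]$m[[nm]] <- b1 * state[[i]]$m[[nm]] + (1 - b1) * g
      state[[i]]$v[[nm]] <- b2 * state[[i]]$v[[nm]] + (1 - b2) * g^2
      step <- lr * (state[[i]]$m[[nm]] / corr1) /
        (sqrt(state[[i]]$v[[nm]] / corr2) + eps)
      if (nm == "w") {
        # FSL: projected update keeps weights non-negative
        model$layers[[i]]$w <- pmax(l$w - step, 0)
      } else {
        model$layers[[i]][[nm]] <- l[[nm]] - step
        if (nm == "W" && !is.null(l$R)) {
          model$layers[[i]]$W <- model$layers[[i]]$W * l$R
        }
      }
    }
  }
  list(model = model, state = state)
}

#' Train a network with Adam and early stopping
#'
#' Minibatches are reshuffled each epoch (seeded); training halts when the
#' validation accuracy has not strictly increased for `patience` epochs (ties
#' do not reset patience) or at the epoch limit, and the returned model is
#' the snapshot from the best epoch.
#'
#' @param model An initialized `isonet` model (see [build_network()]).
#' @param x_train,y_train Training features (samples x features) and binary
#'   labels.
#' @param x_val,y_val Validation data for early stopping.
#' @param config A [training_config()].
#' @param val_accuracy_fn Optional override: `function(model, epoch)`
#'   returning the validation accuracy (used in place of evaluating
#'   `x_val`/`y_val`; intended for testing the stopping contract).
#' @return A list with elements `model` (best-epoch parameters) and `log`
#'   (`data.frame` of per-epoch `train_loss` and `val_accuracy`, plus
#'   attributes) and `best_epoch`, `stopped_epoch`.
#' @export
train <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                  config = training_config(), val_accuracy_fn = NULL) {
  stopifnot(inherits(model, "isonet"), nrow(x_train) == length(y_train))
  if (length(unique(y_train)) < 2) {
    stop("training data contains a single class; both classes are required")
  }
  if (is.null(val_accuracy_fn) && is.null(x_val)) {
    stop("either validation data or val_accuracy_fn must be supplied")
  }
  n <- nrow(x_train)
  state <- adam_init(model)
  t_step <- 0
  best_acc <- -Inf; best_epoch <- 0L; best_model <- model
  wait <- 0L; stopped_epoch <- config$epochs
  epoch_loss <- numeric(0); epoch_acc <- numeric(0)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample(n)
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      losses <- numeric(length(batches))
      for (b in seq_along(batches)) {
        bi <- batches[[b]]
        lg <- nn_loss_grad(model, x_train[bi, , drop = FALSE], y_train[bi],
                           training = TRUE)
        if (!is.finite(lg$loss)) {
          stop("non-finite training loss at epoch ", epoch, ", batch ", b,
               "; consider lowering the learning rate or checking the inputs")
        }
        losses[b] <- lg$loss
        t_step <- t_step + 1
        upd <- adam_step(model, lg$grads, state, t_step, config)
        model <- upd$model; state <- upd$state
      }
      acc <- if (is.null(val_accuracy_fn)) {
        accuracy(predict_proba(model, x_val), y_val)
      } else {
        val_accuracy_fn(model, epoch)
      }
      epoch_loss[epoch] <- mean(losses)
      epoch_acc[epoch] <- acc
      if (acc > best_acc) {
        best_acc <- acc; best_epoch <- epoch; best_model <- model; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) { stopped_epoch <- epoch; break }
      }
      stopped_epoch <- epoch
    }
  })
  log <- data.frame(epoch = seq_along(epoch_loss), train_loss = epoch_loss,
                    val_accuracy = epoch_acc)
  list(model = best_model, log = log, best_epoch = best_epoch,
       stopped_epoch = stopped_epoch, best_val_accuracy = best_acc)
}

#' k-fold cross-validation of a network specification
#'
#' For each fold, the model is rebuilt (fresh initialization), trained on
#' the remaining folds with the held-out fold as early-stopping validation
#' set, and scored by accuracy on the held-out fold.
#'
#' @param spec A [network_spec()].
#' @param masks Relationship matrices for map layers (see [build_network()]).
#' @param x,y Feature matrix and binary labels (training cohort).
#' @param fold Integer fold assignment per row of `x`.
#' @param config A [training_config()].
#' @return List with `mean_accuracy` and `fold_accuracy`.
#' @export
cross_validate <- function(spec, masks = NULL, x, y, fold,
                           config = training_config()) {
  stopifnot(nrow(x) == length(y), length(fold) == length(y))
  folds <- sort(unique(fold))
  accs <- vapply(seq_along(folds), function(k) {
    hold <- fold == folds[k]
    if (length(unique(y[hold])) < 2 || length(unique(y[!hold])) < 2) {
      stop("fold ", folds[k], " leaves a single class on one side")
    }
    model <- build_network(spec, masks = masks, seed = config$seed + k)
    fit <- train(model, x[!hold, , drop = FALSE], y[!hold],
                 x[hold, , drop = FALSE], y[hold], config = config)
    accuracy(predict_proba(fit$model, x[hold, , drop = FALSE]), y[hold])
  }, numeric(1))
  list(mean_accuracy = mean(accs), fold_accuracy = accs)
}

#' Greedy layer-by-layer architecture search
#'
#' Grid-searches the width of the first dense layer over `widths`
#' (2, 4, ..., 512 by default), then repeatedly adds a further dense layer
#' restricted to widths strictly smaller than the previously chosen one
#' (earlier layers are reinitialized for every candidate, which is implicit
#' here because the evaluator fits each candidate from scratch). The search
#' stops when adding a layer does not improve the best score. Ties are
#' broken toward the smaller width.
#'
#' @param evaluator `function(widths)` returning the cross-validation
#'   accuracy of the network whose dense stack has the given widths (any
#'   fsl/map prefix is the evaluator's responsibility); see
#'   [cv_evaluator()].
#' @param widths Candidate widths for the first layer.
#' @return List with `widths` (chosen, strictly decreasing), `accuracy`
#'   (best score) and `table` (`data.frame` of all evaluated candidates).
#' @export
architecture_search <- function(evaluator, widths = 2^(1:9)) {
  chosen <- integer(0)
  best <- -Inf
  rows <- list()
  repeat {
    cand <- if (length(chosen) == 0) widths else widths[widths < chosen[length(chosen)]]
    if (length(cand) == 0) break
    cand <- sort(cand)
    scores <- vapply(cand, function(w) evaluator(c(chosen, w)), numeric(1))
    for (j in seq_along(cand)) {
      rows[[length(rows) + 1]] <- data.frame(depth = length(chosen) + 1L,
                                             width = cand[j], accuracy = scores[j])
    }
    j_best <- which.max(scores)  # first max -> smallest width on ties
    if (scores[j_best] > best) {
      best <- scores[j_best]
      chosen <- c(chosen, cand[j_best])
    } else break
  }
  list(widths = chosen, accuracy = best, table = do.call(rbind, rows))
}

#' Cross-validation evaluator for the architecture search
#'
#' Builds, for a vector of dense widths, the network `prefix_layers` +
#' dense stack + sigmoid output and returns its mean CV accuracy.
#'
#' @param input_dim Input feature count.
#' @param prefix_layers List of [layer_spec()]s placed before the dense
#'   stack (e.g. an FSL and/or a map layer).
#' @param masks Relationship matrices for the prefix map layers.
#' @param x,y,fold,config As in [cross_validate()].
#' @return `function(widths) -> accuracy`, suitable for
#'   [architecture_search()].
#' @export
cv_evaluator <- function(input_dim, prefix_layers = list(), masks = NULL,
                         x, y, fold, config = training_config()) {
  force(list(input_dim, prefix_layers, masks, x, y, fold, config))
  function(widths) {
    dense <- lapply(widths, function(w) layer_spec("dense", w))
    spec <- network_spec(input_dim, c(prefix_layers, dense),
                         dropout = config$dropout, fsl_l1 = config$fsl_l1)
    cross_validate(spec, masks, x, y, fold, config)$mean_accuracy
  }
}

#' Logistic regression by Newton-Raphson (optional ridge)
#'
#' Maximizes the Bernoulli log-likelihood (minus `l2 * ||beta||^2` on the
#' slopes) to gradient max-norm below `tol`. Under perfect separation with
#' `l2 = 0` the likelihood has no finite optimum; a warning is emitted and
#' the current iterate returned.
#'
#' @param X Sample x feature matrix.
#' @param y Binary labels.
#' @param l2 Ridge penalty weight on the slopes (intercept unpenalized).
#' @param max_iter,tol Solver controls.
#' @return List with `intercept`, `coefficients`, `converged`, `n_iter`.
#' @export
fit_logistic <- function(X, y, l2 = 0, max_iter = 200, tol = 1e-8) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  Xd <- cbind(1, X)
  pen <- c(0, rep(l2, ncol(X)))
  beta <- numeric(ncol(Xd))
  obj <- function(b) {
    eta <- drop(Xd %*% b)
    -sum(y * eta - log1p(exp(eta))) + sum(pen * b^2)
  }
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    p <- sigmoid(eta)
    grad <- drop(crossprod(Xd, y - p)) - 2 * pen * beta
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(Xd, Xd * w) + diag(2 * pen, ncol(Xd))
    step <- solve(H, grad)
    f0 <- obj(beta)
    alpha <- 1
    while (obj(beta + alpha * step) > f0 && alpha > 1e-10) alpha <- alpha / 2
    beta <- beta + alpha * step
  }
  p <- sigmoid(drop(Xd %*% beta))
  separated <- l2 == 0 && all((p > 0.5) == (y == 1)) &&
    all(pmin(p, 1 - p) < 1e-4)
  if (separated) {
    warning("perfect separation detected; returning current iterate")
  } else if (!converged) {
    warning("fit_logistic did not reach the gradient tolerance in ",
            max_iter, " iterations")
  }
  list(intercept = beta[1], coefficients = beta[-1], converged = converged,
       n_iter = it)
}

#' Predict probabilities from a linear fit
#'
#' @param fit Result of [fit_logistic()] or [fit_elastic_net()].
#' @param X Feature matrix.
#' @return Probability vector.
#' @export
predict_linear <- function(fit, X) {
  sigmoid(drop(as.matrix(X) %*% fit$coefficients) + fit$intercept)
}

#' Elastic-net logistic regression by proximal gradient
#'
#' Minimizes `mean BCE + l1 * ||beta||_1 + l2 * ||beta||^2` over the slopes
#' (intercept unpenalized) with backtracking proximal-gradient steps; the
#' objective decreases monotonically until the change falls below `tol`.
#'
#' @param X Sample x feature matrix.
#' @param y Binary labels.
#' @param l1,l2 Penalty weights (defaults 0.0005 each).
#' @param max_iter,tol Solver controls.
#' @return List with `intercept`, `coefficients`, `objective`, `converged`,
#'   `n_iter`.
#' @export
fit_elastic_net <- function(X, y, l1 = 5e-4, l2 = 5e-4, max_iter = 100000,
                            tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == length(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  beta <- numeric(ncol(X)); b0 <- 0
  smooth_obj <- function(b0, beta) {
    eta <- drop(X %*% beta) + b0
    mean(pmax(eta, 0) - y * eta + log1p(exp(-abs(eta)))) + l2 * sum(beta^2)
  }
  full_obj <- function(b0, beta) smooth_obj(b0, beta) + l1 * sum(abs(beta))
  # Lipschitz bound for the smooth part
  L <- (svd(cbind(1, X), nu = 0, nv = 0)$d[1]^2) / (4 * n) + 2 * l2
  step <- 1 / L
  f_prev <- full_obj(b0, beta)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + b0
    r <- (sigmoid(eta) - y) / n
    g_beta <- drop(crossprod(X, r)) + 2 * l2 * beta
    g_b0 <- sum(r)
    s <- step
    repeat {
      nb <- beta - s * g_beta
      nb <- sign(nb) * pmax(abs(nb) - s * l1, 0)  # soft threshold
      nb0 <- b0 - s * g_b0
      f_new <- full_obj(nb0, nb)
      if (f_new <= f_prev + 1e-15 || s < 1e-14) break
      s <- s / 2
    }
    move <- max(abs(c(nb - beta, nb0 - b0)))
    beta <- nb; b0 <- nb0; f_prev <- f_new
    if (move < tol) { converged <- TRUE; break }
  }
  list(intercept = b0, coefficients = beta, objective = f_prev,
       converged = converged, n_iter = it)
}
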