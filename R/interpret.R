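# Model interpretation: saliency-map importance (mean absolute gradient of
# the pre-sigmoid output w.r.t. each input feature), FSL weight export, and
# top-fraction feature selection.

#' Saliency-map feature importance
#'
#' `score_k = mean over samples of |d logit / d x_k|`, where the gradient is
#' taken at the pre-sigmoid output (avoiding sigmoid saturation) with
#' dropout disabled.
#'
#' @param model A trained `isonet` model.
#' @param X Sample x feature matrix (nonempty).
#' @return Named non-negative numeric vector, one score per input feature.
#' @export
saliency_importance <- function(model, X) {
  stopifnot(inherits(model, "isonet"))
  if (!is.matrix(X) || nrow(X) == 0) stop("X must be a nonempty sample matrix")
  lg <- nn_loss_grad(model, X, logit_grad = TRUE, input_grad = TRUE)
  scores <- colMeans(abs(lg$input_grad))
  names(scores) <- if (!is.null(model$feature_ids)) model$feature_ids else colnames(X)
  scores
}

#' FSL weights as feature importance
#'
#' Returns the learned non-negative Feature Selection Layer weights, keyed
#' by feature id.
#'
#' @param model An `isonet` model containing an FSL.
#' @return Named non-negative numeric vector.
#' @export
fsl_importance <- function(model) {
  stopifnot(inherits(model, "isonet"))
  fsl <- Filter(function(l) l$kind == "fsl", model$layers)
  if (length(fsl) == 0) stop("model contains no Feature Selection Layer")
  w <- fsl[[1]]$w
  names(w) <- if (!is.null(model$feature_ids)) model$feature_ids else names(w)
  w
}

#' Top fraction of features by importance
#'
#' The `ceiling(q * n)` features with the highest scores; ties at the
#' cutoff are broken by lexicographic feature id.
#'
#' @param importance Named numeric importance vector.
#' @param q Fraction in `(0, 1]` (default 0.2).
#' @return Character vector of selected feature ids.
#' @export
top_fraction <- function(importance, q = 0.2) {
  if (length(importance) == 0) stop("empty importance vector")
  stopifnot(q > 0, q <= 1, !is.null(names(importance)))
  k <- ceiling(q * length(importance))
  o <- order(-importance, names(importance))
  names(importance)[o[seq_len(k)]]
}

#' Summary of an importance vector
#'
#' Count and fraction of strictly positive scores, plus log10 of the
#' positive scores for plotting.
#'
#' @param importance Numeric importance vector.
#' @return List with `n`, `n_nonzero`, `fraction_nonzero`, `log10_scores`.
#' @export
importance_summary <- function(importance) {
  nz <- importance > 0
  list(n = length(importance), n_nonzero = sum(nz),
       fraction_nonzero = if (length(importance)) mean(nz) else NA_real_,
       log10_scores = log10(importance[nz]))
}
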