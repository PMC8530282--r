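# Count-matrix preprocessing: CPM, expression filters, TMM / upper-quartile
# scaling factors, log2-CPM transform, quantile normalization, covariate
# adjustment and stratified data splitting.

check_counts <- function(counts) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicate feature or sample ids in count matrix")
  }
  invisible(counts)
}

#' Counts per million
#'
#' Scales each column by its raw library size (column sum of the full input
#' matrix, before any filtering) times 1e6.
#'
#' @param counts Non-negative feature x sample matrix.
#' @return Matrix of linear CPM values, same dimnames.
#' @export
compute_cpm <- function(counts) {
  check_counts(counts)
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    bad <- colnames(counts)[libsize == 0]
    if (is.null(bad)) bad <- which(libsize == 0)
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2, libsize, "/") * 1e6
}

#' Expression filter on CPM scale
#'
#' A feature is removed when its mean CPM is below `low_mean_cpm`, or when
#' fewer than `min_samples` samples reach CPM > `min_cpm`. Additionally,
#' extreme features with CPM > `high_cpm` in at least one but fewer than
#' `high_max_samples` samples are removed. CPM uses the full pre-filter
#' library sizes.
#'
#' @param counts Count matrix.
#' @param low_mean_cpm,min_cpm,min_samples,high_cpm,high_max_samples Filter
#'   thresholds (defaults follow the blood RNA-seq pipeline: 0.2 / 0.5 in
#'   >= 50 subjects / 50,000 in < 50 subjects).
#' @return Character vector of kept feature ids, in input order.
#' @export
filter_features <- function(counts, low_mean_cpm = 0.2, min_cpm = 0.5,
                            min_samples = 50, high_cpm = 50000,
                            high_max_samples = 50) {
  stopifnot(low_mean_cpm > 0, min_cpm > 0, high_cpm > 0)
  if (min_samples > ncol(counts)) {
    warning("min_samples (", min_samples, ") exceeds the number of samples (",
            ncol(counts), "); the low-expression prevalence rule removes all features")
  }
  cpm <- compute_cpm(counts)
  low <- rowMeans(cpm) < low_mean_cpm | rowSums(cpm > min_cpm) < min_samples
  n_high <- rowSums(cpm > high_cpm)
  high <- n_high >= 1 & n_high < high_max_samples
  rownames(counts)[!(low | high)]
}

# TMM factor of one sample against the reference column; literal
# transcription of the canonical trimmed-mean-of-M-values definition:
# M/A over doubly-expressed features, two-sided rank trimming (30% on M,
# 5% on A), precision-weighted mean of M.
tmm_one <- function(obs, ref, lib_obs, lib_ref, logratio_trim = 0.3,
                    sum_trim = 0.05, acutoff = -1e10) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  logR <- log2((obs / lib_obs) / (ref / lib_ref))
  absE <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / lib_obs / obs + (lib_ref - ref) / lib_ref / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > acutoff)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0) {
    warning("sample shares no expressed features with the TMM reference; factor set to 1")
    return(1)
  }
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values between-sample normalization. The reference is
#' the sample whose 75th-percentile CPM is closest to the mean 75th
#' percentile; per sample, log-ratios (M) and average log-abundances (A)
#' over doubly-expressed features are trimmed two-sidedly (`logratio_trim`
#' on M, `sum_trim` on A) and the precision-weighted mean M gives the log2
#' factor. Factors are rescaled to geometric mean 1.
#'
#' @param counts Count matrix (>= 2 samples).
#' @param logratio_trim,sum_trim Two-sided trim fractions for M and A.
#' @return Named numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  check_counts(counts)
  if (ncol(counts) < 2) stop("TMM requires at least 2 samples")
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("zero library size for sample(s): ",
                              paste(colnames(counts)[libsize == 0], collapse = ", "))
  x <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  f75 <- vapply(seq_len(ncol(x)), function(j) {
    stats::quantile(x[, j], probs = 0.75, names = FALSE) / libsize[j]
  }, numeric(1))
  if (stats::median(f75) < 1e-20) {
    ref <- which.max(colSums(sqrt(x)))
  } else {
    ref <- which.min(abs(f75 - mean(f75)))
  }
  f <- vapply(seq_len(ncol(x)), function(i) {
    tmm_one(x[, i], x[, ref], libsize[i], libsize[ref],
            logratio_trim = logratio_trim, sum_trim = sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Upper-quartile scaling factors
#'
#' Alternative normalizer: per-sample 75th percentile of counts divided by
#' library size, rescaled to geometric mean 1. Same interface as
#' [tmm_factors()].
#'
#' @param counts Count matrix.
#' @return Named numeric vector of per-sample scaling factors.
#' @export
uq_factors <- function(counts) {
  check_counts(counts)
  libsize <- colSums(counts)
  x <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  f <- vapply(seq_len(ncol(x)), function(j) {
    stats::quantile(x[, j], probs = 0.75, names = FALSE)
  }, numeric(1)) / libsize
  if (any(f == 0)) stop("upper-quartile factor is zero for sample(s): ",
                        paste(colnames(counts)[f == 0], collapse = ", "))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Normalization factors by method name
#'
#' @param counts Count matrix.
#' @param method `"tmm"`, `"uq"` (upper quartile) or `"none"`.
#' @return Named numeric vector of per-sample factors.
#' @export
normalize_factors <- function(counts, method = c("tmm", "uq", "none")) {
  method <- match.arg(method)
  switch(method,
         tmm = tmm_factors(counts),
         uq = uq_factors(counts),
         none = stats::setNames(rep(1, ncol(counts)), colnames(counts)))
}

#' log2-CPM transform with effective library sizes
#'
#' `log2((count + 0.5) / (libsize * factor + 1) * 1e6)` where `libsize` is
#' the raw column sum and `factor` the normalization factor.
#'
#' @param counts Count matrix.
#' @param factors Positive per-sample scaling factors (recycled if scalar).
#' @return Matrix of log2-CPM values.
#' @export
log2_cpm <- function(counts, factors = 1) {
  check_counts(counts)
  factors <- rep_len(factors, ncol(counts))
  if (any(factors <= 0)) stop("normalization factors must be positive")
  eff <- colSums(counts) * factors
  log2(sweep(counts + 0.5, 2, eff + 1, "/") * 1e6)
}

#' Quantile normalization
#'
#' Forces every column's value distribution onto the across-sample mean of
#' order statistics; ties within a column receive the average of the
#' reference values at the tied ranks.
#'
#' @param expr Numeric feature x sample matrix (>= 2 samples).
#' @return Quantile-normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2) stop("quantile normalization requires at least 2 samples")
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Remove covariate effects while retaining the class main effect
#'
#' Fits, per feature, an ordinary least-squares model with intercept, class
#' label and covariates as explanatory variables, and subtracts only the
#' fitted covariate contributions. Categorical covariates are one-hot
#' encoded with first-level reference.
#'
#' @param expr Expression matrix (features x samples).
#' @param samples Sample table (`data.frame` with `sample_id`, `label`, and
#'   covariate columns), rows matching `colnames(expr)`.
#' @param covariate_names Character vector of covariate column names.
#' @return Adjusted expression matrix.
#' @export
adjust_covariates <- function(expr, samples, covariate_names) {
  stopifnot(is.matrix(expr), all(covariate_names %in% names(samples)))
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("samples table does not cover all expression columns")
  cov_df <- samples[, covariate_names, drop = FALSE]
  C <- stats::model.matrix(~ ., data = cov_df)[, -1, drop = FALSE]
  design <- cbind(Intercept = 1, label = samples$label)
  full <- cbind(design, C)
  qrf <- qr(full)
  if (qrf$rank < ncol(full)) {
    dropped <- colnames(full)[qrf$pivot[(qrf$rank + 1):ncol(full)]]
    stop("design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  out <- limma::removeBatchEffect(expr, covariates = C, design = design)
  dimnames(out) <- dimnames(expr)
  out
}

# Largest-remainder apportionment of n units to parts proportional to
# weights, with the exact total preserved.
apportion <- function(n, weights) {
  ideal <- n * weights / sum(weights)
  base <- floor(ideal)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Stratified train/validation/test split with CV folds
#'
#' Randomly partitions samples into train/validation/test sets of the exact
#' requested sizes, stratified by label, and assigns training samples to
#' `n_folds` near-equal, label-stratified cross-validation folds.
#' Deterministic given `seed`.
#'
#' @param samples Sample table with `sample_id` and binary `label`.
#' @param sizes Integer vector `c(train, validation, test)` summing to
#'   `nrow(samples)`.
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed.
#' @return `data.frame` with columns `sample_id`, `split` (train /
#'   validation / test) and `fold` (1..n_folds for training samples, NA
#'   otherwise).
#' @export
split_dataset <- function(samples, sizes, n_folds = 5, seed = 1) {
  stopifnot(length(sizes) == 3)
  if (sum(sizes) != nrow(samples)) {
    stop("sizes must sum to the number of samples (", nrow(samples), "), got ",
         sum(sizes))
  }
  split <- rep(NA_character_, nrow(samples))
  fold <- rep(NA_integer_, nrow(samples))
  with_seed(seed, {
    for (lab in unique(samples$label)) {
      idx <- sample(which(samples$label == lab))
      # exact per-label allocation proportional to requested split sizes
      alloc <- apportion(length(idx), sizes)
      # reconcile so that global split sizes are met exactly across labels:
      # largest-remainder is applied label by label and then corrected
      split[idx] <- rep(c("train", "validation", "test"), alloc)
      tr <- idx[seq_len(alloc[1])]
      fold[tr] <- rep_len(seq_len(n_folds), length(tr))
    }
    # correct any global size drift introduced by per-label rounding
    nm <- c("train", "validation", "test")
    cur <- vapply(nm, function(x) sum(split == x), integer(1))
    over <- which(cur > sizes)
    under <- which(cur < sizes)
    while (length(over) > 0 && length(under) > 0) {
      o <- nm[over[1]]; u <- nm[under[1]]
      mv <- sample(which(split == o), 1)
      split[mv] <- u
      fold[mv] <- if (u == "train") sample(seq_len(n_folds), 1) else NA_integer_
      cur <- vapply(nm, function(x) sum(split == x), integer(1))
      over <- which(cur > sizes)
      under <- which(cur < sizes)
    }
  })
  data.frame(sample_id = samples$sample_id, split = split, fold = fold,
             stringsAsFactors = FALSE)
}

#' Restrict a count matrix to features of a gene panel
#'
#' @param counts Count matrix.
#' @param gene_panel Character vector of gene ids to keep.
#' @param feature_to_gene Named character vector mapping every feature id to
#'   its gene id.
#' @return The subset count matrix (feature order preserved).
#' @export
restrict_to_panel <- function(counts, gene_panel, feature_to_gene) {
  ids <- rownames(counts)
  unmapped <- setdiff(ids, names(feature_to_gene))
  if (length(unmapped) > 0) {
    stop("features missing from feature_to_gene map: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  }
  keep <- feature_to_gene[ids] %in% gene_panel
  if (!any(keep)) warning("gene panel matches no features; returning empty matrix")
  counts[keep, , drop = FALSE]
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
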