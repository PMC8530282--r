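# Shared experiment drivers for the synthetic-study checks: preprocess a
# count matrix, train a network, and evaluate held-out AUC. The training
# protocol is the study protocol (Adam 3e-4, 40 epochs, dropout 0.2,
# patience 10, FSL L1 5e-4) with batch size 32, suited to cohorts ~20x
# smaller than the original study.

study_config <- function(seed) training_config(batch_size = 32, seed = seed)

study_split <- function(samples, seed) {
  n <- nrow(samples)
  n_tr <- round(0.6 * n)
  n_va <- round(0.2 * n)
  split_dataset(samples, c(n_tr, n_va, n - n_tr - n_va), seed = seed)
}

# Train `layers` on one resolution of a synthetic dataset and return the
# held-out test AUC plus the fitted model and feature matrix.
train_eval <- function(counts, labels, split, layers, masks = NULL, seed = 1) {
  x <- prep_features(counts)
  tr <- split$split == "train"
  va <- split$split == "validation"
  te <- split$split == "test"
  model <- build_network(network_spec(ncol(x), layers), masks = masks,
                         seed = seed)
  fit <- train(model, x[tr, , drop = FALSE], labels[tr],
               x[va, , drop = FALSE], labels[va], config = study_config(seed))
  list(auc = roc_auc(predict_proba(fit$model, x[te, , drop = FALSE]), labels[te]),
       fit = fit, x = x)
}

# Exon+IML network vs gene-level dense network on one simulated cohort.
signal_experiment <- function(seed, switch_delta = 0.35, n_per_class = 300) {
  spec <- synthetic_spec(seed = seed, switch_delta = switch_delta,
                         n_per_class = n_per_class)
  ds <- suppressWarnings(simulate_dataset(spec))
  split <- study_split(ds$samples, seed)
  y <- ds$samples$label
  exon <- train_eval(ds$counts_exon, y, split,
                     list(layer_spec("iml"), layer_spec("dense", 32)),
                     masks = ds$annotation$iso_map, seed = seed)
  gene <- train_eval(ds$counts_gene, y, split,
                     list(layer_spec("dense", 32)), seed = seed)
  c(exon = exon$auc, gene = gene$auc)
}

# Sparse-signal recovery: 600 exon features, 8 effect genes (16 informative
# private parts), exon+IML+FSL model; returns top-20% recall of the planted
# informative exons for saliency and FSL importance.
recovery_experiment <- function(seed) {
  spec <- synthetic_spec(n_genes = 120, parts_per_isoform = 4,
                         n_effect_genes = 8, seed = seed)
  ds <- suppressWarnings(simulate_dataset(spec))
  split <- study_split(ds$samples, seed)
  y <- ds$samples$label
  res <- train_eval(ds$counts_exon, y, split,
                    list(layer_spec("fsl"), layer_spec("iml"),
                         layer_spec("dense", 32)),
                    masks = ds$annotation$iso_map, seed = seed)
  tr <- split$split == "train"
  sal <- saliency_importance(res$fit$model, res$x[tr, , drop = FALSE])
  fw <- fsl_importance(res$fit$model)
  names(fw) <- colnames(res$x)
  info <- ds$truth$informative_exons
  list(recall_saliency = mean(info %in% top_fraction(sal, 0.2)),
       recall_fsl = mean(info %in% top_fraction(fw, 0.2)),
       saliency = sal, informative = info, auc = res$auc)
}
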