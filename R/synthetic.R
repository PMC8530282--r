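# Synthetic isoform-switch data generator. Produces a toy annotation,
# negative-binomial counts at exon-part / isoform / gene resolution, and the
# planted truth. The class signal is a shift in isoform usage proportions
# with gene-level totals that are class-invariant by construction, so any
# detectable signal is purely isoform-usage driven.

#' Specification of a synthetic isoform-switch dataset
#'
#' Defaults define the reference study conditions: 60 genes with 2 isoforms
#' each, 15 effect genes whose class-1 samples shift `switch_delta` = 0.35
#' of usage mass from isoform 1 to isoform 2, 300 samples per class,
#' negative-binomial dispersion 0.1, log-normal gene baselines.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Isoforms per gene (>= 2 so usage can switch).
#' @param parts_per_isoform Exonic parts per isoform (>= 2 so each isoform
#'   has at least one private and one shared part).
#' @param n_per_class Samples per class.
#' @param n_effect_genes Genes with differential isoform usage.
#' @param switch_delta Usage-proportion mass moved from isoform 1 to
#'   isoform 2 in class 1, in `[0, 1]`.
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`); ignored when `poisson = TRUE`.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline expression.
#' @param library_size_mean Mean per-sample library scaling factor.
#' @param library_size_cv Coefficient of variation of the library scaling.
#' @param poisson Draw Poisson counts (the `nb_dispersion -> 0` limit).
#' @param length_weight Weight exon-part means by part length (default
#'   off: parts contribute equally).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 60, isoforms_per_gene = 2,
                           parts_per_isoform = 3, n_per_class = 300,
                           n_effect_genes = 15, switch_delta = 0.35,
                           nb_dispersion = 0.1, baseline_meanlog = log(100),
                           baseline_sdlog = 1, library_size_mean = 1,
                           library_size_cv = 0.2, poisson = FALSE,
                           length_weight = FALSE, seed = 1) {
  stopifnot(n_genes >= 1, isoforms_per_gene >= 2, n_per_class >= 2,
            n_effect_genes <= n_genes, switch_delta >= 0, switch_delta <= 1,
            nb_dispersion > 0 || poisson)
  if (parts_per_isoform < 2) {
    stop("parts_per_isoform must be >= 2 so every isoform has a private and a shared part")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Build the toy annotation of a synthetic spec
#'
#' Per gene, every isoform consists of `parts_per_isoform - 1` exons shared
#' by all isoforms plus one private exon, so after flattening each isoform
#' has at least one private and one shared exonic part. The annotation is
#' flattened and its relationship matrices built through the annotation
#' module.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `exons`, `parts`, `iso_map`, `gene_map`, `gene_ids`,
#'   `transcript_ids`.
#' @export
make_toy_annotation <- function(spec) {
  K <- spec$isoforms_per_gene
  S <- spec$parts_per_isoform - 1L  # shared exons per gene
  exon_len <- 100L; gap <- 50L
  recs <- list()
  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  for (g in seq_len(spec$n_genes)) {
    base <- (g - 1L) * 100000L + 1L
    n_ex <- S + K
    starts <- base + (seq_len(n_ex) - 1L) * (exon_len + gap)
    ends <- starts + exon_len - 1L
    for (k in seq_len(K)) {
      tx <- sprintf("%s.T%d", gene_ids[g], k)
      use <- c(seq_len(S), S + k)  # shared exons + private exon k
      recs[[length(recs) + 1]] <- data.frame(
        chrom = "chrS", start = starts[use], end = ends[use], strand = "+",
        gene_id = gene_ids[g], transcript_id = tx, stringsAsFactors = FALSE)
    }
  }
  exons <- do.call(rbind, recs)
  rownames(exons) <- NULL
  parts <- exonic_parts(exons)
  list(exons = exons, parts = parts,
       iso_map = build_isoform_map(parts, exons),
       gene_map = build_gene_map(parts, gene_ids),
       gene_ids = gene_ids,
       transcript_ids = unique(exons$transcript_id))
}

#' Simulate per-class isoform usage proportions
#'
#' Class-0 usage is symmetric Dirichlet(alpha = 5) per gene; for effect
#' genes, class 1 moves `switch_delta` of usage mass from isoform 1 to
#' isoform 2 (clamped and renormalized with a warning if the shift would
#' leave a proportion outside `[0, 1]`). Non-effect genes are identical
#' across classes.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `usage0`, `usage1` (gene x isoform matrices, rows sum
#'   to 1) and `effect_genes` (character ids).
#' @export
simulate_usage <- function(spec) {
  K <- spec$isoforms_per_gene
  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  with_seed(spec$seed + 1L, {
    g <- matrix(stats::rgamma(spec$n_genes * K, shape = 5, rate = 1),
                spec$n_genes, K)
    usage0 <- g / rowSums(g)
    effect <- sort(sample(spec$n_genes, spec$n_effect_genes))
  })
  dimnames(usage0) <- list(gene_ids, sprintf("iso%d", seq_len(K)))
  usage1 <- usage0
  u1 <- usage1[effect, 1] - spec$switch_delta
  u2 <- usage1[effect, 2] + spec$switch_delta
  if (any(u1 < 0) || any(u2 > 1)) {
    warning("switch_delta pushes usage outside [0, 1] for some genes; clamping and renormalizing")
    u1 <- pmax(u1, 0); u2 <- pmin(u2, 1)
  }
  usage1[effect, 1] <- u1
  usage1[effect, 2] <- u2
  usage1 <- usage1 / rowSums(usage1)
  list(usage0 = usage0, usage1 = usage1, effect_genes = gene_ids[effect])
}

rcounts <- function(n, mu, spec) {
  if (spec$poisson) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / spec$nb_dispersion, mu = mu)
}

#' Draw counts for a synthetic dataset
#'
#' Per-gene baselines are log-normal and shared across classes; isoform
#' means are baseline x usage x per-sample library scaling; exon-part means
#' are the mask-weighted sums of isoform means. Isoform counts are negative
#' binomial, gene counts are the exact per-gene sums of isoform counts (so
#' gene totals carry no class signal for effect genes), and exon counts are
#' independent negative-binomial draws at the exon-part means.
#'
#' @param spec A [synthetic_spec()].
#' @param annotation Result of [make_toy_annotation()].
#' @param usage Result of [simulate_usage()].
#' @return A `synthetic_dataset` list: `annotation`, `counts_exon`,
#'   `counts_isoform`, `counts_gene`, `samples`, `truth` (effect genes,
#'   informative exon ids, per-class usage), `spec`.
#' @export
sample_counts <- function(spec, annotation, usage) {
  K <- spec$isoforms_per_gene
  n <- 2L * spec$n_per_class
  gene_ids <- annotation$gene_ids
  tx_ids <- annotation$transcript_ids
  labels <- rep(c(0L, 1L), each = spec$n_per_class)
  sample_ids <- sprintf("S%04d", seq_len(n))
  R <- annotation$iso_map[, tx_ids, drop = FALSE]
  storage.mode(R) <- "double"
  part_w <- if (spec$length_weight) {
    w <- with(annotation$parts, end - start + 1)
    w / mean(w)
  } else rep(1, nrow(annotation$parts))
  # transcript k of gene g in column order tx_ids = gene-major
  tx_gene <- match(sub("\\.T\\d+$", "", tx_ids), gene_ids)
  tx_iso <- as.integer(sub("^.*\\.T", "", tx_ids))
  with_seed(spec$seed + 2L, {
    gene_mean <- stats::rlnorm(spec$n_genes, spec$baseline_meanlog, spec$baseline_sdlog)
    sf <- spec$library_size_mean *
      stats::rlnorm(n, -spec$library_size_cv^2 / 2, spec$library_size_cv)
    # isoform expected means per sample (transcripts x samples)
    usage_by_tx <- cbind(usage$usage0[cbind(tx_gene, tx_iso)],
                         usage$usage1[cbind(tx_gene, tx_iso)])
    mu_iso <- outer(gene_mean[tx_gene], sf) *
      usage_by_tx[, labels + 1L, drop = FALSE]
    counts_iso <- matrix(rcounts(length(mu_iso), mu_iso, spec), nrow(mu_iso),
                         dimnames = list(tx_ids, sample_ids))
    mu_exon <- (R %*% mu_iso) * part_w
    counts_exon <- matrix(rcounts(length(mu_exon), mu_exon, spec), nrow(mu_exon),
                          dimnames = list(rownames(annotation$iso_map), sample_ids))
    counts_gene <- rowsum(counts_iso, gene_ids[tx_gene])[gene_ids, , drop = FALSE]
    age <- round(stats::rnorm(n, 60, 8), 1)
    sex <- stats::rbinom(n, 1, 0.5)
  })
  # informative exons: parts whose expected mean differs between classes
  d0 <- drop(R %*% usage$usage0[cbind(tx_gene, tx_iso)])
  d1 <- drop(R %*% usage$usage1[cbind(tx_gene, tx_iso)])
  informative <- rownames(annotation$iso_map)[abs(d1 - d0) > 1e-9]
  samples <- data.frame(sample_id = sample_ids, label = labels, age = age,
                        sex = factor(ifelse(sex == 1, "M", "F")),
                        stringsAsFactors = FALSE)
  structure(list(annotation = annotation, counts_exon = counts_exon,
                 counts_isoform = counts_iso, counts_gene = counts_gene,
                 samples = samples,
                 truth = list(effect_genes = usage$effect_genes,
                              informative_exons = informative,
                              usage0 = usage$usage0, usage1 = usage$usage1),
                 spec = spec),
            class = "synthetic_dataset")
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper: annotation, usage and counts from one spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_dataset`; see [sample_counts()].
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  annotation <- make_toy_annotation(spec)
  usage <- simulate_usage(spec)
  sample_counts(spec, annotation, usage)
}

#' Export a synthetic dataset to a directory
#'
#' Writes `parts.gtf`, `counts_exon.tsv`, `counts_isoform.tsv`,
#' `counts_gene.tsv`, `phenotype.tsv` and `truth.json`; files round-trip
#' losslessly through the package readers (see [read_dataset()]).
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
export_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_parts_gtf(ds$annotation$parts, file.path(dir, "parts.gtf"))
  write_feature_matrix(ds$counts_exon, file.path(dir, "counts_exon.tsv"))
  write_feature_matrix(ds$counts_isoform, file.path(dir, "counts_isoform.tsv"))
  write_feature_matrix(ds$counts_gene, file.path(dir, "counts_gene.tsv"))
  pheno <- ds$samples
  pheno$sex <- as.character(pheno$sex)
  utils::write.table(pheno, file.path(dir, "phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(effect_genes = ds$truth$effect_genes,
         informative_exons = ds$truth$informative_exons,
         usage0 = ds$truth$usage0, usage1 = ds$truth$usage1),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Read back an exported synthetic dataset
#'
#' @param dir Directory written by [export_dataset()].
#' @return List with `parts`, `counts_exon`, `counts_isoform`,
#'   `counts_gene`, `samples`, `truth`.
#' @export
read_dataset <- function(dir) {
  list(parts = read_parts_gtf(file.path(dir, "parts.gtf")),
       counts_exon = read_feature_matrix(file.path(dir, "counts_exon.tsv")),
       counts_isoform = read_feature_matrix(file.path(dir, "counts_isoform.tsv")),
       counts_gene = read_feature_matrix(file.path(dir, "counts_gene.tsv")),
       samples = read_pheno(file.path(dir, "phenotype.tsv")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
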