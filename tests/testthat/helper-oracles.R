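# Independent oracles and fixture builders shared across tests. Oracles are
# deliberately naive (per-base enumeration, all-pairs counting) and never
# share code with the implementation they check.

# Per-base brute-force flattening: label every base of a gene's exon span
# with the sorted set of transcripts covering it (after merging overlapping
# exons within a transcript), then merge runs of equal non-empty labels.
per_base_parts_oracle <- function(exons) {
  lo <- min(exons$start); hi <- max(exons$end)
  labels <- character(hi - lo + 1)
  for (tx in unique(exons$transcript_id)) {
    covered <- logical(hi - lo + 1)
    ex <- exons[exons$transcript_id == tx, , drop = FALSE]
    for (i in seq_len(nrow(ex))) {
      covered[(ex$start[i] - lo + 1):(ex$end[i] - lo + 1)] <- TRUE
    }
    idx <- which(covered)
    labels[idx] <- ifelse(nzchar(labels[idx]), paste0(labels[idx], ",", tx), tx)
  }
  labels <- vapply(strsplit(labels, ",", fixed = TRUE), function(s) {
    paste(sort(s), collapse = ",")
  }, character(1))
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- nzchar(runs$values)
  data.frame(start = starts[keep] + lo - 1, end = ends[keep] + lo - 1,
             transcripts = runs$values[keep], stringsAsFactors = FALSE)
}

# Interval-containment oracle for the isoform map: part i maps to isoform j
# iff every base of part i lies in isoform j's (merged) exon union.
containment_oracle <- function(parts, exons) {
  tx_ids <- unique(exons$transcript_id)
  R <- matrix(0L, nrow(parts), length(tx_ids),
              dimnames = list(parts$part_id, tx_ids))
  for (j in seq_along(tx_ids)) {
    ex <- exons[exons$transcript_id == tx_ids[j], , drop = FALSE]
    bases <- unique(unlist(Map(seq.int, ex$start, ex$end)))
    for (i in seq_len(nrow(parts))) {
      if (parts$gene_id[i] != ex$gene_id[1]) next
      if (all(seq.int(parts$start[i], parts$end[i]) %in% bases)) R[i, j] <- 1L
    }
  }
  R
}

# Random single-gene toy annotation with span <= 10 kb; transcripts get
# non-overlapping exons by walking the coordinate axis left to right.
random_toy_gene <- function(gene_id = "G1", max_tx = 4, max_exons = 4) {
  n_tx <- sample(1:max_tx, 1)
  recs <- list()
  for (k in seq_len(n_tx)) {
    n_ex <- sample(1:max_exons, 1)
    pos <- sample(1:200, 1)
    starts <- ends <- integer(n_ex)
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      len <- sample(20:400, 1)
      ends[e] <- pos + len - 1
      pos <- ends[e] + sample(1:300, 1) + 1
    }
    recs[[k]] <- data.frame(chrom = "chr1", start = starts, end = ends,
                            strand = "+", gene_id = gene_id,
                            transcript_id = paste0(gene_id, ".T", k),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

# All-pairs Mann-Whitney AUC, quadratic.
auc_pair_oracle <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels != 1]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Write a small multi-gene GTF fixture (3 genes, 7 transcripts) and return
# its path plus the raw lines for line-oriented counting oracles.
write_fixture_gtf <- function(path = tempfile(fileext = ".gtf")) {
  lines <- c(
    '# toy annotation',
    'chr1\tsrc\tgene\t1\t5000\t.\t+\t.\tgene_id "GA";',
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "GA"; transcript_id "GA.1";',
    'chr1\tsrc\texon\t300\t400\t.\t+\t.\tgene_id "GA"; transcript_id "GA.1";',
    'chr1\tsrc\texon\t100\t250\t.\t+\t.\tgene_id "GA"; transcript_id "GA.2";',
    'chr1\tsrc\texon\t120\t220\t.\t+\t.\tgene_id "GA"; transcript_id "GA.3";',
    'chr2\tsrc\texon\t1000\t1100\t.\t-\t.\tgene_id "GB"; transcript_id "GB.1";',
    'chr2\tsrc\texon\t1000\t1100\t.\t-\t.\tgene_id "GB"; transcript_id "GB.2";',
    'chr2\tsrc\texon\t1200\t1300\t.\t-\t.\tgene_id "GB"; transcript_id "GB.2";',
    'chr3\tsrc\texon\t10\t90\t.\t+\t.\tgene_id=GC; transcript_id=GC.1',
    'chr3\tsrc\texon\t10\t60\t.\t+\t.\tgene_id "GC"; transcript_id "GC.2";')
  writeLines(lines, path)
  list(path = path, lines = lines)
}

# Quantile-normalized log2-CPM feature matrix (samples x features) from a
# synthetic dataset's counts, the standard model input used in tests.
prep_features <- function(counts) {
  t(quantile_normalize(log2_cpm(counts, tmm_factors(counts))))
}
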