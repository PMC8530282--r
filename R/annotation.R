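# Annotation handling: GTF parsing, flattening of transcript exons into
# disjoint exonic parts, and construction of the binary exon->isoform /
# exon->gene relationship matrices that constrain the map layers.

#' Parse exon records from a GTF file
#'
#' Reads an Ensembl-dialect GTF and returns one row per exon record. Only
#' `exon` feature lines define transcripts; all other feature types (gene,
#' transcript, CDS, ...) are ignored. Both common attribute dialects are
#' accepted: `key "value";` and `key=value`. Coordinates are kept 1-based
#' inclusive, as in the file.
#'
#' @param path Path to a GTF file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id`, one row per exon, ordered by first
#'   appearance of the transcript and by `start` within each transcript.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  recs <- vector("list", sum(keep))
  k <- 0L
  for (i in which(keep)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L) {
      stop(sprintf("malformed GTF line %d: expected 9 tab-delimited fields, got %d",
                   i, length(fields)))
    }
    if (fields[3] != "exon") next
    attrs <- parse_gtf_attributes(fields[9])
    if (is.na(attrs[["transcript_id"]])) {
      stop(sprintf("GTF line %d: exon record missing transcript_id attribute", i))
    }
    if (is.na(attrs[["gene_id"]])) {
      stop(sprintf("GTF line %d: exon record missing gene_id attribute", i))
    }
    start <- suppressWarnings(as.integer(fields[4]))
    end <- suppressWarnings(as.integer(fields[5]))
    if (is.na(start) || is.na(end) || start < 1L || end < start) {
      stop(sprintf("GTF line %d: invalid coordinates '%s'-'%s'", i, fields[4], fields[5]))
    }
    if (!fields[7] %in% c("+", "-")) {
      stop(sprintf("GTF line %d: exon strand must be '+' or '-', got '%s'", i, fields[7]))
    }
    k <- k + 1L
    recs[[k]] <- data.frame(
      chrom = fields[1], start = start, end = end, strand = fields[7],
      gene_id = attrs[["gene_id"]], transcript_id = attrs[["transcript_id"]],
      stringsAsFactors = FALSE
    )
  }
  if (k == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character(),
                      transcript_id = character(), stringsAsFactors = FALSE))
  }
  exons <- do.call(rbind, recs[seq_len(k)])
  # order: transcripts by first appearance, exons by start within transcript
  tx_order <- unique(exons$transcript_id)
  exons <- exons[order(match(exons$transcript_id, tx_order), exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  exons
}

# Parse a GTF attribute string in either `key "value";` or `key=value`
# dialect; returns a named character vector with at least gene_id and
# transcript_id entries (NA when absent).
parse_gtf_attributes <- function(s) {
  out <- c(gene_id = NA_character_, transcript_id = NA_character_)
  tokens <- strsplit(s, ";", fixed = TRUE)[[1]]
  for (tok in tokens) {
    tok <- trimws(tok)
    if (!nzchar(tok)) next
    m <- regmatches(tok, regexec('^(\\S+)\\s+"([^"]*)"$', tok))[[1]]
    if (length(m) == 0L) {
      m <- regmatches(tok, regexec('^(\\S+)\\s*=\\s*"?([^"]*)"?$', tok))[[1]]
    }
    if (length(m) == 3L) out[m[2]] <- m[3]
  }
  out
}

#' Flatten one gene's transcripts into disjoint exonic parts
#'
#' Breaks the union of a gene's exons into maximal disjoint intervals over
#' which the set of covering transcripts is constant ("exonic parts", the
#' exon-level feature unit). Exons that overlap within a single transcript
#' are merged first with a warning. Flattening is strictly per gene: pass
#' exons of exactly one gene.
#'
#' @param exons A `data.frame` as returned by [parse_gtf()], restricted to a
#'   single `gene_id`.
#' @return A `data.frame` with columns `part_id` (`gene:NNN`, 3-digit
#'   zero-padded ordinal along the genome), `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `transcripts` (comma-joined, lexicographically sorted
#'   transcript ids covering the part).
#' @export
flatten_exonic_parts <- function(exons) {
  stopifnot(is.data.frame(exons), nrow(exons) > 0)
  gene <- unique(exons$gene_id)
  if (length(gene) != 1L) {
    stop("flatten_exonic_parts expects exons from exactly one gene, got: ",
         paste(gene, collapse = ", "))
  }
  pieces <- list()
  for (str in unique(exons$strand)) {
    ex <- exons[exons$strand == str, , drop = FALSE]
    chrom <- unique(ex$chrom)
    if (length(chrom) != 1L) {
      stop("gene ", gene, " has exons on multiple chromosomes: ",
           paste(chrom, collapse = ", "))
    }
    tx_ids <- unique(ex$transcript_id)
    tx_ranges <- lapply(tx_ids, function(t) {
      r <- IRanges::IRanges(start = ex$start[ex$transcript_id == t],
                            end = ex$end[ex$transcript_id == t])
      red <- IRanges::reduce(r)
      if (length(red) < length(r)) {
        warning("transcript ", t, ": overlapping/adjacent exons merged before flattening")
      }
      red
    })
    names(tx_ranges) <- tx_ids
    all_ranges <- do.call(c, unname(tx_ranges))
    dj <- IRanges::disjoin(all_ranges)
    cover <- vapply(seq_along(dj), function(i) {
      hit <- vapply(tx_ranges, function(r) {
        length(IRanges::findOverlaps(dj[i], r, type = "within")) > 0
      }, logical(1))
      paste(sort(tx_ids[hit]), collapse = ",")
    }, character(1))
    # merge adjacent runs with identical covering sets
    st <- IRanges::start(dj); en <- IRanges::end(dj)
    o <- order(st)
    st <- st[o]; en <- en[o]; cover <- cover[o]
    ms <- me <- integer(0); mc <- character(0)
    for (i in seq_along(st)) {
      j <- length(ms)
      if (j > 0 && st[i] == me[j] + 1L && cover[i] == mc[j]) {
        me[j] <- en[i]
      } else {
        ms <- c(ms, st[i]); me <- c(me, en[i]); mc <- c(mc, cover[i])
      }
    }
    pieces[[str]] <- data.frame(
      gene_id = gene, chrom = chrom, start = ms, end = me, strand = str,
      transcripts = mc, stringsAsFactors = FALSE
    )
  }
  parts <- do.call(rbind, pieces)
  parts <- parts[order(parts$start, parts$end), , drop = FALSE]
  parts <- data.frame(
    part_id = sprintf("%s:%03d", gene, seq_len(nrow(parts))),
    parts, stringsAsFactors = FALSE
  )
  rownames(parts) <- NULL
  parts
}

#' Flatten every gene of an annotation into exonic parts
#'
#' Applies [flatten_exonic_parts()] per gene (genes in order of first
#' appearance); overlapping genes are flattened independently.
#'
#' @param exons Exon table from [parse_gtf()].
#' @return A combined exonic-part `data.frame`.
#' @export
exonic_parts <- function(exons) {
  genes <- unique(exons$gene_id)
  out <- lapply(genes, function(g) {
    flatten_exonic_parts(exons[exons$gene_id == g, , drop = FALSE])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

part_transcripts <- function(parts) {
  strsplit(parts$transcripts, ",", fixed = TRUE)
}

#' Build the binary exon-to-isoform relationship matrix
#'
#' Entry `R[i, j] = 1` iff exonic part `i` is contained within isoform `j`
#' (i.e. the part's covering transcript set includes the isoform). Rows
#' follow the part order, columns the supplied transcript order.
#'
#' @param parts Exonic-part table from [flatten_exonic_parts()] or
#'   [exonic_parts()].
#' @param transcripts Character vector of transcript ids fixing the column
#'   order, or an exon table from [parse_gtf()] (column order = first
#'   appearance).
#' @return A binary matrix with `part_id` rownames and transcript colnames.
#' @export
build_isoform_map <- function(parts, transcripts) {
  if (is.data.frame(transcripts)) transcripts <- unique(transcripts$transcript_id)
  stopifnot(!anyDuplicated(transcripts), !anyDuplicated(parts$part_id))
  tx_sets <- part_transcripts(parts)
  unknown <- setdiff(unique(unlist(tx_sets)), transcripts)
  if (length(unknown) > 0) {
    stop("exonic parts reference unknown transcripts: ",
         paste(unknown, collapse = ", "))
  }
  R <- matrix(0L, nrow = nrow(parts), ncol = length(transcripts),
              dimnames = list(parts$part_id, transcripts))
  for (i in seq_len(nrow(parts))) R[i, tx_sets[[i]]] <- 1L
  validate_relationship_matrix(R)
  R
}

#' Build the binary exon-to-gene relationship matrix
#'
#' Exactly one `1` per row, in the column of the part's gene.
#'
#' @param parts Exonic-part table.
#' @param gene_ids Character vector of gene ids fixing the column order.
#' @return A binary matrix with `part_id` rownames and gene colnames.
#' @export
build_gene_map <- function(parts, gene_ids) {
  stopifnot(!anyDuplicated(gene_ids))
  unknown <- setdiff(unique(parts$gene_id), gene_ids)
  if (length(unknown) > 0) {
    stop("exonic parts reference unknown genes: ", paste(unknown, collapse = ", "))
  }
  R <- matrix(0L, nrow = nrow(parts), ncol = length(gene_ids),
              dimnames = list(parts$part_id, gene_ids))
  R[cbind(seq_len(nrow(parts)), match(parts$gene_id, gene_ids))] <- 1L
  validate_relationship_matrix(R)
  R
}

# Relationship-matrix invariants: binary entries, no empty rows, unique ids.
validate_relationship_matrix <- function(R) {
  stopifnot(is.matrix(R))
  if (!all(R %in% c(0, 1))) stop("relationship matrix entries must be 0 or 1")
  if (any(rowSums(R) < 1)) stop("relationship matrix has a row with no nonzero entry")
  if (anyDuplicated(rownames(R)) || anyDuplicated(colnames(R))) {
    stop("relationship matrix row/col ids must be duplicate-free")
  }
  invisible(R)
}

#' Write exonic parts as a GTF file
#'
#' Feature type `exonic_part`; attributes `gene_id`, `part_id` and
#' `transcripts` (comma-joined). Coordinates are written 1-based inclusive
#' (GTF convention).
#'
#' @param parts Exonic-part table.
#' @param path Output path.
#' @export
write_parts_gtf <- function(parts, path) {
  lines <- sprintf(
    '%s\tisomapnet\texonic_part\t%d\t%d\t.\t%s\t.\tgene_id "%s"; part_id "%s"; transcripts "%s";',
    parts$chrom, parts$start, parts$end, parts$strand,
    parts$gene_id, parts$part_id, parts$transcripts
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an exonic-parts GTF written by [write_parts_gtf()]
#'
#' @param path Path to the parts GTF.
#' @return An exonic-part `data.frame`.
#' @export
read_parts_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L) {
      stop(sprintf("malformed parts GTF line %d: expected 9 fields, got %d",
                   i, length(fields)))
    }
    attrs_raw <- fields[9]
    get <- function(key) {
      m <- regmatches(attrs_raw,
                      regexec(sprintf('%s "([^"]*)"', key), attrs_raw))[[1]]
      if (length(m) < 2) NA_character_ else m[2]
    }
    data.frame(part_id = get("part_id"), gene_id = get("gene_id"),
               chrom = fields[1], start = as.integer(fields[4]),
               end = as.integer(fields[5]), strand = fields[7],
               transcripts = get("transcripts"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Write a relationship matrix as dense TSV
#'
#' First column `feature_id` (row ids), remaining columns one per isoform or
#' gene.
#'
#' @param R Binary relationship matrix.
#' @param path Output path.
#' @export
write_relationship_matrix <- function(R, path) {
  df <- data.frame(feature_id = rownames(R), R, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a relationship matrix written by [write_relationship_matrix()]
#'
#' @param path Path to the TSV.
#' @return A binary matrix with dimnames.
#' @export
read_relationship_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  R <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(R) <- "integer"
  rownames(R) <- df[[1]]
  validate_relationship_matrix(R)
  R
}
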