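# Expression quantification (RPKM), differential calling at fixed
# FDR/fold-change thresholds, tissue-preferential genes, homoeolog bias and
# the LTR-proximity expression contrast.

#' Construct an expression matrix object
#'
#' @param counts integer matrix, genes x samples (dimnames required).
#' @param gene_length bp per gene (named or parallel to rows).
#' @param lib_size total mapped reads per sample (>= column sums; defaults
#'   to the column sums).
#' @param meta data.frame of sample metadata (`sample`, `tissue`, ...).
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(counts, gene_length, lib_size = NULL,
                              meta = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be >= 0")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts needs gene and sample dimnames")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0)) stopf("lib_size must be > 0")
  if (any(lib_size < colSums(counts)))
    stopf("lib_size must be >= the column sums")
  if (!is.null(names(gene_length)))
    gene_length <- gene_length[rownames(counts)]
  if (any(is.na(gene_length)) || any(gene_length <= 0))
    stopf("gene_length must be > 0 for every gene")
  structure(list(counts = counts, gene_length = as.numeric(gene_length),
                 lib_size = as.numeric(lib_size), meta = meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Reads per kilobase per million mapped reads
#'
#' RPKM(g, s) = 1e9 * count(g, s) / (lib_size(s) * gene_length(g)).
#'
#' @param mat an [expression_matrix()].
#' @return numeric matrix of RPKM values.
#' @export
rpkm <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  1e9 * sweep(mat$counts / mat$gene_length, 2, mat$lib_size, "/")
}

#' Differential expression by exact binomial test
#'
#' Pooled counts of the two groups are compared per gene with a two-sided
#' exact binomial test against the expected proportion
#' lib_a / (lib_a + lib_b); p-values are Benjamini-Hochberg adjusted across
#' genes.  log2 ratios come from group-mean RPKM with a one-read pseudocount
#' in each group (ratio only, never the test).  A gene is significant iff
#' FDR <= `fdr_max` and |log2 ratio| >= `min_abs_log2` (defaults 0.001
#' and 1).
#'
#' @param mat an [expression_matrix()].
#' @param group_a,group_b character vectors of sample names.
#' @param fdr_max,min_abs_log2 significance thresholds.
#' @return data.frame: `gene_id`, `count_a`, `count_b`, `log2_ratio`,
#'   `p_value`, `fdr`, `significant`.
#' @export
call_de <- function(mat, group_a, group_b, fdr_max = 0.001,
                    min_abs_log2 = 1) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (length(group_a) == 0 || length(group_b) == 0)
    stopf("both groups must be non-empty")
  miss <- setdiff(c(group_a, group_b), colnames(mat$counts))
  if (length(miss)) stopf("unknown samples: %s", paste(miss, collapse = ", "))
  ca <- rowSums(mat$counts[, group_a, drop = FALSE])
  cb <- rowSums(mat$counts[, group_b, drop = FALSE])
  la <- sum(mat$lib_size[match(group_a, colnames(mat$counts))])
  lb <- sum(mat$lib_size[match(group_b, colnames(mat$counts))])
  prop <- la / (la + lb)
  p <- vapply(seq_along(ca), function(i) {
    n <- ca[i] + cb[i]
    if (n == 0) return(1)
    binom.test(ca[i], n, p = prop)$p.value
  }, 0)
  fdr <- p.adjust(p, method = "BH")
  r <- rpkm(mat)
  # pseudocount of one read per group, expressed on the RPKM scale
  pc_a <- 1e9 / (la * mat$gene_length)
  pc_b <- 1e9 / (lb * mat$gene_length)
  ra <- rowMeans(r[, group_a, drop = FALSE]) + pc_a
  rb <- rowMeans(r[, group_b, drop = FALSE]) + pc_b
  log2_ratio <- ifelse(ca + cb == 0, 0, log2(ra / rb))
  data.frame(gene_id = rownames(mat$counts), count_a = ca, count_b = cb,
             log2_ratio = log2_ratio, p_value = p, fdr = fdr,
             significant = fdr <= fdr_max & abs(log2_ratio) >= min_abs_log2,
             row.names = NULL)
}

#' Tissue-preferential genes
#'
#' A gene is preferentially expressed in `target_tissue` iff the DE call of
#' target-vs-pooled-others is significant and its mean RPKM is maximal in
#' the target tissue.
#'
#' @param mat an [expression_matrix()] whose `meta` has `sample` and
#'   `tissue` columns (>= 2 tissues).
#' @param target_tissue tissue name.
#' @param fdr_max,min_abs_log2 thresholds passed to [call_de()].
#' @return character vector of gene ids.
#' @export
preferential_genes <- function(mat, target_tissue, fdr_max = 0.001,
                               min_abs_log2 = 1) {
  stopifnot(inherits(mat, "expr_matrix"))
  meta <- mat$meta
  if (is.null(meta) || !all(c("sample", "tissue") %in% names(meta)))
    stopf("sample metadata with 'sample' and 'tissue' is required")
  tissues <- unique(meta$tissue)
  if (length(tissues) < 2) stopf("need >= 2 tissues")
  if (!target_tissue %in% tissues) stopf("unknown tissue '%s'", target_tissue)
  in_t <- meta$sample[meta$tissue == target_tissue]
  out_t <- meta$sample[meta$tissue != target_tissue]
  de <- call_de(mat, in_t, out_t, fdr_max, min_abs_log2)
  up <- de$significant & de$log2_ratio > 0
  r <- rpkm(mat)
  tissue_means <- vapply(tissues, function(tt)
    rowMeans(r[, meta$sample[meta$tissue == tt], drop = FALSE]),
    numeric(nrow(r)))
  is_max <- tissues[max.col(tissue_means, ties.method = "first")] ==
    target_tissue
  rownames(mat$counts)[up & is_max]
}

#' Homoeolog expression bias
#'
#' For each homoeolog pair the two copies' counts across the given samples
#' are compared with the exact binomial DE test (equal library expectation,
#' since both copies come from the same libraries).  `At_biased` iff
#' significant with log2(At/Dt) >= `min_abs_log2`; `Dt_biased`
#' symmetrically; otherwise `balanced`.
#'
#' @param pairs data.frame with `gene_a_id`, `gene_d_id` (see
#'   [bbh_pairs()]).
#' @param mat an [expression_matrix()] quantifying both copies.
#' @param samples samples to pool (default: all).
#' @param fdr_max,min_abs_log2 thresholds as in [call_de()].
#' @return data.frame: `gene_a_id`, `gene_d_id`, `count_a`, `count_d`,
#'   `log2_ratio`, `p_value`, `fdr`, `bias`.  Pairs with a missing member
#'   are skipped with a warning.
#' @export
homoeolog_bias <- function(pairs, mat, samples = NULL, fdr_max = 0.001,
                           min_abs_log2 = 1) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (is.null(samples)) samples <- colnames(mat$counts)
  present <- pairs$gene_a_id %in% rownames(mat$counts) &
    pairs$gene_d_id %in% rownames(mat$counts)
  if (any(!present))
    warning(sprintf("%d pair(s) missing from the matrix; skipped",
                    sum(!present)))
  pairs <- pairs[present, , drop = FALSE]
  ca <- rowSums(mat$counts[pairs$gene_a_id, samples, drop = FALSE])
  cd <- rowSums(mat$counts[pairs$gene_d_id, samples, drop = FALSE])
  len_a <- mat$gene_length[match(pairs$gene_a_id, rownames(mat$counts))]
  len_d <- mat$gene_length[match(pairs$gene_d_id, rownames(mat$counts))]
  p <- vapply(seq_len(nrow(pairs)), function(i) {
    n <- ca[i] + cd[i]
    if (n == 0) return(1)
    binom.test(ca[i], n, p = 0.5)$p.value
  }, 0)
  fdr <- p.adjust(p, method = "BH")
  lib <- sum(mat$lib_size[match(samples, colnames(mat$counts))])
  log2_ratio <- log2(((ca + 1) / len_a) / ((cd + 1) / len_d))
  bias <- ifelse(fdr <= fdr_max & log2_ratio >= min_abs_log2, "At_biased",
          ifelse(fdr <= fdr_max & log2_ratio <= -min_abs_log2, "Dt_biased",
                 "balanced"))
  data.frame(gene_a_id = pairs$gene_a_id, gene_d_id = pairs$gene_d_id,
             count_a = unname(ca), count_d = unname(cd),
             log2_ratio = unname(log2_ratio), p_value = p, fdr = fdr,
             bias = bias, row.names = NULL)
}

#' Expression contrast between LTR-flagged and unflagged genes
#'
#' Compares the mean per-gene RPKM (averaged over samples) of genes with an
#' LTR insertion in their upstream window against the rest, with a seeded
#' label-permutation p-value for the difference.
#'
#' @param mat an [expression_matrix()].
#' @param flags named logical vector over the genes (see
#'   [annotate_ltr_proximity()]).
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return list: `mean_flagged`, `mean_unflagged`, `difference`,
#'   `p_value` (two-sided permutation).
#' @export
ltr_expression_contrast <- function(mat, flags, n_perm = 10000, seed = 1) {
  stopifnot(inherits(mat, "expr_matrix"))
  flags <- flags[rownames(mat$counts)]
  if (any(is.na(flags))) stopf("flags must cover every gene in the matrix")
  if (all(flags) || all(!flags))
    stopf("both strata must be non-empty")
  g_mean <- rowMeans(rpkm(mat))
  obs <- mean(g_mean[flags]) - mean(g_mean[!flags])
  nf <- sum(flags)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(g_mean), nf)
    mean(g_mean[idx]) - mean(g_mean[-idx])
  }, 0))
  list(mean_flagged = mean(g_mean[flags]),
       mean_unflagged = mean(g_mean[!flags]),
       difference = obs,
       p_value = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1))
}
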