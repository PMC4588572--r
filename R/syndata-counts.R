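# Synthetic count matrices with known differential-expression structure.

#' Generate a count matrix with known fold changes
#'
#' Per-gene baseline means are drawn log-uniformly from `base_mean_range`;
#' the first tissue's mean is multiplied by the gene's fold change.  Counts
#' are negative-binomial with the stated means and dispersion (`dispersion
#' = 0` degenerates to Poisson).
#'
#' @param n_genes number of genes.
#' @param tissues tissue names; the first is the "target" tissue whose mean
#'   is scaled by `fold_change`.
#' @param n_rep replicates per tissue.
#' @param fold_change scalar or per-gene vector (>= 0) applied to the first
#'   tissue.
#' @param base_mean_range range of baseline expected counts.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param gene_length_range range of gene lengths in bp.
#' @param seed integer RNG seed.
#' @return list with `mat` (an [expression_matrix()]) and `truth`
#'   (data.frame: `gene_id`, `fold_change`, `de`).
#' @export
gen_counts <- function(n_genes, tissues = c("fiber", "leaf"), n_rep = 3,
                       fold_change = 1, base_mean_range = c(20, 200),
                       dispersion = 0.05,
                       gene_length_range = c(500, 3000), seed = 1) {
  if (any(fold_change < 0)) stopf("fold changes must be >= 0")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  fc <- rep_len(fold_change, n_genes)
  gene_id <- vapply(seq_len(n_genes), function(i) fmt_id("g", i), "")
  samples <- paste0(rep(tissues, each = n_rep), "_r",
                    rep(seq_len(n_rep), length(tissues)))
  tissue_of <- rep(tissues, each = n_rep)
  out <- with_seed(seed, {
    len <- sample(seq(gene_length_range[1], gene_length_range[2]), n_genes,
                  replace = TRUE)
    base <- exp(runif(n_genes, log(base_mean_range[1]),
                      log(base_mean_range[2])))
    counts <- matrix(0L, n_genes, length(samples),
                     dimnames = list(gene_id, samples))
    for (s in seq_along(samples)) {
      mu <- if (tissue_of[s] == tissues[1]) base * fc else base
      counts[, s] <- if (dispersion == 0) rpois(n_genes, mu)
        else rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
    list(counts = counts, len = len)
  })
  meta <- data.frame(sample = samples, tissue = tissue_of)
  list(mat = expression_matrix(out$counts,
                               setNames(out$len, gene_id), meta = meta),
       truth = data.frame(gene_id = gene_id, fold_change = fc,
                          de = fc != 1))
}
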