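# Orchestration: assembly-style summary statistics, configuration, and the
# end-to-end synthetic pipeline run.

#' N50 of a set of sequence lengths
#'
#' The smallest length L such that sequences of length >= L sum to at least
#' half the total.
#'
#' @param lengths positive lengths in bp.
#' @return the N50 in bp.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0 || any(lengths <= 0))
    stopf("lengths must be a non-empty vector of positive sizes")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Summary statistics of a gene model set
#'
#' Arithmetic means (rounded to integer bp) of gene span, CDS, exon and
#' intron sizes, plus counts; introns are the gaps between consecutive
#' exons.
#'
#' @param models list with `genes` and `exons` data.frames (as produced by
#'   [gen_gene_models()]).
#' @return named list of summary statistics.
#' @export
gene_stats <- function(models) {
  genes <- models$genes; exons <- models$exons
  exw <- exons$end - exons$start + 1
  if (any(exw <= 0)) stopf("malformed exons")
  intron_sizes <- numeric(0)
  cds_sizes <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ex <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1) {
      if (any(ex$start[-1] <= ex$end[-nrow(ex)]))
        stopf("overlapping exons in %s", genes$gene_id[i])
      intron_sizes <- c(intron_sizes, ex$start[-1] - ex$end[-nrow(ex)] - 1)
    }
    cds_sizes[i] <- sum(ex$end - ex$start + 1)
  }
  list(gene_count = nrow(genes),
       mean_gene_size = round(mean(genes$end - genes$start + 1)),
       mean_cds_size = round(mean(cds_sizes)),
       mean_exon_size = round(mean(exw)),
       mean_intron_size = if (length(intron_sizes))
         round(mean(intron_sizes)) else 0L,
       exons_per_gene = round(nrow(exons) / nrow(genes), 2),
       max_gene_size = max(genes$end - genes$start + 1),
       intron_count = length(intron_sizes))
}

#' Pipeline configuration with study defaults
#'
#' Every published constant of the cotton analyses is the default here:
#' clock rate r = 2.6e-9, BBH identity/coverage 30%/0.30, DE thresholds
#' FDR <= 0.001 and |log2| >= 1, Ks bin widths 0.001 (orthologs) and 0.01
#' (paralogs), 20-kb LTR window, the 80-80-80 family rule, and the 150-bp /
#' 30-bp pseudogene filters.  Partition thresholds (0.95/0.9/0.02) are
#' package defaults, not printed values.
#'
#' @param ... overrides of the defaults.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    outdir = NULL,
    stages = c("simulate", "homoeolog", "kaks", "ltr", "pseudo", "expr"),
    # printed study constants
    clock_rate = 2.6e-9,
    bbh_min_identity_pct = 30, bbh_min_cov = 0.30, e_max = 1e-3,
    fdr_max = 0.001, min_abs_log2 = 1,
    ks_bin_ortholog = 0.001, ks_bin_paralog = 0.01,
    ltr_window = 20000,
    fam_identity_pct = 80, fam_len_frac = 0.8, fam_aln_len = 80,
    pseudo_min_len = 150, pseudo_max_overlap = 30, junction_gap = 30,
    burst_prominence = 0.25,
    # package defaults (configuration, not printed values)
    part_min_identity = 0.95, part_min_cov = 0.9, part_delta = 0.02,
    # synthetic sizes for the packaged run
    n_genes = 40, n_codons = 300, ks_ad = 0.04, ks_species = 0.005,
    omega = 0.2,
    n_ltr = 40, ltr_len = 400, ltr_ages = c(1e6, 5e6), ltr_bin_years = 1e6,
    n_pseudo = 18, pseudo_ks = 0.08,
    n_expr_genes = 300, expr_fold = 4, expr_frac_de = 0.1)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stopf("unknown config entries: %s",
                         paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Serialize / parse a configuration as key=value text
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  ser <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, "=", if (is.null(v)) "" else paste(v, collapse = ","))
  }, "")
  writeLines(ser, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  base <- pipeline_config()
  cfg <- base
  char_keys <- c("outdir", "stages")
  for (p in kv) {
    k <- p[1]; v <- p[2]
    if (!k %in% names(base)) stopf("unknown config key '%s'", k)
    parts <- if (nzchar(v)) strsplit(v, ",", fixed = TRUE)[[1]]
      else character(0)
    cfg[k] <- list(
      if (length(parts) == 0) NULL
      else if (k %in% char_keys) parts
      else as.numeric(parts))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the enabled stages in dependency order on generated data,
#' writing each stage's tables as TSV under `config$outdir`, and returns a
#' run report.  Reruns with the same seed are byte-identical.
#'
#' @param config a [pipeline_config()] with a non-NULL `outdir`.
#' @return a list of class `run_report`: per-stage record counts, the
#'   parameter echo, output file list and elapsed time.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$outdir)) stopf("config$outdir is required")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stages <- config$stages
  need <- function(stage, dep) {
    if (!dep %in% stages)
      stopf("stage '%s' requires stage '%s', which is disabled", stage, dep)
  }
  counts <- list(); files <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$outdir, name)
    write_tsv(df, p)
    files <<- c(files, p)
    nrow(df)
  }
  sim <- NULL
  if ("simulate" %in% stages) {
    sim <- list()
    sim$poly <- gen_allopolyploid(
      divergence_schedule(AD = config$ks_ad, GbGh = config$ks_species),
      n_genes = config$n_genes, n_codons = config$n_codons,
      omega = config$omega, seed = config$seed)
    sim$ltr <- gen_ltr_elements(
      config$n_ltr,
      data.frame(age_years = config$ltr_ages,
                 weight = rep(1, length(config$ltr_ages))),
      r = config$clock_rate, ltr_len = config$ltr_len,
      seed = sub_seed(config$seed, "ltr"))
    sim$models <- gen_gene_models(12, seed = sub_seed(config$seed, "models"))
    sim$pseudo <- gen_pseudogenes(sim$models, config$n_pseudo,
                                  ks = config$pseudo_ks,
                                  seed = sub_seed(config$seed, "pseudo"))
    fc <- rep(1, config$n_expr_genes)
    fc[seq_len(round(config$expr_frac_de * config$n_expr_genes))] <-
      config$expr_fold
    sim$expr <- gen_counts(config$n_expr_genes, fold_change = fc,
                           seed = sub_seed(config$seed, "expr"))
    write_fasta(sim$poly$sets$At, file.path(config$outdir, "At_cds.fasta"))
    write_fasta(sim$poly$sets$Dt, file.path(config$outdir, "Dt_cds.fasta"))
    files <- c(files, file.path(config$outdir,
                                c("At_cds.fasta", "Dt_cds.fasta")))
    counts$simulate <- emit(sim$poly$truth, "homoeolog_truth.tsv")
  }
  if ("homoeolog" %in% stages) {
    need("homoeolog", "simulate")
    prot <- function(s) {
      p <- vapply(as_seq_chr(s), function(x) translate_cds(prep_cds(x)), "")
      names(p) <- names(s); p
    }
    pairs <- bbh_pairs(prot(sim$poly$sets$At), prot(sim$poly$sets$Dt),
                       min_identity_pct = config$bbh_min_identity_pct,
                       min_cov = config$bbh_min_cov, e_max = config$e_max)
    sim$pairs <- pairs
    counts$homoeolog <- emit(pairs, "homoeolog_pairs.tsv")
  }
  if ("kaks" %in% stages) {
    need("kaks", "homoeolog")
    at <- as_seq_chr(sim$poly$sets$At); dt <- as_seq_chr(sim$poly$sets$Dt)
    est <- lapply(seq_len(nrow(sim$pairs)), function(i) {
      e <- ng86(as_codon_alignment(at[[sim$pairs$gene_a_id[i]]],
                                   dt[[sim$pairs$gene_d_id[i]]],
                                   ids = c(sim$pairs$gene_a_id[i],
                                           sim$pairs$gene_d_id[i])))
      data.frame(gene_a_id = e$ids[1], gene_d_id = e$ids[2], N = e$N,
                 S = e$S, Nd = e$Nd, Sd = e$Sd, Ka = e$Ka, Ks = e$Ks,
                 omega = e$omega, saturated = e$saturated)
    })
    est <- do.call(rbind, est)
    counts$kaks <- emit(est, "kaks.tsv")
    h <- ks_histogram(est$Ks, config$ks_bin_ortholog)
    emit(as.data.frame(h), "ks_histogram.tsv")
  }
  if ("ltr" %in% stages) {
    need("ltr", "simulate")
    ages <- ltr_ages(sim$ltr, r = config$clock_rate)
    fams <- cluster_families_808080(
      sim$ltr$left, min_identity_pct = config$fam_identity_pct,
      min_len_frac = config$fam_len_frac,
      min_aln_len = config$fam_aln_len)
    counts$ltr <- emit(merge(ages, fams, by = "element_id"), "ltr.tsv")
  }
  if ("pseudo" %in% stages) {
    need("pseudo", "simulate")
    cands <- detect_pseudogenes(sim$pseudo$intergenic, sim$models$cds)
    if (nrow(cands)) {
      cands$category <- vapply(seq_len(nrow(cands)), function(i) {
        exseq <- exon_cds_segments(sim$models, cands$parent_gene_id[i])
        as.character(classify_pseudogene(
          as_seq_chr(sim$pseudo$intergenic)[[cands$region_id[i]]], exseq,
          junction_gap = config$junction_gap))
      }, "")
    }
    counts$pseudo <- emit(cands, "pseudogenes.tsv")
  }
  if ("expr" %in% stages) {
    need("expr", "simulate")
    de <- call_de(sim$expr$mat,
                  grep("^fiber", colnames(sim$expr$mat$counts),
                       value = TRUE),
                  grep("^leaf", colnames(sim$expr$mat$counts),
                       value = TRUE),
                  fdr_max = config$fdr_max,
                  min_abs_log2 = config$min_abs_log2)
    counts$expr <- emit(de, "de_calls.tsv")
  }
  structure(list(counts = counts, files = files, config = config,
                 seed = config$seed,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  for (s in names(x$counts))
    cat(sprintf("  %-10s %d records\n", s, x$counts[[s]]))
  cat(sprintf("  %d files in %s (%.1f s)\n", length(x$files),
              x$config$outdir, x$elapsed_s))
  invisible(x)
}

# exon CDS segments of a parent gene, in order
exon_cds_segments <- function(models, gene_id) {
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  ex <- ex[order(ex$exon_rank), , drop = FALSE]
  cds <- as_seq_chr(models$cds)[[gene_id]]
  w <- ex$end - ex$start + 1
  ends <- cumsum(w); starts <- c(1, head(ends, -1) + 1)
  substring(cds, starts, ends)
}
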