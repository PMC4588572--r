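# Pseudogene detection, classification, filtering, divergence to parent.

test_that("an inserted disabled gene copy is detected with its stop", {
  set.seed(61)
  models <- gen_gene_models(6, n_exons_range = c(2, 3), seed = 61)
  ps <- gen_pseudogenes(models, 4, mix = c(processed = 1), ks = 0.02,
                        seed = 62)
  cands <- detect_pseudogenes(ps$intergenic, models$cds)
  expect_equal(nrow(cands), 4)
  expect_equal(cands$parent_gene_id,
               ps$truth$parent_gene_id[match(cands$region_id,
                                             ps$truth$region_id)])
  has_stop <- grepl("premature_stop", ps$truth$disablements)
  expect_true(all(cands$n_stop[has_stop[match(cands$region_id,
                                              ps$truth$region_id)]] >= 1))
  # empty intergenic space
  empty <- detect_pseudogenes(Biostrings::DNAStringSet(), models$cds)
  expect_equal(nrow(empty), 0)
})

test_that("the three categories are classified by their construction", {
  models <- gen_gene_models(8, n_exons_range = c(2, 4), seed = 63)
  ps <- gen_pseudogenes(models, 18, ks = 0.05, seed = 64)
  correct <- 0
  for (i in seq_len(18)) {
    tr <- ps$truth[i, ]
    got <- classify_pseudogene(
      as.character(ps$intergenic)[[tr$region_id]],
      allodiv:::exon_cds_segments(models, tr$parent_gene_id))
    if (as.character(got) == tr$category) correct <- correct + 1
  }
  expect_gte(correct, 17)  # construction matches the decision rules
})

test_that("categories are exhaustive and mutually exclusive", {
  models <- gen_gene_models(5, n_exons_range = c(2, 3), seed = 65)
  ps <- gen_pseudogenes(models, 9, ks = 0.05, seed = 66)
  cats <- vapply(seq_len(9), function(i) {
    tr <- ps$truth[i, ]
    as.character(classify_pseudogene(
      as.character(ps$intergenic)[[tr$region_id]],
      allodiv:::exon_cds_segments(models, tr$parent_gene_id)))
  }, "")
  expect_true(all(cats %in% c("processed", "duplicated", "fragmented")))
  expect_error(classify_pseudogene("ACGT", character(0)), "exon")
})

test_that("exclusion filters drop exactly the violating candidates", {
  cands <- data.frame(
    region_id = paste0("c", 1:5), chrom = "chr1",
    start = c(1000, 5000, 9000, 13000, 20000),
    end = c(1119, 5149, 9500, 13600, 20800),   # c1 is 120 bp, c2 is 150 bp
    parent_gene_id = c("pg1", "pg2", "pg3", "pg4", "pg5"))
  genes <- data.frame(chrom = "chr1", start = 13550, end = 14000)
  labels <- c(pg3 = "TE", pg1 = "nuclear")
  out <- filter_pseudogenes(cands, genes, labels)
  # c1: 120 bp (dropped); c2: exactly 150 bp (kept, strict <);
  # c3: TE parent (dropped); c4: 51 bp gene overlap (dropped); c5: kept
  expect_setequal(out$region_id, c("c2", "c5"))
  # a 30 bp overlap is tolerated ("significant" means > 30 bp)
  genes30 <- data.frame(chrom = "chr1", start = 13571, end = 14000)
  out30 <- filter_pseudogenes(cands[4, ], genes30, labels)
  expect_equal(nrow(out30), 1)
})

test_that("the exclusion rules commute", {
  set.seed(67)
  cands <- data.frame(
    region_id = paste0("c", 1:12), chrom = "chr1",
    start = seq(1000, by = 4000, length.out = 12),
    end = seq(1000, by = 4000, length.out = 12) +
      sample(c(100, 200, 400), 12, replace = TRUE),
    parent_gene_id = sample(c("p1", "p2", "p3"), 12, replace = TRUE))
  genes <- data.frame(chrom = "chr1", start = c(5000, 21000),
                      end = c(5300, 21300))
  labels <- c(p2 = "TE")
  full <- filter_pseudogenes(cands, genes, labels)
  step1 <- filter_pseudogenes(cands, genes = NULL, parent_labels = NULL)
  step2 <- filter_pseudogenes(step1, genes = NULL, parent_labels = labels,
                              min_len = 0)
  step3 <- filter_pseudogenes(step2, genes = genes, parent_labels = NULL,
                              min_len = 0)
  expect_setequal(full$region_id, step3$region_id)
})

test_that("ks_to_parent is near zero for fresh copies and unbiased at
          moderate divergence", {
  models <- gen_gene_models(6, n_exons_range = c(2, 3), seed = 68)
  fresh <- gen_pseudogenes(models, 3, mix = c(processed = 1), ks = 0,
                           seed = 69)
  for (i in 1:3) {
    tr <- fresh$truth[i, ]
    e <- ks_to_parent(as.character(fresh$intergenic)[[tr$region_id]],
                      as.character(models$cds)[[tr$parent_gene_id]])
    expect_lt(e$Ks, 0.005)
  }
  div <- gen_pseudogenes(models, 30, mix = c(processed = 1), ks = 0.08,
                         seed = 70)
  ks <- vapply(1:30, function(i) {
    tr <- div$truth[i, ]
    ks_to_parent(as.character(div$intergenic)[[tr$region_id]],
                 as.character(models$cds)[[tr$parent_gene_id]])$Ks
  }, 0)
  expect_lt(abs(mean(ks) - 0.08), 3 * sd(ks) / sqrt(30))
  # unalignable input errors with its own condition class
  expect_error(ks_to_parent(paste(rep("ACGT", 100), collapse = ""),
                            as.character(models$cds)[[1]]),
               class = "allodiv_unalignable")
})

test_that("pseudogene Ks distribution shows a 0.06-0.1 style peak", {
  # 300 neutral copies of 800-codon parents; the modal 0.001 bin of the
  # Ks-to-parent histogram must fall in the printed 0.06-0.1 band
  models <- gen_gene_models(10, n_exons_range = c(2, 3),
                            exon_codons_range = c(260, 270), seed = 71)
  ps <- gen_pseudogenes(models, 300, mix = c(processed = 1), ks = 0.08,
                        flank_len = 250, seed = 72)
  ks <- vapply(seq_len(300), function(i) {
    tr <- ps$truth[i, ]
    ks_to_parent(as.character(ps$intergenic)[[tr$region_id]],
                 as.character(models$cds)[[tr$parent_gene_id]])$Ks
  }, 0)
  pk <- find_peak(ks_histogram(ks, 0.001))
  expect_gte(pk, 0.06)
  expect_lte(pk, 0.10)
  expect_lt(abs(mean(ks) - 0.08), 0.01)
})

test_that("pseudogenes evolve with weaker constraint than genes", {
  # directional property: mean Ka/Ks of neutral pseudogene copies exceeds
  # that of constraint-evolved gene pairs
  models <- gen_gene_models(6, n_exons_range = c(2, 3), seed = 73)
  ps <- gen_pseudogenes(models, 15, mix = c(processed = 1), ks = 0.08,
                        seed = 74)
  om_ps <- vapply(1:15, function(i) {
    tr <- ps$truth[i, ]
    ks_to_parent(as.character(ps$intergenic)[[tr$region_id]],
                 as.character(models$cds)[[tr$parent_gene_id]])$omega
  }, 0)
  sim <- gen_allopolyploid(divergence_schedule(AD = 0.08, GbGh = NULL),
                           n_genes = 15, n_codons = 500, omega = 0.2,
                           seed = 75)
  at <- as.character(sim$sets$At); dt <- as.character(sim$sets$Dt)
  om_g <- vapply(1:15, function(i)
    ng86(as_codon_alignment(at[i], dt[i]))$omega, 0)
  expect_gt(mean(om_ps, na.rm = TRUE), mean(om_g, na.rm = TRUE))
})
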