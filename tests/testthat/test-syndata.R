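# Synthetic-data generators: determinism, postconditions, and statistical
# recovery of the parameters they were given.

test_that("gen_ancestral_cds satisfies its postconditions", {
  s <- gen_ancestral_cds(1, 2, seed = 7)
  expect_equal(Biostrings::width(s), 6)
  expect_equal(substr(as.character(s)[[1]], 1, 3), "ATG")
  expect_false(substr(as.character(s)[[1]], 4, 6) %in%
                 c("TAA", "TAG", "TGA"))

  a <- gen_ancestral_cds(50, 100, seed = 1)
  b <- gen_ancestral_cds(50, 100, seed = 1)
  expect_identical(as.character(a), as.character(b))
  c2 <- gen_ancestral_cds(50, 100, seed = 2)
  expect_false(identical(as.character(a), as.character(c2)))
  for (s in as.character(a)[1:5]) {
    cods <- split_codons(s)
    expect_false(any(cods[-1] %in% c("TAA", "TAG", "TGA")))
  }
  expect_error(gen_ancestral_cds(5, 1), "n_codons")
})

test_that("evolve_sequence: zero branch, kappa limit, parameter checks", {
  s <- "ACGTACGTACGTACGT"
  expect_equal(as.character(evolve_sequence(s, evolve_params(0))), s)
  expect_error(evolve_params(-0.1), "d_target")
  expect_error(evolve_params(0.1, kappa = 0), "kappa")
  # kappa -> infinity: transversions vanish
  set.seed(3)
  long <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                collapse = "")
  mut <- evolve_sequence(long, evolve_params(0.1, kappa = 1e6))
  expect_equal(unname(attr(mut, "events")["transversions"]), 0)
  expect_gt(unname(attr(mut, "events")["transitions"]), 0)
})

test_that("K2P estimates recover the simulated branch length", {
  # 200 replicates at d = 0.1 over 10-kb sequences: the mean K2P estimate
  # must sit within 3 standard errors of the truth
  set.seed(13)
  anc <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
               collapse = "")
  ests <- vapply(1:200, function(i) {
    mut <- evolve_sequence(anc, evolve_params(0.1))
    as.numeric(k2p_distance(anc, mut))
  }, 0)
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.1), 3 * se)
})

test_that("realized substitution proportion converges to d_target", {
  set.seed(14)
  anc <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
               collapse = "")
  d <- 0.05
  mut <- evolve_sequence(anc, evolve_params(d))
  p_obs <- mean(strsplit(anc, "")[[1]] != strsplit(mut, "")[[1]])
  p_exp <- allodiv:::k80_mismatch(d, 2)
  se <- sqrt(p_exp * (1 - p_exp) / 1e5)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("gen_allopolyploid hits its Ks targets in expectation", {
  sim <- gen_allopolyploid(divergence_schedule(AD = 0.04, GbGh = 0.005),
                           n_genes = 40, n_codons = 2000, seed = 15)
  at <- as.character(sim$sets$At); dt <- as.character(sim$sets$Dt)
  gh <- as.character(sim$sets$GhAt)
  ks_ad <- vapply(1:40, function(i)
    ng86(as_codon_alignment(at[i], dt[i]))$Ks, 0)
  ks_sp <- vapply(1:40, function(i)
    ng86(as_codon_alignment(at[i], gh[i]))$Ks, 0)
  expect_lt(abs(mean(ks_ad) - 0.04), 3 * sd(ks_ad) / sqrt(40))
  expect_lt(abs(mean(ks_sp) - 0.005), 3 * sd(ks_sp) / sqrt(40))
  # truth bookkeeping
  expect_equal(nrow(sim$truth), 40)
  expect_equal(sim$truth$gene_a_id, names(at))
  # empty case
  empty <- gen_allopolyploid(divergence_schedule(), 0)
  expect_equal(length(empty$sets$At), 0)
  expect_equal(nrow(empty$truth), 0)
  expect_error(divergence_schedule(AD = 0.004, GbGh = 0.005), "younger")
})

test_that("gen_allopolyploid is deterministic for a fixed seed", {
  a <- gen_allopolyploid(divergence_schedule(), 5, n_codons = 100, seed = 5)
  b <- gen_allopolyploid(divergence_schedule(), 5, n_codons = 100, seed = 5)
  expect_identical(as.character(a$sets$At), as.character(b$sets$At))
  expect_identical(as.character(a$sets$Dt), as.character(b$sets$Dt))
})

test_that("gen_ltr_elements: age zero gives identical repeats; distances
          scale as 2 r age", {
  z <- gen_ltr_elements(5, data.frame(age_years = 0, weight = 1), seed = 2)
  expect_identical(as.character(z$left), as.character(z$right))

  el <- gen_ltr_elements(60, data.frame(age_years = 5e6, weight = 1),
                         ltr_len = 2000, seed = 3)
  k <- vapply(1:60, function(i)
    as.numeric(k2p_distance(as.character(el$left)[i],
                            as.character(el$right)[i])), 0)
  expect_lt(abs(mean(k) - 2 * 2.6e-9 * 5e6), 3 * sd(k) / sqrt(60))
  expect_error(gen_ltr_elements(5, data.frame(age_years = 1e6, weight = 1),
                                ltr_len = 30), "ltr_len")
  expect_error(gen_ltr_elements(5, data.frame(age_years = -1, weight = 1)),
               "ages")
})

test_that("gen_pseudogenes constructs categories as specified", {
  models <- gen_gene_models(10, n_exons_range = c(2, 4), seed = 21)
  # processed at zero divergence: locus contains the concatenated exons with
  # only the injected disablement(s)
  pr <- gen_pseudogenes(models, 6, mix = c(processed = 1), ks = 0,
                        seed = 22)
  expect_true(all(pr$truth$category == "processed"))
  for (i in 1:6) {
    tr <- pr$truth[i, ]
    ps <- substr(as.character(pr$intergenic)[[tr$region_id]],
                 tr$insert_start, tr$insert_end)
    cds <- as.character(models$cds)[[tr$parent_gene_id]]
    # at ks = 0 the copy differs from the mRNA only by its disablements
    d <- adist(ps, cds)
    expect_lte(as.integer(d), 4)
  }
  fr <- gen_pseudogenes(models, 6, mix = c(fragmented = 1), ks = 0,
                        seed = 23)
  for (i in 1:6) {
    tr <- fr$truth[i, ]
    plen <- tr$insert_end - tr$insert_start + 1
    expect_lt(plen / nchar(as.character(models$cds)[[tr$parent_gene_id]]),
              0.70)
  }
  # every copy carries at least one disablement
  all3 <- gen_pseudogenes(models, 12, seed = 24)
  expect_true(all(nchar(all3$truth$disablements) > 0))
  single <- gen_gene_models(3, n_exons_range = c(1, 1), seed = 25)
  expect_error(gen_pseudogenes(single, 3, mix = c(processed = 1)),
               "exons")
})

test_that("gen_reads samples faithfully and validates its inputs", {
  set.seed(31)
  ga <- Biostrings::DNAStringSet(c(a1 = paste(
    sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")))
  gd <- Biostrings::DNAStringSet(c(d1 = paste(
    sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")))
  rd <- gen_reads(ga, gd, read_len = 100, n_reads = 50, err = 0, seed = 4)
  for (i in 1:10) {
    src <- if (rd$truth$origin[i] == "A") as.character(ga)[[1]]
      else as.character(gd)[[1]]
    expect_equal(as.character(rd$reads)[[i]],
                 substr(src, rd$truth$pos[i], rd$truth$pos[i] + 99))
  }
  expect_equal(nrow(gen_reads(ga, gd, n_reads = 0)$truth), 0)
  expect_error(gen_reads(ga, gd, err = 0.5), "err")
  expect_error(gen_reads(ga, gd, read_len = 5000), "read_len")
})

test_that("gen_counts: dispersion zero degenerates to Poisson", {
  g <- gen_counts(2000, tissues = c("a", "b"), n_rep = 10,
                  fold_change = 1, base_mean_range = c(100, 100),
                  dispersion = 0, seed = 6)
  v <- apply(g$mat$counts, 1, var)
  m <- rowMeans(g$mat$counts)
  # variance/mean ratio concentrates near 1 for Poisson
  expect_lt(abs(mean(v / m) - 1), 0.05)
  expect_error(gen_counts(10, fold_change = -1), "fold")
})

test_that("generated FASTA round-trips through the package readers", {
  s <- gen_ancestral_cds(5, 80, seed = 8)
  p <- tempfile(fileext = ".fasta")
  write_fasta(s, p)
  back <- read_fasta(p)
  expect_identical(as.character(back), as.character(s))
  unlink(p)
})
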