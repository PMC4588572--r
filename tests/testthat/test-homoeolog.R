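# BBH homoeolog identification, unique genes, and subgenome partitioning.

test_that("identical gene sets pair one-to-one under BBH", {
  set.seed(51)
  prots <- setNames(vapply(1:3, function(i) paste(
    sample(rownames(allodiv:::blosum62())[1:20], 120, replace = TRUE),
    collapse = ""), ""), c("gA", "gB", "gC"))
  pairs <- bbh_pairs(prots, setNames(prots, c("hA", "hB", "hC")))
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$gene_d_id[match(c("gA", "gB", "gC"),
                                     pairs$gene_a_id)],
               c("hA", "hB", "hC"))
  expect_true(all(pairs$identity_pct == 100))
})

test_that("a one-sided best hit never forms a pair", {
  set.seed(52)
  base <- paste(sample(rownames(allodiv:::blosum62())[1:20], 150,
                       replace = TRUE), collapse = "")
  variant <- base
  substr(variant, 1, 8) <- "WWWWWWWW"   # slightly worse match to d
  # a and a2 both hit d; d's best is a (exact copy), so (a2, d) must not pair
  pairs <- bbh_pairs(c(a = base, a2 = variant), c(d = base))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$gene_a_id, "a")
  expect_false("a2" %in% pairs$gene_a_id)
})

test_that("BBH is symmetric under swapping the input sets", {
  sim <- gen_allopolyploid(divergence_schedule(AD = 0.04, GbGh = NULL),
                           n_genes = 20, n_codons = 300, omega = 0.2,
                           seed = 53)
  pa <- prot_set(sim$sets$At); pd <- prot_set(sim$sets$Dt)
  fwd <- bbh_pairs(pa, pd)
  swp <- bbh_pairs(pd, pa)
  expect_setequal(paste(fwd$gene_a_id, fwd$gene_d_id),
                  paste(swp$gene_d_id, swp$gene_a_id))
  # truth recovery at this scale is complete
  expect_equal(nrow(fwd), 20)
  expect_true(all(fwd$gene_d_id ==
                    sub("^At", "Dt", fwd$gene_a_id)))
  expect_true(all(fwd$identity_pct > 30 & fwd$q_coverage > 0.30))
})

test_that("unique_genes applies both clauses with a strict 1/3 boundary", {
  set.seed(54)
  cds <- setNames(vapply(1:2, function(i) rand_cds(120), ""),
                  c("u1", "u2"))
  prots <- prot_set(cds)
  # u1 has an identical protein in the other set -> not unique
  prots_y <- c(y1 = prots[["u1"]])
  L <- nchar(cds[["u1"]])
  # genome carrying exactly one third of u2's CDS: HSP length == L/3,
  # which fails the strict < rule, so u2 is not unique either
  genome_third <- c(chr1 = substr(cds[["u2"]], 1, L / 3))
  u <- unique_genes(prots, prots_y, genome_third, cds)
  expect_false("u1" %in% u)
  expect_false("u2" %in% u)
  # a genome with less than one third -> u2 becomes unique
  genome_less <- c(chr1 = substr(cds[["u2"]], 1, L / 3 - 6))
  u2 <- unique_genes(prots, prots_y, genome_less, cds)
  expect_true("u2" %in% u2)
  expect_false("u1" %in% u2)
  expect_error(unique_genes(prots, prots_y, genome_third,
                            cds[1]), "missing CDS")
})

test_that("partition labels constructed reads correctly", {
  set.seed(55)
  shared <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  a_only <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  ref_a <- c(ra = paste0(shared, a_only))
  ref_d <- c(rd = shared)
  reads <- c(r_a = substr(a_only, 50, 149),   # A-specific segment
             r_sh = substr(shared, 50, 149))  # identical in both
  pl <- partition_sequences(reads, ref_a, ref_d)
  expect_equal(pl$label[pl$sequence_id == "r_a"], "A_unique")
  expect_equal(pl$label[pl$sequence_id == "r_sh"], "shared")
  expect_error(partition_sequences(reads, ref_a, ref_d, delta = -1),
               "delta")
})

test_that("reads from diverged references are assigned to their genome", {
  set.seed(56)
  anc <- vapply(1:6, function(i) paste(
    sample(c("A", "C", "G", "T"), 1500, replace = TRUE), collapse = ""), "")
  # neutral 4% divergence between the two references (genome-wide scale)
  ref_a <- setNames(vapply(anc, function(s)
    as.character(evolve_sequence(s, evolve_params(0.02))), ""),
    paste0("a", 1:6))
  ref_d <- setNames(vapply(anc, function(s)
    as.character(evolve_sequence(s, evolve_params(0.02))), ""),
    paste0("d", 1:6))
  rd <- gen_reads(Biostrings::DNAStringSet(ref_a),
                  Biostrings::DNAStringSet(ref_d),
                  read_len = 100, n_reads = 120, err = 0.01, seed = 57)
  pl <- partition_sequences(rd$reads, ref_a, ref_d)
  correct <- (rd$truth$origin == "A" & pl$label == "A_unique") |
    (rd$truth$origin == "D" & pl$label == "D_unique")
  expect_gte(mean(correct), 0.90)
  # labels partition the set
  expect_true(all(pl$label %in% c("A_unique", "D_unique", "shared",
                                  "none")))
})

test_that("raising min_identity never promotes a sequence to unique", {
  set.seed(58)
  anc <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
               collapse = "")
  ref_a <- c(a = as.character(evolve_sequence(anc, evolve_params(0.02))))
  ref_d <- c(d = as.character(evolve_sequence(anc, evolve_params(0.02))))
  rd <- gen_reads(Biostrings::DNAStringSet(ref_a),
                  Biostrings::DNAStringSet(ref_d),
                  read_len = 100, n_reads = 40, err = 0.02, seed = 59)
  lo <- partition_sequences(rd$reads, ref_a, ref_d, min_identity = 0.90)
  hi <- partition_sequences(rd$reads, ref_a, ref_d, min_identity = 0.98)
  was_soft <- lo$label %in% c("none", "shared")
  expect_false(any(was_soft &
                     hi$label %in% c("A_unique", "D_unique")))
})
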