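# Ka/Ks estimation, K2P distances, histograms and clock dating.

test_that("ng86 reproduces hand-computed site and difference counts", {
  e <- ng86(as_codon_alignment("GTTGCT", "GTCGCT"))
  expect_equal(e$N, 4)
  expect_equal(e$S, 2)
  expect_equal(e$Nd, 0)
  expect_equal(e$Sd, 1)
  expect_equal(e$pS, 0.5)
  expect_equal(round(e$Ks, 4), 0.8240)
  expect_equal(e$Ka, 0)
  expect_false(e$saturated)

  ident <- ng86(as_codon_alignment("ATGGTT", "ATGGTT"))
  expect_equal(ident$Ka, 0)
  expect_equal(ident$Ks, 0)
  expect_equal(ident$Nd + ident$Sd, 0)
})

test_that("ng86 flags degenerate proportions as saturated", {
  e <- ng86(as_codon_alignment("TTT", "TTC"))
  expect_equal(e$S, 1 / 3)
  expect_equal(e$Sd, 1)
  expect_equal(e$pS, 3)
  expect_true(e$saturated)
  expect_true(is.na(e$Ks))
})

test_that("ng86 counts agree with the pathway-enumeration oracle", {
  set.seed(41)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  for (rep in 1:40) {
    nc <- sample(1:4, 1)
    c1 <- sample(sense, nc, replace = TRUE)
    c2 <- sample(sense, nc, replace = TRUE)
    e <- ng86(as_codon_alignment(paste(c1, collapse = ""),
                                 paste(c2, collapse = "")))
    o <- oracle_ng86_counts(c1, c2)
    expect_equal(e$S, o$S, tolerance = 1e-12)
    expect_equal(e$N, o$N, tolerance = 1e-12)
    expect_equal(e$Sd, o$Sd, tolerance = 1e-12)
    expect_equal(e$Nd, o$Nd, tolerance = 1e-12)
  }
})

test_that("ng86 is symmetric and zero iff sequences identical", {
  set.seed(42)
  for (rep in 1:10) {
    a <- rand_cds(30); b <- rand_cds(30)
    e1 <- ng86(as_codon_alignment(a, b))
    e2 <- ng86(as_codon_alignment(b, a))
    expect_equal(e1$Ks, e2$Ks)
    expect_equal(e1$Ka, e2$Ka)
    expect_equal(e1$S, e2$S)
    if (!e1$saturated && identical(a, b) == FALSE)
      expect_gt(e1$Nd + e1$Sd, 0)
  }
})

test_that("codon_align produces whole-codon gaps", {
  a <- "ATGGTTGCTAAA"
  aln <- codon_align(a, a)
  expect_false(grepl("-", aln$aln1, fixed = TRUE))
  # delete one codon from the middle
  b <- paste0(substr(a, 1, 6), substr(a, 10, 12))
  aln2 <- codon_align(a, b)
  expect_equal(nchar(aln2$aln2), 12)
  gaps <- gregexpr("-+", aln2$aln2)[[1]]
  expect_equal(attr(gaps, "match.length"), 3L)
  expect_error(codon_align("ACGTA", a), "multiple of 3")
  expect_error(codon_align("ATGTAAAAA", a), "stop")
})

test_that("k2p_distance matches the closed form and flags saturation", {
  # 20 sites: 2 transitions, 1 transversion -> P = 0.1, Q = 0.05
  a <- "AAAAAAAAAACCCCCCCCCC"
  b <- "GGAAAAAAAAACCCCCCCCC"  # two A>G transitions, one C>A transversion
  K <- k2p_distance(a, b)
  expect_equal(attr(K, "P"), 0.1)
  expect_equal(attr(K, "Q"), 0.05)
  expect_equal(as.numeric(K), -0.5 * log((1 - 0.25) * sqrt(1 - 0.1)))
  expect_equal(round(as.numeric(K), 4), 0.1702)

  expect_equal(as.numeric(k2p_distance("ACGT", "ACGT")), 0)
  # P = 0.5, Q = 0 -> log of zero
  expect_error(k2p_distance("AAAA", "GGAA"), class = "allodiv_saturated")
})

test_that("k2p agrees with ape and dominates the p-distance", {
  set.seed(7)
  for (rep in 1:5) {
    anc <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
    mut <- as.character(evolve_sequence(anc, evolve_params(0.15)))
    K <- k2p_distance(anc, mut)
    m <- rbind(strsplit(tolower(anc), "")[[1]],
               strsplit(tolower(mut), "")[[1]])
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
    expect_equal(as.numeric(K), ref, tolerance = 1e-8)
    p <- mean(strsplit(anc, "")[[1]] != strsplit(mut, "")[[1]])
    expect_gte(as.numeric(K), p)
  }
})

test_that("ks_histogram bins left-closed from zero and excludes NAs", {
  h <- ks_histogram(c(0.0104, 0.0106), 0.001)
  expect_equal(h$count[h$bin_left == 0.010], 2)
  h2 <- ks_histogram(c(0.011), 0.001)
  expect_equal(h2$count[round(h2$bin_left, 10) == 0.011], 1)
  h3 <- ks_histogram(c(0.5, NA, Inf, 0.25), 0.01)
  expect_equal(attr(h3, "n"), 2)
  expect_equal(attr(h3, "n_excluded"), 2)
  expect_warning(ks_histogram(c(NA_real_, Inf), 0.01), "empty")
  expect_error(ks_histogram(c(0.1), 0), "bin_width")
})

test_that("find_peak picks the modal bin, ties toward smaller Ks", {
  h <- ks_histogram(c(rep(0.0005, 5), rep(0.0015, 9)), 0.001)
  expect_equal(find_peak(h), 0.0015)
  tie <- ks_histogram(c(rep(0.0005, 5), rep(0.0015, 5)), 0.001)
  expect_equal(find_peak(tie), 0.0005)
  empty <- suppressWarnings(ks_histogram(numeric(0), 0.001))
  expect_error(find_peak(empty), "empty")
})

test_that("clock dating is linear and reproduces the printed dates", {
  expect_equal(clock_convert(0), 0)
  expect_equal(clock_convert(0.005), 0.005 / (2 * 2.6e-9))
  expect_equal(round(clock_convert(0.005) / 1e6, 2), 0.96)  # ~1 Mya
  expect_equal(round(clock_convert(0.04) / 1e6, 2), 7.69)   # ~8 Mya
  a <- runif(5)
  expect_equal(clock_convert(3 * a), 3 * clock_convert(a))
  expect_error(clock_convert(-0.1), ">= 0")
  expect_error(clock_convert(0.1, r = 0), "> 0")
})
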